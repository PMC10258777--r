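# Layered target-decoy FDR control: decoy-anchored score mixture model,
# target-decoy q-values, the group-specific PSM filter (separate score
# thresholds for glycosylated and non-glycosylated PSMs), peptide- and
# protein-level filters, sequential protein filtering, and entrapment audit.

#' Fit a two-component score mixture
#'
#' Semi-parametric mixture on target scores: the negative component is a
#' kernel density estimate anchored on decoy scores (Silverman bandwidth);
#' the positive component is a Gaussian fitted by EM together with the
#' mixing proportion. The returned posterior is clipped monotone
#' non-decreasing in the score.
#'
#' @param target_scores,decoy_scores Numeric vectors (>= 100 each).
#' @param max_iter,tol EM controls.
#' @return List of class `score_mixture` with `pi`, `mu`, `sigma`,
#'   `loglik_trace`, and `posterior(s)` (a function).
#' @export
fit_score_mixture <- function(target_scores, decoy_scores,
                              max_iter = 200L, tol = 1e-8) {
  if (length(target_scores) < 100 || length(decoy_scores) < 100) {
    stop("need at least 100 target and 100 decoy scores")
  }
  if (stats::sd(target_scores) == 0 || stats::sd(decoy_scores) == 0) {
    stop("degenerate (all-equal) scores; fall back to raw q-values")
  }
  rng <- range(c(target_scores, decoy_scores))
  pad <- 0.1 * diff(rng) + 1e-6
  kd <- stats::density(decoy_scores, bw = "nrd0",
                       from = rng[1] - pad, to = rng[2] + pad, n = 512)
  f_neg <- stats::approxfun(kd$x, pmax(kd$y, 1e-12), rule = 2)
  # EM for pi and the positive Gaussian; negative density held fixed
  s <- target_scores
  pi_ <- 0.5
  mu <- stats::quantile(s, 0.75, names = FALSE)
  sigma <- stats::sd(s)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d_pos <- stats::dnorm(s, mu, sigma)
    d_neg <- f_neg(s)
    num <- pi_ * d_pos
    den <- num + (1 - pi_) * d_neg
    ll <- sum(log(pmax(den, 1e-300)))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && ll - ll_trace[it - 1L] < tol * abs(ll_trace[it - 1L]) + tol) {
      break
    }
    r <- num / pmax(den, 1e-300)
    pi_ <- mean(r)
    mu <- sum(r * s) / sum(r)
    sigma <- sqrt(sum(r * (s - mu)^2) / sum(r))
    sigma <- max(sigma, 1e-3)
  }
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = 1024)
  post <- pi_ * stats::dnorm(grid, mu, sigma) /
    pmax(pi_ * stats::dnorm(grid, mu, sigma) + (1 - pi_) * f_neg(grid),
         1e-300)
  post <- cummax(pmin(pmax(post, 0), 1))  # clip monotone
  post_fun <- stats::approxfun(grid, post, rule = 2)
  structure(list(pi = pi_, mu = mu, sigma = sigma,
                 loglik_trace = ll_trace, grid = grid,
                 posterior = post_fun, f_neg = f_neg),
            class = "score_mixture")
}

#' Target-decoy competition q-values
#'
#' At score threshold t, FDR-hat(t) = #decoys >= t / max(1, #targets >= t);
#' the q-value of an item is the minimum FDR-hat over thresholds at or below
#' its score. At equal scores decoys are counted before targets
#' (conservative). Values are capped at 1.
#'
#' @param scores Numeric scores (higher = better).
#' @param decoy_flags Logical vector, TRUE for decoys.
#' @param correction Added to the decoy count (default 0, the plain
#'   estimator; the FDR filters use 1, the standard finite-sample
#'   correction that makes target-decoy FDR control non-anti-conservative).
#' @return Numeric q-values, one per input item (decoys included).
#' @export
tdc_qvalues <- function(scores, decoy_flags, correction = 0) {
  stopifnot(length(scores) == length(decoy_flags))
  if (sum(!decoy_flags) == 0) stop("need at least one target")
  n <- length(scores)
  # descending score; decoys first within ties
  ord <- order(-scores, !decoy_flags)
  dec <- decoy_flags[ord]
  cum_d <- cumsum(dec)
  cum_t <- cumsum(!dec)
  fdr <- (cum_d + correction) / pmax(1, cum_t)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  # an item's threshold is its own score, so all members of a tie block get
  # the q at the last position of the block (where the whole block is in)
  s_sorted <- scores[ord]
  r <- rle(s_sorted)
  last_pos <- rep(cumsum(r$lengths), r$lengths)
  out <- numeric(n)
  out[ord] <- q[last_pos]
  out
}

#' Group-specific PSM filter
#'
#' Splits PSMs into glycosylated (delta mass >= cutoff) and non-glycosylated
#' groups and applies target-decoy q-value filtering independently within
#' each group, so the small glyco fraction gets its own score threshold.
#'
#' @param psms PSM data.frame with `delta_mass`, `hyperscore`, `is_decoy`.
#' @param cutoff_da Delta-mass split (default 145 Da, the smallest glycan
#'   considered).
#' @param fdr_level Per-group FDR level (default 0.01).
#' @param score_col Score column name.
#' @return List of class `filter_outcome`: `psms` (input plus `group`,
#'   `psm_q`, `accepted`), `thresholds` (per group), `summary`.
#' @export
group_specific_filter <- function(psms, cutoff_da = 145, fdr_level = 0.01,
                                  score_col = "hyperscore") {
  psms$group <- ifelse(psms$delta_mass >= cutoff_da, "glyco", "nonglyco")
  psms$psm_q <- NA_real_
  psms$accepted <- FALSE
  thresholds <- c(glyco = Inf, nonglyco = Inf)
  for (g in c("glyco", "nonglyco")) {
    idx <- which(psms$group == g)
    if (length(idx) == 0) next
    if (sum(!psms$is_decoy[idx]) == 0) {
      message("group '", g, "' has no target PSMs; returning it empty")
      next
    }
    q <- tdc_qvalues(psms[[score_col]][idx], psms$is_decoy[idx],
                     correction = 1)
    psms$psm_q[idx] <- q
    acc <- q <= fdr_level & !psms$is_decoy[idx]
    psms$accepted[idx] <- acc
    if (any(acc)) thresholds[g] <- min(psms[[score_col]][idx][acc])
  }
  summary <- data.frame(
    group = c("glyco", "nonglyco"),
    threshold = thresholds[c("glyco", "nonglyco")],
    n_targets = c(sum(psms$group == "glyco" & !psms$is_decoy),
                  sum(psms$group == "nonglyco" & !psms$is_decoy)),
    n_decoys = c(sum(psms$group == "glyco" & psms$is_decoy),
                 sum(psms$group == "nonglyco" & psms$is_decoy)),
    n_accepted = c(sum(psms$accepted & psms$group == "glyco"),
                   sum(psms$accepted & psms$group == "nonglyco")),
    row.names = NULL)
  structure(list(psms = psms, thresholds = thresholds, summary = summary),
            class = "filter_outcome")
}

#' Pooled (non-group) PSM filter
#'
#' The standard single-threshold procedure, retained to demonstrate the
#' false-discovery enrichment it causes in the glyco fraction.
#'
#' @inheritParams group_specific_filter
#' @return A `filter_outcome`.
#' @export
pooled_filter <- function(psms, fdr_level = 0.01, score_col = "hyperscore",
                          cutoff_da = 145) {
  psms$group <- ifelse(psms$delta_mass >= cutoff_da, "glyco", "nonglyco")
  q <- tdc_qvalues(psms[[score_col]], psms$is_decoy, correction = 1)
  psms$psm_q <- q
  psms$accepted <- q <= fdr_level & !psms$is_decoy
  thr <- if (any(psms$accepted)) min(psms[[score_col]][psms$accepted]) else Inf
  structure(list(psms = psms,
                 thresholds = c(pooled = thr),
                 summary = data.frame(group = "pooled", threshold = thr,
                                      n_targets = sum(!psms$is_decoy),
                                      n_decoys = sum(psms$is_decoy),
                                      n_accepted = sum(psms$accepted))),
            class = "filter_outcome")
}

#' Peptide-level filter
#'
#' Collapses accepted PSMs to their best PSM per (peptide, decoy status),
#' computes target-decoy q-values over peptides, and accepts q <= level.
#'
#' @param psms Accepted-PSM data.frame with `peptide`, `is_decoy`, score.
#' @param fdr_level FDR level (default 0.01).
#' @param score_col Score column name.
#' @return List with `peptides` (best-PSM table with `pep_q`, `accepted`)
#'   and `threshold`.
#' @export
peptide_level_filter <- function(psms, fdr_level = 0.01,
                                 score_col = "hyperscore") {
  if (nrow(psms) == 0 || sum(!psms$is_decoy) == 0) {
    empty <- psms[0, , drop = FALSE]
    empty$pep_q <- numeric(0)
    empty$accepted <- logical(0)
    return(list(peptides = empty, threshold = Inf))
  }
  key <- paste0(psms$peptide, "|", psms$is_decoy)
  best <- tapply(psms[[score_col]], key, max)
  first <- psms[!duplicated(key), , drop = FALSE]
  first <- first[match(names(best), paste0(first$peptide, "|",
                                           first$is_decoy)), , drop = FALSE]
  first[[score_col]] <- as.numeric(best)
  q <- tdc_qvalues(first[[score_col]], first$is_decoy)
  first$pep_q <- q
  first$accepted <- q <= fdr_level & !first$is_decoy
  rownames(first) <- NULL
  thr <- if (any(first$accepted)) min(first[[score_col]][first$accepted])
         else Inf
  list(peptides = first, threshold = thr)
}

# Exact minimum set cover by increasing subset size (bitmask over peptides),
# used for small instances; greedy cover otherwise.
.cover_exact_max <- 15L

greedy_cover <- function(sets, n_items, order_hint) {
  chosen <- integer(0)
  covered <- rep(FALSE, n_items)
  repeat {
    gain <- vapply(sets, function(s) sum(!covered[s]), integer(1))
    gain[chosen] <- -1L
    if (all(gain <= 0)) break
    pick <- order(-gain, -lengths(sets), order_hint)[1]
    chosen <- c(chosen, pick)
    covered[sets[[pick]]] <- TRUE
    if (all(covered)) break
  }
  chosen
}

exact_cover <- function(sets, n_items, order_hint) {
  ord <- order(-lengths(sets), order_hint)
  for (k in seq_along(sets)) {
    combs <- utils::combn(ord, k, simplify = FALSE)
    for (cc in combs) {
      covered <- rep(FALSE, n_items)
      for (j in cc) covered[sets[[j]]] <- TRUE
      if (all(covered)) return(sort(cc))
    }
  }
  integer(0)
}

#' Protein-level filter with parsimony inference
#'
#' Proteins are inferred by parsimony over the accepted peptides: the
#' minimal protein set covering all peptides (exact for <= 15 candidate
#' proteins after grouping indistinguishable ones, greedy beyond that; ties
#' by more covered peptides, then more total peptides, then accession).
#' Each retained protein is scored as the sum of `-ln(1 - posterior)` over
#' its assigned peptides, and protein-level target-decoy q-values are
#' computed with decoy proteins.
#'
#' @param peptides Accepted-peptide data.frame with `peptide`, `proteins`
#'   (";"-separated `accession:start-end`), `is_decoy`, and `posterior`
#'   (best-PSM posterior; the score column is used when absent).
#' @param fdr_level Protein FDR level (default 0.01).
#' @param score_col Fallback score column used to derive a pseudo-posterior
#'   when no `posterior` column exists.
#' @return List with `proteins` (accession, is_decoy, score, n_peptides,
#'   prot_q, accepted), `accepted_accessions`, and `assignment` (peptide ->
#'   representative protein).
#' @export
protein_level_filter <- function(peptides, fdr_level = 0.01,
                                 score_col = "hyperscore") {
  if (nrow(peptides) == 0) {
    return(list(proteins = data.frame(), accepted_accessions = character(0),
                assignment = data.frame()))
  }
  post <- if ("posterior" %in% names(peptides)) {
    peptides$posterior
  } else {
    s <- peptides[[score_col]]
    stats::plogis(scale(s)[, 1])          # rank-preserving pseudo-posterior
  }
  post <- pmin(pmax(post, 0), 1 - 1e-6)
  acc_of <- function(p) sub(":[0-9]+-[0-9]+$", "",
                            strsplit(p, ";", fixed = TRUE)[[1]])
  pep_prots <- lapply(peptides$proteins, acc_of)
  sel <- integer(0)
  out_assign <- list()
  prot_rows <- list()
  for (dec in c(FALSE, TRUE)) {
    idx <- which(peptides$is_decoy == dec)
    if (length(idx) == 0) next
    prots <- sort(unique(unlist(pep_prots[idx])))
    sets <- lapply(prots, function(a) {
      which(vapply(pep_prots[idx], function(x) a %in% x, logical(1)))
    })
    names(sets) <- prots
    # group proteins with identical peptide sets; keep first accession
    setkey <- vapply(sets, function(s) paste(s, collapse = ","), character(1))
    rep_first <- !duplicated(setkey)
    sets_u <- sets[rep_first]
    prots_u <- prots[rep_first]
    chosen <- if (length(sets_u) <= .cover_exact_max) {
      exact_cover(sets_u, length(idx), seq_along(sets_u))
    } else {
      greedy_cover(sets_u, length(idx), seq_along(sets_u))
    }
    # deterministic peptide -> protein assignment: peptide goes to the
    # chosen protein covering it with the most peptides, ties by accession
    chosen_sizes <- lengths(sets_u[chosen])
    ord_ch <- chosen[order(-chosen_sizes, prots_u[chosen])]
    assign_to <- rep(NA_character_, length(idx))
    for (j in ord_ch) {
      free <- sets_u[[j]][is.na(assign_to[sets_u[[j]]])]
      assign_to[free] <- prots_u[j]
    }
    for (j in ord_ch) {
      members <- which(assign_to == prots_u[j])
      score <- sum(-log(1 - post[idx][members]))
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        accession = prots_u[j], is_decoy = dec, score = score,
        n_peptides = length(members), stringsAsFactors = FALSE)
    }
    out_assign[[length(out_assign) + 1L]] <- data.frame(
      peptide = peptides$peptide[idx], is_decoy = dec,
      protein = assign_to, stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, prot_rows)
  assignment <- do.call(rbind, out_assign)
  if (sum(!proteins$is_decoy) == 0) {
    proteins$prot_q <- NA_real_; proteins$accepted <- FALSE
  } else {
    proteins$prot_q <- tdc_qvalues(proteins$score, proteins$is_decoy)
    proteins$accepted <- proteins$prot_q <= fdr_level & !proteins$is_decoy
  }
  rownames(proteins) <- NULL
  list(proteins = proteins,
       accepted_accessions = proteins$accession[proteins$accepted],
       assignment = assignment)
}

#' Sequential protein filter
#'
#' Removes PSMs none of whose proteins passed the protein-level FDR.
#'
#' @param psms PSM data.frame with a `proteins` column.
#' @param accepted_accessions Character vector of accepted accessions.
#' @return The subset of `psms` with at least one accepted protein.
#' @export
sequential_protein_filter <- function(psms, accepted_accessions) {
  if (nrow(psms) == 0) return(psms)
  keep <- vapply(psms$proteins, function(p) {
    accs <- sub(":[0-9]+-[0-9]+$", "", strsplit(p, ";", fixed = TRUE)[[1]])
    any(accs %in% accepted_accessions)
  }, logical(1), USE.NAMES = FALSE)
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Entrapment rate among glyco PSMs
#'
#' Fraction of final glyco-group PSMs that map exclusively to entrapment
#' (foreign-species) proteins; PSMs with mixed provenance do not count.
#'
#' @param final_psms Final PSM data.frame with `group` and `proteins`.
#' @param proteins Protein data.frame with `accession` and `species_tag`.
#' @param entrapment_tag Tag marking entrapment proteins.
#' @return List with `rate` and `offending` (the entrapment-only PSM rows).
#' @export
entrapment_rate <- function(final_psms, proteins, entrapment_tag) {
  ent_accs <- proteins$accession[!is.na(proteins$species_tag) &
                                   proteins$species_tag == entrapment_tag]
  if (length(ent_accs) == 0) {
    stop("entrapment tag '", entrapment_tag, "' absent from the database")
  }
  ent_accs <- c(ent_accs, paste0("rev_", ent_accs))
  gl <- final_psms[final_psms$group == "glyco", , drop = FALSE]
  if (nrow(gl) == 0) return(list(rate = 0, offending = gl))
  only_ent <- vapply(gl$proteins, function(p) {
    accs <- sub(":[0-9]+-[0-9]+$", "", strsplit(p, ";", fixed = TRUE)[[1]])
    all(accs %in% ent_accs)
  }, logical(1), USE.NAMES = FALSE)
  list(rate = mean(only_ent), offending = gl[only_ent, , drop = FALSE])
}
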