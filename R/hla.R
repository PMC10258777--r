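# HLA class II analysis: allele assignment from percentile ranks, PWM
# mixture EM deconvolution of binding motifs and core offsets, core-relative
# glycosite positioning, Fisher exact testing of motif conservation, and
# per-gene-group summaries.

AA_ALPHABET <- names(AA_MASSES)[!duplicated(names(AA_MASSES))]

#' Assign peptides to HLA alleles from a percentile-rank table
#'
#' A peptide goes to its lowest-rank (strongest predicted binding) allele if
#' that rank is <= `threshold`, otherwise to `"TRASH"` (treated as an MS
#' co-immunoprecipitated contaminant). Rank ties resolve to the
#' lexicographically first allele.
#'
#' @param peptides Character vector of peptide sequences.
#' @param rank_table data.frame with columns `peptide`, `allele`, `rank`
#'   (percentile rank in \[0, 100\]) and optionally `core_offset` (0-based).
#' @param threshold Rank threshold (default 20; the boundary is inclusive).
#' @return data.frame with `peptide`, `allele` (or `"TRASH"`), `rank`,
#'   `core_offset` (NA when trash or absent from the table).
#' @export
assign_alleles <- function(peptides, rank_table, threshold = 20) {
  missing <- setdiff(peptides, rank_table$peptide)
  if (length(missing) > 0) {
    stop("peptide(s) absent from the rank table: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ...")
  }
  if (any(rank_table$rank < 0 | rank_table$rank > 100)) {
    stop("percentile ranks must lie in [0, 100]")
  }
  has_offset <- "core_offset" %in% names(rank_table)
  rows <- lapply(peptides, function(p) {
    sub <- rank_table[rank_table$peptide == p, , drop = FALSE]
    sub <- sub[order(sub$rank, sub$allele), , drop = FALSE]
    best <- sub[1, ]
    if (best$rank <= threshold) {
      data.frame(peptide = p, allele = best$allele, rank = best$rank,
                 core_offset = if (has_offset) best$core_offset
                               else NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(peptide = p, allele = "TRASH", rank = best$rank,
                 core_offset = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# log-likelihood matrix of all 9-mer windows of a peptide under a PWM,
# relative to background
pwm_window_scores <- function(peptide, log_ratio) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  L <- length(aa)
  n_off <- L - 9L + 1L
  ai <- match(aa, AA_ALPHABET)
  vapply(seq_len(n_off), function(o) {
    sum(log_ratio[cbind(1:9, ai[o:(o + 8L)])])
  }, numeric(1))
}

#' Deconvolve binding motifs by PWM mixture EM
#'
#' Fits a mixture of K position-weight-matrix classes over latent (class,
#' 9-mer core offset) assignments, plus one always-present flat-background
#' "trash" class. The E-step weights each (class, offset) by class weight x
#' offset weight x PWM likelihood ratio against background; the M-step
#' updates pseudocount-regularized PWMs (alpha = 0.1), class weights, and a
#' per-class offset-preference vector shared across peptide lengths. K <=
#' `K_max` is selected by BIC; each K is fitted from `runs` random restarts
#' and the best final log-likelihood is kept.
#'
#' @param peptides Character vector (>= 50 peptides of length >= `min_len`
#'   required after filtering).
#' @param K_max Maximum number of motif classes (default 10).
#' @param runs Random restarts per K (default 20).
#' @param min_len Minimum peptide length (default 12).
#' @param seed RNG seed.
#' @param max_iter,tol EM controls.
#' @return List of class `motif_model`: `pwms` (list of 9 x 20 matrices),
#'   `class_weights`, `offset_weights`, `responsibilities`, `core_offset`
#'   (argmax offset per peptide), `assigned_class` (0 = trash), `loglik`,
#'   `loglik_trace`, `K`, `bic`.
#' @export
deconvolve_motifs <- function(peptides, K_max = 10L, runs = 20L,
                              min_len = 12L, seed = 1L, max_iter = 100L,
                              tol = 1e-6) {
  peptides <- peptides[nchar(peptides) >= min_len]
  peptides <- peptides[!grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptides)]
  n <- length(peptides)
  if (n < 50) stop("need at least 50 peptides of length >= ", min_len)
  if (n <= K_max) stop("fewer peptides than classes")
  bg <- rep(1 / 20, 20)
  aa_idx <- lapply(strsplit(peptides, "", fixed = TRUE),
                   match, table = AA_ALPHABET)
  n_off <- nchar(peptides) - 9L + 1L
  max_off <- max(n_off)

  fit_one <- function(K, run_seed) {
    set.seed(run_seed)
    # init PWMs from random peptide windows with heavy smoothing
    pwms <- lapply(seq_len(K), function(k) {
      i <- sample.int(n, 1)
      o <- sample.int(n_off[i], 1)
      m <- matrix(1, 9, 20)
      for (p in 1:9) m[p, aa_idx[[i]][o + p - 1L]] <- 5
      m / rowSums(m)
    })
    w <- rep(1 / (K + 1), K + 1)           # last = trash
    ow <- matrix(1 / max_off, K, max_off)
    ll_trace <- numeric(0)
    resp_cls <- NULL
    core_off <- integer(n)
    for (it in seq_len(max_iter)) {
      # E-step: per peptide, joint over (class, offset) + trash
      lr <- lapply(pwms, function(m) log(m) - log(matrix(bg, 9, 20,
                                                         byrow = TRUE)))
      post_cls <- matrix(0, n, K + 1)
      exp_counts <- lapply(seq_len(K), function(k) matrix(0, 9, 20))
      exp_off <- matrix(0, K, max_off)
      ll <- 0
      best_off <- integer(n)
      for (i in seq_len(n)) {
        offs <- seq_len(n_off[i])
        mat <- matrix(-Inf, K, n_off[i])
        for (k in seq_len(K)) {
          sc <- pwm_window_scores(peptides[i], lr[[k]])
          osub <- ow[k, offs] / sum(ow[k, offs])
          mat[k, ] <- log(w[k]) + log(osub) + sc
        }
        trash_l <- log(w[K + 1])            # flat: likelihood ratio 1
        m0 <- max(c(mat, trash_l))
        joint <- exp(mat - m0)
        tj <- exp(trash_l - m0)
        Z <- sum(joint) + tj
        ll <- ll + m0 + log(Z)
        pj <- joint / Z
        post_cls[i, seq_len(K)] <- rowSums(pj)
        post_cls[i, K + 1] <- tj / Z
        exp_off[, offs] <- exp_off[, offs] + pj
        # accumulate PWM counts
        for (k in seq_len(K)) {
          for (o in offs) {
            pko <- pj[k, o]
            if (pko > 1e-12) {
              idx <- cbind(1:9, aa_idx[[i]][o:(o + 8L)])
              exp_counts[[k]][idx] <- exp_counts[[k]][idx] + pko
            }
          }
        }
        flat <- pj
        best <- which(flat == max(flat), arr.ind = TRUE)[1, ]
        best_off[i] <- best[2] - 1L
      }
      ll_trace <- c(ll_trace, ll)
      if (it > 1 && ll - ll_trace[it - 1L] < tol * (abs(ll_trace[it - 1L]) + 1)) {
        resp_cls <- post_cls; core_off <- best_off
        break
      }
      # M-step
      alpha <- 0.1
      pwms <- lapply(exp_counts, function(cm) {
        cm <- cm + alpha
        cm / rowSums(cm)
      })
      w <- colSums(post_cls) + alpha
      w <- w / sum(w)
      ow <- exp_off + alpha
      ow <- ow / rowSums(ow)
      resp_cls <- post_cls; core_off <- best_off
    }
    list(pwms = pwms, class_weights = w, offset_weights = ow,
         responsibilities = resp_cls, core_offset = core_off,
         loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace, K = K)
  }

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max %/% 2L, max(1, K_max * runs))
  # K = 0 is the trash-only model: every peptide in the flat background
  # class, log-likelihood 0 on the likelihood-ratio scale, zero parameters.
  best_model <- list(
    pwms = list(), class_weights = 1, offset_weights = NULL,
    responsibilities = matrix(1, n, 1), core_offset = rep(0L, n),
    loglik = 0, loglik_trace = 0, K = 0L)
  best_bic <- 0
  best_model$bic <- 0
  for (K in seq_len(K_max)) {
    fits <- lapply(seq_len(runs), function(r) {
      fit_one(K, run_seeds[(K - 1L) * runs + r])
    })
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    fit <- fits[[which.max(lls)]]
    npar <- K * (9 * 19 + (max_off - 1)) + K   # PWMs + offsets + weights
    bic <- -2 * fit$loglik + npar * log(n)
    if (bic < best_bic) {
      best_bic <- bic
      best_model <- fit
      best_model$bic <- bic
    }
  }
  post <- best_model$responsibilities
  best_model$assigned_class <- apply(post, 1, which.max)
  best_model$assigned_class[best_model$assigned_class == best_model$K + 1] <- 0L
  best_model$peptides <- peptides
  class(best_model) <- "motif_model"
  best_model
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model: K =", x$K, "classes (+ trash), n =",
      length(x$peptides), "peptides, logLik =",
      format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Mean per-position correlation between two PWMs
#'
#' Positions where either PWM row has zero variance (perfectly uniform
#' rows carry no motif information) are skipped.
#'
#' @param recovered,planted 9 x 20 PWMs.
#' @return Mean Pearson correlation over informative positions.
#' @export
pwm_recovery_correlation <- function(recovered, planted) {
  stopifnot(all(dim(recovered) == dim(planted)))
  cors <- vapply(seq_len(nrow(planted)), function(p) {
    if (stats::sd(recovered[p, ]) == 0 || stats::sd(planted[p, ]) == 0) {
      NA_real_
    } else {
      stats::cor(recovered[p, ], planted[p, ])
    }
  }, numeric(1))
  mean(cors, na.rm = TRUE)
}

#' Glycosite position relative to the HLA-binding core
#'
#' @param site_index_0based Glycosite index within the peptide (0-based).
#' @param core_offset_0based Start of the 9-mer binding core (0-based).
#' @param peptide_length Optional; when given, bounds are checked.
#' @return List with `p` (site - offset) and `category`: `"upstream"`
#'   (p < 0), `"core"` (0 <= p <= 8), `"downstream"` (p >= 9).
#' @export
relative_glyco_position <- function(site_index_0based, core_offset_0based,
                                    peptide_length = NULL) {
  if (!is.null(peptide_length)) {
    if (any(site_index_0based < 0 | site_index_0based >= peptide_length)) {
      stop("glycosite outside the peptide")
    }
    if (any(core_offset_0based < 0 |
            core_offset_0based + 9 > peptide_length)) {
      stop("binding core does not fit in the peptide")
    }
  }
  p <- site_index_0based - core_offset_0based
  category <- ifelse(p < 0, "upstream", ifelse(p <= 8, "core", "downstream"))
  list(p = p, category = category)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact enumeration of the hypergeometric distribution with fixed margins;
#' the p-value sums the probabilities of all tables at most as probable as
#' the observed one (with a 1e-7 relative tolerance on the comparison).
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(table_2x2) {
  t <- as.matrix(table_2x2)
  stopifnot(all(dim(t) == c(2, 2)))
  if (any(t < 0) || any(t != round(t))) {
    stop("counts must be non-negative integers")
  }
  a <- t[1, 1]
  m <- sum(t[1, ]); n <- sum(t[2, ]); k <- sum(t[, 1])
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  x <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Motif conservation test per allele
#'
#' For each allele with at least one glycosylated and one non-glycosylated
#' peptide among those whose best-ranked allele it is, tests whether the
#' binder (assigned) vs. trash split differs between glycosylated and
#' non-glycosylated peptides (two-sided Fisher's exact test on the 2x2).
#'
#' @param rank_table Percentile-rank table (see [assign_alleles()]).
#' @param peptides Character vector of peptides to test.
#' @param glyco_flags Logical vector parallel to `peptides`.
#' @param threshold Rank threshold (default 20).
#' @return data.frame with `allele`, `p_value`, and the four cell counts.
#'   Degenerate margins give p = 1 with a warning.
#' @export
motif_conservation_test <- function(rank_table, peptides, glyco_flags,
                                    threshold = 20) {
  stopifnot(length(peptides) == length(glyco_flags))
  if (!any(glyco_flags) || !all(glyco_flags)) {
    # both classes must exist overall; per-allele checks below
  }
  # best allele per peptide regardless of threshold
  best <- lapply(peptides, function(p) {
    sub <- rank_table[rank_table$peptide == p, , drop = FALSE]
    sub <- sub[order(sub$rank, sub$allele), , drop = FALSE]
    sub[1, c("allele", "rank")]
  })
  best_allele <- vapply(best, function(b) b$allele, character(1))
  best_rank <- vapply(best, function(b) b$rank, numeric(1))
  binder <- best_rank <= threshold
  rows <- list()
  for (al in sort(unique(best_allele))) {
    sel <- best_allele == al
    if (!any(glyco_flags[sel]) || all(glyco_flags[sel])) next
    tab <- matrix(c(sum(binder[sel] & glyco_flags[sel]),
                    sum(binder[sel] & !glyco_flags[sel]),
                    sum(!binder[sel] & glyco_flags[sel]),
                    sum(!binder[sel] & !glyco_flags[sel])),
                  2, 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("degenerate margins for allele ", al, "; p set to 1")
      p <- 1
    } else {
      p <- fisher_exact_two_sided(tab)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      allele = al, p_value = p,
      binder_glyco = tab[1, 1], binder_nonglyco = tab[1, 2],
      trash_glyco = tab[2, 1], trash_nonglyco = tab[2, 2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(allele = character(0), p_value = numeric(0),
                      binder_glyco = integer(0), binder_nonglyco = integer(0),
                      trash_glyco = integer(0), trash_nonglyco = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' HLA gene group from an allele name
#'
#' @param allele Character vector of allele names (e.g. `"DRB1*12:01"`).
#' @return `"DP"`, `"DQ"`, or `"DR"`.
#' @export
hla_gene_group <- function(allele) {
  pre <- toupper(substr(allele, 1, 3))
  grp <- ifelse(pre %in% c("DPA", "DPB"), "DP",
         ifelse(pre %in% c("DQA", "DQB"), "DQ",
         ifelse(pre %in% c("DRA", "DRB"), "DR", NA_character_)))
  if (anyNA(grp)) {
    stop("unparseable allele name(s): ",
         paste(unique(allele[is.na(grp)]), collapse = ", "))
  }
  grp
}

#' Summarize glycosite positions and glycan types per HLA gene group
#'
#' @param assignments data.frame with columns `allele` (no TRASH rows
#'   required; they are skipped), `rel_position` (core-relative glycosite
#'   position) and optionally `type_class`.
#' @return List with `positions` (per group: fraction of sites inside
#'   (0 <= p <= 8) vs. outside the binding core) and `glycan_types` (per
#'   group type-class fractions, when available).
#' @export
summarize_positions <- function(assignments) {
  a <- assignments[assignments$allele != "TRASH" &
                     !is.na(assignments$rel_position), , drop = FALSE]
  if (nrow(a) == 0) stop("no assigned glycosites to summarize")
  a$group <- hla_gene_group(a$allele)
  inside <- a$rel_position >= 0 & a$rel_position <= 8
  pos <- do.call(rbind, lapply(split(inside, a$group), function(x) {
    data.frame(inside_core = mean(x), outside_core = mean(!x),
               n = length(x))
  }))
  pos$group <- rownames(pos); rownames(pos) <- NULL
  res <- list(positions = pos[, c("group", "inside_core", "outside_core",
                                  "n")])
  if ("type_class" %in% names(a) && any(!is.na(a$type_class))) {
    b <- a[!is.na(a$type_class), , drop = FALSE]
    tl <- c("truncated", "high-mannose", "complex/hybrid")
    gt <- do.call(rbind, lapply(split(b$type_class, b$group), function(x) {
      f <- table(factor(x, levels = tl)) / length(x)
      as.data.frame(t(as.numeric(f)))
    }))
    names(gt) <- tl
    gt$group <- rownames(gt); rownames(gt) <- NULL
    res$glycan_types <- gt[, c("group", tl)]
  }
  res
}
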