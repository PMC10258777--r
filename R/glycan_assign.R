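# Glycan composition assignment for glyco-group PSMs: candidate retrieval
# from the delta mass, diagnostic-ion scoring, decoy-glycan competition,
# and glycan-level q-values.

#' Candidate glycan compositions for a delta mass
#'
#' @param delta_mass Observed delta mass (Da), expected >= the glyco group
#'   cutoff.
#' @param db Glycan database data.frame.
#' @param tol_ppm Tolerance in ppm of the delta mass (default 20).
#' @param isotope_errors Allowed monoisotopic-peak errors (default 0,1,2).
#' @return Subset of `db` rows with columns `iso` and `ppm_error` added;
#'   empty (zero-row) when nothing matches.
#' @export
candidate_glycans <- function(delta_mass, db, tol_ppm = 20,
                              isotope_errors = c(0L, 1L, 2L)) {
  if (is.null(db) || nrow(db) == 0) stop("empty glycan database")
  tol <- ppm_tol_da(delta_mass, tol_ppm)
  hits <- list()
  for (iso in isotope_errors) {
    corrected <- delta_mass - iso * MASS_CONSTANTS[["isotope"]]
    d <- corrected - db$mass
    sel <- which(abs(d) <= tol)
    if (length(sel) > 0) {
      h <- db[sel, , drop = FALSE]
      h$iso <- as.integer(iso)
      h$ppm_error <- d[sel] / db$mass[sel] * 1e6
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0) {
    out <- db[0, , drop = FALSE]
    out$iso <- integer(0); out$ppm_error <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, hits)
  out <- out[!duplicated(paste0(out$composition, "@", out$iso)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Expected diagnostic ions for a composition: the HexNAc oxonium series and
# Hex always; NeuAc ions only for sialylated compositions; Y0/Y1/Y2 always;
# Yc only when the composition can contain the full HexNAc2Hex3 core;
# Y1+Fuc as the fucose diagnostic. `mass_shift` displaces the Y ions
# (used for decoy glycans).
expected_diagnostic_ions <- function(comp_counts, peptide_mass,
                                     mass_shift = 0) {
  proton <- MASS_CONSTANTS[["proton"]]
  cnt <- function(nm) if (nm %in% names(comp_counts))
    comp_counts[[nm]] else 0L
  panel <- default_oxonium_panel()
  oxo <- panel[panel$name %in% c("HexNAc-H2O", "HexNAc", "Hex"), ]
  if (cnt("NeuAc") > 0) {
    oxo <- rbind(oxo, panel[panel$name %in% c("NeuAc-H2O", "NeuAc"), ])
  }
  if (cnt("Hex") > 0 && cnt("HexNAc") > 0) {
    oxo <- rbind(oxo, panel[panel$name == "HexHexNAc", ])
  }
  hexnac <- MONOSACCHARIDES[["HexNAc"]]
  y <- c(Y0 = 0, Y1 = hexnac)
  if (cnt("HexNAc") >= 2) y <- c(y, Y2 = 2 * hexnac)
  if (cnt("HexNAc") >= 2 && cnt("Hex") >= 3) {
    y <- c(y, Yc = 2 * hexnac + 3 * MONOSACCHARIDES[["Hex"]])
  }
  if (cnt("Fuc") > 0) {
    y <- c(y, Y1F = hexnac + MONOSACCHARIDES[["Fuc"]])
  }
  ydf <- data.frame(
    label = names(y),
    mz = peptide_mass + mass_shift + y + proton,
    stringsAsFactors = FALSE)
  rbind(data.frame(label = oxo$name, mz = oxo$mz, stringsAsFactors = FALSE),
        ydf)
}

#' Score a glycan composition against a spectrum
#'
#' Additive evidence score over the composition's expected diagnostic ions
#' (oxonium subset plus Y ladder): `+w_hit` per matched ion, `-w_miss` per
#' absent ion, minus `lambda * |ppm mass error|` of the composition against
#' the (isotope-corrected) delta mass.
#'
#' @param spectrum Spectrum record.
#' @param peptide Peptide sequence (Y ions are peptide-mass anchored).
#' @param comp_counts Named counts of the candidate composition.
#' @param ppm_error Signed ppm error of the candidate (from
#'   [candidate_glycans()]).
#' @param frag_tol_ppm Fragment tolerance (ppm).
#' @param w_hit,w_miss,lambda Score weights (defaults 1, 0.5, 0.02).
#' @param mass_shift Y-ion mass displacement, used for decoy glycans.
#' @param mods Peptide modification tag.
#' @return Numeric score.
#' @export
score_glycan <- function(spectrum, peptide, comp_counts, ppm_error = 0,
                         frag_tol_ppm = 15, w_hit = 1, w_miss = 0.5,
                         lambda = 0.02, mass_shift = 0, mods = "") {
  pm <- peptide_mass(peptide)
  if (nzchar(mods)) pm <- sum(residue_ladder(peptide, mods)) +
      MASS_CONSTANTS[["water"]]
  ions <- expected_diagnostic_ions(comp_counts, pm, mass_shift)
  inten <- match_fragments(spectrum, ions, frag_tol_ppm)
  hit <- inten > 0
  sum(hit) * w_hit - sum(!hit) * w_miss - lambda * abs(ppm_error)
}

# Seed-controlled decoy mass shifts, one per composition: magnitude
# Uniform(0.5, 2.5) Da, random sign. Derived from a fixed seed so the
# competition is reproducible.
decoy_glycan_shifts <- function(compositions, seed = 7L) {
  n <- length(compositions)
  rs <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    stats::runif(n, 0.5, 2.5) * sample(c(-1, 1), n, replace = TRUE)
  })
  stats::setNames(rs, compositions)
}

#' Assign glycan compositions with decoy competition and q-values
#'
#' For each glyco-group PSM, all candidate compositions within tolerance of
#' the delta mass are scored, together with one decoy glycan per candidate
#' (same composition, Y ions displaced by a seed-controlled shift of
#' 0.5-2.5 Da). The best target competes with the best decoy; q-values are
#' target-decoy q-values over the competition winners, and decoy-winning
#' PSMs get q = 1.
#'
#' @param psms PSM data.frame (only `group == "glyco"` rows are assigned).
#' @param spectra List of spectrum records (matched to PSMs by `scan`).
#' @param db Glycan database.
#' @param config `search_config` (tolerances, glycan q threshold).
#' @param q_threshold Glycan q threshold (default from config, 0.05).
#' @param decoy_seed Seed for decoy mass shifts.
#' @return List with `assignments` (per glyco PSM: `scan`, `glycan`,
#'   `glycan_score`, `decoy_score`, `decoy_best`, `glycan_q`, `glycan_iso`,
#'   `type_class`, `retained`) and `psms` (input glyco PSMs annotated and
#'   filtered to retained ones).
#' @export
assign_glycans <- function(psms, spectra, db, config = search_config(),
                           q_threshold = config$glycan_q, decoy_seed = 7L) {
  gl <- psms[psms$group == "glyco" & !psms$is_decoy, , drop = FALSE]
  if (nrow(gl) == 0) {
    empty <- data.frame(scan = character(0), glycan = character(0),
                        glycan_score = numeric(0), decoy_score = numeric(0),
                        decoy_best = logical(0), glycan_q = numeric(0),
                        glycan_iso = integer(0), type_class = character(0),
                        retained = logical(0))
    return(list(assignments = empty, psms = gl))
  }
  scan_ids <- vapply(spectra, `[[`, character(1), "scan")
  missing <- setdiff(gl$scan, scan_ids)
  if (length(missing) > 0) {
    stop("spectra missing for scan(s): ", paste(missing, collapse = ", "))
  }
  shifts <- decoy_glycan_shifts(db$composition, seed = decoy_seed)
  count_cols <- intersect(names(MONOSACCHARIDES), names(db))
  rows <- vector("list", nrow(gl))
  for (i in seq_len(nrow(gl))) {
    sp <- spectra[[match(gl$scan[i], scan_ids)]]
    cand <- candidate_glycans(gl$delta_mass[i], db,
                              tol_ppm = config$precursor_tol_ppm,
                              isotope_errors = config$isotope_errors)
    if (nrow(cand) == 0) {
      rows[[i]] <- data.frame(
        scan = gl$scan[i], glycan = NA_character_, glycan_score = NA_real_,
        decoy_score = NA_real_, decoy_best = NA, glycan_q = NA_real_,
        glycan_iso = NA_integer_, type_class = NA_character_,
        retained = FALSE, stringsAsFactors = FALSE)
      next
    }
    t_scores <- d_scores <- numeric(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      cc <- stats::setNames(as.integer(cand[j, count_cols]), count_cols)
      t_scores[j] <- score_glycan(sp, gl$peptide[i], cc,
                                  ppm_error = cand$ppm_error[j],
                                  frag_tol_ppm = config$fragment_tol_ppm,
                                  mods = gl$mods[i])
      d_scores[j] <- score_glycan(sp, gl$peptide[i], cc,
                                  ppm_error = cand$ppm_error[j],
                                  frag_tol_ppm = config$fragment_tol_ppm,
                                  mass_shift = shifts[[cand$composition[j]]],
                                  mods = gl$mods[i])
    }
    bt <- order(-t_scores, cand$composition)[1]
    bd <- which.max(d_scores)
    decoy_best <- d_scores[bd] > t_scores[bt]
    rows[[i]] <- data.frame(
      scan = gl$scan[i],
      glycan = cand$composition[bt],
      glycan_score = t_scores[bt],
      decoy_score = d_scores[bd],
      decoy_best = decoy_best,
      glycan_q = NA_real_,
      glycan_iso = cand$iso[bt],
      type_class = cand$type_class[bt],
      retained = FALSE,
      stringsAsFactors = FALSE)
  }
  asg <- do.call(rbind, rows)
  scored <- which(!is.na(asg$decoy_best))
  if (length(scored) > 0 && any(!asg$decoy_best[scored])) {
    win_score <- ifelse(asg$decoy_best[scored], asg$decoy_score[scored],
                        asg$glycan_score[scored])
    q <- tdc_qvalues(win_score, asg$decoy_best[scored])
    asg$glycan_q[scored] <- q
    asg$glycan_q[scored][asg$decoy_best[scored]] <- 1
    asg$retained[scored] <- !asg$decoy_best[scored] &
      asg$glycan_q[scored] <= q_threshold
  }
  out_psms <- gl[asg$retained, , drop = FALSE]
  keep_cols <- c("glycan", "glycan_score", "glycan_q", "glycan_iso",
                 "type_class")
  out_psms[keep_cols] <- asg[asg$retained, keep_cols]
  rownames(out_psms) <- NULL
  list(assignments = asg, psms = out_psms)
}
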