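# Mass-offset glycopeptide search: theoretical b/y (+Y) fragments,
# MSFragger-style hyperscore, and best-PSM selection per spectrum.

#' Default search configuration
#'
#' Defaults follow the class II immunopeptidome settings: 20/15 ppm
#' precursor/fragment tolerances, isotope errors 0/+1/+2, peptide lengths
#' 7-25, oxonium gate at 10% of base peak, glyco/non-glyco delta-mass split
#' at 145 Da, 1% PSM/peptide/protein FDR, glycan q <= 0.05, percentile-rank
#' threshold 20.
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `search_config`.
#' @export
search_config <- function(...) {
  cfg <- list(
    precursor_tol_ppm = 20,
    fragment_tol_ppm = 15,
    isotope_errors = c(0L, 1L, 2L),
    length_range = c(7L, 25L),
    oxonium_threshold = 0.10,
    delta_cutoff = 145,
    psm_fdr = 0.01,
    peptide_fdr = 0.01,
    protein_fdr = 0.01,
    glycan_q = 0.05,
    rank_threshold = 20,
    max_var_mods = 2L,
    frag_max_charge = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (any(unlist(cfg[c("precursor_tol_ppm", "fragment_tol_ppm")]) <= 0)) {
    stop("tolerances must be positive")
  }
  frac <- unlist(cfg[c("oxonium_threshold", "psm_fdr", "peptide_fdr",
                       "protein_fdr", "glycan_q")])
  if (any(frac <= 0 | frac >= 1)) {
    stop("fractional thresholds must lie in (0, 1)")
  }
  class(cfg) <- "search_config"
  cfg
}

# Residue mass ladder for a peptide with deterministically localized
# variable modifications ("acetyl_nt@0;ox_M@k;cysteinyl@k" tag format:
# the first k eligible residues carry the modification).
residue_ladder <- function(peptide, mods = "") {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  res <- unname(AA_MASSES[aa])
  if (nzchar(mods)) {
    for (tag in strsplit(mods, ";", fixed = TRUE)[[1]]) {
      parts <- strsplit(tag, "@", fixed = TRUE)[[1]]
      what <- parts[1]; k <- as.integer(parts[2])
      if (what == "acetyl_nt") {
        res[1] <- res[1] + VARIABLE_MODS[["acetyl_nt"]]
      } else if (what == "ox_M") {
        pos <- which(aa == "M")[seq_len(k)]
        res[pos] <- res[pos] + VARIABLE_MODS[["ox_M"]]
      } else if (what == "cysteinyl") {
        pos <- which(aa == "C")[seq_len(k)]
        res[pos] <- res[pos] + VARIABLE_MODS[["cysteinyl"]]
      }
    }
  }
  res
}

#' Theoretical fragment ions for a (glyco)peptide
#'
#' Backbone b1..b(n-1) and y1..y(n-1) ions; for glycopeptides additionally
#' the Y-ion ladder retaining the intact peptide: Y0 (bare peptide), Y1
#' (+HexNAc), Y2 (+2 HexNAc), and Yc (+ the HexNAc2Hex3 core), each at
#' charges 1..2.
#'
#' @param peptide Peptide sequence.
#' @param glycan_mass Glycan mass in Da, or NULL for a plain peptide.
#' @param max_charge Maximum backbone fragment charge (default 1).
#' @param mods Modification tag string (see index construction).
#' @return data.frame with columns `label` and `mz`.
#' @export
theoretical_fragments <- function(peptide, glycan_mass = NULL,
                                  max_charge = 1L, mods = "") {
  res <- residue_ladder(peptide, mods)
  n <- length(res)
  proton <- MASS_CONSTANTS[["proton"]]
  water <- MASS_CONSTANTS[["water"]]
  cs <- cumsum(res)
  b_neutral <- cs[seq_len(n - 1L)]
  y_neutral <- (cs[n] - cs[n - seq_len(n - 1L)]) + water
  labels <- character(0); mz <- numeric(0)
  for (z in seq_len(max_charge)) {
    labels <- c(labels,
                paste0("b", seq_len(n - 1L), if (z > 1) paste0("^", z)),
                paste0("y", seq_len(n - 1L), if (z > 1) paste0("^", z)))
    mz <- c(mz, (b_neutral + z * proton) / z, (y_neutral + z * proton) / z)
  }
  if (!is.null(glycan_mass)) {
    pep_mass <- cs[n] + water
    hexnac <- MONOSACCHARIDES[["HexNAc"]]
    core <- 2 * hexnac + 3 * MONOSACCHARIDES[["Hex"]]
    y_ladder <- c(Y0 = pep_mass, Y1 = pep_mass + hexnac,
                  Y2 = pep_mass + 2 * hexnac, Yc = pep_mass + core)
    for (z in 1:2) {
      labels <- c(labels, paste0(names(y_ladder),
                                 if (z > 1) paste0("^", z)))
      mz <- c(mz, (y_ladder + z * proton) / z)
    }
  }
  data.frame(label = labels, mz = unname(mz), stringsAsFactors = FALSE)
}

# Fast path of match_fragments for a bare m/z vector (tol_fac = ppm * 1e-6)
.match_max_intensity <- function(spectrum, mz, tol_fac) {
  tol <- mz * tol_fac
  lo <- findInterval(mz - tol, spectrum$mz) + 1L
  hi <- findInterval(mz + tol, spectrum$mz)
  out <- numeric(length(mz))
  for (j in which(hi >= lo)) out[j] <- max(spectrum$intensity[lo[j]:hi[j]])
  out
}

# Match theoretical ions against a sorted peak list: each theoretical ion
# takes its single most intense peak within the ppm window (or none).
match_fragments <- function(spectrum, fragments, frag_tol_ppm) {
  tol <- ppm_tol_da(fragments$mz, frag_tol_ppm)
  lo <- findInterval(fragments$mz - tol, spectrum$mz) + 1L
  hi <- findInterval(fragments$mz + tol, spectrum$mz)
  inten <- numeric(nrow(fragments))
  hitj <- which(hi >= lo)
  for (j in hitj) {
    inten[j] <- max(spectrum$intensity[lo[j]:hi[j]])
  }
  inten
}

#' MSFragger-style hyperscore
#'
#' `ln(Nb!) + ln(Ny!) + ln(max(1, sum I_b)) + ln(max(1, sum I_y))` where
#' Nb/Ny are matched b-/y-type ion counts (Y ions count toward the y type)
#' and the sums are over matched intensities. Each theoretical ion matches
#' at most one peak.
#'
#' @param spectrum Spectrum record.
#' @param fragments data.frame from [theoretical_fragments()].
#' @param frag_tol_ppm Fragment tolerance (ppm).
#' @return List with `score`, `n_b`, `n_y`.
#' @export
hyperscore <- function(spectrum, fragments, frag_tol_ppm = 15) {
  stopifnot(nrow(fragments) > 0)
  inten <- match_fragments(spectrum, fragments, frag_tol_ppm)
  is_b <- startsWith(fragments$label, "b")
  is_y <- !is_b                       # y and Y series
  nb <- sum(inten[is_b] > 0); ny <- sum(inten[is_y] > 0)
  if (nb + ny == 0) return(list(score = 0, n_b = 0L, n_y = 0L))
  score <- lfactorial(nb) + lfactorial(ny) +
    log(max(1, sum(inten[is_b]))) + log(max(1, sum(inten[is_y])))
  list(score = score, n_b = as.integer(nb), n_y = as.integer(ny))
}

#' Search a single spectrum
#'
#' Candidates are the non-glyco index lookup plus, when the oxonium gate
#' passes, the glyco lookup (sequon-bearing peptides with a glycan mass
#' offset). The best hyperscore wins; ties break by smaller absolute delta
#' mass, then lexicographic peptide, then unmodified first.
#'
#' @param spectrum Spectrum record.
#' @param index `peptide_index`.
#' @param glycan_db Glycan database data.frame (or NULL to disable the
#'   glyco branch).
#' @param config `search_config`.
#' @param gate_pass Optional precomputed gate decision (logical); computed
#'   from the spectrum when NULL.
#' @return A one-row PSM data.frame, or NULL when no candidate matches.
#' @export
search_spectrum <- function(spectrum, index, glycan_db = NULL,
                            config = search_config(), gate_pass = NULL) {
  prec <- precursor_neutral_mass(spectrum)
  cand <- lookup_peptides(index, prec, config$precursor_tol_ppm,
                          config$isotope_errors, glycan_masses = NULL)
  if (!is.null(glycan_db) && nrow(glycan_db) > 0) {
    if (is.null(gate_pass)) {
      gate_pass <- oxonium_gate(
        spectrum, frag_tol_ppm = config$fragment_tol_ppm,
        threshold_fraction = config$oxonium_threshold)$pass
    }
    if (isTRUE(gate_pass)) {
      gl <- lookup_peptides(index, prec, config$precursor_tol_ppm,
                            config$isotope_errors,
                            glycan_masses = glycan_db$mass)
      if (nrow(gl) > 0) {
        # glycan identity does not change fragments or delta mass; score
        # each (peptide form, isotope) once, keeping the glycan hypothesis
        # with the smallest mass residual
        resid <- abs(prec - gl$iso * MASS_CONSTANTS[["isotope"]] -
                       index$table$mass[gl$row] - gl$glycan_mass)
        gl <- gl[order(resid), , drop = FALSE]
        gl <- gl[!duplicated(gl[c("row", "iso")]), , drop = FALSE]
        cand <- rbind(cand, gl)
      }
    }
  }
  if (nrow(cand) == 0) return(NULL)
  tab <- index$table
  is_glyco_cand <- !is.na(cand$glycan_idx)
  scores <- numeric(nrow(cand)); nb <- ny <- integer(nrow(cand))
  proton <- MASS_CONSTANTS[["proton"]]
  water <- MASS_CONSTANTS[["water"]]
  hexnac <- MONOSACCHARIDES[["HexNAc"]]
  core <- 2 * hexnac + 3 * MONOSACCHARIDES[["Hex"]]
  tol_fac <- config$fragment_tol_ppm * 1e-6
  for (i in seq_len(nrow(cand))) {
    r <- cand$row[i]
    cs <- index$ladders[[r]]
    n <- length(cs)
    b_mz <- y_mz <- numeric(0)
    for (z in seq_len(config$frag_max_charge)) {
      b_mz <- c(b_mz, (cs[-n] + z * proton) / z)
      y_mz <- c(y_mz, (cs[n] - cs[-n] + water + z * proton) / z)
    }
    if (is_glyco_cand[i]) {
      pm <- cs[n] + water
      yl <- pm + c(0, hexnac, 2 * hexnac, core)
      y_mz <- c(y_mz, yl + proton, (yl + 2 * proton) / 2)
    }
    hb <- .match_max_intensity(spectrum, b_mz, tol_fac)
    hy <- .match_max_intensity(spectrum, y_mz, tol_fac)
    nbi <- sum(hb > 0); nyi <- sum(hy > 0)
    nb[i] <- nbi; ny[i] <- nyi
    scores[i] <- if (nbi + nyi == 0) 0 else
      lfactorial(nbi) + lfactorial(nyi) +
        log(max(1, sum(hb))) + log(max(1, sum(hy)))
  }
  delta <- prec - cand$iso * MASS_CONSTANTS[["isotope"]] -
    tab$mass[cand$row]
  # tie-break on the residual against the matched mass hypothesis (for
  # non-glyco candidates this is |delta mass| itself), then fewest assumed
  # isotope errors, then lexicographic peptide, unmodified first
  resid <- abs(delta - cand$glycan_mass)
  ord <- order(-scores, resid, cand$iso, tab$sequence[cand$row],
               nchar(tab$mods[cand$row]))
  i <- ord[1]
  r <- cand$row[i]
  data.frame(
    scan = spectrum$scan,
    peptide = tab$sequence[r],
    mods = tab$mods[r],
    proteins = tab$proteins[r],
    is_decoy = tab$is_decoy[r],
    precursor_mass = prec,
    iso = cand$iso[i],
    delta_mass = delta[i],
    hyperscore = scores[i],
    n_b = nb[i], n_y = ny[i],
    group = if (delta[i] >= config$delta_cutoff) "glyco" else "nonglyco",
    n_sequons = tab$n_sequons[r],
    sequon_positions = tab$sequon_positions[r],
    stringsAsFactors = FALSE)
}

#' Search a batch of spectra
#'
#' @param spectra List of spectrum records.
#' @inheritParams search_spectrum
#' @param gate Optional gate report from [oxonium_gate_report()]; computed
#'   when NULL and a glycan database is given.
#' @return PSM data.frame (rank-1 PSM per spectrum with any candidate).
#' @export
search_spectra <- function(spectra, index, glycan_db = NULL,
                           config = search_config(), gate = NULL) {
  if (!is.null(glycan_db) && is.null(gate)) {
    gate <- oxonium_gate_report(
      spectra, frag_tol_ppm = config$fragment_tol_ppm,
      threshold_fraction = config$oxonium_threshold)
  }
  rows <- vector("list", length(spectra))
  for (k in seq_along(spectra)) {
    gp <- if (is.null(gate)) FALSE else gate$pass[k]
    rows[[k]] <- search_spectrum(spectra[[k]], index, glycan_db, config,
                                 gate_pass = gp)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(scan = character(0), peptide = character(0),
                      mods = character(0), proteins = character(0),
                      is_decoy = logical(0), precursor_mass = numeric(0),
                      iso = integer(0), delta_mass = numeric(0),
                      hyperscore = numeric(0), n_b = integer(0),
                      n_y = integer(0), group = character(0),
                      n_sequons = integer(0),
                      sequon_positions = character(0))
  }
  rownames(out) <- NULL
  out
}
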