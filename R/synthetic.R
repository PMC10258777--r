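# Ground-truth synthetic generators: proteomes with planted sequons,
# b/y (+Y, oxonium) spectra, scored PSM populations with a search-space
# asymmetry between the glyco and non-glyco fractions, and percentile-rank
# tables with planted binding motifs. Everything is deterministic under
# (config, seed) and every generator emits its truth table.

#' Generate a synthetic proteome with planted sequons
#'
#' Residues are i.i.d. at background frequencies (uniform by default);
#' N-X-S/T sequons are planted at the requested density, and a fraction of
#' proteins is tagged as entrapment (foreign-species) entries in their
#' FASTA headers.
#'
#' @param n_proteins Number of proteins.
#' @param length Protein length (residues).
#' @param sequon_density Planted sequons per residue, in \[0, 0.2\].
#' @param entrapment_fraction Fraction of proteins tagged as entrapment.
#' @param seed RNG seed.
#' @param background Residue sampling weights (named, default uniform over
#'   the 20 standard residues).
#' @return List with `proteins` (data.frame as from [read_fasta()]) and
#'   `truth` (per protein: accession, n_planted_sequons, is_entrapment).
#' @export
generate_proteome <- function(n_proteins = 20L, length = 60L,
                              sequon_density = 0.02,
                              entrapment_fraction = 0, seed = 1L,
                              background = NULL) {
  if (sequon_density < 0 || sequon_density > 0.2) {
    stop("sequon_density must lie in [0, 0.2]")
  }
  set.seed(seed)
  aa <- AA_ALPHABET
  w <- if (is.null(background)) rep(1, 20) else background[aa]
  n_ent <- round(entrapment_fraction * n_proteins)
  is_ent <- seq_len(n_proteins) <= n_ent
  seqs <- character(n_proteins)
  planted <- integer(n_proteins)
  st <- c("S", "T")
  mid <- setdiff(aa, "P")
  for (i in seq_len(n_proteins)) {
    s <- sample(aa, length, replace = TRUE, prob = w)
    k <- round(sequon_density * length)
    if (k > 0) {
      # non-overlapping anchor positions, >= 3 apart, away from the ends
      avail <- 1:(length - 2L)
      pos <- integer(0)
      while (base::length(pos) < k && base::length(avail) > 0) {
        p <- sample(avail, 1)
        pos <- c(pos, p)
        avail <- setdiff(avail, (p - 2L):(p + 2L))
      }
      for (p in pos) {
        s[p] <- "N"
        s[p + 1L] <- sample(mid, 1)
        s[p + 2L] <- sample(st, 1)
      }
      planted[i] <- base::length(pos)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  acc <- sprintf("%s%03d", ifelse(is_ent, "ENT", "SYN"),
                 seq_len(n_proteins))
  proteins <- data.frame(
    accession = acc, sequence = seqs, is_decoy = FALSE,
    species_tag = ifelse(is_ent, "entrapment", NA_character_),
    stringsAsFactors = FALSE)
  truth <- data.frame(accession = acc, n_planted_sequons = planted,
                      is_entrapment = is_ent, stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth)
}

#' Generate synthetic tandem spectra
#'
#' Builds b/y fragment spectra (plus the Y-ion ladder and oxonium ions for
#' glycopeptides) with log-normal intensities and uniform-m/z noise peaks.
#' The precursor is the peptide (+glycan) mass with isotope-error injection.
#' Glycopeptide spectra carry oxonium intensity summing to at least the
#' gate threshold of the base peak by construction.
#'
#' @param peptide_table data.frame with columns `peptide`, `glycan`
#'   (composition string or NA), and optionally `charge` (default 2).
#' @param noise_peaks Number of uniform noise peaks per spectrum.
#' @param seed RNG seed.
#' @param intensity_meanlog,intensity_sdlog Log-normal fragment intensity
#'   parameters (defaults ln 1000 and 1).
#' @param iso_error_probs Probabilities of 0/+1/+2 monoisotopic errors.
#' @param oxonium_fraction Oxonium summed intensity as a fraction of the
#'   base peak for glyco spectra (default 0.25).
#' @param frag_max_charge Backbone fragment charges to emit (default 1).
#' @return List with `spectra` (list of records) and `truth` (per scan:
#'   peptide, glycan, glycan_mass, charge, iso_error).
#' @export
generate_spectra <- function(peptide_table, noise_peaks = 0L, seed = 1L,
                             intensity_meanlog = log(1000),
                             intensity_sdlog = 1,
                             iso_error_probs = c(`0` = 1, `1` = 0, `2` = 0),
                             oxonium_fraction = 0.25,
                             frag_max_charge = 1L) {
  set.seed(seed)
  proton <- MASS_CONSTANTS[["proton"]]
  n <- nrow(peptide_table)
  charge <- if ("charge" %in% names(peptide_table)) {
    peptide_table$charge
  } else rep(2L, n)
  iso_err <- sample(as.integer(names(iso_error_probs)), n, replace = TRUE,
                    prob = iso_error_probs)
  spectra <- vector("list", n)
  g_mass <- numeric(n)
  panel <- default_oxonium_panel()
  for (i in seq_len(n)) {
    pep <- peptide_table$peptide[i]
    gstr <- peptide_table$glycan[i]
    has_glycan <- !is.na(gstr) && nzchar(gstr)
    gm <- if (has_glycan) attr(parse_glycan_string(gstr), "mass") else 0
    g_mass[i] <- gm
    fr <- theoretical_fragments(pep, glycan_mass = NULL,
                                max_charge = frag_max_charge)
    inten <- stats::rlnorm(nrow(fr), intensity_meanlog, intensity_sdlog)
    mz <- fr$mz
    it <- inten
    if (has_glycan) {
      # composition-dependent diagnostic ions (oxonium subset + Y ladder,
      # incl. the Fuc and core diagnostics real glycopeptides produce)
      comp <- unclass(parse_glycan_string(gstr))
      diag <- expected_diagnostic_ions(comp, peptide_mass(pep))
      base <- max(it)
      is_oxo <- !startsWith(diag$label, "Y")
      diag_i <- stats::rlnorm(nrow(diag), intensity_meanlog,
                              intensity_sdlog)
      # scale oxonium peaks so their sum clears the gate threshold
      oxo_target <- oxonium_fraction * base
      diag_i[is_oxo] <- diag_i[is_oxo] / sum(diag_i[is_oxo]) * oxo_target
      mz <- c(mz, diag$mz)
      it <- c(it, diag_i)
    }
    if (noise_peaks > 0) {
      prec_mz <- (peptide_mass(pep) + gm) / charge[i] + proton
      nz <- stats::runif(noise_peaks, 100, max(500, prec_mz * charge[i]))
      ni <- stats::rlnorm(noise_peaks, intensity_meanlog - 2,
                          intensity_sdlog)
      mz <- c(mz, nz); it <- c(it, ni)
    }
    neutral <- peptide_mass(pep) + gm + iso_err[i] * MASS_CONSTANTS[["isotope"]]
    pepmass <- neutral / charge[i] + proton
    spectra[[i]] <- new_spectrum(sprintf("synscan_%05d", i), pepmass,
                                 charge[i], mz, it)
  }
  truth <- data.frame(scan = sprintf("synscan_%05d", seq_len(n)),
                      peptide = peptide_table$peptide,
                      glycan = peptide_table$glycan,
                      glycan_mass = g_mass,
                      charge = charge, iso_error = iso_err,
                      stringsAsFactors = FALSE)
  list(spectra = spectra, truth = truth)
}

#' Generate a scored PSM population with known labels
#'
#' Models the score structure of a nonspecific search at the PSM level:
#' each spectrum yields a correct target match with probability depending
#' on its group, otherwise a random (incorrect) match that lands on a
#' target or a decoy with equal probability. Correct scores are
#' N(mu1, sd1), incorrect and decoy scores N(mu0, sd0). The glyco group
#' (delta mass >= 145 Da, fraction `glyco_fraction`) has its incorrect-match
#' odds inflated by `space_asymmetry`, emulating the much larger glycan x
#' peptide search space.
#'
#' @param n Number of spectra (>= 1000).
#' @param glyco_fraction Fraction of glyco-group spectra (default 0.03; the
#'   glycosylated share of identified spectra in unenriched data is < 5%).
#' @param space_asymmetry Ratio inflating the glyco incorrect-match odds
#'   (default 30).
#' @param p_correct_nonglyco Probability a non-glyco spectrum yields its
#'   correct match (default 0.7, typical of curated immunopeptidome runs;
#'   with the 30:1 asymmetry this leaves the glyco group with ~7% correct
#'   matches, i.e. around 200 true glyco PSMs per 100,000 spectra --
#'   above the 1/level floor that any 1% FDR procedure needs to return a
#'   non-empty discovery set).
#' @param score_params List with `mu1`, `sd1`, `mu0`, `sd0`
#'   (defaults 10, 1, 5, 1).
#' @param seed RNG seed.
#' @return data.frame with `scan`, `group`, `is_decoy`, `hyperscore`,
#'   `delta_mass`, `correct` (ground-truth label; NA for decoys).
#' @export
generate_psm_population <- function(n = 100000L, glyco_fraction = 0.03,
                                    space_asymmetry = 30,
                                    p_correct_nonglyco = 0.7,
                                    score_params = list(mu1 = 10, sd1 = 1,
                                                        mu0 = 5, sd0 = 1),
                                    seed = 1L) {
  if (n < 1000) stop("n must be at least 1000")
  if (score_params$mu1 <= score_params$mu0) {
    stop("mu1 must exceed mu0 (otherwise the mixture is unidentifiable)")
  }
  set.seed(seed)
  is_glyco <- stats::runif(n) < glyco_fraction
  odds_non <- (1 - p_correct_nonglyco) / p_correct_nonglyco
  p_correct_glyco <- 1 / (1 + odds_non * space_asymmetry)
  p_correct <- ifelse(is_glyco, p_correct_glyco, p_correct_nonglyco)
  correct <- stats::runif(n) < p_correct
  # incorrect spectra: the best random match is target or decoy with equal
  # probability (standard target-decoy competition assumption)
  decoy <- !correct & stats::runif(n) < 0.5
  score <- ifelse(correct,
                  stats::rnorm(n, score_params$mu1, score_params$sd1),
                  stats::rnorm(n, score_params$mu0, score_params$sd0))
  delta <- ifelse(is_glyco,
                  stats::runif(n, 203, 2500),
                  stats::rnorm(n, 0, 0.003))
  data.frame(scan = sprintf("psm_%06d", seq_len(n)),
             group = ifelse(is_glyco, "glyco", "nonglyco"),
             is_decoy = decoy,
             hyperscore = score,
             delta_mass = delta,
             correct = ifelse(decoy, NA, correct),
             stringsAsFactors = FALSE)
}

#' Generate peptides carrying planted binding motifs
#'
#' Emits peptides whose 9-mer core at a random offset is drawn from an
#' allele-specific PWM, plus motif-free background peptides.
#'
#' @param alleles Named list of 9 x 20 PWMs (rows sum to 1; columns in
#'   `AA_ALPHABET` order).
#' @param n_per_allele Motif-carrying peptides per allele.
#' @param n_background Motif-free peptides.
#' @param length_range Peptide length range (default 12-20).
#' @param seed RNG seed.
#' @return data.frame with `peptide`, `allele` (NA for background),
#'   `core_offset` (0-based planted offset, NA for background).
#' @export
generate_motif_peptides <- function(alleles, n_per_allele = 100L,
                                    n_background = 100L,
                                    length_range = c(12L, 20L), seed = 1L) {
  set.seed(seed)
  aa <- AA_ALPHABET
  draw_bg <- function(len) paste(sample(aa, len, replace = TRUE),
                                 collapse = "")
  rows <- list()
  for (al in names(alleles)) {
    pwm <- alleles[[al]]
    for (i in seq_len(n_per_allele)) {
      len <- sample(length_range[1]:length_range[2], 1)
      off <- sample(0:(len - 9L), 1)
      core <- vapply(1:9, function(p) sample(aa, 1, prob = pwm[p, ]),
                     character(1))
      flank <- sample(aa, len - 9L, replace = TRUE)
      pep <- character(len)
      pep[(off + 1L):(off + 9L)] <- core
      pep[setdiff(seq_len(len), (off + 1L):(off + 9L))] <- flank
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = paste(pep, collapse = ""), allele = al,
        core_offset = off, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_background)) {
    len <- sample(length_range[1]:length_range[2], 1)
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = draw_bg(len), allele = NA_character_,
      core_offset = NA_integer_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a percentile-rank table consistent with planted motifs
#'
#' Motif-carrying peptides get a low Beta-distributed rank (scaled to
#' \[0, 20\]) for their planted allele (with a small miss probability) and
#' non-binding ranks in (20, 100\] elsewhere; background peptides get
#' non-binding ranks for every allele.
#'
#' @param peptide_truth data.frame from [generate_motif_peptides()].
#' @param alleles Named list of PWMs (names define the allele set).
#' @param seed RNG seed.
#' @param miss_prob Probability a planted binder is missed (default 0.02).
#' @return data.frame with `peptide`, `allele`, `rank`, `core_offset`.
#' @export
generate_rank_table <- function(peptide_truth, alleles, seed = 1L,
                                miss_prob = 0.02) {
  set.seed(seed)
  allele_names <- names(alleles)
  rows <- list()
  for (i in seq_len(nrow(peptide_truth))) {
    pep <- peptide_truth$peptide[i]
    planted <- peptide_truth$allele[i]
    len <- nchar(pep)
    for (al in allele_names) {
      if (!is.na(planted) && al == planted &&
          stats::runif(1) >= miss_prob) {
        rank <- 20 * stats::rbeta(1, 1.2, 8)
        off <- peptide_truth$core_offset[i]
      } else {
        rank <- 20 + 80 * stats::rbeta(1, 2, 2)
        off <- sample(0:(len - 9L), 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, allele = al, rank = rank,
        core_offset = as.integer(off), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a random allele PWM with a sharp planted motif
#'
#' Anchor positions get a dominant residue (weight `strength`), the rest is
#' near-uniform. Convenience generator for simulations.
#'
#' @param seed RNG seed.
#' @param anchors Anchor positions within the 9-mer (default 1, 4, 6, 9).
#' @param strength Anchor residue weight (default 0.85).
#' @return 9 x 20 PWM (rows sum to 1).
#' @export
random_allele_pwm <- function(seed = 1L, anchors = c(1, 4, 6, 9),
                              strength = 0.85) {
  set.seed(seed)
  pwm <- matrix(1 / 20, 9, 20, dimnames = list(NULL, AA_ALPHABET))
  for (p in anchors) {
    res <- sample(AA_ALPHABET, 1)
    pwm[p, ] <- (1 - strength) / 19
    pwm[p, res] <- strength
  }
  pwm
}
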