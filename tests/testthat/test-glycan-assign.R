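test_that("candidate glycans honour tolerance and isotope errors", {
  db <- small_glycan_db()
  c0 <- candidate_glycans(1216.4229, db, tol_ppm = 20)
  expect_true("HexNAc(2)Hex(5)" %in% c0$composition)
  expect_equal(c0$iso[c0$composition == "HexNAc(2)Hex(5)"][1], 0L)

  c1 <- candidate_glycans(1216.4229 + 1.00335, db, tol_ppm = 20)
  expect_true(any(c1$composition == "HexNAc(2)Hex(5)" & c1$iso == 1L))

  narrow <- db[db$mass > 2000, , drop = FALSE]
  expect_equal(nrow(candidate_glycans(500, narrow, tol_ppm = 20)), 0)
  expect_error(candidate_glycans(500, db[0, ]), "empty")
})

test_that("glycan scoring rewards evidence and penalizes mass error", {
  comp <- c(HexNAc = 2L, Hex = 5L)
  pm <- peptide_mass("VNGTKLL")
  ions <- expected_diagnostic_ions(comp, pm)
  sp <- new_spectrum("s", 800, 2, ions$mz, rep(100, nrow(ions)))
  s_full <- score_glycan(sp, "VNGTKLL", comp, ppm_error = 0)
  expect_equal(s_full, nrow(ions))      # all hits, no penalty

  # score decreases monotonically with |ppm error|
  errs <- c(0, 5, 10, 20)
  scores <- vapply(errs, function(e)
    score_glycan(sp, "VNGTKLL", comp, ppm_error = e), numeric(1))
  expect_true(all(diff(scores) < 0))

  # sialylated isobar penalized when NeuAc oxonium ions are absent
  sial <- c(HexNAc = 2L, Hex = 2L, NeuAc = 1L)
  s_sial <- score_glycan(sp, "VNGTKLL", sial, ppm_error = 0)
  nonsial <- c(HexNAc = 2L, Hex = 2L, Fuc = 2L)
  sp2_ions <- expected_diagnostic_ions(nonsial, pm)
  # spectrum lacks NeuAc ions at 274.092/292.103: sialylated candidate
  # pays w_miss for each
  expect_lt(s_sial, s_full)
})

test_that("assignment retains correct compositions and is seeded", {
  w <- tiny_search_world(seed = 51)
  db <- w$glycan_db
  seqp <- w$peptides[w$peptides$n_sequons > 0 & !w$peptides$is_decoy, ]
  set.seed(9)
  n <- 60
  tab <- data.frame(peptide = sample(seqp$sequence, n, replace = TRUE),
                    glycan = sample(db$composition, n, replace = TRUE))
  gs <- generate_spectra(tab, noise_peaks = 20, seed = 10)
  psms <- data.frame(
    scan = gs$truth$scan, peptide = gs$truth$peptide, mods = "",
    proteins = "SYN001:0-9", is_decoy = FALSE, precursor_mass = NA,
    iso = gs$truth$iso_error,
    delta_mass = gs$truth$glycan_mass + gs$truth$iso_error * 1.00335,
    hyperscore = 20, group = "glyco", n_sequons = 1,
    sequon_positions = "0")
  ga <- assign_glycans(psms, gs$spectra, db)
  a <- ga$assignments
  truth <- gs$truth$glycan[match(a$scan, gs$truth$scan)]
  expect_gt(sum(a$retained), 0.8 * n)
  expect_true(mean(a$glycan[a$retained] != truth[a$retained]) <= 0.05)
  # determinism under the fixed decoy seed
  ga2 <- assign_glycans(psms, gs$spectra, db)
  expect_identical(ga$assignments, ga2$assignments)
  # threshold 1 retains all target-winning assignments
  ga3 <- assign_glycans(psms, gs$spectra, db, q_threshold = 1)
  expect_equal(sum(ga3$assignments$retained),
               sum(!ga3$assignments$decoy_best, na.rm = TRUE))
})

test_that("glycan q-values agree with brute-force competition oracle", {
  w <- tiny_search_world(seed = 52)
  db <- w$glycan_db
  seqp <- w$peptides[w$peptides$n_sequons > 0 & !w$peptides$is_decoy, ]
  set.seed(11)
  n <- 50
  tab <- data.frame(peptide = sample(seqp$sequence, n, replace = TRUE),
                    glycan = sample(db$composition, n, replace = TRUE))
  gs <- generate_spectra(tab, noise_peaks = 40, seed = 12)
  psms <- data.frame(
    scan = gs$truth$scan, peptide = gs$truth$peptide, mods = "",
    proteins = "SYN001:0-9", is_decoy = FALSE, precursor_mass = NA,
    iso = gs$truth$iso_error,
    delta_mass = gs$truth$glycan_mass + gs$truth$iso_error * 1.00335,
    hyperscore = 20, group = "glyco", n_sequons = 1,
    sequon_positions = "0")
  ga <- assign_glycans(psms, gs$spectra, db, decoy_seed = 7L)
  a <- ga$assignments
  # oracle: recompute every competition independently
  shifts <- glycoMHC:::decoy_glycan_shifts(db$composition, seed = 7L)
  count_cols <- intersect(names(MONOSACCHARIDES), names(db))
  win_score <- numeric(nrow(a)); win_decoy <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    sp <- gs$spectra[[match(a$scan[i], gs$truth$scan)]]
    cand <- candidate_glycans(psms$delta_mass[i], db, 20)
    ts <- ds <- numeric(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      cc <- stats::setNames(as.integer(cand[j, count_cols]), count_cols)
      ts[j] <- score_glycan(sp, psms$peptide[i], cc, cand$ppm_error[j])
      ds[j] <- score_glycan(sp, psms$peptide[i], cc, cand$ppm_error[j],
                            mass_shift = shifts[[cand$composition[j]]])
    }
    win_decoy[i] <- max(ds) > max(ts)
    win_score[i] <- max(ts, ds)
  }
  expect_identical(a$decoy_best, win_decoy)
  oq <- oracle_tdc_q(win_score, win_decoy)
  oq[win_decoy] <- 1
  expect_equal(a$glycan_q, oq, tolerance = 1e-12)
})

test_that("assignment errors and empty input behave as specified", {
  db <- small_glycan_db()
  psms <- data.frame(
    scan = "missing_scan", peptide = "VNGTKLL", mods = "",
    proteins = "X:0-7", is_decoy = FALSE, precursor_mass = NA, iso = 0L,
    delta_mass = 1216.4229, hyperscore = 10, group = "glyco",
    n_sequons = 1, sequon_positions = "0")
  expect_error(assign_glycans(psms, list(), db), "missing_scan")
  out <- assign_glycans(psms[0, ], list(), db)
  expect_equal(nrow(out$assignments), 0)
})
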