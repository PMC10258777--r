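test_that("theoretical fragments: counts, y1, and the Y-ion ladder", {
  fr <- theoretical_fragments("PEPTIDE")
  expect_equal(nrow(fr), 2 * (7 - 1))
  expect_equal(fr$mz[fr$label == "y1"], 148.0604, tolerance = 1e-4)

  frg <- theoretical_fragments("PEPTIDE", glycan_mass = 1216.4229)
  pm <- peptide_mass("PEPTIDE")
  expect_equal(frg$mz[frg$label == "Y0"], pm + 1.00727646677,
               tolerance = 1e-6)
  expect_equal(frg$mz[frg$label == "Y1"], pm + 203.079373 + 1.00727646677,
               tolerance = 1e-6)
  expect_equal(nrow(frg), 12 + 8)   # backbone + 4 Y ions x 2 charges
})

test_that("hyperscore evaluates its formula and algebra", {
  # spectrum engineered so b1,b2 and y1 match with intensities 60+40, 50
  fr <- theoretical_fragments("PEPTIDE")
  b1 <- fr$mz[fr$label == "b1"]; b2 <- fr$mz[fr$label == "b2"]
  y1 <- fr$mz[fr$label == "y1"]
  sp <- new_spectrum("h", 500, 2, c(b1, b2, y1), c(60, 40, 50))
  h <- hyperscore(sp, fr, 15)
  expect_equal(h$n_b, 2L); expect_equal(h$n_y, 1L)
  expect_equal(h$score, log(2) + 0 + log(100) + log(50), tolerance = 1e-9)
  expect_equal(log(2) + log(100) + log(50), 9.2103, tolerance = 1e-4)

  # no matches -> 0
  empty <- new_spectrum("z", 500, 2, c(1000, 1100), c(5, 5))
  expect_equal(hyperscore(empty, fr, 15)$score, 0)

  # doubling matched intensities raises the score by 2 ln 2
  sp2 <- new_spectrum("h2", 500, 2, c(b1, b2, y1), 2 * c(60, 40, 50))
  expect_equal(hyperscore(sp2, fr, 15)$score - h$score, 2 * log(2),
               tolerance = 1e-9)
})

test_that("search recovers generating peptides on noise-free spectra", {
  w <- tiny_search_world(seed = 31)
  seqp <- w$peptides[!w$peptides$is_decoy & w$peptides$n_sequons > 0, ]
  plain <- w$peptides[!w$peptides$is_decoy, ]
  set.seed(5)
  tab <- data.frame(
    peptide = c(sample(plain$sequence, 30), sample(seqp$sequence, 10)),
    glycan = c(rep(NA, 30),
               sample(w$glycan_db$composition[w$glycan_db$mass < 1800], 10)))
  gs <- generate_spectra(tab, noise_peaks = 0, seed = 6)
  psms <- search_spectra(gs$spectra, w$index, w$glycan_db)
  m <- match(psms$scan, gs$truth$scan)
  expect_true(mean(psms$peptide == gs$truth$peptide[m]) >= 0.99)
  # glyco spectra recover the glycan mass through the delta
  gl <- which(!is.na(gs$truth$glycan[m]))
  expect_equal(psms$delta_mass[gl],
               gs$truth$glycan_mass[m][gl], tolerance = 1e-2)
  expect_true(all(psms$group[gl] == "glyco"))
})

test_that("gate failure prevents glyco-group PSMs", {
  w <- tiny_search_world(seed = 32)
  seqp <- w$peptides[!w$peptides$is_decoy & w$peptides$n_sequons > 0, ]
  tab <- data.frame(peptide = seqp$sequence[1],
                    glycan = "HexNAc(2)Hex(5)")
  gs <- generate_spectra(tab, noise_peaks = 0, seed = 7)
  # strip the oxonium region so the gate fails
  sp <- gs$spectra[[1]]
  keep <- sp$mz > 400
  sp2 <- new_spectrum(sp$scan, sp$pepmass, sp$charge, sp$mz[keep],
                      sp$intensity[keep])
  expect_false(oxonium_gate(sp2)$pass)
  psm <- search_spectrum(sp2, w$index, w$glycan_db, gate_pass = FALSE)
  expect_true(is.null(psm) || psm$group != "glyco")
})

test_that("search is deterministic and ties break by the stated rule", {
  w <- tiny_search_world(seed = 33)
  tab <- data.frame(peptide = w$peptides$sequence[!w$peptides$is_decoy][1:5],
                    glycan = NA)
  gs <- generate_spectra(tab, noise_peaks = 5, seed = 8)
  p1 <- search_spectra(gs$spectra, w$index, w$glycan_db)
  p2 <- search_spectra(gs$spectra, w$index, w$glycan_db)
  expect_identical(p1, p2)

  # two zero-score candidates: winner is smallest |delta|, then peptide
  sp <- new_spectrum("tie", w$index$table$mass[10] / 2 + 1.00727646677,
                     2, 1500, 1)
  psm <- search_spectrum(sp, w$index, NULL)
  if (!is.null(psm) && psm$hyperscore == 0) {
    cand <- lookup_peptides(w$index, precursor_neutral_mass(sp), 20)
    delta <- abs(precursor_neutral_mass(sp) - cand$iso * 1.00335 -
                   w$index$table$mass[cand$row])
    best <- order(delta, w$index$table$sequence[cand$row])[1]
    expect_identical(psm$peptide, w$index$table$sequence[cand$row[best]])
  }
})
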