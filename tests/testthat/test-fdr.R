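test_that("tdc_qvalues matches the worked example and edge cases", {
  q <- tdc_qvalues(c(10, 9, 8, 7, 9.5, 6), c(F, F, F, F, T, T))
  expect_equal(q[1:4], c(0, 0.25, 0.25, 0.25), tolerance = 1e-12)

  expect_equal(tdc_qvalues(c(5, 4, 3), c(F, F, F)), c(0, 0, 0))
  # all decoys above all targets -> capped at 1
  expect_equal(tdc_qvalues(c(1, 2, 9, 9.5), c(F, F, T, T)), c(1, 1, 1, 1))
  expect_error(tdc_qvalues(c(1, 2), c(TRUE, TRUE)), "target")
})

test_that("tdc_qvalues agrees with the brute-force threshold oracle", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    scores <- round(rnorm(n, 5, 2), 1)   # ties likely
    decoy <- runif(n) < 0.4
    if (all(decoy)) decoy[1] <- FALSE
    expect_equal(tdc_qvalues(scores, decoy), oracle_tdc_q(scores, decoy),
                 tolerance = 1e-12)
  }
})

test_that("score mixture: posterior behaviour and EM monotonicity", {
  set.seed(42)
  targets <- c(rnorm(400, 10, 1), rnorm(400, 5, 1))
  decoys <- rnorm(400, 5, 1)
  m <- fit_score_mixture(targets, decoys)
  expect_true(all(diff(m$loglik_trace) > -1e-6 * abs(m$loglik_trace[-1])))
  expect_gt(m$posterior(14), 0.99)
  expect_lt(m$posterior(2), 0.2)
  # monotone non-decreasing
  grid <- seq(0, 15, by = 0.1)
  expect_true(all(diff(m$posterior(grid)) >= -1e-12))
  # roughly half-half mixture recovered
  expect_equal(m$pi, 0.5, tolerance = 0.15)
  expect_equal(m$mu, 10, tolerance = 0.5)

  expect_error(fit_score_mixture(rep(5, 200), rep(5, 200)), "degenerate")
  expect_error(fit_score_mixture(rnorm(50), rnorm(200)), "at least 100")
})

test_that("group-specific filter splits by delta and is deterministic", {
  set.seed(43)
  mk <- function(delta) data.frame(
    scan = paste0("s", 1:40), delta_mass = delta,
    hyperscore = c(seq(10, 6, length.out = 20), seq(9, 5, length.out = 20)),
    is_decoy = rep(c(FALSE, TRUE), each = 20))
  psms <- rbind(mk(rep(203.08, 40)), mk(rep(0.001, 40)))
  out <- group_specific_filter(psms, cutoff_da = 145, fdr_level = 0.25)
  expect_identical(unique(out$psms$group[psms$delta_mass > 145]), "glyco")
  expect_identical(unique(out$psms$group[psms$delta_mass < 145]),
                   "nonglyco")
  # identical score lists in both groups -> identical thresholds
  expect_equal(out$thresholds[["glyco"]], out$thresholds[["nonglyco"]])
  # thresholds reproduce the accepted set exactly (idempotence)
  for (g in c("glyco", "nonglyco")) {
    sel <- out$psms$group == g & !out$psms$is_decoy
    expect_identical(out$psms$accepted[sel],
                     out$psms$hyperscore[sel] >= out$thresholds[[g]])
  }
})

test_that("peptide filter keeps best PSM per peptide and matches oracle", {
  psms <- data.frame(
    peptide = c("AAA", "AAA", "AAA", "BBB"),
    is_decoy = FALSE,
    hyperscore = c(5, 9, 7, 4))
  out <- peptide_level_filter(psms, fdr_level = 0.5)
  expect_equal(nrow(out$peptides), 2)
  expect_equal(out$peptides$hyperscore[out$peptides$peptide == "AAA"], 9)
  expect_equal(out$peptides$pep_q, c(0, 0))

  set.seed(44)
  big <- data.frame(
    peptide = sample(paste0("P", 1:60), 200, replace = TRUE),
    is_decoy = runif(200) < 0.3,
    hyperscore = rnorm(200, 6, 2))
  got <- peptide_level_filter(big, fdr_level = 0.05)
  key <- paste0(big$peptide, "|", big$is_decoy)
  oracle_best <- tapply(big$hyperscore, key, max)
  m <- match(paste0(got$peptides$peptide, "|", got$peptides$is_decoy),
             names(oracle_best))
  expect_equal(got$peptides$hyperscore, as.numeric(oracle_best[m]))
  oq <- oracle_tdc_q(got$peptides$hyperscore, got$peptides$is_decoy)
  expect_equal(got$peptides$pep_q, oq, tolerance = 1e-12)
})

test_that("protein parsimony equals exhaustive minimal set cover", {
  set.seed(45)
  for (rep in 1:25) {
    n_prot <- sample(3:8, 1)
    n_pep <- sample(4:12, 1)
    # random bipartite membership, every peptide in >= 1 protein
    membership <- lapply(seq_len(n_pep), function(i) {
      sample(seq_len(n_prot), sample(1:min(3, n_prot), 1))
    })
    peptides <- data.frame(
      peptide = paste0("pep", seq_len(n_pep)),
      proteins = vapply(membership, function(m) {
        paste0("prot", m, ":0-7", collapse = ";")
      }, character(1)),
      is_decoy = FALSE,
      hyperscore = rnorm(n_pep, 8, 1),
      posterior = runif(n_pep, 0.5, 0.99))
    out <- protein_level_filter(peptides, fdr_level = 1)
    # compare to the exhaustive minimum cover over protein *groups*
    prots <- sort(unique(unlist(lapply(membership, function(m)
      paste0("prot", m)))))
    sets <- lapply(prots, function(a) {
      which(vapply(membership, function(m) a %in% paste0("prot", m),
                   logical(1)))
    })
    setkey <- vapply(sets, paste, character(1), collapse = ",")
    sets_u <- sets[!duplicated(setkey)]
    expect_equal(nrow(out$proteins),
                 oracle_min_cover_size(sets_u, n_pep))
    # every peptide assigned to exactly one retained protein
    expect_false(anyNA(out$assignment$protein))
  }
})

test_that("protein scores favour strong multi-peptide evidence", {
  peptides <- data.frame(
    peptide = c("A1", "B1", "B2", "B3"),
    proteins = c("weak:0-7", "strong:0-7", "strong:8-15", "strong:16-23"),
    is_decoy = FALSE, hyperscore = 8,
    posterior = c(0.3, 0.95, 0.95, 0.95))
  out <- protein_level_filter(peptides, fdr_level = 1)
  s <- out$proteins
  expect_gt(s$score[s$accession == "strong"], s$score[s$accession == "weak"])
})

test_that("sequential filter only removes, never adds", {
  psms <- data.frame(
    scan = c("a", "b", "c"),
    proteins = c("P1:0-7", "P1:0-7;P2:3-10", "P3:0-7"))
  out <- sequential_protein_filter(psms, c("P2"))
  expect_identical(out$scan, "b")
  expect_true(all(out$scan %in% psms$scan))
  expect_equal(nrow(sequential_protein_filter(psms, character(0))), 0)
})

test_that("entrapment rate counts entrapment-only glyco PSMs", {
  prot <- data.frame(accession = c("H1", "E1"),
                     species_tag = c(NA, "plant"))
  psms <- data.frame(
    scan = c("a", "b", "c", "d"),
    group = c("glyco", "glyco", "glyco", "nonglyco"),
    proteins = c("H1:0-7", "E1:0-7", "H1:0-7;E1:2-9", "E1:0-7"))
  out <- entrapment_rate(psms, prot, "plant")
  expect_equal(out$rate, 1 / 3)
  expect_identical(out$offending$scan, "b")
  expect_error(entrapment_rate(psms, prot, "fungus"), "absent")
})
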