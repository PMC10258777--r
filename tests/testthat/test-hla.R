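test_that("allele assignment follows the lowest-rank rule", {
  rt <- data.frame(
    peptide = c("PEPA", "PEPA", "PEPB", "PEPB", "PEPC"),
    allele = c("DRB1*12:01", "DRB3*02:02", "DRB1*12:01", "DRB3*02:02",
               "DQB1*03:01"),
    rank = c(3.2, 15.0, 25, 40, 20.0),
    core_offset = c(1L, 2L, 0L, 0L, 3L))
  out <- assign_alleles(c("PEPA", "PEPB", "PEPC"), rt, threshold = 20)
  expect_identical(out$allele, c("DRB1*12:01", "TRASH", "DQB1*03:01"))
  expect_equal(out$core_offset, c(1L, NA_integer_, 3L))
  expect_error(assign_alleles(c("PEPA", "NOPE"), rt), "NOPE")
  # tie -> lexicographically first allele
  tie <- data.frame(peptide = "T", allele = c("B*1", "A*1"), rank = c(5, 5),
                    core_offset = 0L)
  expect_identical(assign_alleles("T", tie)$allele, "A*1")
  # pure function: rerun identical
  expect_identical(out, assign_alleles(c("PEPA", "PEPB", "PEPC"), rt))
})

test_that("core-relative positions and categories", {
  expect_equal(relative_glyco_position(12, 3)$p, 9)
  expect_identical(relative_glyco_position(12, 3)$category, "downstream")
  expect_equal(relative_glyco_position(11, 3)$p, 8)
  expect_identical(relative_glyco_position(11, 3)$category, "core")
  expect_equal(relative_glyco_position(1, 3)$p, -2)
  expect_identical(relative_glyco_position(1, 3)$category, "upstream")
  expect_error(relative_glyco_position(30, 3, peptide_length = 15),
               "outside")
  # translation equivariance
  for (c_shift in c(1, 3, 5)) {
    expect_equal(relative_glyco_position(7 + c_shift, 2 + c_shift)$p,
                 relative_glyco_position(7, 2)$p)
  }
})

test_that("Fisher exact two-sided matches enumeration and stats oracle", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisher_exact_two_sided(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 0, 0, 2), 2)),
               "non-negative")
  set.seed(61)
  for (rep in 1:100) {
    t <- matrix(rpois(4, sample(1:8, 1)), 2)
    p_ours <- fisher_exact_two_sided(t)
    p_ref <- stats::fisher.test(t)$p.value
    expect_equal(p_ours, p_ref, tolerance = 1e-8)
  }
})

test_that("motif conservation test builds the stated 2x2", {
  # identical binder fractions -> p = 1
  rt <- data.frame(
    peptide = paste0("P", 1:20),
    allele = "DRB1*01:01",
    rank = rep(c(5, 50), 10))
  glyco <- rep(c(TRUE, FALSE), each = 10)
  out <- motif_conservation_test(rt, rt$peptide, glyco)
  expect_equal(out$p_value, 1.0)

  # all glyco in trash, all nonglyco bound (n = 10 each) -> p < 0.01
  rt2 <- data.frame(
    peptide = paste0("Q", 1:20),
    allele = "DQB1*03:01",
    rank = c(rep(90, 10), rep(2, 10)))
  out2 <- motif_conservation_test(rt2, rt2$peptide,
                                  c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_lt(out2$p_value, 0.01)

  # one row per allele with both classes present
  rt3 <- rbind(rt, data.frame(peptide = paste0("R", 1:4),
                              allele = "DPB1*04:01",
                              rank = 5))
  out3 <- motif_conservation_test(rt3, c(rt$peptide, paste0("R", 1:4)),
                                  c(glyco, rep(TRUE, 4)))
  expect_equal(nrow(out3), 1)   # DP allele has glyco only -> skipped
})

test_that("gene groups parse and position summaries recount", {
  expect_identical(hla_gene_group(c("DRB1*12:01", "DQA1*05:05",
                                    "DPB1*04:01")), c("DR", "DQ", "DP"))
  expect_error(hla_gene_group("HLA-A*02:01"), "unparseable")

  asg <- data.frame(
    allele = c(rep("DPB1*04:01", 4), rep("DRB1*12:01", 5), "TRASH"),
    rel_position = c(8, 8, 8, 8, -2, 0, 9, 12, 3, 1),
    type_class = c(rep("truncated", 4), rep("high-mannose", 5), NA))
  s <- summarize_positions(asg)
  dp <- s$positions[s$positions$group == "DP", ]
  expect_equal(dp$inside_core, 1.0)
  dr <- s$positions[s$positions$group == "DR", ]
  expect_equal(dr$inside_core, 2 / 5)   # p in {-2,0,9,12,3}: 0 and 3 inside
  expect_equal(dp$inside_core + dp$outside_core, 1)
  expect_equal(s$glycan_types$truncated[s$glycan_types$group == "DP"], 1)
})

test_that("deconvolution recovers a planted motif and obeys EM", {
  pwm <- random_allele_pwm(seed = 71)
  peps <- generate_motif_peptides(list(A = pwm), n_per_allele = 120,
                                  n_background = 0, seed = 72)
  m <- deconvolve_motifs(peps$peptide, K_max = 2, runs = 3, seed = 73)
  expect_equal(m$K, 1)
  expect_gt(pwm_recovery_correlation(m$pwms[[1]], pwm), 0.9)
  expect_true(all(diff(m$loglik_trace) > -1e-6 * (abs(m$loglik_trace[-1]) + 1)))
  # reproducible under the same seed
  m2 <- deconvolve_motifs(peps$peptide, K_max = 2, runs = 3, seed = 73)
  expect_equal(m$loglik, m2$loglik)
  expect_identical(m$core_offset, m2$core_offset)

  # pure-random peptides -> trash absorbs everything
  bg <- generate_motif_peptides(list(), 0, 120, seed = 74)
  mb <- deconvolve_motifs(bg$peptide, K_max = 2, runs = 3, seed = 75)
  expect_gte(mean(mb$responsibilities[, ncol(mb$responsibilities)]), 0.9)

  expect_error(deconvolve_motifs(peps$peptide[1:30]), "at least 50")
  expect_error(deconvolve_motifs(peps$peptide[1:60], K_max = 70,
                                 runs = 1), "fewer peptides")
})
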