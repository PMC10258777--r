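test_that("FASTA reading parses headers, uppercases, and validates", {
  path <- write_tiny_fasta()
  prot <- read_fasta(path)
  expect_equal(nrow(prot), 2)
  expect_identical(prot$accession, c("sp|P1|PROT1", "sp|P2|PROT2"))
  expect_identical(prot$sequence[2], toupper("ttvnksaeeflnmsygh"))
  expect_identical(prot$species_tag, c(NA, "entrapment"))

  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.fasta")
  writeLines(c(">A x", "PEPTIDEK", ">A y", "GGGGGGG"), dup)
  expect_error(read_fasta(dup), "duplicate")
  empty <- file.path(dir, "empty.fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty))
})

test_that("decoys are full reversals with prefixed accessions", {
  prot <- data.frame(accession = c("A", "B"),
                     sequence = c("VNGTK", "ABA" ),
                     is_decoy = FALSE, species_tag = NA)
  # 'ABA' is not a valid protein but reversal is sequence-agnostic
  dec <- make_decoys(prot)
  expect_identical(dec$sequence, c("KTGNV", "ABA"))
  expect_identical(dec$accession, c("rev_A", "rev_B"))
  expect_true(all(dec$is_decoy))
  expect_equal(nrow(dec), nrow(prot))
})

test_that("sequon detection matches the N-X-S/T pattern and its mirror", {
  expect_identical(find_sequons("VNGTK")[[1]], 1L)
  expect_identical(find_sequons("NPSA")[[1]], integer(0))
  expect_identical(find_sequons("KTGNV", is_decoy = TRUE)[[1]], 1L)
  expect_identical(find_sequons("NN")[[1]], integer(0))   # too short
  # proline exclusion is switchable
  expect_identical(find_sequons("NPSA", exclude_proline = FALSE)[[1]], 0L)
  # overlapping sequons are all reported
  expect_identical(find_sequons("NNTT")[[1]], c(0L, 1L))
})

test_that("nonspecific enumeration counts, dedups, and bounds lengths", {
  prot <- data.frame(accession = "A", sequence = "ACDEFGHIKL",
                     is_decoy = FALSE, species_tag = NA)
  peps <- enumerate_nonspecific_peptides(prot, c(7, 25))
  expect_equal(nrow(peps), 4 + 3 + 2 + 1)

  short <- data.frame(accession = "S", sequence = "ACDEF",
                      is_decoy = FALSE, species_tag = NA)
  expect_equal(nrow(enumerate_nonspecific_peptides(short, c(7, 12))), 0)

  expect_error(enumerate_nonspecific_peptides(prot, c(3, 12)), "length_range")

  # dedup with merged provenance
  two <- data.frame(accession = c("A", "B"),
                    sequence = c("ACDEFGH", "ACDEFGH"),
                    is_decoy = FALSE, species_tag = NA)
  peps2 <- enumerate_nonspecific_peptides(two, c(7, 12))
  expect_equal(nrow(peps2), 1)
  expect_identical(peps2$proteins, "A:0-7;B:0-7")
  # masses consistent with residue arithmetic
  expect_equal(peps2$mass, peptide_mass("ACDEFGH"), tolerance = 1e-8)
})

test_that("decoy parity is exact for random proteomes", {
  for (seed in c(11, 12, 13)) {
    gp <- generate_proteome(6, 45, sequon_density = 0.05, seed = seed)
    prot <- rbind(gp$proteins, make_decoys(gp$proteins))
    peps <- enumerate_nonspecific_peptides(prot, c(7, 12))
    n_t <- sum(!peps$is_decoy & peps$n_sequons > 0)
    n_d <- sum(peps$is_decoy & peps$n_sequons > 0)
    expect_identical(n_t, n_d)
    # no duplicated (sequence, is_decoy)
    expect_false(anyDuplicated(paste(peps$sequence, peps$is_decoy)) > 0)
  }
})

test_that("variable-modification expansion respects the cap", {
  cand <- data.frame(sequence = "MCMK", mass = peptide_mass("MCMK"),
                     is_decoy = FALSE, proteins = "A:0-4",
                     sequon_positions = "", n_sequons = 0L, nterm = TRUE)
  # M x2, C x1, nterm: forms with 1..2 mods of {ox up to 2, cys up to 1, ac}
  ex <- expand_variable_mods(cand, max_var_mods = 2)
  expect_true(all(vapply(strsplit(ex$mods[ex$mods != ""], ";"),
                         function(x) {
                           sum(as.integer(sub("^.*@", "", x)) +
                                 (x == "acetyl_nt@0")) <= 2
                         }, logical(1))))
  expect_identical(ex$mods[1], "")
  # mass deltas consistent
  ox1 <- ex[ex$mods == "ox_M@1", ]
  expect_equal(ox1$mass, cand$mass + 15.994915, tolerance = 1e-8)
  # cap 0 disables
  ex0 <- expand_variable_mods(cand, max_var_mods = 0)
  expect_equal(nrow(ex0), 1)
})

test_that("index lookup handles isotopes, glycans, and sequon gating", {
  w <- tiny_search_world(seed = 21, n_proteins = 4, plen = 40)
  idx <- w$index
  tab <- idx$table
  # isotope-corrected match: query at peptide mass + 1.00335
  r <- 25
  hit <- lookup_peptides(idx, tab$mass[r] + 1.00335, tol_ppm = 20,
                         isotope_errors = c(0, 1, 2))
  expect_true(any(hit$row == r & hit$iso == 1))

  # glyco lookup: precursor = sequon peptide + HexNAc(2)Hex(5)
  sq <- which(tab$n_sequons > 0)[1]
  gm <- glycan_mass(c(HexNAc = 2, Hex = 5))
  gdb <- w$glycan_db
  gi <- which(gdb$composition == "HexNAc(2)Hex(5)")
  hit2 <- lookup_peptides(idx, tab$mass[sq] + gm, tol_ppm = 20,
                          glycan_masses = gdb$mass)
  expect_true(any(hit2$row == sq & hit2$glycan_idx == gi))
  # glyco lookup never returns sequon-free peptides
  expect_true(all(tab$n_sequons[hit2$row] > 0))

  expect_error(lookup_peptides(idx, 1000, tol_ppm = -1), "positive")
})

test_that("index lookup agrees with a brute-force linear scan", {
  w <- tiny_search_world(seed = 22, n_proteins = 4, plen = 40)
  idx <- w$index
  tab <- idx$table
  set.seed(99)
  queries <- runif(200, min(tab$mass), max(tab$mass) + 3)
  for (q in queries) {
    got <- lookup_peptides(idx, q, tol_ppm = 20,
                           isotope_errors = c(0, 1, 2))
    tol <- q * 20e-6
    brute <- unlist(lapply(c(0, 1, 2), function(iso) {
      which(abs(q - iso * 1.00335 - tab$mass) <= tol)
    }))
    expect_setequal(got$row, unique(brute))
  }
})
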