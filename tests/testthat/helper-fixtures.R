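# Shared fixture builders; everything is generated in code at test time.

# tiny deterministic FASTA on disk; returns the path
write_tiny_fasta <- function(dir = withr::local_tempdir(.local_envir =
                                                          parent.frame())) {
  path <- file.path(dir, "tiny.fasta")
  writeLines(c(
    ">sp|P1|PROT1 first test protein",
    "MKVNGTKLLEYANCSAQW",
    ">sp|P2|PROT2 second test protein species=entrapment",
    "ttvnksaeeflnmsygh"), path)
  path
}

# small glycan database for fast assignment tests
small_glycan_db <- function() {
  build_default_glycan_db(limits = list(
    max_counts = c(HexNAc = 3, Hex = 6, Fuc = 2, NeuAc = 2, NeuGc = 0),
    mass_range = c(145, 2500)))
}

# a minimal synthetic search world: proteome, index, glycan db
tiny_search_world <- function(seed = 3, n_proteins = 8, plen = 50,
                              length_range = c(7, 14), max_var_mods = 0) {
  gp <- generate_proteome(n_proteins, plen, sequon_density = 0.06,
                          entrapment_fraction = 0, seed = seed)
  prot <- rbind(gp$proteins, make_decoys(gp$proteins))
  peps <- enumerate_nonspecific_peptides(prot, length_range)
  idx <- build_peptide_index(peps, max_var_mods = max_var_mods)
  list(proteome = gp, proteins = prot, peptides = peps, index = idx,
       glycan_db = small_glycan_db())
}

# independent brute-force TDC q-value oracle: enumerate all thresholds
oracle_tdc_q <- function(scores, decoy) {
  n <- length(scores)
  q <- numeric(n)
  for (i in seq_len(n)) {
    # thresholds at or below this item's score
    ts <- unique(scores[scores <= scores[i]])
    fdrs <- vapply(ts, function(t) {
      d <- sum(decoy & scores >= t)
      tt <- sum(!decoy & scores >= t)
      min(1, d / max(1, tt))
    }, numeric(1))
    q[i] <- min(fdrs)
  }
  q
}

# brute-force minimum set cover size (exhaustive over all subsets)
oracle_min_cover_size <- function(sets, n_items) {
  m <- length(sets)
  for (k in 1:m) {
    for (cc in utils::combn(m, k, simplify = FALSE)) {
      covered <- rep(FALSE, n_items)
      for (j in cc) covered[sets[[j]]] <- TRUE
      if (all(covered)) return(k)
    }
  }
  m
}
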