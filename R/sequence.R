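# Protein sequence space: FASTA I/O, reversed decoys, sequon detection with
# target/decoy parity, nonspecific peptide enumeration with variable
# modifications, and a mass-sorted candidate index.

# X marks the residue between N and S/T; proline is excluded from it and the
# unknown residue X never counts, so a sequon is never reported across
# ambiguous sequence. The decoy pattern is the mirror image, which makes
# substring reversal a bijection between sequon-bearing target peptides and
# reversed-sequon-bearing decoy peptides.
.SEQUON_MID <- "[ACDEFGHIKLMNQRSTVWY]"

#' Read a protein FASTA file
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession` (full first header token),
#'   `sequence` (uppercased), `is_decoy` (FALSE), `species_tag` (parsed from
#'   a `species=<tag>` token in the description, else NA).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  acc <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1)
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  tag <- rep(NA_character_, length(acc))
  hit <- regmatches(headers, regexpr("species=[^ \t]+", headers))
  has <- grepl("species=", headers)
  tag[has] <- sub("^species=", "", hit)
  data.frame(accession = acc,
             sequence = toupper(as.character(seqs)),
             is_decoy = FALSE,
             species_tag = tag,
             stringsAsFactors = FALSE)
}

#' Write proteins to FASTA
#'
#' @param proteins data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- proteins$accession
  if ("species_tag" %in% names(proteins)) {
    has <- !is.na(proteins$species_tag)
    hdr[has] <- paste0(hdr[has], " species=", proteins$species_tag[has])
  }
  lines <- character(2 * nrow(proteins))
  lines[c(TRUE, FALSE)] <- paste0(">", hdr)
  lines[c(FALSE, TRUE)] <- proteins$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Generate reversed decoy proteins
#'
#' One decoy per target: the full sequence reversed, accession prefixed.
#'
#' @param proteins Target protein data.frame.
#' @param prefix Decoy accession prefix (default `"rev_"`).
#' @return data.frame of decoy entries (`is_decoy = TRUE`).
#' @export
make_decoys <- function(proteins, prefix = "rev_") {
  stopifnot(!any(proteins$is_decoy))
  rev_seq <- vapply(proteins$sequence, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out <- proteins
  out$accession <- paste0(prefix, proteins$accession)
  out$sequence <- rev_seq
  out$is_decoy <- TRUE
  out
}

#' Find N-glycosylation sequons
#'
#' Targets: positions i (0-based) with `N` at i, non-proline at i+1, `S`/`T`
#' at i+2. Decoys use the reversed pattern (`S`/`T`, non-proline, `N`) so
#' that reversal preserves the number of potential glycopeptides.
#'
#' @param sequence Character vector of sequences.
#' @param is_decoy Logical scalar: use the reversed pattern.
#' @param exclude_proline Exclude proline at the middle position (default
#'   TRUE; the biological motif is N-X-S/T with X != P).
#' @return A list of integer vectors (0-based positions), one per sequence.
#' @export
find_sequons <- function(sequence, is_decoy = FALSE, exclude_proline = TRUE) {
  mid <- if (exclude_proline) .SEQUON_MID else "[ACDEFGHIKLMNPQRSTVWY]"
  pat <- if (is_decoy) paste0("[ST](?=", mid, "N)")
         else paste0("N(?=", mid, "[ST])")
  res <- gregexpr(pat, sequence, perl = TRUE)
  lapply(res, function(m) {
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  })
}

#' Enumerate nonspecific peptides
#'
#' Every substring with length in `length_range`, across all proteins,
#' deduplicated by (sequence, decoy status) with merged provenance.
#' Peptides containing non-standard residues are dropped.
#'
#' @param proteins data.frame of proteins (targets and/or decoys).
#' @param length_range Length-2 integer vector within \[5, 60\]
#'   (default `c(7, 25)`, the class II setting; class I uses `c(7, 12)`).
#' @param exclude_proline Passed to [find_sequons()].
#' @return data.frame with columns `sequence`, `mass`, `is_decoy`,
#'   `proteins` (";"-separated `accession:start-end`, 0-based half-open),
#'   `sequon_positions` (","-separated 0-based indices), `n_sequons`,
#'   `nterm` (TRUE if any occurrence starts at a protein N-terminus).
#' @export
enumerate_nonspecific_peptides <- function(proteins,
                                           length_range = c(7L, 25L),
                                           exclude_proline = TRUE) {
  lo <- as.integer(length_range[1]); hi <- as.integer(length_range[2])
  if (lo < 5L || hi > 60L || lo > hi) {
    stop("length_range must be within [5, 60] and increasing")
  }
  pieces <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    s <- proteins$sequence[i]
    L <- nchar(s)
    if (L < lo) { pieces[[i]] <- NULL; next }
    starts <- integer(0); lens <- integer(0)
    for (l in lo:min(hi, L)) {
      st <- seq_len(L - l + 1L)
      starts <- c(starts, st)
      lens <- c(lens, rep.int(l, length(st)))
    }
    pieces[[i]] <- data.frame(
      sequence = substring(s, starts, starts + lens - 1L),
      start = starts - 1L,              # 0-based
      end = starts + lens - 1L,         # half-open
      accession = proteins$accession[i],
      is_decoy = proteins$is_decoy[i],
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, pieces)
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(sequence = character(0), mass = numeric(0),
                      is_decoy = logical(0), proteins = character(0),
                      sequon_positions = character(0),
                      n_sequons = integer(0), nterm = logical(0)))
  }
  ok <- !grepl("[^ACDEFGHIKLMNPQRSTVWY]", all$sequence)
  all <- all[ok, , drop = FALSE]
  key <- paste0(all$sequence, "|", all$is_decoy)
  prov <- paste0(all$accession, ":", all$start, "-", all$end)
  first <- !duplicated(key)
  uniq <- all[first, c("sequence", "is_decoy")]
  uniq$proteins <- vapply(split(prov, factor(key, levels = key[first])),
                          paste, character(1), collapse = ";")
  uniq$nterm <- vapply(split(all$start == 0L,
                             factor(key, levels = key[first])),
                       any, logical(1))
  uniq$mass <- peptide_mass(uniq$sequence)
  # sequons per distinct peptide, using the pattern matching its decoy status
  sq <- vector("list", nrow(uniq))
  for (dec in c(FALSE, TRUE)) {
    idx <- which(uniq$is_decoy == dec)
    if (length(idx) > 0) {
      sq[idx] <- find_sequons(uniq$sequence[idx], is_decoy = dec,
                              exclude_proline = exclude_proline)
    }
  }
  uniq$sequon_positions <- vapply(sq, paste, character(1), collapse = ",")
  uniq$n_sequons <- lengths(sq)
  rownames(uniq) <- NULL
  uniq[, c("sequence", "mass", "is_decoy", "proteins", "sequon_positions",
           "n_sequons", "nterm")]
}

# Expand variable modifications on enumerated peptides. Localization is
# deterministic (first eligible residues) so fragment generation is
# reproducible; protein N-terminal acetylation only on peptides that occur
# at a protein N-terminus.
expand_variable_mods <- function(candidates, max_var_mods = 2L,
                                 mods = VARIABLE_MODS) {
  if (max_var_mods < 1L || nrow(candidates) == 0) {
    candidates$mods <- ""
    return(candidates)
  }
  n_m <- vapply(gregexpr("M", candidates$sequence, fixed = TRUE),
                function(x) if (x[1] == -1L) 0L else length(x), integer(1))
  n_c <- vapply(gregexpr("C", candidates$sequence, fixed = TRUE),
                function(x) if (x[1] == -1L) 0L else length(x), integer(1))
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    base <- candidates[i, , drop = FALSE]
    base$mods <- ""
    forms <- list(base)
    for (kox in 0:min(n_m[i], max_var_mods)) {
      for (kcy in 0:min(n_c[i], max_var_mods - kox)) {
        for (ac in 0:(if (candidates$nterm[i]) 1L else 0L)) {
          if (kox + kcy + ac == 0L || kox + kcy + ac > max_var_mods) next
          f <- base
          f$mass <- base$mass + kox * mods[["ox_M"]] +
            kcy * mods[["cysteinyl"]] + ac * mods[["acetyl_nt"]]
          tags <- c(if (ac) "acetyl_nt@0",
                    if (kox) paste0("ox_M@", kox),
                    if (kcy) paste0("cysteinyl@", kcy))
          f$mods <- paste(tags, collapse = ";")
          forms[[length(forms) + 1L]] <- f
        }
      }
    }
    out[[i]] <- do.call(rbind, forms)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a mass-sorted peptide candidate index
#'
#' @param candidates data.frame from [enumerate_nonspecific_peptides()].
#' @param max_var_mods Maximum number of variable modifications per peptide
#'   (0 disables modification expansion).
#' @return An object of class `peptide_index`.
#' @export
build_peptide_index <- function(candidates, max_var_mods = 2L) {
  tab <- expand_variable_mods(candidates, max_var_mods = max_var_mods)
  ord <- order(tab$mass)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  # cached cumulative residue-mass ladders (mods applied) for fast
  # fragment generation during search
  ladders <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ladders[[i]] <- cumsum(residue_ladder(tab$sequence[i], tab$mods[i]))
  }
  structure(list(table = tab, mass = tab$mass, ladders = ladders),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat("peptide_index:", nrow(x$table), "candidate forms,",
      sum(!x$table$is_decoy), "target /", sum(x$table$is_decoy), "decoy\n")
  invisible(x)
}

#' Look up candidates for a precursor mass
#'
#' Returns candidate forms whose mass matches
#' `precursor - iso * 1.00335 - glycan` within a ppm window of the precursor
#' mass, for isotope errors `iso` and (for the glyco branch) every glycan
#' mass. Glyco lookups are restricted to sequon-bearing candidates.
#'
#' @param index A `peptide_index`.
#' @param precursor_mass Neutral precursor mass (Da).
#' @param tol_ppm Precursor tolerance in ppm (default 20).
#' @param isotope_errors Integer vector of allowed monoisotopic-peak errors
#'   (default `c(0, 1, 2)`).
#' @param glycan_masses Numeric vector of glycan masses for the glyco
#'   branch, or NULL for a non-glyco lookup.
#' @return data.frame with columns `row` (row in `index$table`), `iso`,
#'   `glycan_idx` (NA for non-glyco), `glycan_mass` (0 for non-glyco).
#' @export
lookup_peptides <- function(index, precursor_mass, tol_ppm = 20,
                            isotope_errors = c(0L, 1L, 2L),
                            glycan_masses = NULL) {
  if (tol_ppm <= 0) stop("tolerance must be positive")
  glyco <- !is.null(glycan_masses)
  g <- if (glyco) glycan_masses else 0
  gi <- if (glyco) seq_along(glycan_masses) else NA_integer_
  grid <- expand.grid(iso = isotope_errors, k = seq_along(g))
  target <- precursor_mass - grid$iso * MASS_CONSTANTS[["isotope"]] - g[grid$k]
  tol <- ppm_tol_da(precursor_mass, tol_ppm)
  lo <- findInterval(target - tol, index$mass) + 1L
  hi <- findInterval(target + tol, index$mass)
  n <- pmax(0L, hi - lo + 1L)
  if (sum(n) == 0) {
    return(data.frame(row = integer(0), iso = integer(0),
                      glycan_idx = integer(0), glycan_mass = numeric(0)))
  }
  rows <- unlist(lapply(which(n > 0), function(j) lo[j]:hi[j]))
  rep_j <- rep.int(which(n > 0), n[n > 0])
  out <- data.frame(row = rows,
                    iso = as.integer(grid$iso[rep_j]),
                    glycan_idx = if (glyco) as.integer(grid$k[rep_j])
                                 else NA_integer_,
                    glycan_mass = g[grid$k[rep_j]] * as.numeric(glyco))
  if (glyco) out <- out[index$table$n_sequons[out$row] > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
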