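# Glycan composition database: parsing, masses, default database generation,
# type classification, and TSV I/O. Compositions are plain named integer
# vectors (residue name -> count); the canonical string form is
# "HexNAc(2)Hex(5)..." in fixed residue order.

#' Construct a glycan composition
#'
#' @param counts Named integer vector (residue name -> non-negative count).
#'   At least one count must be positive; names must be known residues.
#' @param table Monosaccharide residue mass table (named numeric).
#' @return An object of class `glycan_composition`: the counts, with
#'   attributes `mass` (Da) and `type_class`.
#' @export
glycan_composition <- function(counts, table = MONOSACCHARIDES) {
  if (length(counts) == 0 || all(counts == 0)) {
    stop("glycan composition must contain at least one residue")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("glycan counts must be non-negative integers")
  }
  unknown <- setdiff(names(counts), names(table))
  if (length(unknown) > 0) {
    stop("unknown monosaccharide residue(s): ", paste(unknown, collapse = ", "))
  }
  # canonical order, zero-count residues dropped
  counts <- counts[counts > 0]
  ord <- intersect(GLYCAN_RESIDUE_ORDER, names(counts))
  extra <- setdiff(names(counts), ord)
  counts <- as.integer(counts[c(ord, extra)])
  names(counts) <- c(ord, extra)
  structure(counts,
            mass = glycan_mass(counts, table),
            type_class = classify_glycan(counts),
            class = "glycan_composition")
}

#' Monoisotopic mass of a glycan composition
#'
#' @param comp Named integer vector of residue counts (or a
#'   `glycan_composition`).
#' @param table Monosaccharide residue mass table.
#' @return Mass in Da (sum of count x residue mass).
#' @export
glycan_mass <- function(comp, table = MONOSACCHARIDES) {
  if (length(comp) == 0 || all(comp == 0)) {
    stop("glycan composition must contain at least one residue")
  }
  unknown <- setdiff(names(comp), names(table))
  if (length(unknown) > 0) {
    stop("unknown monosaccharide residue(s): ", paste(unknown, collapse = ", "))
  }
  sum(unclass(comp) * table[names(comp)])
}

#' Parse a glycan composition string
#'
#' Accepts the "Name(count)Name(count)..." form in any residue order, e.g.
#' `"HexNAc(2)Hex(5)Fuc(1)"`.
#'
#' @param text A single composition string.
#' @param table Monosaccharide residue mass table.
#' @return A `glycan_composition`.
#' @export
parse_glycan_string <- function(text, table = MONOSACCHARIDES) {
  stopifnot(is.character(text), length(text) == 1)
  pat <- "([A-Za-z]+)\\(([0-9]+)\\)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("malformed glycan string at offset 0: '", text, "'")
  # verify tokens tile the whole string; report first bad offset
  ends <- m + attr(m, "match.length") - 1L
  expect <- 1L
  for (i in seq_along(m)) {
    if (m[i] != expect) {
      stop("malformed glycan string at offset ", expect - 1L, ": '", text, "'")
    }
    expect <- ends[i] + 1L
  }
  if (expect != nchar(text) + 1L) {
    stop("malformed glycan string at offset ", expect - 1L, ": '", text, "'")
  }
  toks <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  nm <- sub(pat, "\\1", toks, perl = TRUE)
  ct <- as.integer(sub(pat, "\\2", toks, perl = TRUE))
  counts <- tapply(ct, nm, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  glycan_composition(counts, table)
}

#' Canonical string form of a glycan composition
#'
#' @param comp Named integer counts or `glycan_composition`.
#' @return A string in fixed residue order (HexNAc, Hex, Fuc, NeuAc, NeuGc).
#' @export
format_glycan <- function(comp) {
  cnt <- unclass(comp)
  cnt <- cnt[cnt > 0]
  ord <- c(intersect(GLYCAN_RESIDUE_ORDER, names(cnt)),
           setdiff(names(cnt), GLYCAN_RESIDUE_ORDER))
  paste0(ord, "(", cnt[ord], ")", collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format_glycan(x), sprintf(" [%.4f Da, %s]\n",
                                attr(x, "mass"), attr(x, "type_class")))
  invisible(x)
}

#' Classify a glycan composition into a type class
#'
#' Rules (count-based; the boundaries are configurable because composition
#' alone cannot resolve structure):
#' * high-mannose: HexNAc == 2, Hex >= `hm_min_hex`, no Fuc or sialic acids;
#' * truncated: HexNAc <= `tr_max_hexnac`, Hex <= `tr_max_hex`, no sialic
#'   acids (degraded core or smaller, fucosylated forms included);
#' * complex/hybrid: everything else (antennary HexNAc or sialylation).
#'
#' @param comp Named integer counts.
#' @param hm_min_hex Minimum Hex for high-mannose (default 4).
#' @param tr_max_hexnac,tr_max_hex Truncated thresholds (defaults 2 and 3,
#'   so the N-glycan core HexNAc(2)Hex(3) and anything smaller is truncated).
#' @return One of `"high-mannose"`, `"truncated"`, `"complex/hybrid"`.
#' @export
classify_glycan <- function(comp, hm_min_hex = 4, tr_max_hexnac = 2,
                            tr_max_hex = 3) {
  cnt <- function(nm) if (nm %in% names(comp)) unclass(comp)[[nm]] else 0L
  hexnac <- cnt("HexNAc"); hex <- cnt("Hex"); fuc <- cnt("Fuc")
  sia <- cnt("NeuAc") + cnt("NeuGc")
  if (hexnac == 2 && hex >= hm_min_hex && fuc == 0 && sia == 0) {
    "high-mannose"
  } else if (hexnac <= tr_max_hexnac && hex <= tr_max_hex && sia == 0) {
    "truncated"
  } else {
    "complex/hybrid"
  }
}

#' Generate the default glycan composition database
#'
#' Combinatorial enumeration over per-residue count limits, filtered to a
#' mass window, deduplicated, and mass-sorted. The default limits span the
#' common N-glycan composition space and always include the N-glycan core
#' HexNAc(2)Hex(3) and its singly truncated forms down to HexNAc(1).
#'
#' @param limits List with `max_counts` (named integer vector of per-residue
#'   maxima) and `mass_range` (length-2 numeric, Da).
#' @param require_hexnac Require HexNAc >= 1 (all N-glycans are attached via
#'   a HexNAc; default TRUE).
#' @return A data.frame with columns `composition` (canonical string),
#'   `mass` (Da), `type_class`, plus one count column per residue, sorted by
#'   increasing mass (ties by composition string).
#' @export
build_default_glycan_db <- function(limits = list(
                                      max_counts = c(HexNAc = 6, Hex = 10,
                                                     Fuc = 3, NeuAc = 4,
                                                     NeuGc = 0),
                                      mass_range = c(145, 4000)),
                                    require_hexnac = TRUE) {
  mc <- limits$max_counts
  if (is.null(mc) || length(mc) == 0 || all(mc == 0)) {
    stop("empty glycan limit set")
  }
  mr <- limits$mass_range
  if (is.null(mr)) mr <- c(0, Inf)
  unknown <- setdiff(names(mc), names(MONOSACCHARIDES))
  if (length(unknown) > 0) {
    stop("unknown monosaccharide residue(s): ", paste(unknown, collapse = ", "))
  }
  grid <- expand.grid(lapply(mc, function(k) 0:k), KEEP.OUT.ATTRS = FALSE)
  keep <- rowSums(grid) > 0
  if (require_hexnac && "HexNAc" %in% names(grid)) {
    keep <- keep & grid$HexNAc >= 1
  }
  grid <- grid[keep, , drop = FALSE]
  mass <- as.numeric(as.matrix(grid) %*% MONOSACCHARIDES[names(grid)])
  keep <- mass >= mr[1] & mass <= mr[2]
  grid <- grid[keep, , drop = FALSE]
  mass <- mass[keep]
  comp_str <- apply(grid, 1, function(r) {
    format_glycan(stats::setNames(as.integer(r), names(grid)))
  })
  dup <- duplicated(comp_str)
  grid <- grid[!dup, , drop = FALSE]; mass <- mass[!dup]
  comp_str <- comp_str[!dup]
  type <- apply(grid, 1, function(r) {
    classify_glycan(stats::setNames(as.integer(r), names(grid)))
  })
  db <- data.frame(composition = comp_str, mass = mass, type_class = type,
                   grid, stringsAsFactors = FALSE, row.names = NULL)
  db[order(db$mass, db$composition), , drop = FALSE] -> db
  rownames(db) <- NULL
  db
}

#' Read a glycan database TSV
#'
#' Expected columns: `composition` (required) and optionally `mass`; a
#' supplied mass is checked against the recomputed value (1e-3 Da).
#'
#' @param path TSV file path.
#' @return data.frame like [build_default_glycan_db()].
#' @export
read_glycan_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"composition" %in% names(tab)) {
    stop("glycan TSV must have a 'composition' column")
  }
  comps <- lapply(tab$composition, parse_glycan_string)
  mass <- vapply(comps, function(g) attr(g, "mass"), numeric(1))
  if ("mass" %in% names(tab)) {
    bad <- which(abs(tab$mass - mass) > 1e-3)
    if (length(bad) > 0) {
      stop("declared mass disagrees with composition for: ",
           paste(tab$composition[bad], collapse = ", "))
    }
  }
  type <- vapply(comps, function(g) attr(g, "type_class"), character(1))
  cnts <- matrix(0L, nrow = length(comps), ncol = length(GLYCAN_RESIDUE_ORDER),
                 dimnames = list(NULL, GLYCAN_RESIDUE_ORDER))
  for (i in seq_along(comps)) {
    cnts[i, names(unclass(comps[[i]]))] <- unclass(comps[[i]])
  }
  db <- data.frame(composition = vapply(comps, format_glycan, character(1)),
                   mass = mass, type_class = type, cnts,
                   stringsAsFactors = FALSE)
  db <- db[order(db$mass, db$composition), , drop = FALSE]
  rownames(db) <- NULL
  db
}

#' Write a glycan database TSV
#'
#' @param db data.frame from [build_default_glycan_db()].
#' @param path Output path.
#' @export
write_glycan_tsv <- function(db, path) {
  utils::write.table(db[, c("composition", "mass", "type_class")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
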