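# Spectrum I/O (MGF required, minimal mzML) and oxonium-ion triage.
# Spectra are assumed centroided/deisotoped; each record is a list with
# scan, pepmass (precursor m/z), charge, rtinseconds, mz, intensity.

#' Construct a spectrum record
#'
#' @param scan Scan identifier.
#' @param pepmass Precursor m/z.
#' @param charge Precursor charge (>= 1).
#' @param mz,intensity Peak list (sorted by m/z on construction).
#' @param rtinseconds Optional retention time.
#' @param charge_imputed Flag set by readers when the charge was imputed.
#' @return A spectrum record (list).
#' @export
new_spectrum <- function(scan, pepmass, charge, mz, intensity,
                         rtinseconds = NA_real_, charge_imputed = FALSE) {
  ord <- order(mz)
  list(scan = scan, pepmass = pepmass, charge = as.integer(charge),
       rtinseconds = rtinseconds, mz = mz[ord], intensity = intensity[ord],
       charge_imputed = charge_imputed)
}

#' Neutral precursor mass of a spectrum
#'
#' @param spectrum A spectrum record.
#' @return (m/z - proton) * charge, in Da.
#' @export
precursor_neutral_mass <- function(spectrum) {
  (spectrum$pepmass - MASS_CONSTANTS[["proton"]]) * spectrum$charge
}

#' Read spectra from MGF or mzML
#'
#' @param path File path.
#' @param format `"MGF"` or `"mzML"`; guessed from the extension by default.
#' @param default_charge Charge to impute (with a flag) when a scan carries
#'   none (default 2).
#' @return List of spectrum records with sorted peak lists. Records without
#'   a precursor are skipped with a warning.
#' @export
read_spectra <- function(path, format = NULL, default_charge = 2L) {
  if (is.null(format)) {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML"
              else "MGF"
  }
  switch(toupper(format),
         MGF = read_mgf(path, default_charge = default_charge),
         MZML = read_mzml(path, default_charge = default_charge),
         stop("unsupported spectrum format: ", format))
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path, default_charge = 2L) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("unbalanced BEGIN/END IONS in ", path)
  out <- vector("list", length(begins))
  skipped <- 0L
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    is_hdr <- grepl("=", block, fixed = TRUE)
    hdr <- block[is_hdr]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    pm <- getv("PEPMASS")
    if (is.na(pm)) { skipped <- skipped + 1L; next }
    pepmass <- as.numeric(strsplit(pm, "[ \t]+")[[1]][1])
    ch_raw <- getv("CHARGE")
    if (is.na(ch_raw)) {
      charge <- default_charge; imputed <- TRUE
    } else {
      charge <- as.integer(sub("\\+$", "", ch_raw)); imputed <- FALSE
    }
    scan <- getv("TITLE")
    if (is.na(scan)) scan <- paste0("scan_", k)
    rt <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    pk <- block[!is_hdr]
    pk <- pk[nzchar(pk)]
    if (length(pk) > 0) {
      m <- do.call(rbind, strsplit(trimws(pk), "[ \t]+"))
      mz <- as.numeric(m[, 1]); it <- as.numeric(m[, 2])
    } else {
      mz <- numeric(0); it <- numeric(0)
    }
    out[[k]] <- new_spectrum(scan, pepmass, charge, mz, it, rt, imputed)
  }
  if (skipped > 0) {
    warning(skipped, " scan(s) without precursor skipped in ", path)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Write spectra to MGF
#'
#' @param spectra List of spectrum records.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$scan),
                 sprintf("PEPMASS=%.6f", sp$pepmass),
                 paste0("CHARGE=", sp$charge, "+"),
                 if (!is.na(sp$rtinseconds))
                   sprintf("RTINSECONDS=%.2f", sp$rtinseconds),
                 sprintf("%.5f %.2f", sp$mz, sp$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

# Minimal mzML reader: MS2 spectra with uncompressed or zlib-compressed
# 32/64-bit little-endian m/z and intensity arrays. Covers msconvert-style
# centroided output; anything fancier should be exported to MGF first.
read_mzml <- function(path, default_charge = 2L) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrum")
  out <- list()
  skipped <- 0L
  decode <- function(bda) {
    cvs <- xml2::xml_find_all(bda, "./cvParam")
    accs <- xml2::xml_attr(cvs, "accession")
    bits <- if ("MS:1000523" %in% accs) 8L else 4L
    zlib <- "MS:1000574" %in% accs
    kind <- if ("MS:1000514" %in% accs) "mz"
            else if ("MS:1000515" %in% accs) "intensity" else "other"
    raw <- jsonlite::base64_dec(xml2::xml_text(
      xml2::xml_find_first(bda, "./binary")))
    if (zlib) raw <- memDecompress(raw, type = "gzip")
    vals <- readBin(raw, "double", n = length(raw) %/% bits, size = bits,
                    endian = "little")
    list(kind = kind, values = vals)
  }
  for (sp in nodes) {
    cvs <- xml2::xml_find_all(sp, "./cvParam")
    lv <- xml2::xml_attr(cvs, "accession")
    ms_level <- xml2::xml_attr(cvs, "value")[match("MS:1000511", lv)]
    if (!is.na(ms_level) && as.integer(ms_level) != 2L) next
    prec <- xml2::xml_find_first(
      sp, ".//selectedIonList/selectedIon")
    if (is.na(prec) || inherits(prec, "xml_missing")) {
      skipped <- skipped + 1L; next
    }
    pcv <- xml2::xml_find_all(prec, "./cvParam")
    pacc <- xml2::xml_attr(pcv, "accession")
    pval <- xml2::xml_attr(pcv, "value")
    pepmass <- as.numeric(pval[match("MS:1000744", pacc)])
    if (is.na(pepmass)) { skipped <- skipped + 1L; next }
    ch <- suppressWarnings(as.integer(pval[match("MS:1000041", pacc)]))
    imputed <- is.na(ch)
    if (imputed) ch <- default_charge
    arrays <- lapply(xml2::xml_find_all(sp, ".//binaryDataArray"), decode)
    mz <- intensity <- numeric(0)
    for (a in arrays) {
      if (a$kind == "mz") mz <- a$values
      if (a$kind == "intensity") intensity <- a$values
    }
    id <- xml2::xml_attr(sp, "id")
    out[[length(out) + 1L]] <-
      new_spectrum(id, pepmass, ch, mz, intensity, NA_real_, imputed)
  }
  if (skipped > 0) {
    warning(skipped, " spectrum(a) without precursor skipped in ", path)
  }
  out
}

#' Oxonium-ion gate
#'
#' Decides whether a spectrum shows enough glycan oxonium signal to enter
#' the glyco search branch: the summed intensity of peaks matching the panel
#' (each panel ion contributes its single most intense match within
#' tolerance) must reach `threshold_fraction` of the base peak.
#'
#' @param spectrum Spectrum record with at least one peak.
#' @param panel data.frame with columns `name`, `mz`
#'   (default [default_oxonium_panel()]).
#' @param frag_tol_ppm Fragment match tolerance in ppm (default 15).
#' @param threshold_fraction Pass threshold (default 0.10, i.e. 10% of the
#'   base peak).
#' @return List with `pass` (logical) and `fraction`.
#' @export
oxonium_gate <- function(spectrum, panel = default_oxonium_panel(),
                         frag_tol_ppm = 15, threshold_fraction = 0.10) {
  if (length(spectrum$mz) == 0) stop("empty spectrum: ", spectrum$scan)
  base <- max(spectrum$intensity)
  tol <- ppm_tol_da(panel$mz, frag_tol_ppm)
  matched <- vapply(seq_len(nrow(panel)), function(i) {
    inwin <- abs(spectrum$mz - panel$mz[i]) <= tol[i]
    if (any(inwin)) max(spectrum$intensity[inwin]) else 0
  }, numeric(1))
  fraction <- sum(matched) / base
  list(pass = fraction >= threshold_fraction, fraction = fraction)
}

#' Run the oxonium gate over many spectra
#'
#' @param spectra List of spectrum records.
#' @inheritParams oxonium_gate
#' @return data.frame with columns `scan`, `fraction`, `pass`.
#' @export
oxonium_gate_report <- function(spectra, panel = default_oxonium_panel(),
                                frag_tol_ppm = 15,
                                threshold_fraction = 0.10) {
  res <- lapply(spectra, oxonium_gate, panel = panel,
                frag_tol_ppm = frag_tol_ppm,
                threshold_fraction = threshold_fraction)
  data.frame(scan = vapply(spectra, `[[`, character(1), "scan"),
             fraction = vapply(res, `[[`, numeric(1), "fraction"),
             pass = vapply(res, `[[`, logical(1), "pass"),
             stringsAsFactors = FALSE)
}
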