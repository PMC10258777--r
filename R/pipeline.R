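# End-to-end orchestration: search -> layered FDR -> glycan assignment ->
# allele assignment and glycosite characterization, with TSV outputs and
# structured log lines at every stage.

#' Build a pipeline configuration
#'
#' All search defaults are the class II settings (see [search_config()]).
#' Unknown keys are rejected.
#'
#' @param fasta,mgf Input paths (required for [run_pipeline()]).
#' @param out_dir Output directory.
#' @param glycan_tsv Optional glycan database TSV (default database used
#'   when NULL).
#' @param rank_tsv Optional percentile-rank table TSV.
#' @param known_sites_tsv Optional known-glycosite TSV
#'   (`accession`, `site_1b`).
#' @param seed Seed for the decoy-glycan shifts.
#' @param ... Overrides of [search_config()] fields.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, mgf = NULL, out_dir = "glyco_out",
                            glycan_tsv = NULL, rank_tsv = NULL,
                            known_sites_tsv = NULL, seed = 7L, ...) {
  cfg <- list(fasta = fasta, mgf = mgf, out_dir = out_dir,
              glycan_tsv = glycan_tsv, rank_tsv = rank_tsv,
              known_sites_tsv = known_sites_tsv, seed = seed,
              search = search_config(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read/write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return A `pipeline_config` (for the reader).
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  top <- c("fasta", "mgf", "out_dir", "glycan_tsv", "rank_tsv",
           "known_sites_tsv", "seed")
  unknown <- setdiff(names(raw), c(top, "search"))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  args <- raw[intersect(top, names(raw))]
  search <- if ("search" %in% names(raw)) raw$search else list()
  do.call(pipeline_config, c(args, search))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$search <- unclass(out$search)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Glycosite rows (one per glyco PSM x target provenance) with 1-based
# protein coordinates; the reported site is the first sequon of the peptide.
psm_glycosites <- function(psms) {
  gl <- psms[psms$group == "glyco" & !psms$is_decoy &
               psms$n_sequons > 0, , drop = FALSE]
  if (nrow(gl) == 0) {
    return(data.frame(scan = character(0), peptide = character(0),
                      site_pep_0b = integer(0), accession = character(0),
                      site_1b = integer(0)))
  }
  rows <- list()
  for (i in seq_len(nrow(gl))) {
    site_pep <- as.integer(strsplit(gl$sequon_positions[i], ",")[[1]][1])
    for (prov in strsplit(gl$proteins[i], ";", fixed = TRUE)[[1]]) {
      m <- regmatches(prov, regexec("^(.*):([0-9]+)-([0-9]+)$", prov))[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        scan = gl$scan[i], peptide = gl$peptide[i],
        site_pep_0b = site_pep, accession = m[2],
        site_1b = as.integer(m[3]) + site_pep + 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate glycosites against a known-site table
#'
#' Each (protein, site) is labeled `known_site` when present in the table,
#' `known_protein_new_site` when only the protein is, and `new_protein`
#' otherwise; fractions are reported at the PSM, peptide, and site levels.
#'
#' @param final_psms Final PSM data.frame (glyco rows are annotated).
#' @param known_sites data.frame with `accession` and `site_1b` columns.
#' @return List with `sites` (per PSM x provenance, labeled) and `summary`
#'   (fractions per level).
#' @export
annotate_known_sites <- function(final_psms, known_sites) {
  if (!all(c("accession", "site_1b") %in% names(known_sites))) {
    stop("known-site table must have 'accession' and 'site_1b' columns")
  }
  sites <- psm_glycosites(final_psms)
  if (nrow(sites) == 0) {
    return(list(sites = sites,
                summary = data.frame(level = character(0),
                                     known_site = numeric(0),
                                     known_protein_new_site = numeric(0),
                                     new_protein = numeric(0))))
  }
  known_key <- paste0(known_sites$accession, "@", known_sites$site_1b)
  site_key <- paste0(sites$accession, "@", sites$site_1b)
  sites$category <- ifelse(site_key %in% known_key, "known_site",
                    ifelse(sites$accession %in% known_sites$accession,
                           "known_protein_new_site", "new_protein"))
  # best (most-known) category per PSM / peptide / distinct site
  lvl <- c("known_site", "known_protein_new_site", "new_protein")
  best_cat <- function(x) lvl[min(match(x, lvl))]
  frac <- function(keys) {
    cats <- vapply(split(sites$category, keys), best_cat, character(1))
    as.numeric(table(factor(cats, levels = lvl))) / length(cats)
  }
  summary <- rbind(
    data.frame(level = "psm", t(frac(sites$scan))),
    data.frame(level = "peptide", t(frac(sites$peptide))),
    data.frame(level = "site", t(frac(site_key))))
  names(summary)[2:4] <- lvl
  list(sites = sites, summary = summary)
}

#' Run the full pipeline
#'
#' Stages, in order: FASTA + reversed decoys -> nonspecific digestion and
#' mass index -> spectrum loading and oxonium gating -> search -> group-
#' specific PSM FDR -> peptide FDR -> protein FDR (parsimony) -> sequential
#' protein filter -> glycan assignment with q-value filter -> optional
#' allele assignment and glycosite characterization. Every stage writes a
#' TSV under `config$out_dir` and logs its counts.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config) {
  sc <- config$search
  for (f in c("fasta", "mgf")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("missing input file: ", f, " = ",
           if (is.null(config[[f]])) "NULL" else config[[f]])
    }
  }
  for (f in c("glycan_tsv", "rank_tsv", "known_sites_tsv")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("missing input file: ", f, " = ", config[[f]])
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)

  targets <- read_fasta(config$fasta)
  proteins <- rbind(targets, make_decoys(targets))
  log_stage("database", nrow(targets), " targets + ", nrow(targets),
            " decoys")
  cands <- enumerate_nonspecific_peptides(proteins, sc$length_range)
  index <- build_peptide_index(cands, max_var_mods = sc$max_var_mods)
  log_stage("digest", nrow(cands), " distinct peptides, ",
            nrow(index$table), " candidate forms")

  glycan_db <- if (is.null(config$glycan_tsv)) build_default_glycan_db()
               else read_glycan_tsv(config$glycan_tsv)
  log_stage("glycans", nrow(glycan_db), " compositions")

  spectra <- read_spectra(config$mgf)
  gate <- oxonium_gate_report(spectra, frag_tol_ppm = sc$fragment_tol_ppm,
                              threshold_fraction = sc$oxonium_threshold)
  write_tsv(gate, out("gate.tsv"))
  log_stage("gate", sum(gate$pass), "/", nrow(gate), " spectra pass")

  psms <- search_spectra(spectra, index, glycan_db, sc, gate = gate)
  write_tsv(psms, out("psm.tsv"))
  log_stage("search", nrow(psms), " PSMs (",
            sum(psms$group == "glyco" & !psms$is_decoy),
            " glyco targets)")

  gf <- group_specific_filter(psms, cutoff_da = sc$delta_cutoff,
                              fdr_level = sc$psm_fdr)
  write_tsv(gf$summary, out("filter_psm.tsv"))
  acc_psms <- gf$psms[gf$psms$accepted | gf$psms$is_decoy, , drop = FALSE]
  log_stage("psm_fdr", sum(gf$psms$accepted), " accepted (glyco ",
            gf$summary$n_accepted[gf$summary$group == "glyco"], ")")

  pf <- peptide_level_filter(acc_psms, fdr_level = sc$peptide_fdr)
  peps <- pf$peptides[pf$peptides$accepted | pf$peptides$is_decoy, ,
                      drop = FALSE]
  log_stage("peptide_fdr", sum(pf$peptides$accepted), " peptides")

  n_t <- sum(!peps$is_decoy); n_d <- sum(peps$is_decoy)
  if (n_t >= 100 && n_d >= 100 &&
      stats::sd(peps$hyperscore[!peps$is_decoy]) > 0) {
    mix <- fit_score_mixture(peps$hyperscore[!peps$is_decoy],
                             peps$hyperscore[peps$is_decoy])
    peps$posterior <- mix$posterior(peps$hyperscore)
  }
  prf <- protein_level_filter(peps, fdr_level = sc$protein_fdr)
  write_tsv(prf$proteins, out("proteins.tsv"))
  log_stage("protein_fdr", length(prf$accepted_accessions), " proteins")

  final <- sequential_protein_filter(
    gf$psms[gf$psms$accepted, , drop = FALSE], prf$accepted_accessions)
  # peptide-level survivors only
  final <- final[final$peptide %in% peps$peptide[!peps$is_decoy], ,
                 drop = FALSE]
  log_stage("sequential", nrow(final), " PSMs after protein filter")

  ga <- assign_glycans(final, spectra, glycan_db, sc,
                       decoy_seed = config$seed)
  write_tsv(ga$assignments, out("glycan_assignments.tsv"))
  glyco_final <- ga$psms
  final_all <- rbind(
    cbind(final[final$group == "nonglyco", , drop = FALSE],
          glycan = NA_character_, glycan_score = NA_real_,
          glycan_q = NA_real_, glycan_iso = NA_integer_,
          type_class = NA_character_),
    glyco_final)
  write_tsv(final_all, out("glycopsm.tsv"))
  log_stage("glycan_q", nrow(glyco_final), " glyco PSMs retained at q <= ",
            sc$glycan_q)

  results <- list(psms = psms, filter = gf, peptides = peps,
                  proteins = prf$proteins, final = final_all,
                  glycan_assignments = ga$assignments)

  if (!is.null(config$known_sites_tsv)) {
    known <- utils::read.delim(config$known_sites_tsv,
                               stringsAsFactors = FALSE)
    ann <- annotate_known_sites(final_all, known)
    write_tsv(ann$summary, out("known_sites_summary.tsv"))
    results$known_sites <- ann
    log_stage("known_sites", nrow(ann$sites), " site observations")
  }

  if (!is.null(config$rank_tsv)) {
    rank_table <- utils::read.delim(config$rank_tsv,
                                    stringsAsFactors = FALSE)
    have <- unique(final_all$peptide[final_all$peptide %in%
                                       rank_table$peptide])
    if (length(have) > 0) {
      aa <- assign_alleles(have, rank_table,
                           threshold = sc$rank_threshold)
      gl <- final_all[!is.na(final_all$glycan), , drop = FALSE]
      gl$site_pep <- vapply(strsplit(gl$sequon_positions, ","), function(x)
        as.integer(x[1]), integer(1))
      gl <- merge(gl, aa, by = "peptide")
      gl$rel_position <- ifelse(
        gl$allele == "TRASH", NA_integer_, gl$site_pep - gl$core_offset)
      gl$position_category <- ifelse(
        is.na(gl$rel_position), NA_character_,
        ifelse(gl$rel_position < 0, "upstream",
               ifelse(gl$rel_position <= 8, "core", "downstream")))
      # 1-based companions for reporting
      gl$site_pep_1b <- gl$site_pep + 1L
      gl$core_offset_1b <- gl$core_offset + 1L
      write_tsv(gl, out("assignments.tsv"))
      results$allele_assignments <- gl
      ok <- gl[gl$allele != "TRASH" & !is.na(gl$rel_position), ,
               drop = FALSE]
      if (nrow(ok) > 0) {
        smry <- summarize_positions(ok)
        write_tsv(smry$positions, out("summary.tsv"))
        results$position_summary <- smry
        log_stage("characterize", nrow(ok), " glyco PSMs with cores")
      }
    }
  }
  invisible(results)
}
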