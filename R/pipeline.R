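#' Read a pipeline configuration file
#'
#' Reads a YAML configuration driving the full analysis. Recognised keys:
#' \code{proteins_fasta}, \code{peptide_list}, \code{motif_list},
#' \code{group_map} (CSV \code{accession,group}), \code{transition_report},
#' \code{class_map} (CSV \code{peptide_sequence,protein_class}),
#' \code{elisa_table}, \code{wheat_markers}, \code{digest} (mapping with
#' \code{enzyme}, \code{max_missed_cleavages}, \code{min_length},
#' \code{proline_rule}), \code{detection_threshold}, \code{rank_margin},
#' \code{report_dir}, \code{seed}, \code{verbose}. Paths are resolved
#' relative to the configuration file's directory.
#'
#' @param path YAML file, or a list already holding the configuration.
#' @return a validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (is.list(path)) {
    cfg <- path
  } else {
    if (!file.exists(path))
      gs_config_error("configuration file not found: %s", path)
    cfg <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    for (key in c("proteins_fasta", "peptide_list", "motif_list",
                  "group_map", "transition_report", "class_map",
                  "elisa_table", "wheat_markers", "report_dir")) {
      if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]]))
        cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  defaults <- list(detection_threshold = 0, rank_margin = 3,
                   report_dir = "glutenscreen_reports", seed = 1L,
                   verbose = TRUE,
                   digest = list(enzyme = "trypsin",
                                 max_missed_cleavages = 2L, min_length = 5L,
                                 proline_rule = TRUE))
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in names(defaults$digest))
    if (is.null(cfg$digest[[k]])) cfg$digest[[k]] <- defaults$digest[[k]]
  if (!cfg$digest$enzyme %in% c("trypsin", "chymotrypsin"))
    gs_config_error("unsupported enzyme '%s'", cfg$digest$enzyme)
  for (key in c("proteins_fasta", "peptide_list", "group_map",
                "transition_report", "class_map", "elisa_table"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      gs_config_error("configured input missing: %s = %s", key, cfg[[key]])
  cfg
}

configMotifs <- function(config) {
  if (is.null(config$motif_list)) defaultMotifList()
  else readMotifList(config$motif_list)
}

readTwoColumnMap <- function(path, key, value) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(c(key, value), names(df))
  if (length(missing))
    gs_format_error("%s lacks column(s): %s", path,
                    paste(missing, collapse = ", "))
  setNames(as.character(df[[value]]), df[[key]])
}

writeManifest <- function(config, stage, counts, inputs, dir) {
  paths <- unlist(inputs)
  paths <- paths[!is.na(paths) & file.exists(paths)]
  manifest <- list(
    tool = "glutenscreen",
    version = as.character(utils::packageVersion("glutenscreen")),
    stage = stage,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[setdiff(names(config), "verbose")],
    input_checksums = as.list(tools::md5sum(paths)),
    record_counts = counts)
  path <- file.path(dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the epitope census stage
#'
#' Scans the configured protein FASTA and/or detected-peptide list against
#' the epitope motif list and writes protein- and peptide-level census
#' reports plus a run manifest to the report directory.
#'
#' @param config a configuration list or YAML path
#'   (see \code{\link{readPipelineConfig}}).
#' @return invisibly, a list with the \code{protein_census} and
#'   \code{peptide_census} \linkS4class{CensusReport}s (either may be
#'   absent).
#' @export
runCensus <- function(config) {
  config <- readPipelineConfig(config)
  op <- options(glutenscreen.verbose = isTRUE(config$verbose))
  on.exit(options(op))
  if (is.null(config$proteins_fasta) && is.null(config$peptide_list))
    gs_config_error("census needs proteins_fasta and/or peptide_list")
  motifs <- configMotifs(config)
  dir.create(config$report_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  counts <- list(motifs = length(motifs))
  if (!is.null(config$proteins_fasta)) {
    proteins <- readProteinFasta(config$proteins_fasta)
    groupMap <- if (!is.null(config$group_map))
      readTwoColumnMap(config$group_map, "accession", "group") else NULL
    gs_log("census: %d proteins", length(proteins))
    out$protein_census <- censusProteins(proteins, motifs, groupMap)
    counts$proteins <- length(proteins)
    counts$protein_hits <- nrow(censusHits(out$protein_census))
  }
  if (!is.null(config$peptide_list)) {
    peps <- readPeptideList(config$peptide_list)
    gs_log("census: %d distinct peptides", length(peps))
    if (!length(peps)) gs_log("peptide list is empty; zero-count census")
    out$peptide_census <- censusPeptides(peps, motifs)
    counts$peptides <- length(peps)
    counts$peptide_hits <- nrow(censusHits(out$peptide_census))
  }
  writeManifest(config, "census", counts,
                config[c("proteins_fasta", "peptide_list", "motif_list",
                         "group_map")], config$report_dir)
  if (!is.null(out$protein_census))
    writeCensusReport(out$protein_census,
                      file.path(config$report_dir, "protein_census"))
  if (!is.null(out$peptide_census))
    writeCensusReport(out$peptide_census,
                      file.path(config$report_dir, "peptide_census"))
  gs_log("census reports written to %s", config$report_dir)
  invisible(out)
}

#' Run the quantitation stage
#'
#' Aggregates the configured transition report into peptide quantities with
#' replicate CVs, protein-class summaries and net hordein totals, builds
#' the annotated abundance heatmap matrix, evaluates the wheat marker
#' panel, and (when an ELISA table is configured) the ELISA-versus-LC-MS
#' concordance report. All outputs plus a manifest go to the report
#' directory.
#'
#' @param config a configuration list or YAML path.
#' @return invisibly, a list with \code{peptide_quants},
#'   \code{class_summary}, \code{heatmap}, \code{wheat},
#'   \code{concordance}.
#' @export
runQuant <- function(config) {
  config <- readPipelineConfig(config)
  op <- options(glutenscreen.verbose = isTRUE(config$verbose))
  on.exit(options(op))
  if (is.null(config$transition_report))
    gs_config_error("quant needs transition_report")
  if (is.null(config$class_map))
    gs_config_error("quant needs class_map")
  dir.create(config$report_dir, showWarnings = FALSE, recursive = TRUE)
  meas <- readTransitionReport(config$transition_report)
  gs_log("quant: %d transition measurements", nrow(meas))
  quants <- quantifyPeptides(meas, config$detection_threshold)
  classMap <- readTwoColumnMap(config$class_map, "peptide_sequence",
                               "protein_class")
  summary <- summariseClasses(quants, classMap)
  motifs <- configMotifs(config)
  ann <- annotatePeptides(unique(quants$peptide_sequence), motifs)
  ann$protein_class <- unname(classMap[ann$peptide_sequence])
  hm <- heatmapMatrix(quants, ann)
  markers <- if (!is.null(config$wheat_markers))
    utils::read.csv(config$wheat_markers, stringsAsFactors = FALSE,
                    comment.char = "#")
  else defaultWheatMarkers()
  wheat <- wheatPanel(quants, markers)
  conc <- NULL
  if (!is.null(config$elisa_table)) {
    elisa <- readElisaTable(config$elisa_table)
    unmatched <- setdiff(summary$net_hordein$sample_id, elisa$sample_id)
    if (length(unmatched))
      gs_validation_error("sample id(s) in quant absent from ELISA table: %s",
                          paste(unmatched, collapse = ", "))
    conc <- elisaConcordance(elisa, summary$net_hordein,
                             rankMargin = config$rank_margin)
  }
  counts <- list(transitions = nrow(meas), peptide_quants = nrow(quants),
                 class_rows = nrow(summary$classes),
                 samples = nrow(summary$net_hordein))
  writeManifest(config, "quant", counts,
                config[c("transition_report", "class_map", "elisa_table",
                         "wheat_markers", "motif_list")], config$report_dir)
  rd <- config$report_dir
  utils::write.table(quants, file.path(rd, "peptide_quant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(summary$classes, file.path(rd, "class_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary$net_hordein, file.path(rd, "net_hordein.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeHeatmapMatrix(hm, file.path(rd, "heatmap_matrix.tsv"))
  utils::write.table(wheat, file.path(rd, "wheat_panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(conc))
    jsonlite::write_json(conc, file.path(rd, "concordance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  gs_log("quant reports written to %s", rd)
  invisible(list(peptide_quants = quants, class_summary = summary,
                 heatmap = hm, wheat = wheat, concordance = conc))
}

#' Run the complete pipeline
#'
#' Census plus quantitation, followed by a joined peptide annotation table
#' merging epitope status (R5 / immunogenic) and protein class into the
#' quant rows, written as \code{annotated_quant.tsv}.
#'
#' @param config a configuration list or YAML path.
#' @return invisibly, a list with \code{census}, \code{quant} and
#'   \code{annotated} (the joined data.frame).
#' @export
runAll <- function(config) {
  config <- readPipelineConfig(config)
  census <- if (!is.null(config$proteins_fasta) ||
                !is.null(config$peptide_list)) runCensus(config) else NULL
  quant <- runQuant(config)
  motifs <- configMotifs(config)
  ann <- annotatePeptides(unique(quant$peptide_quants$peptide_sequence),
                          motifs)
  joined <- merge(quant$peptide_quants, ann, by = "peptide_sequence",
                  sort = TRUE)
  classMap <- readTwoColumnMap(config$class_map, "peptide_sequence",
                               "protein_class")
  joined$protein_class <- unname(classMap[joined$peptide_sequence])
  joined <- joined[order(joined$sample_id, joined$peptide_sequence), ,
                   drop = FALSE]
  rownames(joined) <- NULL
  utils::write.table(joined,
                     file.path(config$report_dir, "annotated_quant.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(census = census, quant = quant, annotated = joined))
}

#' Generate a synthetic study bundle on disk
#'
#' Runs \code{\link{simulateStudy}} and writes its outputs in the exact
#' formats the pipeline consumes (FASTA, transition CSV, ELISA CSV, class
#' map CSV) plus truth tables and a ready-to-run \code{config.yaml}.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param ... passed to \code{\link{simulateStudy}}.
#' @return invisibly, the path to the written \code{config.yaml}.
#' @export
runSimulate <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulateStudy(seed = seed, ...)
  fa <- file.path(dir, "proteins.fasta")
  aa <- bundle$proteins
  names(aa) <- paste(names(aa), "simulated prolamin-like protein")
  Biostrings::writeXStringSet(aa, fa)
  utils::write.csv(bundle$transitions, file.path(dir, "transitions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$elisa, file.path(dir, "elisa.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(peptide_sequence = names(bundle$class_map),
                              protein_class = unname(bundle$class_map)),
                   file.path(dir, "class_map.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(unique(bundle$peptides$sequence),
             file.path(dir, "detected_peptides.txt"))
  utils::write.csv(bundle$truth_motifs, file.path(dir, "truth_motifs.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$truth_abundance,
                   file.path(dir, "truth_abundance.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- list(proteins_fasta = "proteins.fasta",
              peptide_list = "detected_peptides.txt",
              transition_report = "transitions.csv",
              class_map = "class_map.csv", elisa_table = "elisa.csv",
              report_dir = "reports", seed = seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
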