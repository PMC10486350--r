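#' Read an epitope motif list from file
#'
#' Reads a comma-separated motif configuration with columns \code{motif_id},
#' \code{sequence}, \code{epitope_class}, \code{source} and optionally
#' \code{min_core_match}. Missing \code{min_core_match} values default to 9
#' for DQ cores and T-cell epitopes and to the motif length for R5 motifs.
#'
#' @param path path to the CSV file. Lines starting with \code{#} are
#'   treated as comments.
#' @return An \linkS4class{EpitopeMotifList}.
#' @export
readMotifList <- function(path) {
  if (!file.exists(path))
    gs_config_error("motif list not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("motif_id", "sequence", "epitope_class")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    gs_format_error("motif list %s lacks column(s): %s", path,
                    paste(missing, collapse = ", "))
  if (is.null(df$source)) df$source <- "unspecified"
  mcm <- if ("min_core_match" %in% names(df)) {
    v <- suppressWarnings(as.integer(df$min_core_match))
    ifelse(is.na(v),
           ifelse(df$epitope_class == "R5", nchar(df$sequence), 9L), v)
  } else NULL
  EpitopeMotifList(df$motif_id, df$sequence, df$epitope_class, df$source,
                   min_core_match = mcm)
}

#' The shipped default epitope motif list
#'
#' The four R5 antibody recognition motifs (QQPFP, QQQFP, QLPFP, LQPFP) plus
#' a curated starter set of HLA-DQ2.5/DQ8 core epitopes (native, i.e.
#' non-deamidated Q-form 9-mers following the Sollid coeliac epitope
#' nomenclature) and confirmed immunogenic T-cell epitope regions, including
#' the C-hordein repeat PQQPFPQPQQPFP (IEDB epitope 226653). The DQ and
#' T-cell entries are curated from the epitope literature, not an exhaustive
#' inventory; supply your own list via \code{\link{readMotifList}} for a
#' different epitope panel.
#'
#' @return An \linkS4class{EpitopeMotifList}.
#' @export
#' @examples
#' ml <- defaultMotifList()
#' sum(epitopeClasses(ml) == "R5")  # 4
defaultMotifList <- function() {
  readMotifList(system.file("extdata", "epitope_motifs.csv",
                            package = "glutenscreen", mustWork = TRUE))
}

#' Subset a motif list to the R5 antibody motifs
#'
#' @param motifs an \linkS4class{EpitopeMotifList} (default the shipped list).
#' @return An \linkS4class{EpitopeMotifList} of the R5-class motifs.
#' @export
r5Motifs <- function(motifs = defaultMotifList()) {
  motifs[which(motifs@epitope_class == "R5")]
}

#' The shipped wheat-contamination marker panel
#'
#' Wheat-specific peptide markers used to flag wheat contamination in
#' barley-based samples. The panel is curated: it contains the HMW-glutenin
#' tryptic marker DVSPGCRPITVSPGTR together with wheat-specific peptides
#' from CM17 (Q41540), a peroxiredoxin (Q6W8Q2) and a small heat-shock
#' protein (A0A3B6JKI7) observed in barley-beer discovery proteomics. Any
#' peptide list can be supplied to \code{\link{wheatPanel}} instead.
#'
#' @return data.frame with columns \code{peptide_sequence}, \code{source}.
#' @export
defaultWheatMarkers <- function() {
  utils::read.csv(system.file("extdata", "wheat_markers.csv",
                              package = "glutenscreen", mustWork = TRUE),
                  stringsAsFactors = FALSE, comment.char = "#")
}
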