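#' Build a peptide-by-sample abundance matrix
#'
#' Arranges peptide quantities as a \code{SummarizedExperiment} with one
#' \code{"area"} assay (rows = peptides, columns = samples). Cells where a
#' peptide was not detected are \code{NA} (the distinguished missing marker,
#' rendered grey in abundance heatmaps). Row annotations (protein class,
#' enzyme, R5 and immunogenic epitope status) are carried in \code{rowData}.
#' Row and column order are deterministic: peptides sorted within protein
#' class, samples sorted by identifier.
#'
#' @param peptideQuants data.frame from \code{\link{quantifyPeptides}}.
#' @param annotations optional data.frame keyed by \code{peptide_sequence}
#'   with additional row annotation columns, e.g. the output of
#'   \code{\link{annotatePeptides}} and/or a \code{protein_class} column.
#' @return A \code{SummarizedExperiment}.
#' @export
heatmapMatrix <- function(peptideQuants, annotations = NULL) {
  peptides <- sort(unique(peptideQuants$peptide_sequence))
  samples <- sort(unique(peptideQuants$sample_id))
  m <- matrix(NA_real_, nrow = length(peptides), ncol = length(samples),
              dimnames = list(peptides, samples))
  det <- peptideQuants[peptideQuants$detected, , drop = FALSE]
  m[cbind(match(det$peptide_sequence, peptides),
          match(det$sample_id, samples))] <- det$summed_area
  rd <- S4Vectors::DataFrame(peptide_sequence = peptides, row.names = peptides)
  if (!is.null(annotations)) {
    if (!"peptide_sequence" %in% names(annotations))
      gs_validation_error("annotations must contain a peptide_sequence column")
    ann <- annotations[match(peptides, annotations$peptide_sequence), ,
                       drop = FALSE]
    for (col in setdiff(names(ann), "peptide_sequence"))
      rd[[col]] <- ann[[col]]
    if ("protein_class" %in% names(rd)) {
      ord <- order(as.character(rd$protein_class), peptides)
      m <- m[ord, , drop = FALSE]
      rd <- rd[ord, , drop = FALSE]
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(area = m), rowData = rd,
    colData = S4Vectors::DataFrame(sample_id = samples, row.names = samples))
}

#' Write a heatmap matrix with its annotation sidecar
#'
#' Writes the \code{"area"} assay as a tab-separated matrix (missing cells
#' as \code{NA}) and the row annotations as a sidecar
#' \code{<path>_annotations.tsv}.
#'
#' @param se a \code{SummarizedExperiment} from \code{\link{heatmapMatrix}}.
#' @param path output path for the matrix.
#' @return character vector of written paths, invisibly.
#' @export
writeHeatmapMatrix <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "area")
  df <- data.frame(peptide_sequence = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- paste0(sub("\\.tsv$", "", path), "_annotations.tsv")
  utils::write.table(as.data.frame(SummarizedExperiment::rowData(se)), side,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, side))
}
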