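#' Wheat-contamination marker panel
#'
#' Summarises, per sample, how many wheat-specific marker peptides were
#' detected and their total summed area, and raises a contamination flag
#' when at least one marker is present. Wheat-specific peptides in a
#' barley-based sample indicate wheat incorporated as an ingredient or as a
#' contaminant somewhere in production.
#'
#' @param peptideQuants data.frame from \code{\link{quantifyPeptides}}.
#' @param markers marker peptide sequences: a character vector or a
#'   data.frame with a \code{peptide_sequence} column (default the shipped
#'   curated panel, \code{\link{defaultWheatMarkers}}).
#' @return data.frame with columns \code{sample_id},
#'   \code{markers_detected}, \code{marker_area_total},
#'   \code{contaminated}; the per-marker long table is in the
#'   \code{"detail"} attribute.
#' @export
wheatPanel <- function(peptideQuants, markers = defaultWheatMarkers()) {
  if (is.data.frame(markers)) markers <- markers$peptide_sequence
  markers <- unique(toupper(markers))
  if (!length(markers))
    gs_validation_error("wheat marker list is empty")
  samples <- sort(unique(peptideQuants$sample_id))
  q <- peptideQuants[peptideQuants$peptide_sequence %in% markers, ,
                     drop = FALSE]
  detail <- expand.grid(sample_id = samples, peptide_sequence = markers,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(paste(detail$sample_id, detail$peptide_sequence),
             paste(q$sample_id, q$peptide_sequence))
  detail$detected <- !is.na(i) & q$detected[i]
  detail$summed_area <- ifelse(detail$detected, q$summed_area[i], 0)
  out <- do.call(rbind, lapply(split(detail, detail$sample_id), function(g)
    data.frame(sample_id = g$sample_id[1],
               markers_detected = sum(g$detected),
               marker_area_total = sum(g$summed_area),
               contaminated = any(g$detected), stringsAsFactors = FALSE)))
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "detail") <- detail[order(detail$sample_id,
                                      detail$peptide_sequence), ,
                                drop = FALSE]
  out
}
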