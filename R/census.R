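overlapLattice <- function(carrier_classes) {
  # carrier_classes: list keyed by carrier, each a character vector of
  # epitope classes hitting that carrier. Returns the full subset lattice.
  subset_of <- vapply(carrier_classes, function(cl)
    paste(sort(unique(cl)), collapse = "+"), character(1))
  tab <- table(subset_of)
  data.frame(subset = names(tab), carrier_count = as.integer(tab),
             stringsAsFactors = FALSE)
}

pooledOverlapTable <- function(carrier_classes) {
  # Pool DQ_core and immunogenic_Tcell into one "DQ or T-cell" group and
  # partition carriers into R5-only / DQ-or-Tcell-only / both.
  r5 <- vapply(carrier_classes, function(cl) "R5" %in% cl, logical(1))
  dq <- vapply(carrier_classes, function(cl)
    any(cl %in% c("DQ_core", "immunogenic_Tcell")), logical(1))
  data.frame(subset = c("R5_only", "DQ_or_Tcell_only", "both"),
             carrier_count = c(sum(r5 & !dq), sum(dq & !r5), sum(r5 & dq)),
             stringsAsFactors = FALSE)
}

buildCensus <- function(hits, target_kind, n_targets) {
  cc <- do.call(rbind, lapply(EPITOPE_CLASSES, function(cl) {
    h <- hits[hits$epitope_class == cl, , drop = FALSE]
    data.frame(epitope_class = cl, instance_count = nrow(h),
               carrier_count = length(unique(h$target_id)),
               stringsAsFactors = FALSE)
  }))
  carrier_classes <- split(hits$epitope_class, hits$target_id)
  new("CensusReport", target_kind = target_kind,
      n_targets = as.integer(n_targets), class_counts = cc,
      overlap = overlapLattice(carrier_classes),
      overlap_pooled = pooledOverlapTable(carrier_classes), hits = hits)
}

#' Protein-level epitope census
#'
#' Scans every protein for full motif occurrences (all start positions,
#' overlapping occurrences included) and tabulates, per epitope class, the
#' total number of occurrences (\emph{instances}) and the number of distinct
#' carriers. When a protein grouping is supplied (e.g. protein groups from a
#' database search), carriers are counted once per group, giving a
#' conservative carrier estimate; the default is one group per accession.
#'
#' @param proteins \code{AAStringSet} named by accession (or named character
#'   vector).
#' @param motifs an \linkS4class{EpitopeMotifList}.
#' @param groupMap optional named character vector mapping accession to
#'   group identifier; every name must be a known accession.
#' @return A \linkS4class{CensusReport} with \code{target_kind = "protein"};
#'   \code{target_id} in the hit table is the group identifier.
#' @export
#' @examples
#' prots <- c(p1 = "AAQQPFPAA", p2 = "LLQQPFPLL")
#' censusProteins(prots, r5Motifs(), groupMap = c(p1 = "g", p2 = "g"))
censusProteins <- function(proteins, motifs, groupMap = NULL) {
  seqs <- if (is(proteins, "XStringSet"))
    setNames(as.character(proteins), names(proteins)) else proteins
  if (!length(seqs))
    gs_validation_error("protein collection is empty")
  accs <- names(seqs)
  if (is.null(groupMap)) {
    groupMap <- setNames(accs, accs)
  } else {
    unknown <- setdiff(names(groupMap), accs)
    if (length(unknown))
      gs_validation_error("group map references unknown accession(s): %s",
                          paste(unknown, collapse = ", "))
    missing <- setdiff(accs, names(groupMap))
    groupMap <- c(groupMap, setNames(missing, missing))
  }
  hits <- scanProteins(seqs, motifs)
  hits$accession <- hits$target_id
  hits$target_id <- unname(groupMap[hits$accession])
  hits <- hits[order(hits$target_id, hits$accession, hits$position,
                     hits$motif_id), , drop = FALSE]
  rownames(hits) <- NULL
  buildCensus(hits, "protein", length(unique(groupMap)))
}

#' Peptide-level intact-epitope census
#'
#' Counts, per epitope class, the distinct detected peptide sequences that
#' carry at least one intact epitope core (the >= 9 contiguous residue
#' criterion for DQ cores and T-cell epitopes; the full motif for R5).
#' Duplicate peptide sequences are counted once: the same immunogenic
#' peptide often maps to multiple homologous prolamins.
#'
#' @param peptides character vector of peptide sequences (deduplicated
#'   internally).
#' @param motifs an \linkS4class{EpitopeMotifList}.
#' @return A \linkS4class{CensusReport} with \code{target_kind = "peptide"}.
#'   \code{instance_count} is the total number of intact motif hits,
#'   \code{carrier_count} the number of distinct peptides with >= 1 hit.
#' @export
#' @examples
#' censusPeptides(c("IIPQQPQQPFPL", "AAAAA"), defaultMotifList())
censusPeptides <- function(peptides, motifs) {
  peptides <- unique(toupper(peptides))
  if (!length(peptides)) {
    return(buildCensus(emptyHits(), "peptide", 0L))
  }
  hits <- do.call(rbind, lapply(peptides, function(p) intactCoreHits(p, motifs)))
  if (is.null(hits)) hits <- emptyHits()
  rownames(hits) <- NULL
  buildCensus(hits, "peptide", length(peptides))
}

#' Write census report tables
#'
#' Writes the class counts, the overlap lattice, the pooled overlap and the
#' hit table of a \linkS4class{CensusReport} as tab-separated files sharing
#' a path prefix.
#'
#' @param census a \linkS4class{CensusReport}.
#' @param prefix output path prefix; files
#'   \code{<prefix>_class_counts.tsv}, \code{<prefix>_overlap.tsv},
#'   \code{<prefix>_overlap_pooled.tsv}, \code{<prefix>_hits.tsv} are
#'   written.
#' @return character vector of the written paths, invisibly.
#' @export
writeCensusReport <- function(census, prefix) {
  stopifnot(is(census, "CensusReport"))
  paths <- c(class_counts = paste0(prefix, "_class_counts.tsv"),
             overlap = paste0(prefix, "_overlap.tsv"),
             overlap_pooled = paste0(prefix, "_overlap_pooled.tsv"),
             hits = paste0(prefix, "_hits.tsv"))
  utils::write.table(classCounts(census), paths["class_counts"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(overlapCounts(census), paths["overlap"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pooledOverlap(census), paths["overlap_pooled"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(censusHits(census), paths["hits"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
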