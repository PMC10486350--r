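#' Scan a sequence for full epitope motif occurrences
#'
#' Reports every occurrence of every motif, including overlapping
#' occurrences (prolamin repeat regions make overlaps common, and dropping
#' them would bias censuses). Matching is exact: the ambiguous residue X in
#' the target never matches a motif letter. Hits are ordered by
#' (position, motif_id).
#'
#' @param sequence a single amino-acid string.
#' @param motifs an \linkS4class{EpitopeMotifList}.
#' @param targetId identifier recorded in the hit table.
#' @param targetKind \code{"protein"} or \code{"peptide"}.
#' @return data.frame with columns \code{motif_id}, \code{epitope_class},
#'   \code{target_id}, \code{target_kind}, \code{position},
#'   \code{matched_span}, \code{intact} (always \code{TRUE} here: full-motif
#'   matches are intact by definition).
#' @export
#' @examples
#' ml <- EpitopeMotifList("r5_QQPFP", "QQPFP", "R5", "Osman 2001")
#' scanSequence("QPQQPFPQPQQPFPL", ml)  # hits at positions 3 and 10
scanSequence <- function(sequence, motifs, targetId = "target",
                         targetKind = c("protein", "peptide")) {
  targetKind <- match.arg(targetKind)
  if (!is(motifs, "EpitopeMotifList") || length(motifs) == 0L)
    gs_config_error("motif list is empty or not an EpitopeMotifList")
  sequence <- toupper(sequence)
  checkAASequences(sequence, ids = targetId, what = "target sequence")
  subj <- Biostrings::AAString(sequence)
  rows <- lapply(seq_len(length(motifs)), function(k) {
    pat <- motifs@sequence[k]
    if (nchar(pat) > nchar(sequence)) return(NULL)
    st <- Biostrings::start(Biostrings::matchPattern(pat, subj))
    if (!length(st)) return(NULL)
    data.frame(motif_id = motifs@motif_id[k],
               epitope_class = motifs@epitope_class[k],
               target_id = targetId, target_kind = targetKind,
               position = as.integer(st), matched_span = pat,
               intact = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(emptyHits())
  out <- out[order(out$position, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyHits <- function() {
  data.frame(motif_id = character(0), epitope_class = character(0),
             target_id = character(0), target_kind = character(0),
             position = integer(0), matched_span = character(0),
             intact = logical(0), stringsAsFactors = FALSE)
}

#' Scan a protein collection
#'
#' Applies \code{\link{scanSequence}} to every sequence of an
#' \code{AAStringSet} (or named character vector).
#'
#' @param proteins \code{AAStringSet} named by accession, or a named
#'   character vector.
#' @param motifs an \linkS4class{EpitopeMotifList}.
#' @return combined hit data.frame (see \code{\link{scanSequence}}).
#' @export
scanProteins <- function(proteins, motifs) {
  seqs <- if (is(proteins, "XStringSet"))
    setNames(as.character(proteins), names(proteins)) else proteins
  if (is.null(names(seqs)))
    gs_validation_error("protein sequences must be named by accession")
  out <- lapply(names(seqs), function(acc)
    scanSequence(seqs[[acc]], motifs, targetId = acc, targetKind = "protein"))
  res <- do.call(rbind, out)
  if (is.null(res)) emptyHits() else res
}

#' Intact-core epitope hits in a peptide
#'
#' Implements the intact-core criterion for peptide-level immunogenicity:
#' for each motif, the longest contiguous substring of the motif present in
#' the peptide is found, and a hit is emitted only when its length reaches
#' the motif's \code{min_core_match} (9 residues for HLA-DQ cores and
#' confirmed T-cell epitopes, the full motif for R5). A peptide that was
#' cleaved inside an epitope but retains a 9-residue core region is still
#' immunogenic, which this criterion captures.
#'
#' Ties in span length are broken deterministically: the leftmost qualifying
#' motif substring, at its first occurrence in the peptide.
#'
#' @param peptideSequence a single peptide sequence.
#' @param motifs an \linkS4class{EpitopeMotifList}.
#' @param targetId identifier recorded in the hit table (default the
#'   peptide sequence itself).
#' @return hit data.frame as in \code{\link{scanSequence}}, with
#'   \code{matched_span} the retained motif core and \code{intact}
#'   \code{TRUE} for every emitted hit.
#' @export
#' @examples
#' ml <- EpitopeMotifList("iedb_226653", "PQQPFPQPQQPFP", "immunogenic_Tcell",
#'                        "IEDB 226653")
#' intactCoreHits("QPQQPFPQPQQPFPL", ml)  # 13-residue intact core
intactCoreHits <- function(peptideSequence, motifs, targetId = peptideSequence) {
  if (!is(motifs, "EpitopeMotifList") || length(motifs) == 0L)
    gs_config_error("motif list is empty or not an EpitopeMotifList")
  peptideSequence <- toupper(peptideSequence)
  checkAASequences(peptideSequence, ids = targetId, what = "peptide sequence")
  rows <- lapply(seq_len(length(motifs)), function(k) {
    motif <- motifs@sequence[k]
    mlen <- nchar(motif)
    need <- motifs@min_core_match[k]
    longest <- min(mlen, nchar(peptideSequence))
    if (longest < need) return(NULL)
    best <- NULL
    for (len in seq(from = longest, by = -1L, to = need)) {
      for (off in seq_len(mlen - len + 1L)) {
        core <- substr(motif, off, off + len - 1L)
        pos <- regexpr(core, peptideSequence, fixed = TRUE)
        if (pos > 0L) {
          best <- list(core = core, pos = as.integer(pos))
          break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) return(NULL)
    data.frame(motif_id = motifs@motif_id[k],
               epitope_class = motifs@epitope_class[k],
               target_id = targetId, target_kind = "peptide",
               position = best$pos, matched_span = best$core,
               intact = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(emptyHits())
  out <- out[order(out$position, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate peptides with epitope status
#'
#' Per-peptide R5 and immunogenic flags of the kind used to annotate
#' targeted-quantitation heatmaps: \code{r5_positive} when the peptide
#' contains a full R5 motif, \code{immunogenic_positive} when it carries an
#' intact (>= \code{min_core_match}) core of any DQ or T-cell epitope.
#'
#' @param peptides character vector of peptide sequences.
#' @param motifs an \linkS4class{EpitopeMotifList}.
#' @return data.frame with columns \code{peptide_sequence},
#'   \code{r5_positive}, \code{immunogenic_positive}.
#' @export
#' @examples
#' annotatePeptides("IIPQQPQQPFPL", defaultMotifList())
annotatePeptides <- function(peptides, motifs = defaultMotifList()) {
  peptides <- toupper(peptides)
  r5 <- motifs[which(motifs@epitope_class == "R5")]
  imm <- motifs[which(motifs@epitope_class != "R5")]
  r5_pos <- vapply(peptides, function(p)
    length(r5) > 0L && nrow(scanSequence(p, r5, targetId = p,
                                         targetKind = "peptide")) > 0L,
    logical(1))
  imm_pos <- vapply(peptides, function(p)
    length(imm) > 0L && nrow(intactCoreHits(p, imm)) > 0L, logical(1))
  data.frame(peptide_sequence = peptides, r5_positive = unname(r5_pos),
             immunogenic_positive = unname(imm_pos), stringsAsFactors = FALSE)
}
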