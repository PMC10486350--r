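#' @import methods
NULL

#' Digestion parameters
#'
#' Parameters for in silico enzymatic digestion. Trypsin cleaves C-terminal
#' to K or R; chymotrypsin (broad specificity) C-terminal to F, W, Y, L or M.
#' With \code{prolineRule = TRUE} a candidate site immediately followed by
#' proline is suppressed: it is not cleaved and does not count as a missed
#' cleavage. The ambiguous residue X never acts as a cleavage residue.
#'
#' @slot enzyme character, \code{"trypsin"} or \code{"chymotrypsin"}.
#' @slot residues character vector of cleavage residues (configurable for
#'   chymotrypsin; fixed to K/R for trypsin).
#' @slot maxMissedCleavages integer, maximum internal cleavage sites retained
#'   in a reported peptide (0--5).
#' @slot minLength integer, minimum reported peptide length.
#' @slot prolineRule logical, suppress cleavage before proline.
#'
#' @export
setClass("DigestParams",
  representation(enzyme = "character",
                 residues = "character",
                 maxMissedCleavages = "integer",
                 minLength = "integer",
                 prolineRule = "logical"))

setValidity("DigestParams", function(object) {
  msgs <- character(0)
  if (!object@enzyme %in% c("trypsin", "chymotrypsin"))
    msgs <- c(msgs, sprintf("unknown enzyme '%s'", object@enzyme))
  if (length(object@maxMissedCleavages) != 1L ||
      is.na(object@maxMissedCleavages) ||
      object@maxMissedCleavages < 0L || object@maxMissedCleavages > 5L)
    msgs <- c(msgs, "maxMissedCleavages must be a single integer in 0..5")
  if (length(object@minLength) != 1L || is.na(object@minLength) ||
      object@minLength < 1L)
    msgs <- c(msgs, "minLength must be a single integer >= 1")
  if (!all(object@residues %in% AA_LETTERS))
    msgs <- c(msgs, "cleavage residues must be standard amino-acid letters")
  if (length(msgs)) msgs else TRUE
})

#' Construct digestion parameters
#'
#' @param enzyme \code{"trypsin"} or \code{"chymotrypsin"}.
#' @param maxMissedCleavages maximum missed cleavages (default 2).
#' @param minLength minimum peptide length (default 5).
#' @param prolineRule suppress cleavage before proline (default \code{TRUE}).
#' @param residues cleavage residue set; defaults to K/R for trypsin and
#'   F/W/Y/L/M for chymotrypsin. Only the chymotrypsin set is meant to be
#'   customised (e.g. to drop M for a narrow specificity).
#'
#' @return A \linkS4class{DigestParams} object.
#' @export
#' @examples
#' DigestParams("trypsin")
#' DigestParams("chymotrypsin", residues = c("F", "W", "Y", "L"))
DigestParams <- function(enzyme = c("trypsin", "chymotrypsin"),
                         maxMissedCleavages = 2L, minLength = 5L,
                         prolineRule = TRUE, residues = NULL) {
  if (length(enzyme) != 1L || !enzyme %in% c("trypsin", "chymotrypsin"))
    gs_config_error("unknown enzyme '%s' (use 'trypsin' or 'chymotrypsin')",
                    paste(enzyme, collapse = "/"))
  if (is.null(residues))
    residues <- switch(enzyme,
                       trypsin = c("K", "R"),
                       chymotrypsin = c("F", "W", "Y", "L", "M"))
  new("DigestParams", enzyme = enzyme, residues = toupper(residues),
      maxMissedCleavages = as.integer(maxMissedCleavages),
      minLength = as.integer(minLength), prolineRule = isTRUE(prolineRule))
}

setMethod("show", "DigestParams", function(object) {
  cat(sprintf("DigestParams: %s (cleave after %s%s), missed cleavages <= %d, length >= %d\n",
              object@enzyme, paste(object@residues, collapse = "/"),
              if (object@prolineRule) ", not before P" else "",
              object@maxMissedCleavages, object@minLength))
})

#' Epitope motif list
#'
#' A collection of immunogenic or antibody-recognition sequence motifs used
#' for epitope scanning: R5 antibody motifs (5-mers recognised by the R5
#' monoclonal antibody used in regulatory gluten ELISAs), HLA-DQ 9-residue
#' core epitopes, and longer confirmed T-cell epitope regions. Each motif
#' carries \code{min_core_match}, the number of contiguous motif residues
#' that must survive intact in a peptide for a peptide-level hit: 9 for
#' DQ cores and T-cell epitopes (the intact-core criterion), the full motif
#' length for R5 motifs.
#'
#' @slot motif_id character, unique identifiers.
#' @slot sequence character, amino-acid motif sequences (length >= 5).
#' @slot epitope_class factor-like character: \code{"R5"}, \code{"DQ_core"}
#'   or \code{"immunogenic_Tcell"}.
#' @slot source character, literature source for each motif.
#' @slot min_core_match integer, intact-core threshold per motif.
#'
#' @seealso \code{\link{defaultMotifList}}, \code{\link{readMotifList}}
#' @export
setClass("EpitopeMotifList",
  representation(motif_id = "character",
                 sequence = "character",
                 epitope_class = "character",
                 source = "character",
                 min_core_match = "integer"))

setValidity("EpitopeMotifList", function(object) {
  n <- length(object@motif_id)
  msgs <- character(0)
  if (length(object@sequence) != n || length(object@epitope_class) != n ||
      length(object@source) != n || length(object@min_core_match) != n)
    return("all slots must have equal length")
  if (anyDuplicated(object@motif_id))
    msgs <- c(msgs, "motif_id values must be unique")
  if (anyDuplicated(paste(object@sequence, object@epitope_class)))
    msgs <- c(msgs, "duplicate (sequence, class) pairs are not allowed")
  if (!all(object@epitope_class %in% EPITOPE_CLASSES))
    msgs <- c(msgs, sprintf("epitope_class must be one of: %s",
                            paste(EPITOPE_CLASSES, collapse = ", ")))
  bad <- grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"),
               object@sequence)
  if (any(bad))
    msgs <- c(msgs, sprintf("invalid residue letters in motif(s): %s",
                            paste(object@motif_id[bad], collapse = ", ")))
  short <- nchar(object@sequence) < 5L
  if (any(short))
    msgs <- c(msgs, sprintf("motif sequences must be >= 5 residues: %s",
                            paste(object@motif_id[short], collapse = ", ")))
  dq <- object@epitope_class == "DQ_core"
  if (any(dq & (nchar(object@sequence) != 9L | object@min_core_match != 9L)))
    msgs <- c(msgs, "DQ_core motifs must be 9-mers with min_core_match 9")
  tc <- object@epitope_class == "immunogenic_Tcell"
  if (any(tc & object@min_core_match != 9L))
    msgs <- c(msgs, "immunogenic_Tcell motifs must have min_core_match 9")
  r5 <- object@epitope_class == "R5"
  if (any(r5 & object@min_core_match != nchar(object@sequence)))
    msgs <- c(msgs, "R5 motifs require the full motif intact (min_core_match = length)")
  if (length(msgs)) msgs else TRUE
})

#' Construct an epitope motif list
#'
#' @param motif_id unique motif identifiers.
#' @param sequence amino-acid motif sequences.
#' @param epitope_class one of \code{"R5"}, \code{"DQ_core"},
#'   \code{"immunogenic_Tcell"} per motif (recycled if length 1).
#' @param source literature source strings (recycled if length 1).
#' @param min_core_match intact-core thresholds; defaults to 9 for DQ cores
#'   and T-cell epitopes and to the motif length for R5 motifs.
#'
#' @return An \linkS4class{EpitopeMotifList}.
#' @export
#' @examples
#' EpitopeMotifList(c("r5_QQPFP"), c("QQPFP"), "R5", "Osman 2001")
EpitopeMotifList <- function(motif_id, sequence, epitope_class,
                             source = "unspecified", min_core_match = NULL) {
  n <- length(motif_id)
  sequence <- toupper(sequence)
  epitope_class <- rep_len(as.character(epitope_class), n)
  source <- rep_len(as.character(source), n)
  bad <- grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"), sequence)
  if (any(bad))
    gs_validation_error("invalid residue letters in motif(s): %s",
                        paste(motif_id[bad], collapse = ", "))
  if (is.null(min_core_match))
    min_core_match <- ifelse(epitope_class == "R5", nchar(sequence), 9L)
  new("EpitopeMotifList", motif_id = as.character(motif_id),
      sequence = sequence, epitope_class = epitope_class, source = source,
      min_core_match = as.integer(min_core_match))
}

#' @describeIn EpitopeMotifList-class number of motifs
#' @param x an \code{EpitopeMotifList}
#' @export
setMethod("length", "EpitopeMotifList", function(x) length(x@motif_id))

#' @describeIn EpitopeMotifList-class subset motifs
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "EpitopeMotifList", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@motif_id)
  initialize(x, motif_id = x@motif_id[i], sequence = x@sequence[i],
             epitope_class = x@epitope_class[i], source = x@source[i],
             min_core_match = x@min_core_match[i])
})

#' Coerce an EpitopeMotifList to data.frame
#' @param x an \code{EpitopeMotifList}
#' @param ... ignored
#' @export
#' @method as.data.frame EpitopeMotifList
as.data.frame.EpitopeMotifList <- function(x, ...) {
  data.frame(motif_id = x@motif_id, sequence = x@sequence,
             epitope_class = x@epitope_class, source = x@source,
             min_core_match = x@min_core_match, stringsAsFactors = FALSE)
}
setMethod("as.data.frame", "EpitopeMotifList", as.data.frame.EpitopeMotifList)

setMethod("show", "EpitopeMotifList", function(object) {
  tab <- table(factor(object@epitope_class, levels = EPITOPE_CLASSES))
  cat(sprintf("EpitopeMotifList with %d motifs (%s)\n", length(object),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  df <- as.data.frame(object)
  print(utils::head(df, 8), row.names = FALSE)
  if (nrow(df) > 8) cat(sprintf("... and %d more\n", nrow(df) - 8))
})

#' Accessors for EpitopeMotifList
#'
#' @param x an \linkS4class{EpitopeMotifList}
#' @return \code{motifIds}, \code{motifSequences} and \code{epitopeClasses}
#'   return character vectors; \code{minCoreMatch} an integer vector.
#' @name motif-accessors
NULL

#' @rdname motif-accessors
#' @export
motifIds <- function(x) x@motif_id
#' @rdname motif-accessors
#' @export
motifSequences <- function(x) setNames(x@sequence, x@motif_id)
#' @rdname motif-accessors
#' @export
epitopeClasses <- function(x) setNames(x@epitope_class, x@motif_id)
#' @rdname motif-accessors
#' @export
minCoreMatch <- function(x) setNames(x@min_core_match, x@motif_id)

#' Epitope census report
#'
#' Result of a protein- or peptide-level epitope census: per-class instance
#' and carrier counts, the carrier overlap partition over epitope classes,
#' and the underlying hit table.
#'
#' @slot target_kind \code{"protein"} or \code{"peptide"}.
#' @slot n_targets number of distinct targets scanned (after grouping /
#'   deduplication).
#' @slot class_counts data.frame with columns \code{epitope_class},
#'   \code{instance_count}, \code{carrier_count}.
#' @slot overlap data.frame over the full subset lattice of epitope classes
#'   (columns \code{subset}, \code{carrier_count}), plus the pooled
#'   R5-versus-(DQ or T-cell) partition in \code{overlap_pooled}.
#' @slot overlap_pooled data.frame with rows \code{R5_only},
#'   \code{DQ_or_Tcell_only}, \code{both}.
#' @slot hits data.frame of individual hits.
#'
#' @export
setClass("CensusReport",
  representation(target_kind = "character",
                 n_targets = "integer",
                 class_counts = "data.frame",
                 overlap = "data.frame",
                 overlap_pooled = "data.frame",
                 hits = "data.frame"))

setValidity("CensusReport", function(object) {
  cc <- object@class_counts
  if (any(cc$carrier_count > cc$instance_count))
    return("carrier_count cannot exceed instance_count")
  TRUE
})

setMethod("show", "CensusReport", function(object) {
  cat(sprintf("CensusReport (%s level): %d targets, %d hits\n",
              object@target_kind, object@n_targets, nrow(object@hits)))
  print(object@class_counts, row.names = FALSE)
  cat("Carrier overlap (R5 vs DQ/T-cell):\n")
  print(object@overlap_pooled, row.names = FALSE)
})

#' Accessors for CensusReport
#'
#' @param x a \linkS4class{CensusReport}
#' @return \code{classCounts}, \code{overlapCounts}, \code{pooledOverlap} and
#'   \code{censusHits} return data.frames.
#' @name census-accessors
NULL

#' @rdname census-accessors
#' @export
classCounts <- function(x) x@class_counts
#' @rdname census-accessors
#' @export
overlapCounts <- function(x) x@overlap
#' @rdname census-accessors
#' @export
pooledOverlap <- function(x) x@overlap_pooled
#' @rdname census-accessors
#' @export
censusHits <- function(x) x@hits
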