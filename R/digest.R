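#' Cleavage site positions
#'
#' Positions \code{i} such that the peptide bond after residue \code{i} is
#' cleaved under the given enzyme rule. With the proline rule active, a
#' candidate site immediately followed by P is suppressed entirely (it is
#' not a site and does not count toward missed cleavages). The terminal
#' residue is never a site. X never matches a cleavage residue.
#'
#' @param sequence a single amino-acid string.
#' @param params a \linkS4class{DigestParams}.
#' @return integer vector of cleavage positions (possibly empty).
#' @export
#' @examples
#' cleavageSites("MKAAARPLK", DigestParams("trypsin"))  # 2 (RP suppressed)
cleavageSites <- function(sequence, params) {
  stopifnot(is(params, "DigestParams"))
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2L) return(integer(0))
  cand <- which(res[-n] %in% params@residues)
  if (params@prolineRule)
    cand <- cand[res[cand + 1L] != "P"]
  cand
}

#' In silico enzymatic digestion
#'
#' Digests protein sequences with trypsin or chymotrypsin cleavage rules and
#' returns every peptide spanning at most \code{maxMissedCleavages} internal
#' sites with length at least \code{minLength}, with 1-based coordinates in
#' the parent. Order is deterministic by (parent, start, end).
#'
#' @param x a character vector of sequences (named by accession), a single
#'   sequence, or an \code{AAStringSet} as returned by
#'   \code{\link{readProteinFasta}}.
#' @param params a \linkS4class{DigestParams}.
#' @return data.frame with columns \code{sequence}, \code{parent_accession},
#'   \code{start}, \code{end}, \code{missed_cleavages}, \code{enzyme}.
#' @export
#' @examples
#' inSilicoDigest(c(prot = "MKAAARPLK"),
#'                DigestParams("trypsin", maxMissedCleavages = 0,
#'                             minLength = 1))
setGeneric("inSilicoDigest", function(x, params) standardGeneric("inSilicoDigest"))

#' @rdname inSilicoDigest
#' @export
setMethod("inSilicoDigest", "character", function(x, params) {
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  checkAASequences(toupper(x), ids = ids, what = "protein sequence")
  out <- lapply(seq_along(x), function(i)
    digestOne(toupper(x[[i]]), ids[i], params))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- emptyDigest()
  rownames(res) <- NULL
  res
})

#' @rdname inSilicoDigest
#' @export
setMethod("inSilicoDigest", "AAStringSet", function(x, params) {
  inSilicoDigest(setNames(as.character(x), names(x)), params)
})

emptyDigest <- function() {
  data.frame(sequence = character(0), parent_accession = character(0),
             start = integer(0), end = integer(0),
             missed_cleavages = integer(0), enzyme = character(0),
             stringsAsFactors = FALSE)
}

digestOne <- function(sequence, accession, params) {
  stopifnot(is(params, "DigestParams"))
  sites <- cleavageSites(sequence, params)
  bounds <- c(0L, sites, nchar(sequence))
  nfrag <- length(bounds) - 1L
  rows <- vector("list", 0L)
  maxmc <- min(params@maxMissedCleavages, nfrag - 1L)
  for (i in seq_len(nfrag)) {
    for (m in 0:maxmc) {
      j <- i + m
      if (j > nfrag) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      if (end - start + 1L < params@minLength) next
      rows[[length(rows) + 1L]] <- list(
        sequence = substr(sequence, start, end),
        parent_accession = accession, start = start, end = end,
        missed_cleavages = m, enzyme = params@enzyme)
    }
  }
  if (!length(rows)) return(NULL)
  res <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  res[order(res$start, res$end), , drop = FALSE]
}
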