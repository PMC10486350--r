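#' Read protein sequences from FASTA
#'
#' Reads a protein FASTA file into an \code{\link[Biostrings]{AAStringSet}}.
#' Headers are parsed into an accession (the first whitespace-delimited
#' token; UniProt-style \code{db|ACC|name} tokens are reduced to \code{ACC})
#' and a free-text description, stored in the element metadata columns.
#' Sequences are uppercased and stop characters (\code{*}) stripped.
#'
#' @param path path to a FASTA file.
#' @param proteinClass optional protein class annotation applied to all
#'   records (one of \code{"B-hordein"}, \code{"C-hordein"},
#'   \code{"D-hordein"}, \code{"gamma-hordein"}, \code{"ALP"},
#'   \code{"wheat-HMW-glutenin"}, \code{"other"}), or a named vector keyed
#'   by accession.
#' @param speciesTag optional species annotation (\code{"barley"},
#'   \code{"wheat"}, \code{"shared-Poaceae"}, \code{"other"}), recycled or
#'   named as for \code{proteinClass}.
#'
#' @return An \code{AAStringSet} named by accession with metadata columns
#'   \code{accession}, \code{description}, \code{protein_class},
#'   \code{species_tag}. An empty file returns an empty set with a warning.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P06470 B1-hordein", "QQPFPQQ"), fa)
#' readProteinFasta(fa)
readProteinFasta <- function(path, proteinClass = NA_character_,
                             speciesTag = NA_character_) {
  if (!file.exists(path))
    gs_config_error("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    warning(sprintf("empty FASTA file: %s", path))
    aa <- Biostrings::AAStringSet()
    S4Vectors::mcols(aa) <- S4Vectors::DataFrame(
      accession = character(0), description = character(0),
      protein_class = character(0), species_tag = character(0))
    return(aa)
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    gs_format_error("malformed FASTA (no '>' on first non-blank line %d): %s",
                    nonblank[1], path)
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        gs_validation_error("invalid residue letters in %s", path)
      invokeRestart("muffleWarning")
    })
  seqs <- toupper(gsub("\\*", "", as.character(aa)))
  hdr <- parseFastaHeaders(names(aa))
  checkAASequences(seqs, ids = hdr$accession, what = "protein sequence")
  if (anyDuplicated(hdr$accession))
    gs_validation_error("duplicate accessions in %s: %s", path,
                        paste(unique(hdr$accession[duplicated(hdr$accession)]),
                              collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- hdr$accession
  cls <- annotationFor(hdr$accession, proteinClass, PROTEIN_CLASSES,
                       "protein_class")
  sp <- annotationFor(hdr$accession, speciesTag,
                      c("barley", "wheat", "shared-Poaceae", "other"),
                      "species_tag")
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    accession = hdr$accession, description = hdr$description,
    protein_class = cls, species_tag = sp)
  out
}

# Resolve a per-record annotation from a scalar or an accession-named vector.
annotationFor <- function(accessions, value, allowed, what) {
  if (length(value) == 1L && is.null(names(value)))
    value <- rep(value, length(accessions))
  else if (!is.null(names(value)))
    value <- unname(value[accessions])
  else if (length(value) != length(accessions))
    gs_validation_error("%s annotation must be scalar, named, or one per record",
                        what)
  value <- as.character(value)
  known <- is.na(value) | value %in% allowed
  if (!all(known))
    gs_validation_error("unknown %s value(s): %s", what,
                        paste(unique(value[!known]), collapse = ", "))
  value
}

parseFastaHeaders <- function(headers) {
  first <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  # UniProt "db|ACC|entry_name" -> ACC
  parts <- strsplit(first, "|", fixed = TRUE)
  acc <- vapply(parts, function(p)
    if (length(p) == 3L && nzchar(p[2])) p[2] else paste(p, collapse = "|"),
    character(1))
  list(accession = acc, description = desc)
}

#' Read a detected-peptide list
#'
#' Accepts either a FASTA file or a plain one-sequence-per-line text file
#' and returns the peptide sequences (uppercased, validated).
#'
#' @param path input file.
#' @param dedupe drop duplicate sequences (default \code{TRUE}; peptide-level
#'   censuses count each distinct sequence once).
#' @return character vector of peptide sequences.
#' @export
readPeptideList <- function(path, dedupe = TRUE) {
  if (!file.exists(path))
    gs_config_error("peptide list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank)) {
    warning(sprintf("empty peptide list: %s", path))
    return(character(0))
  }
  if (startsWith(trimws(nonblank[1]), ">")) {
    aa <- readProteinFasta(path)
    peps <- as.character(aa)
  } else {
    peps <- toupper(trimws(nonblank))
    checkAASequences(peps, ids = peps, what = "peptide sequence")
  }
  if (dedupe) peps <- unique(peps)
  unname(peps)
}

#' Write digestion peptides to FASTA
#'
#' Writes peptides produced by \code{\link{inSilicoDigest}} with headers of
#' the form \code{parent_accession|start-end|enzyme|mcN}, which round-trip
#' through \code{\link{readProteinFasta}} / \code{\link{readPeptideList}}.
#'
#' @param peptides data.frame from \code{\link{inSilicoDigest}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePeptidesFasta <- function(peptides, path) {
  if (!is.data.frame(peptides) || nrow(peptides) == 0L)
    gs_validation_error("peptides must be a non-empty digestion data.frame")
  headers <- sprintf("%s|%d-%d|%s|mc%d", peptides$parent_accession,
                     peptides$start, peptides$end, peptides$enzyme,
                     peptides$missed_cleavages)
  aa <- Biostrings::AAStringSet(peptides$sequence)
  names(aa) <- headers
  tryCatch(Biostrings::writeXStringSet(aa, filepath = path),
           error = function(e) gs_stop("glutenscreen_io_error",
                                       "cannot write FASTA to %s: %s",
                                       path, conditionMessage(e)))
  invisible(path)
}

#' Parse peptide FASTA headers back to coordinates
#'
#' Inverse of the header scheme used by \code{\link{writePeptidesFasta}}.
#'
#' @param headers character vector of \code{acc|start-end|enzyme|mcN} headers.
#' @return data.frame with columns \code{parent_accession}, \code{start},
#'   \code{end}, \code{enzyme}, \code{missed_cleavages}.
#' @export
parsePeptideHeaders <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    gs_format_error("unparseable peptide header(s): %s",
                    paste(headers[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  coord <- strsplit(m[, 2], "-", fixed = TRUE)
  data.frame(parent_accession = m[, 1],
             start = as.integer(vapply(coord, `[`, "", 1L)),
             end = as.integer(vapply(coord, `[`, "", 2L)),
             enzyme = m[, 3],
             missed_cleavages = as.integer(sub("^mc", "", m[, 4])),
             stringsAsFactors = FALSE)
}
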