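# Internal helpers shared across the package.

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif sd cor setNames aggregate
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Amino-acid alphabet accepted in protein sequences: the 20 standard residues
# plus X for ambiguous positions.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_LETTERS, "X")

EPITOPE_CLASSES <- c("R5", "DQ_core", "immunogenic_Tcell")

PROTEIN_CLASSES <- c("B-hordein", "C-hordein", "D-hordein", "gamma-hordein",
                     "ALP", "wheat-HMW-glutenin", "other")

# Hordein subclasses that contribute to the net hordein total; avenin-like
# proteins (ALPs) are prolamins but not hordeins and are excluded.
HORDEIN_CLASSES <- c("B-hordein", "C-hordein", "D-hordein", "gamma-hordein")

#' Protein classes counted in net hordein totals
#'
#' The four hordein subclasses (B, C, D and gamma). Avenin-like proteins are
#' excluded from net hordein totals because they are not strictly hordeins.
#'
#' @return Character vector of the four hordein class labels.
#' @export
#' @examples
#' hordeinClasses()
hordeinClasses <- function() HORDEIN_CLASSES

gs_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "glutenscreen_error")))
}

gs_config_error <- function(fmt, ...) gs_stop("glutenscreen_config_error", fmt, ...)
gs_format_error <- function(fmt, ...) gs_stop("glutenscreen_format_error", fmt, ...)
gs_validation_error <- function(fmt, ...) gs_stop("glutenscreen_validation_error", fmt, ...)

# INFO-level narration; silenced with options(glutenscreen.verbose = FALSE).
gs_log <- function(fmt, ...) {
  if (isTRUE(getOption("glutenscreen.verbose", TRUE)))
    message(sprintf(paste0("[glutenscreen] ", fmt), ...))
  invisible(NULL)
}

# Validate amino-acid sequences; returns invisibly or raises a validation
# error naming the offending identifiers.
checkAASequences <- function(sequences, ids = names(sequences),
                             allow_x = TRUE, what = "sequence") {
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  allowed <- if (allow_x) AA_ALLOWED else AA_LETTERS
  bad_rx <- paste0("[^", paste(allowed, collapse = ""), "]")
  empty <- !nzchar(sequences) | is.na(sequences)
  if (any(empty))
    gs_validation_error("empty %s for: %s", what,
                        paste(ids[empty], collapse = ", "))
  bad <- grepl(bad_rx, sequences)
  if (any(bad))
    gs_validation_error("invalid residue letters in %s: %s", what,
                        paste(ids[bad], collapse = ", "))
  invisible(TRUE)
}

# Deterministic substring helper (vectorised over start).
substrs <- function(x, start, stop) substring(x, start, stop)
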