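#' Read a transition-level MRM peak-area report
#'
#' Reads a comma-separated transition results export (of the kind produced
#' by targeted-proteomics software) into validated transition measurements.
#' Column names are adapted through \code{columnMap}; blank or \code{#N/A}
#' areas are treated as missing (not zero) and dropped with a log message.
#'
#' @param x path to a CSV file, or a data.frame already in memory.
#' @param columnMap named character vector mapping standard names
#'   (\code{sample}, \code{replicate}, \code{peptide}, \code{modification},
#'   \code{transition}, \code{area}, \code{retention_time}) to the file's
#'   header names, e.g. \code{c(area = "TotalArea")}. Unmapped standard
#'   names must match the header directly (case-insensitively).
#' @return data.frame with columns \code{sample_id}, \code{replicate},
#'   \code{peptide_sequence}, \code{mod_state} (\code{"reduced"},
#'   \code{"met_oxidised"} or \code{"none"}), \code{transition_id},
#'   \code{peak_area}, \code{retention_time} (NA when absent).
#' @export
readTransitionReport <- function(x, columnMap = NULL) {
  if (is.character(x)) {
    if (!file.exists(x))
      gs_config_error("transition report not found: %s", x)
    df <- utils::read.csv(x, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", "#N/A", ""))
  } else if (is.data.frame(x)) {
    df <- x
  } else gs_validation_error("transition report must be a path or data.frame")

  std <- c(sample = "sample", replicate = "replicate", peptide = "peptide",
           modification = "modification", transition = "transition",
           area = "area", retention_time = "retention_time")
  if (!is.null(columnMap)) std[names(columnMap)] <- columnMap
  lookup <- function(name) {
    hit <- match(tolower(std[[name]]), tolower(names(df)))
    if (is.na(hit)) NA_integer_ else hit
  }
  mandatory <- c("sample", "replicate", "peptide", "transition", "area")
  idx <- vapply(mandatory, lookup, integer(1))
  if (anyNA(idx))
    gs_format_error("transition report lacks mandatory column(s): %s",
                    paste(std[mandatory[is.na(idx)]], collapse = ", "))
  area <- suppressWarnings(as.numeric(df[[idx[["area"]]]]))
  missing <- is.na(area)
  if (any(missing))
    gs_log("dropping %d transition row(s) with missing peak area", sum(missing))
  neg <- which(!missing & area < 0)
  if (length(neg))
    gs_validation_error("negative peak area at row(s): %s",
                        paste(neg, collapse = ", "))
  mod_i <- lookup("modification")
  mod <- if (is.na(mod_i)) rep("none", nrow(df)) else {
    m <- tolower(as.character(df[[mod_i]]))
    m[is.na(m) | m %in% c("", "none", "unmodified")] <- "none"
    m[m %in% c("reduced")] <- "reduced"
    m[grepl("ox", m)] <- "met_oxidised"
    m
  }
  bad_mod <- !mod %in% c("none", "reduced", "met_oxidised")
  if (any(bad_mod))
    gs_validation_error("unknown modification state(s): %s",
                        paste(unique(mod[bad_mod]), collapse = ", "))
  rt_i <- lookup("retention_time")
  out <- data.frame(
    sample_id = as.character(df[[idx[["sample"]]]]),
    replicate = as.integer(df[[idx[["replicate"]]]]),
    peptide_sequence = toupper(as.character(df[[idx[["peptide"]]]])),
    mod_state = mod,
    transition_id = as.character(df[[idx[["transition"]]]]),
    peak_area = area,
    retention_time = if (is.na(rt_i)) NA_real_ else
      suppressWarnings(as.numeric(df[[rt_i]])),
    stringsAsFactors = FALSE)
  out <- out[!missing, , drop = FALSE]
  key <- with(out, paste(sample_id, replicate, peptide_sequence, mod_state,
                         transition_id))
  if (anyDuplicated(key))
    gs_validation_error("duplicate (sample, replicate, peptide, modification, transition) row(s): %s",
                        paste(utils::head(unique(key[duplicated(key)]), 3),
                              collapse = "; "))
  checkAASequences(unique(out$peptide_sequence),
                   ids = unique(out$peptide_sequence),
                   what = "peptide sequence")
  rownames(out) <- NULL
  out
}

#' Aggregate transitions into peptide-level quantities
#'
#' For each (sample, peptide): transition peak areas are summed within each
#' replicate, across transitions and across Met-oxidation states (the
#' oxidised and reduced precursors of the same peptide are two measurements
#' of one analyte and are always merged). The peptide abundance
#' \code{summed_area} is the mean of the replicate-level sums and \code{cv}
#' their coefficient of variation (sample SD / mean, n-1 denominator).
#' A peptide absent from some replicates of a sample in which it occurs has
#' those replicate sums treated as 0 and is flagged.
#'
#' @param measurements validated transition data.frame from
#'   \code{\link{readTransitionReport}}.
#' @param detectionThreshold \code{detected} is \code{summed_area >}
#'   this value (default 0).
#' @return data.frame with columns \code{sample_id},
#'   \code{peptide_sequence}, \code{summed_area}, \code{cv},
#'   \code{n_replicates}, \code{n_missing_replicates}, \code{detected}.
#' @export
quantifyPeptides <- function(measurements, detectionThreshold = 0) {
  req <- c("sample_id", "replicate", "peptide_sequence", "transition_id",
           "peak_area")
  missing <- setdiff(req, names(measurements))
  if (length(missing))
    gs_format_error("measurements lack column(s): %s",
                    paste(missing, collapse = ", "))
  if (!nrow(measurements))
    return(data.frame(sample_id = character(0),
                      peptide_sequence = character(0),
                      summed_area = numeric(0), cv = numeric(0),
                      n_replicates = integer(0),
                      n_missing_replicates = integer(0),
                      detected = logical(0), stringsAsFactors = FALSE))
  # Replicate universe per sample: every replicate observed for the sample.
  sample_reps <- lapply(split(measurements$replicate, measurements$sample_id),
                        function(r) sort(unique(r)))
  repsums <- stats::aggregate(peak_area ~ sample_id + peptide_sequence + replicate,
                              data = measurements, FUN = sum)
  out <- do.call(rbind, lapply(split(repsums, list(repsums$sample_id,
                                                   repsums$peptide_sequence),
                                     drop = TRUE), function(g) {
    reps <- sample_reps[[g$sample_id[1]]]
    sums <- setNames(rep(0, length(reps)), reps)
    sums[as.character(g$replicate)] <- g$peak_area
    n_missing <- length(reps) - nrow(g)
    m <- mean(sums)
    data.frame(sample_id = g$sample_id[1],
               peptide_sequence = g$peptide_sequence[1],
               summed_area = m,
               cv = if (length(sums) > 1L && m > 0) stats::sd(sums) / m
                    else NA_real_,
               n_replicates = length(reps),
               n_missing_replicates = n_missing,
               detected = m > detectionThreshold,
               stringsAsFactors = FALSE)
  }))
  flagged <- out$n_missing_replicates > 0L
  if (any(flagged))
    gs_log("%d (sample, peptide) pair(s) missing from some replicates; absent replicate sums treated as 0",
           sum(flagged))
  out <- out[order(out$sample_id, out$peptide_sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise peptide quantities by protein class
#'
#' Per (sample, protein class): mean, SD and net (summed) area over member
#' peptides' \code{summed_area}; additionally a per-sample net hordein total
#' over the B-, C-, D- and gamma-hordein classes only (avenin-like proteins
#' are prolamins but not hordeins and are excluded from the net total).
#'
#' @param peptideQuants data.frame from \code{\link{quantifyPeptides}}.
#' @param classMap named character vector mapping peptide sequence to a
#'   protein class (see \code{\link{hordeinClasses}} and
#'   \code{"ALP"}/\code{"wheat-HMW-glutenin"}/\code{"other"}). Unmapped
#'   peptides are excluded with a warning and listed in the
#'   \code{"unmapped"} attribute of the result.
#' @return list with elements \code{classes} (data.frame \code{sample_id},
#'   \code{protein_class}, \code{mean_area}, \code{sd_area},
#'   \code{net_area}, \code{n_peptides}) and \code{net_hordein} (data.frame
#'   \code{sample_id}, \code{net_area}).
#' @export
summariseClasses <- function(peptideQuants, classMap) {
  if (is.null(names(classMap)))
    gs_validation_error("classMap must be named by peptide sequence")
  bad_cls <- setdiff(unique(classMap), PROTEIN_CLASSES)
  if (length(bad_cls))
    gs_validation_error("unknown protein class(es): %s",
                        paste(bad_cls, collapse = ", "))
  q <- peptideQuants
  q$protein_class <- unname(classMap[q$peptide_sequence])
  unmapped <- sort(unique(q$peptide_sequence[is.na(q$protein_class)]))
  if (length(unmapped)) {
    warning(sprintf("%d peptide(s) missing from class map excluded from class totals: %s",
                    length(unmapped),
                    paste(utils::head(unmapped, 5), collapse = ", ")))
    q <- q[!is.na(q$protein_class), , drop = FALSE]
  }
  samples <- sort(unique(peptideQuants$sample_id))
  classes <- if (nrow(q)) {
    do.call(rbind, lapply(split(q, list(q$sample_id, q$protein_class),
                                drop = TRUE), function(g)
      data.frame(sample_id = g$sample_id[1],
                 protein_class = g$protein_class[1],
                 mean_area = mean(g$summed_area),
                 sd_area = if (nrow(g) > 1L) stats::sd(g$summed_area)
                           else NA_real_,
                 net_area = sum(g$summed_area), n_peptides = nrow(g),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(sample_id = character(0), protein_class = character(0),
               mean_area = numeric(0), sd_area = numeric(0),
               net_area = numeric(0), n_peptides = integer(0),
               stringsAsFactors = FALSE)
  }
  classes <- classes[order(classes$sample_id, classes$protein_class), ,
                     drop = FALSE]
  rownames(classes) <- NULL
  hc <- classes[classes$protein_class %in% HORDEIN_CLASSES, , drop = FALSE]
  net <- setNames(rep(0, length(samples)), samples)
  if (nrow(hc)) {
    agg <- tapply(hc$net_area, hc$sample_id, sum)
    net[names(agg)] <- agg
  }
  net_hordein <- data.frame(sample_id = samples, net_area = unname(net),
                            stringsAsFactors = FALSE)
  out <- list(classes = classes, net_hordein = net_hordein)
  attr(out, "unmapped") <- unmapped
  out
}
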