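#' Read an ELISA results table
#'
#' Reads a comma-separated table with columns \code{sample_id},
#' \code{gluten_mg_per_kg} and optionally \code{label_group}
#' (\code{"control"} or \code{"low_gluten"}); when \code{label_group} is
#' absent it is inferred from the sample identifier prefix (\code{LG} =
#' low gluten, otherwise control).
#'
#' @param path CSV path. Lines starting with \code{#} are comments.
#' @return data.frame with columns \code{sample_id},
#'   \code{gluten_mg_per_kg}, \code{label_group}.
#' @export
readElisaTable <- function(path) {
  if (!file.exists(path))
    gs_config_error("ELISA table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "gluten_mg_per_kg")
  missing <- setdiff(need, names(df))
  if (length(missing))
    gs_format_error("ELISA table %s lacks column(s): %s", path,
                    paste(missing, collapse = ", "))
  v <- suppressWarnings(as.numeric(df$gluten_mg_per_kg))
  if (any(is.na(v) | !is.finite(v) | v < 0))
    gs_validation_error("ELISA values must be finite and non-negative")
  if (is.null(df$label_group))
    df$label_group <- ifelse(grepl("^LG", df$sample_id), "low_gluten",
                             "control")
  bad <- !df$label_group %in% c("control", "low_gluten")
  if (any(bad))
    gs_validation_error("unknown label_group value(s): %s",
                        paste(unique(df$label_group[bad]), collapse = ", "))
  if (anyDuplicated(df$sample_id))
    gs_validation_error("duplicate sample_id in ELISA table")
  data.frame(sample_id = df$sample_id, gluten_mg_per_kg = v,
             label_group = df$label_group, stringsAsFactors = FALSE)
}

#' The shipped beer-survey ELISA table
#'
#' R5 competitive ELISA gluten concentrations (mg/kg) for the 14-beer
#' survey: five control beers C1-C5 and nine low-gluten beers LG1-LG9.
#'
#' @return data.frame as from \code{\link{readElisaTable}}.
#' @export
#' @examples
#' beerElisaTable()
beerElisaTable <- function() {
  readElisaTable(system.file("extdata", "beer_elisa.csv",
                             package = "glutenscreen", mustWork = TRUE))
}

#' ELISA versus LC-MS concordance report
#'
#' Compares antibody-based (ELISA) gluten estimates with LC-MS net hordein
#' peak areas across samples. Reports (a) group means of the ELISA values;
#' (b) the low-gluten group mean as a percentage of the maximum control
#' ELISA value; (c) the Spearman rank correlation between ELISA mg/kg and
#' net hordein area; and (d) a mismatch table of samples whose ELISA rank
#' and LC-MS rank differ by more than \code{rankMargin} (rank 1 = highest
#' gluten under both measures). Large rank mismatches are the signature of
#' ELISA signal suppression in hydrolysed samples.
#'
#' Printed values follow reporting precision conventions: group means to
#' 1 decimal (mg/kg), percentages to the nearest integer; the unrounded
#' values are retained alongside.
#'
#' @param elisa data.frame from \code{\link{readElisaTable}}.
#' @param netHordein data.frame with columns \code{sample_id},
#'   \code{net_area} (the \code{net_hordein} element of
#'   \code{\link{summariseClasses}}), or \code{NULL} to report the ELISA
#'   arithmetic only.
#' @param rankMargin mismatch threshold on absolute rank difference
#'   (default 3).
#' @return list with elements \code{group_means} (data.frame
#'   \code{label_group}, \code{mean_mg_per_kg}, \code{printed}),
#'   \code{lg_percent_of_max_control} (list \code{value}, \code{printed},
#'   \code{max_control_sample}), \code{spearman} (numeric or \code{NA}),
#'   \code{mismatches} (data.frame), \code{n_paired}.
#' @export
#' @examples
#' elisaConcordance(beerElisaTable())$group_means
elisaConcordance <- function(elisa, netHordein = NULL, rankMargin = 3) {
  gm <- stats::aggregate(gluten_mg_per_kg ~ label_group, data = elisa,
                         FUN = mean)
  names(gm)[2] <- "mean_mg_per_kg"
  gm$printed <- round(gm$mean_mg_per_kg, 1)
  ctrl <- elisa[elisa$label_group == "control", , drop = FALSE]
  lg_mean <- gm$mean_mg_per_kg[gm$label_group == "low_gluten"]
  pct <- if (length(lg_mean) && nrow(ctrl)) {
    imax <- which.max(ctrl$gluten_mg_per_kg)
    list(value = 100 * lg_mean / ctrl$gluten_mg_per_kg[imax],
         printed = round(100 * lg_mean / ctrl$gluten_mg_per_kg[imax]),
         max_control_sample = ctrl$sample_id[imax])
  } else list(value = NA_real_, printed = NA_real_,
              max_control_sample = NA_character_)

  spearman <- NA_real_
  mism <- data.frame(sample_id = character(0), elisa_rank = integer(0),
                     ms_rank = integer(0), rank_diff = integer(0),
                     stringsAsFactors = FALSE)
  n_paired <- 0L
  if (!is.null(netHordein)) {
    unmatched <- setdiff(netHordein$sample_id, elisa$sample_id)
    if (length(unmatched))
      gs_validation_error("net hordein sample(s) absent from ELISA table: %s",
                          paste(unmatched, collapse = ", "))
    paired <- merge(elisa, netHordein, by = "sample_id")
    n_paired <- nrow(paired)
    if (n_paired < 3L) {
      warning("fewer than 3 paired samples; correlation omitted")
    } else {
      spearman <- stats::cor(paired$gluten_mg_per_kg, paired$net_area,
                             method = "spearman")
      # rank 1 = highest signal under each measure
      er <- rank(-paired$gluten_mg_per_kg, ties.method = "average")
      mr <- rank(-paired$net_area, ties.method = "average")
      d <- abs(er - mr)
      sel <- d > rankMargin
      mism <- data.frame(sample_id = paired$sample_id[sel],
                         elisa_rank = er[sel], ms_rank = mr[sel],
                         rank_diff = d[sel], stringsAsFactors = FALSE)
      mism <- mism[order(-mism$rank_diff, mism$sample_id), , drop = FALSE]
      rownames(mism) <- NULL
    }
  }
  list(group_means = gm, lg_percent_of_max_control = pct,
       spearman = spearman, mismatches = mism, n_paired = n_paired,
       rank_margin = rankMargin)
}
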