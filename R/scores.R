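#' Ratio of two non-negative metrics
#'
#' Vectorized numerator / denominator for per-patient density or
#' percentage metrics (e.g. the CD8/CD4 ratio or the intra-tumoral /
#' peri-tumoral ratio of a metric). A zero denominator yields a missing
#' value (with a warning), never infinity: downstream rank tests cannot
#' order infinities meaningfully. Missing inputs stay missing.
#'
#' @param numerator,denominator Numeric vectors (recycled to common
#'   length); must be non-negative where not `NA`.
#' @return Numeric vector of ratios with `NA` for missing or
#'   zero-denominator entries.
#' @export
#' @examples
#' ratio_metric(4, 2) # I/P ratio 2
ratio_metric <- function(numerator, denominator) {
  if (any(numerator < 0, na.rm = TRUE) || any(denominator < 0, na.rm = TRUE)) {
    ctx_abort("densities and percentages cannot be negative.")
  }
  out <- numerator / denominator
  zero_den <- !is.na(denominator) & denominator == 0
  if (any(zero_den)) {
    warn(sprintf("%d ratio(s) with zero denominator set to NA.",
                 sum(zero_den)))
    out[zero_den] <- NA_real_
  }
  out
}

#' Median dichotomization of a per-patient metric
#'
#' Splits patients into `"high"` (value strictly above the cohort median)
#' and `"low"` (value at or below the median). The median is computed on
#' the analyzed patients' non-missing values; missing values stay
#' missing. The tie policy sends values equal to the median to `"low"`,
#' so `"high"` always means strictly above the median. When all values
#' are identical every patient is `"low"` (degenerate split, warned).
#'
#' @param values Numeric vector (optionally named by patient).
#' @return List with `labels` (character vector, `"high"`/`"low"`/`NA`,
#'   names preserved) and `rule` (tibble: `median`, `n`, `tie_policy`).
#' @export
#' @examples
#' dichotomize_by_median(c(1, 2, 3, 4))$labels
dichotomize_by_median <- function(values) {
  usable <- values[!is.na(values)]
  if (length(usable) < 2L) {
    ctx_abort("median dichotomization needs at least 2 non-missing values.")
  }
  med <- stats::median(usable)
  labels <- ifelse(is.na(values), NA_character_,
                   ifelse(values > med, "high", "low"))
  names(labels) <- names(values)
  if (length(unique(usable)) == 1L) {
    warn("all values identical: degenerate dichotomization, every patient 'low'.")
  }
  list(
    labels = labels,
    rule = tibble(median = med, n = length(usable),
                  tie_policy = "median_to_low")
  )
}

#' Immunoscore from CD3/CD8 densities in tumor and stroma
#'
#' The metastatic-melanoma Immunoscore variant: each of the four density
#' metrics (CD3 and CD8, each in the tumor and stroma compartments) is
#' dichotomized by its own cohort median; the score is the number of
#' `"high"` indicators (0-4) and the class maps 0 to `I0`, 4 to `I4` and
#' 1-3 to the intermediate class `IntI`. CD3 densities come from panel 1
#' and CD8 densities from panel 2 (the only panels carrying those
#' markers). Patients missing any of the four metrics get a missing
#' score/class.
#'
#' @param densities Data frame with columns `patient_id`, `cd3_tumor`,
#'   `cd3_stroma`, `cd8_tumor`, `cd8_stroma` (cells/mm^2); medians are
#'   computed on the cohort passed in.
#' @return Tibble of class `immunoscore_tbl`: one row per patient with
#'   the four binary indicators (1 = high), `score` and `class`
#'   (`"I0"`, `"IntI"`, `"I4"`).
#' @export
compute_immunoscore <- function(densities) {
  needed <- c("patient_id", "cd3_tumor", "cd3_stroma", "cd8_tumor", "cd8_stroma")
  missing <- setdiff(needed, names(densities))
  if (length(missing)) {
    ctx_abort(paste0("`densities` lacks column(s): ",
                     paste(missing, collapse = ", ")))
  }
  metrics <- needed[-1]
  ind <- lapply(metrics, function(m) {
    lab <- suppressWarnings(dichotomize_by_median(densities[[m]])$labels)
    ifelse(is.na(lab), NA_integer_, as.integer(lab == "high"))
  })
  names(ind) <- paste0(metrics, "_high")
  out <- tibble(patient_id = densities$patient_id, !!!ind)
  score <- rowSums(as.data.frame(ind))
  out$score <- as.integer(score)
  out$class <- dplyr::case_when(
    is.na(score) ~ NA_character_,
    score == 0 ~ "I0",
    score == 4 ~ "I4",
    TRUE ~ "IntI"
  )
  class(out) <- c("immunoscore_tbl", class(out))
  out
}

#' Lymphoid/myeloid concordance group
#'
#' Combines the high/low labels of intra-tumoral CD3+ T-cell and CD68+
#' macrophage densities: equal labels (`high/high` or `low/low`) are
#' `"concordant"`, unequal labels `"discordant"`. Missing labels yield a
#' missing group.
#'
#' @param cd3_label,cd68_label Character vectors of `"high"`/`"low"`
#'   labels (recycled to common length).
#' @return Character vector: `"concordant"`, `"discordant"` or `NA`.
#' @export
concordance_group <- function(cd3_label, cd68_label) {
  ok <- function(x) is.na(x) | x %in% c("high", "low")
  if (!all(ok(cd3_label)) || !all(ok(cd68_label))) {
    ctx_abort("labels must be 'high', 'low' or NA.")
  }
  ifelse(is.na(cd3_label) | is.na(cd68_label), NA_character_,
         ifelse(cd3_label == cd68_label, "concordant", "discordant"))
}

#' Disease-control classification from RECIST response
#'
#' Disease control (group `"CD"`) comprises complete response, partial
#' response and stable disease under RECIST 1.1; progressive disease is
#' group `"PD"`. The disease control rate is the proportion of `"CD"`
#' patients.
#'
#' @param recist Character vector with values in `CR`, `PR`, `SD`, `PD`.
#' @param patient_id Optional identifiers (same length).
#' @return Tibble: `patient_id` (if given), `recist`, `dcr_group`.
#' @export
#' @examples
#' classify_response(c("PD", "SD", "PR", "CR"))
classify_response <- function(recist, patient_id = NULL) {
  bad <- setdiff(unique(recist[!is.na(recist)]), c("CR", "PR", "SD", "PD"))
  if (length(bad)) {
    ctx_abort(sprintf(
      "unknown RECIST code '%s'; allowed: CR, PR, SD, PD.", bad[1]
    ))
  }
  out <- tibble(
    recist = recist,
    dcr_group = ifelse(is.na(recist), NA_character_,
                       ifelse(recist %in% c("CR", "PR", "SD"), "CD", "PD"))
  )
  if (!is.null(patient_id)) out <- tibble(patient_id = patient_id, !!!out)
  out
}
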