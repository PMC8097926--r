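#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Non-parametric two-group comparison used for all group contrasts
#' (responders vs progressors, liver vs extra-hepatic, ...). The U
#' statistic uses midranks for ties. The p-value is exact (full
#' enumeration) when `n1 + n2 <= 12` and there are no ties, matching
#' small-cohort use, and otherwise uses the normal approximation with tie
#' and continuity corrections. No multiple-testing correction is applied
#' anywhere in the package; raw p-values are reported.
#'
#' @param x,y Numeric samples (non-empty).
#' @return An object of class `ctx_mw_test` with elements `statistic`
#'   (U for `x`), `p_value`, `n1`, `n2`, `method` (`"exact"` or
#'   `"normal-approximation"`).
#' @export
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))$p_value # exact 0.1
mann_whitney_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) {
    ctx_abort("both samples must be non-empty.")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  structure(
    list(
      statistic = unname(ht$statistic),
      p_value = min(1, unname(ht$p.value)),
      n1 = length(x), n2 = length(y),
      method = if (exact) "exact" else "normal-approximation"
    ),
    class = "ctx_mw_test"
  )
}

#' @export
print.ctx_mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney test (%s): U = %g, n = %d/%d, p = %.4g\n",
              x$method, x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Spearman rank correlation with a 95% confidence interval
#'
#' Spearman's r from midranked Pearson correlation; the 95% CI uses the
#' Fisher z-transform with the rank-correlation variance adjustment
#' `1.06 / (n - 3)`. At least 3 pairs are needed for r and 4 for the CI.
#' Constant inputs yield an undefined (NA) coefficient with a warning.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values
#'   are dropped.
#' @return Object of class `ctx_spearman`: `r`, `ci_low`, `ci_high`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) ctx_abort("`x` and `y` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) ctx_abort("Spearman correlation needs at least 3 complete pairs.")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warn("constant input: Spearman correlation undefined.")
    r <- NA_real_
  } else {
    r <- stats::cor(x, y, method = "spearman")
  }
  ci <- c(NA_real_, NA_real_)
  if (!is.na(r) && n >= 4L && abs(r) < 1) {
    z <- atanh(r)
    se <- sqrt(1.06 / (n - 3))
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else if (!is.na(r) && abs(r) == 1) {
    ci <- c(r, r) # degenerate: perfect monotone association
  }
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], n = n),
            class = "ctx_spearman")
}

#' @export
print.ctx_spearman <- function(x, ...) {
  cat(sprintf("Spearman r = %.4f (95%% CI %.3f to %.3f), n = %d\n",
              x$r, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

km_median_from_steps <- function(time, surv) {
  # Smallest event time at which S(t) <= 0.5; undefined (NA) if never.
  idx <- which(surv <= 0.5 + 1e-12)
  if (length(idx) == 0L) NA_real_ else time[min(idx)]
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of overall survival, overall or per group.
#' At tied times events precede censorings (the standard risk-set
#' convention). The median is the smallest time at which the estimated
#' survival drops to 0.5 or below, and is explicitly undefined (`NA`)
#' when the curve never reaches 0.5.
#'
#' @param records Data frame with columns `time` (months, > 0), `event`
#'   (1 = death, 0 = censored) and optionally the grouping column.
#' @param group Optional name of a grouping column.
#' @return Object of class `ctx_km`: `steps` (tibble `group`, `time`,
#'   `n_risk`, `n_event`, `surv`), `medians` (tibble `group`, `n`,
#'   `events`, `median`), and the underlying [survival::survfit] object.
#' @export
kaplan_meier <- function(records, group = NULL) {
  records <- as_tibble(records)
  if (nrow(records) < 1L) ctx_abort("at least one record required.")
  if (any(records$time <= 0 | !is.finite(records$time))) {
    ctx_abort("survival times must be positive and finite.")
  }
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
    groups <- rep("all", length(fit$time))
    grp_levels <- "all"
  } else {
    records$.group <- as.factor(records[[group]])
    fit <- survival::survfit(survival::Surv(time, event) ~ .group,
                             data = records)
    grp_levels <- sub("^\\.group=", "", names(fit$strata))
    groups <- rep(grp_levels, fit$strata)
  }
  steps <- tibble(
    group = groups, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, surv = fit$surv
  )
  medians <- dplyr::bind_rows(lapply(grp_levels, function(g) {
    s <- steps[steps$group == g, ]
    n_g <- if (is.null(group)) nrow(records) else sum(records$.group == g)
    tibble(
      group = g,
      n = n_g,
      events = sum(s$n_event),
      median = km_median_from_steps(s$time, s$surv)
    )
  }))
  structure(list(steps = steps, medians = medians, fit = fit,
                 group = group %||% NA_character_),
            class = "ctx_km")
}

#' @export
print.ctx_km <- function(x, ...) {
  cat("Kaplan-Meier estimate\n")
  print(as.data.frame(x$medians), row.names = FALSE)
  invisible(x)
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' Mantel-Cox statistic: at every event time the observed minus expected
#' events in one group, with hypergeometric variance; the squared
#' standardized sum is referred to a chi-square distribution with 1 df.
#' With zero events the statistic is undefined and flagged `NA`.
#'
#' @param records Data frame with `time`, `event` and the grouping
#'   column.
#' @param group Name of the grouping column (exactly 2 levels).
#' @return Object of class `ctx_logrank`: `chisq`, `p_value`, `n`,
#'   `n_events`.
#' @export
logrank_test <- function(records, group) {
  records <- as_tibble(records)
  records$.group <- as.factor(records[[group]])
  if (nlevels(records$.group) != 2L) {
    ctx_abort("log-rank test requires exactly two groups.")
  }
  if (any(table(records$.group) == 0L)) {
    ctx_abort("both groups must be non-empty.")
  }
  if (sum(records$event) == 0L) {
    warn("no events: log-rank statistic undefined.")
    return(structure(list(chisq = NA_real_, p_value = NA_real_,
                          n = nrow(records), n_events = 0L),
                     class = "ctx_logrank"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ .group,
                           data = records)
  chisq <- unname(sd$chisq)
  structure(
    list(chisq = chisq,
         p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
         n = nrow(records), n_events = sum(records$event)),
    class = "ctx_logrank"
  )
}

#' @export
print.ctx_logrank <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chisq(1) = %.4f, p = %.4g (n = %d, events = %d)\n",
              x$chisq, x$p_value, x$n, x$n_events))
  invisible(x)
}

#' Cox proportional-hazards hazard ratio for a binary covariate
#'
#' Univariable Cox model fit by partial-likelihood maximization with
#' Efron handling of tied event times (median-split data are heavily
#' tied). The hazard ratio is reported for `level` relative to the other
#' level, with a Wald 95% CI on the log scale. Complete separation
#' (monotone likelihood, unbounded estimate) is detected and flagged,
#' with an unbounded CI.
#'
#' @param records Data frame with `time`, `event` and the covariate
#'   column.
#' @param covariate Name of the binary covariate column.
#' @param level Level whose hazard is in the numerator; default the last
#'   factor level (e.g. `"high"` against `"low"`).
#' @return Object of class `ctx_cox`: `hr`, `ci_low`, `ci_high`,
#'   `log_hr`, `se`, `p_value`, `n`, `n_events`, `separation` flag.
#' @export
cox_hazard_ratio <- function(records, covariate, level = NULL) {
  records <- as_tibble(records)
  f <- as.factor(records[[covariate]])
  if (nlevels(f) != 2L) ctx_abort("covariate must have exactly two levels.")
  if (sum(records$event) < 2L) ctx_abort("at least two events required.")
  lv <- levels(f)
  level <- level %||% lv[2]
  if (!level %in% lv) ctx_abort(sprintf("level '%s' not found.", level))
  records$.x <- as.integer(f == level)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ .x, data = records,
                    ties = "efron")
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  separation <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 1e3
  if (separation) {
    warn("complete separation: hazard ratio unbounded.")
    ci <- c(0, Inf)
  } else {
    ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  structure(
    list(
      hr = exp(beta), ci_low = ci[1], ci_high = ci[2],
      log_hr = beta, se = se,
      p_value = if (separation) NA_real_ else
        2 * stats::pnorm(-abs(beta / se)),
      n = nrow(records), n_events = sum(records$event),
      covariate = covariate, level = level, separation = separation
    ),
    class = "ctx_cox"
  )
}

#' @export
print.ctx_cox <- function(x, ...) {
  cat(sprintf(
    "Cox PH: HR(%s = %s) = %.3f (95%% CI %.3f-%.3f), p = %.4g (n = %d, events = %d)%s\n",
    x$covariate, x$level, x$hr, x$ci_low, x$ci_high, x$p_value,
    x$n, x$n_events, if (x$separation) " [separation]" else ""
  ))
  invisible(x)
}
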