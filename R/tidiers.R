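#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Mann-Whitney test
#' @param x A `ctx_mw_test`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p.value`, `n1`, `n2`, `method`.
#' @method tidy ctx_mw_test
#' @export
tidy.ctx_mw_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n1 = x$n1, n2 = x$n2, method = x$method)
}

#' Tidy a Spearman correlation
#' @param x A `ctx_spearman`.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `n`.
#' @method tidy ctx_spearman
#' @export
tidy.ctx_spearman <- function(x, ...) {
  tibble(estimate = x$r, conf.low = x$ci_low, conf.high = x$ci_high,
         n = x$n)
}

#' Tidy a Kaplan-Meier fit (the step function)
#' @param x A `ctx_km`.
#' @param ... Unused.
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @method tidy ctx_km
#' @export
tidy.ctx_km <- function(x, ...) x$steps

#' Per-group KM summary
#' @param x A `ctx_km`.
#' @param ... Unused.
#' @return Tibble: `group`, `n`, `events`, `median` (`NA` when the curve
#'   never reaches 0.5).
#' @method glance ctx_km
#' @export
glance.ctx_km <- function(x, ...) x$medians

#' Tidy a log-rank test
#' @param x A `ctx_logrank`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p.value`, `df`, `n`, `n.events`.
#' @method tidy ctx_logrank
#' @export
tidy.ctx_logrank <- function(x, ...) {
  tibble(statistic = x$chisq, p.value = x$p_value, df = 1L,
         n = x$n, n.events = x$n_events)
}

#' Tidy a Cox hazard-ratio fit
#' @param x A `ctx_cox`.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate` (HR), `conf.low`,
#'   `conf.high`, `log.estimate`, `std.error`, `p.value`.
#' @method tidy ctx_cox
#' @export
tidy.ctx_cox <- function(x, ...) {
  tibble(
    term = paste0(x$covariate, "=", x$level),
    estimate = x$hr, conf.low = x$ci_low, conf.high = x$ci_high,
    log.estimate = x$log_hr, std.error = x$se, p.value = x$p_value
  )
}

#' Model-level Cox summary
#' @param x A `ctx_cox`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n.events`, `separation`.
#' @method glance ctx_cox
#' @export
glance.ctx_cox <- function(x, ...) {
  tibble(n = x$n, n.events = x$n_events, separation = x$separation)
}
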