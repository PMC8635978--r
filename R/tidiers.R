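#' Tidy a Gaussian mixture fit
#'
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @return One row per component: `component`, `mean`, `sd`, `weight`.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 mean = x$means, sd = x$sds, weight = x$weights)
}

#' One-row summary of a Gaussian mixture fit
#'
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the fit-level statistics.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 variance_model = x$variance_model,
                 log_likelihood = x$log_likelihood,
                 n_params = x$n_params, aic = x$aic, bic = x$bic,
                 n = x$n, converged = x$converged,
                 variance_floored = x$variance_floored)
}

#' Tidy a bimodality analysis
#'
#' @param x A `bimodality_result`.
#' @param ... Unused.
#' @return Component rows of the two-component fit (see [tidy.gmm_fit()]).
#' @export
tidy.bimodality_result <- function(x, ...) tidy(x$fit2)

#' One-row summary of a bimodality analysis
#'
#' @param x A `bimodality_result`.
#' @param ... Unused.
#' @return A one-row tibble: `delta_aic`, `relative_likelihood`,
#'   `favored`, `delta_bic`, `n`.
#' @export
glance.bimodality_result <- function(x, ...) {
  dplyr::mutate(x$comparison, n = x$fit1$n)
}

#' Tidy a generalization analysis
#'
#' @param x A `generalization_result`.
#' @param ... Unused.
#' @return The window and change t-tests as a tibble.
#' @export
tidy.generalization_result <- function(x, ...) x$tests

#' Tidy a response-time ANOVA
#'
#' @param x An `rt_anova_result`.
#' @param ... Unused.
#' @return The F table as a tibble: `effect`, `df1`, `df2`, `statistic`,
#'   `p_value`.
#' @export
tidy.rt_anova_result <- function(x, ...) x$anova

#' Tidy a switch-cost analysis
#'
#' @param x A `switch_cost_result`.
#' @param ... Unused.
#' @return The observed-minus-predicted costs with CIs, plus the slope row.
#' @export
tidy.switch_cost_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(kind = "rt_weight_slope_ms_per_N",
                   estimate_ms = x$slope_ms_per_N,
                   ci_lo = NA_real_, ci_hi = NA_real_, n = NA_integer_),
    x$costs
  )
}
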