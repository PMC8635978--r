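#' Fit a univariate Gaussian mixture by maximum likelihood
#'
#' Fits a one- or two-component Gaussian mixture to a numeric vector by
#' expectation-maximization with maximum-likelihood (1/n) variance
#' estimates. The one-component fit is closed form. Two-component fits run
#' EM to convergence (log-likelihood change below `tol`) from a quantile
#' split (lower/upper half of the sorted data) plus `n_restarts - 1` random
#' initializations, keeping the best final log-likelihood; results are
#' deterministic given `seed`. Component variances are floored at `1e-6`
#' times the data variance to prevent degenerate collapse (fits that hit
#' the floor are flagged). Components are stored in increasing order of
#' mean.
#'
#' `aic = 2 * n_params - 2 * log_likelihood` with 2 parameters for one
#' component, 4 for two components with equal variances, and 5 with unequal
#' variances. BIC is computed and reported but not used for the headline
#' model comparison.
#'
#' @param values Numeric vector; length must be at least
#'   `2 * n_components + 1`.
#' @param n_components 1 or 2.
#' @param variance_model `"unequal"` (default for data analysis) or
#'   `"equal"`.
#' @param n_restarts Number of EM initializations for two components.
#' @param seed Integer seed for the random restarts.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Iteration cap per restart.
#' @return An object of class `gmm_fit`.
#' @export
fit_gmm <- function(values, n_components = 2,
                    variance_model = c("unequal", "equal"),
                    n_restarts = 20, seed = 1L, tol = 1e-8,
                    max_iter = 1000) {
  variance_model <- match.arg(variance_model)
  x <- as.numeric(values)
  if (any(!is.finite(x))) abort("`values` must be finite.")
  n <- length(x)
  if (!n_components %in% c(1, 2)) abort("`n_components` must be 1 or 2.")
  if (n < 2 * n_components + 1) {
    abort("Need at least 2 * n_components + 1 observations.")
  }

  if (n_components == 1) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    ll <- sum(dnorm(x, mu, sigma, log = TRUE))
    return(new_gmm_fit(1, variance_model, mu, sigma, 1, ll,
                       n_params = 2, n = n, data = x,
                       converged = TRUE, floored = FALSE,
                       loglik_path = ll))
  }

  var_floor <- 1e-6 * max(var(x), .Machine$double.eps)
  inits <- withr::with_seed(seed, {
    qs <- sort(x)
    half <- ceiling(n / 2)
    first <- list(mu = c(mean(qs[seq_len(half)]), mean(qs[(half + 1):n])),
                  sigma = rep(max(sd(x) / 2, sqrt(var_floor)), 2),
                  w = c(0.5, 0.5))
    rest <- purrr::map(seq_len(max(n_restarts - 1, 0)), function(i) {
      list(mu = sort(sample(x, 2)),
           sigma = rep(max(sd(x), sqrt(var_floor)), 2),
           w = c(0.5, 0.5))
    })
    c(list(first), rest)
  })

  best <- NULL
  for (init in inits) {
    fit <- em_two_gaussian(x, init, variance_model, tol, max_iter, var_floor)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  ord <- order(best$mu)
  n_params <- if (variance_model == "equal") 4 else 5
  new_gmm_fit(2, variance_model, best$mu[ord], best$sigma[ord],
              best$w[ord], best$ll, n_params = n_params, n = n, data = x,
              converged = best$converged, floored = best$floored,
              loglik_path = best$path)
}

# One EM run for a two-component univariate mixture.
em_two_gaussian <- function(x, init, variance_model, tol, max_iter,
                            var_floor) {
  mu <- init$mu; sigma <- init$sigma; w <- init$w
  n <- length(x)
  floored <- FALSE
  path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E step (log-sum-exp for stability)
    la <- log(w[1]) + dnorm(x, mu[1], sigma[1], log = TRUE)
    lb <- log(w[2]) + dnorm(x, mu[2], sigma[2], log = TRUE)
    m <- pmax(la, lb)
    lse <- m + log(exp(la - m) + exp(lb - m))
    ll <- sum(lse)
    path <- c(path, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r1 <- exp(la - lse)
    r2 <- 1 - r1
    # M step with MLE (1/n) variances
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-12 || n2 < 1e-12) break
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    v1 <- sum(r1 * (x - mu[1])^2) / n1
    v2 <- sum(r2 * (x - mu[2])^2) / n2
    if (variance_model == "equal") {
      v1 <- v2 <- (n1 * v1 + n2 * v2) / n
    }
    if (v1 < var_floor || v2 < var_floor) floored <- TRUE
    sigma <- sqrt(pmax(c(v1, v2), var_floor))
  }
  list(mu = mu, sigma = sigma, w = w, ll = ll, converged = converged,
       floored = floored, path = path)
}

new_gmm_fit <- function(k, variance_model, means, sds, weights, ll,
                        n_params, n, data, converged, floored,
                        loglik_path) {
  structure(list(
    n_components = k,
    variance_model = variance_model,
    means = means,
    sds = sds,
    weights = weights,
    log_likelihood = ll,
    n_params = n_params,
    n = n,
    aic = 2 * n_params - 2 * ll,
    bic = n_params * log(n) - 2 * ll,
    data = data,
    converged = converged,
    variance_floored = floored,
    loglik_path = loglik_path
  ), class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit> K =", x$n_components,
      paste0("(", x$variance_model, " variance), n = ", x$n), "\n")
  cat("  means:", signif(x$means, 4),
      " sds:", signif(x$sds, 4),
      " weights:", signif(x$weights, 3), "\n")
  cat("  logLik:", signif(x$log_likelihood, 6),
      " AIC:", signif(x$aic, 6), " BIC:", signif(x$bic, 6), "\n")
  invisible(x)
}

#' Relative likelihood of the AIC-favored model
#'
#' `exp(|delta_aic| / 2)`: how many times more probable the favored model
#' is, given the data, than the alternative.
#'
#' @param delta_aic AIC difference (single-component minus two-component).
#' @return Relative likelihood (>= 1).
#' @export
relative_likelihood <- function(delta_aic) {
  exp(abs(delta_aic) / 2)
}

#' Compare single- and two-component mixture fits by AIC
#'
#' `delta_aic = AIC(K = 1) - AIC(K = 2)`, with positive values in favor of
#' the two-component mixture, together with the relative likelihood of the
#' favored model.
#'
#' @param fit1 A `gmm_fit` with one component.
#' @param fit2 A `gmm_fit` with two components, fitted to the same data.
#' @return A one-row tibble: `delta_aic`, `relative_likelihood`, `favored`
#'   (`"two_gaussian"`, `"single_gaussian"`, or `"tie"`), `delta_bic`.
#' @export
compare_models <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "gmm_fit"), inherits(fit2, "gmm_fit"))
  if (fit1$n_components != 1 || fit2$n_components != 2) {
    abort("`fit1` must have 1 component and `fit2` 2 components.")
  }
  if (fit1$n != fit2$n) abort("Fits must be on identical data.")
  delta <- fit1$aic - fit2$aic
  tibble::tibble(
    delta_aic = delta,
    relative_likelihood = relative_likelihood(delta),
    favored = if (delta > 0) "two_gaussian"
              else if (delta < 0) "single_gaussian" else "tie",
    delta_bic = fit1$bic - fit2$bic
  )
}

#' Parametric-bootstrap confidence intervals on component means
#'
#' Draws `n_boot` samples of the original size from the fitted mixture,
#' refits with the same settings, and returns percentile confidence
#' intervals on the component means (label switching resolved by ordering
#' components by mean). Errors if more than 1% of refits fail to converge.
#'
#' @param fit A converged `gmm_fit`.
#' @param n_boot Number of bootstrap samples.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @param n_restarts EM restarts per refit.
#' @return A tibble per component: `mean`, `ci_lo`, `ci_hi`, `boot_se`,
#'   with attributes `n_boot` and `n_nonconverged`.
#' @export
bootstrap_component_ci <- function(fit, n_boot = 10000, seed = 1L,
                                   conf = 0.95, n_restarts = 5) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (!fit$converged) abort("`fit` did not converge.")
  k <- fit$n_components
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      comp <- sample.int(k, fit$n, replace = TRUE, prob = fit$weights)
      x <- rnorm(fit$n, fit$means[comp], fit$sds[comp])
      rf <- fit_gmm(x, n_components = k,
                    variance_model = fit$variance_model,
                    n_restarts = n_restarts,
                    seed = sample.int(.Machine$integer.max, 1))
      list(means = sort(rf$means), converged = rf$converged)
    })
  })
  bad <- sum(!vapply(draws, `[[`, logical(1), "converged"))
  if (bad > 0.01 * n_boot) {
    abort(paste0(bad, " of ", n_boot, " bootstrap refits failed to ",
                 "converge (> 1%)."))
  }
  mat <- do.call(rbind, lapply(draws, `[[`, "means"))
  alpha <- (1 - conf) / 2
  out <- tibble::tibble(
    component = seq_len(k),
    mean = fit$means,
    ci_lo = apply(mat, 2, quantile, alpha),
    ci_hi = apply(mat, 2, quantile, 1 - alpha),
    boot_se = apply(mat, 2, sd)
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "n_nonconverged") <- bad
  out
}

#' Classify observations by mixture-component responsibility
#'
#' Assigns each value to the component with the greater posterior
#' responsibility under a two-component fit; exact ties go to the
#' lower-mean component. With `learner_component = "upper"` (heavy
#' outliers) the upper-mean component is labeled `"learner"`; use
#' `"lower"` for light outliers.
#'
#' @param values Numeric vector to classify (defaults to the fitted data).
#' @param fit2 A two-component `gmm_fit`.
#' @param learner_component Which component corresponds to learners.
#' @return A tibble: `value`, `component` (1 = lower mean), `posterior_2`,
#'   `label` factor (`"non-learner"`/`"learner"`).
#' @export
classify_learners <- function(values = NULL, fit2,
                              learner_component = c("upper", "lower")) {
  stopifnot(inherits(fit2, "gmm_fit"), fit2$n_components == 2)
  learner_component <- match.arg(learner_component)
  x <- values %||% fit2$data
  la <- log(fit2$weights[1]) + dnorm(x, fit2$means[1], fit2$sds[1],
                                     log = TRUE)
  lb <- log(fit2$weights[2]) + dnorm(x, fit2$means[2], fit2$sds[2],
                                     log = TRUE)
  m <- pmax(la, lb)
  p2 <- exp(lb - m) / (exp(la - m) + exp(lb - m))
  comp <- ifelse(p2 > 0.5, 2L, 1L)  # ties (p2 == 0.5) -> lower mean
  learner_idx <- if (learner_component == "upper") 2L else 1L
  tibble::tibble(
    value = x,
    component = comp,
    posterior_2 = p2,
    label = factor(ifelse(comp == learner_idx, "learner", "non-learner"),
                   levels = c("non-learner", "learner"))
  )
}

#' End-of-test outlier learning values for mixture analysis
#'
#' Builds the per-participant vector entering the bimodality analysis: for
#' laboratory tables, the difference between the anticipatory force for the
#' test object and the family-predicted weight over the final 16 test
#' cycles; for web tables, the mean anticipatory force for the test object
#' over the final 5 test cycles.
#'
#' @param table Behavior tibble (possibly several pooled conditions of one
#'   setting).
#' @return A tibble: `participant_id`, `condition`, `value`.
#' @export
mixture_input <- function(table) {
  web <- identical(table$setting[1], "web")
  table |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(d, key) {
      if (web) {
        win <- tail(cycles_of(d, "test"), 5)
        d |>
          dplyr::filter(.data$cycle %in% win, .data$object_id == 3L) |>
          dplyr::group_by(.data$participant_id) |>
          dplyr::summarise(value = mean(.data$anticipatory_force_N),
                           .groups = "drop")
      } else {
        fp <- family_predicted_weight(dplyr::mutate(d,
                                                    condition = key$condition))
        tibble::tibble(participant_id = fp$participant_id,
                       value = fp$learning_N)
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "condition", "value")
}

#' Bimodality analysis of outlier learning
#'
#' Fits single- and two-component Gaussian mixtures to the per-participant
#' outlier learning values and compares them by AIC.
#'
#' @param values Numeric vector (see [mixture_input()]).
#' @param variance_model Variance model for the two-component fit.
#' @param n_restarts,seed Passed to [fit_gmm()].
#' @return A list of class `bimodality_result`: `fit1`, `fit2`,
#'   `comparison`.
#' @export
bimodality_analysis <- function(values, variance_model = "unequal",
                                n_restarts = 20, seed = 1L) {
  fit1 <- fit_gmm(values, 1, variance_model, n_restarts, seed)
  fit2 <- fit_gmm(values, 2, variance_model, n_restarts, seed)
  structure(list(fit1 = fit1, fit2 = fit2,
                 comparison = compare_models(fit1, fit2)),
            class = "bimodality_result")
}

#' @export
print.bimodality_result <- function(x, ...) {
  cmp <- x$comparison
  cat("<bimodality_result> n =", x$fit1$n, "\n")
  cat(sprintf("  delta AIC = %.2f, relative likelihood = %.1f, favored: %s\n",
              cmp$delta_aic, cmp$relative_likelihood, cmp$favored))
  cat("  two-component means:", signif(x$fit2$means, 4), "\n")
  invisible(x)
}
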