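# Internal helpers over a single-condition behavior table -------------------

cycles_of <- function(table, phase) {
  sort(unique(table$cycle[table$phase == phase]))
}

assert_single_condition <- function(table) {
  if (length(unique(table$condition)) > 1) {
    abort("This analysis expects a single-condition table; filter first.")
  }
}

test_object_id <- function(table) 3L  # mid-size object, by package convention

#' End-of-training correlation between force and weight
#'
#' Pearson correlation between the scheduled object weight and the
#' anticipatory force over training-object trials in a cycle window
#' (default: the final eight training cycles), with a 95% confidence
#' interval from the Fisher z-transformation,
#' `tanh(atanh(r) +/- 1.96/sqrt(n - 3))`. Two variants are reported: the
#' correlation pooled over participants and trials (n = number of trials),
#' and the mean of per-participant correlations (averaged on the z scale,
#' with a t-interval over participants), since the effective n of a pooled
#' analysis is debatable.
#'
#' @param table Single-condition behavior tibble.
#' @param cycle_window Integer cycles to include; default final 8 training
#'   cycles.
#' @return A tibble with rows `pooled` and `participant_mean`: `r`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
endphase_correlation <- function(table, cycle_window = NULL) {
  assert_single_condition(table)
  cycle_window <- cycle_window %||% tail(cycles_of(table, "training"), 8)
  d <- dplyr::filter(table, .data$cycle %in% cycle_window,
                     .data$object_id != test_object_id(table))
  if (nrow(d) < 4) abort("Need at least 4 trials in the window.")
  w <- weight_to_force(d$mass_g)
  f <- d$anticipatory_force_N
  if (sd(w) == 0 || sd(f) == 0) {
    abort("Correlation undefined: zero variance in the window.")
  }
  r_pool <- cor(w, f)
  n_pool <- nrow(d)
  z <- atanh(r_pool)
  half <- 1.96 / sqrt(n_pool - 3)
  pooled <- tibble::tibble(method = "pooled", r = r_pool,
                           ci_lo = tanh(z - half), ci_hi = tanh(z + half),
                           n = n_pool)
  zs <- d |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      r = cor(weight_to_force(.data$mass_g), .data$anticipatory_force_N),
      .groups = "drop") |>
    dplyr::filter(is.finite(.data$r), abs(.data$r) < 1) |>
    dplyr::mutate(z = atanh(.data$r))
  pm <- if (nrow(zs) >= 2) {
    tt <- t.test(zs$z)
    tibble::tibble(method = "participant_mean", r = tanh(mean(zs$z)),
                   ci_lo = tanh(tt$conf.int[1]), ci_hi = tanh(tt$conf.int[2]),
                   n = nrow(zs))
  } else {
    tibble::tibble(method = "participant_mean", r = NA_real_,
                   ci_lo = NA_real_, ci_hi = NA_real_, n = nrow(zs))
  }
  dplyr::bind_rows(pooled, pm)
}

#' Family-predicted weight of the test object
#'
#' Per participant, fits an ordinary least-squares regression of
#' anticipatory force on object volume over training-object trials in a
#' cycle window (default: the final 16 test cycles) and evaluates it at the
#' test object's volume, thereby adjusting for any prediction error on the
#' training objects. Because the test volume is the mean training volume,
#' the prediction algebraically equals the mean training force -- which is
#' also why the same measure is meaningful in the uncorrelated condition.
#' The participant's mean anticipatory force for the test object over the
#' same window, and the difference (`learning_N`), are returned alongside.
#'
#' @param table Single-condition behavior tibble.
#' @param cycle_window Cycles to include; default final 16 test cycles.
#' @param analysis_trials_only Drop rows flagged `analysis_excluded` (1:1
#'   phase trials where the outlier followed itself)?
#' @return A tibble per participant: `slope_N_per_cm3`, `intercept_N`,
#'   `family_predicted_N`, `outlier_force_N`, `learning_N`.
#' @export
family_predicted_weight <- function(table, cycle_window = NULL,
                                    analysis_trials_only = TRUE) {
  assert_single_condition(table)
  cycle_window <- cycle_window %||% tail(cycles_of(table, "test"), 16)
  d <- dplyr::filter(table, .data$cycle %in% cycle_window)
  if (analysis_trials_only && "analysis_excluded" %in% names(d)) {
    d <- dplyr::filter(d, .data$analysis_excluded == 0)
  }
  test_id <- test_object_id(table)
  test_vol <- unique(d$volume_cm3[d$object_id == test_id])
  if (length(test_vol) != 1) abort("Test-object trials missing from window.")
  d |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(g, key) {
      tr <- dplyr::filter(g, .data$object_id != test_id)
      if (dplyr::n_distinct(tr$object_id) < 4) {
        abort("All four training objects must appear in the window.")
      }
      fit <- lm(anticipatory_force_N ~ volume_cm3, data = tr)
      tibble::tibble(
        slope_N_per_cm3 = coef(fit)[["volume_cm3"]],
        intercept_N = coef(fit)[["(Intercept)"]],
        family_predicted_N = unname(predict(fit,
          newdata = data.frame(volume_cm3 = test_vol))),
        outlier_force_N =
          mean(g$anticipatory_force_N[g$object_id == test_id])
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(learning_N = .data$outlier_force_N -
                    .data$family_predicted_N)
}

#' One-tailed test of outlier-weight learning
#'
#' Paired one-tailed t-test of the per-participant difference between the
#' anticipatory force for the test object and its family-predicted weight
#' over the analysis window (default: final 16 test cycles). The null is
#' that the test-object weight was not learned; the alternative is positive
#' learning for heavier-than-family outliers and negative for lighter.
#'
#' @param table Single-condition behavior tibble.
#' @param direction `"auto"` (from the sign of the outlier's weight
#'   discrepancy in the table), `"greater"` or `"less"`.
#' @param cycle_window Cycles to include; default final 16 test cycles.
#' @return A one-row tibble: group means, `statistic` (t), `df`,
#'   `p_value`, `direction`, `n`.
#' @export
outlier_learning_test <- function(table, direction = c("auto", "greater",
                                                       "less"),
                                  cycle_window = NULL) {
  direction <- match.arg(direction)
  fp <- family_predicted_weight(table, cycle_window)
  if (nrow(fp) < 2) abort("Need at least 2 participants.")
  if (direction == "auto") {
    test_id <- test_object_id(table)
    fam_mass <- mean(unique(table$mass_g[table$object_id != test_id]))
    out_mass <- utils::tail(table$mass_g[table$object_id == test_id], 1)
    direction <- if (out_mass >= fam_mass) "greater" else "less"
  }
  x <- fp$learning_N
  if (sd(x) < 1e-12) {
    # degenerate: all participants at an identical difference
    stat <- if (abs(mean(x)) < 1e-12) 0 else sign(mean(x)) * Inf
    pv <- if (stat == 0) 0.5 else {
      up <- direction == "greater"
      if ((stat > 0) == up) 0 else 1
    }
    tt <- list(statistic = stat, parameter = length(x) - 1, p.value = pv)
  } else {
    tt <- t.test(x, alternative = direction)
  }
  tibble::tibble(
    mean_outlier_N = mean(fp$outlier_force_N),
    mean_family_predicted_N = mean(fp$family_predicted_N),
    mean_learning_N = mean(fp$learning_N),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    direction = direction,
    n = nrow(fp)
  )
}

#' Single-trial generalization from the outlier to the family
#'
#' Measures how lifting the test object shifts the anticipatory force on
#' the immediately following training-object trial (the second trial of
#' each test cycle; later trials are diluted by washout). Per participant,
#' the force on each position-2 trial is compared with that object's own
#' mean force at the end of the training phase (default: final four
#' training cycles) and expressed as a percentage of the outlier's weight
#' discrepancy. Windows: `early` = first four test cycles, `end` = final
#' sixteen. Two-tailed t-tests are run within each window and on the
#' early-to-end change.
#'
#' @param table Single-condition behavior tibble.
#' @param discrepancy_N Outlier weight discrepancy (N); default derived
#'   from the table's condition definition.
#' @return A list of class `generalization_result`: `per_participant`
#'   (tibble participant x window x percent) and `tests` (tibble of
#'   t-tests).
#' @export
single_trial_generalization <- function(table, discrepancy_N = NULL) {
  assert_single_condition(table)
  if (is.null(discrepancy_N)) {
    cond <- condition(table$condition[1],
                      if (identical(table$setting[1], "web")) "web" else "lab")
    discrepancy_N <- cond$discrepancy_N
  }
  train_cyc <- cycles_of(table, "training")
  test_cyc <- cycles_of(table, "test")
  base_win <- tail(train_cyc, 4)
  windows <- list(early = head(test_cyc, 4), end = tail(test_cyc, 16))
  test_id <- test_object_id(table)

  per <- table |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(g, key) {
      base <- g |>
        dplyr::filter(.data$cycle %in% base_win,
                      .data$object_id != test_id) |>
        dplyr::group_by(.data$object_id) |>
        dplyr::summarise(baseline = mean(.data$anticipatory_force_N),
                         .groups = "drop")
      if (nrow(base) == 0) abort("Baseline training cycles missing.")
      pos2 <- g |>
        dplyr::filter(.data$phase == "test") |>
        dplyr::arrange(.data$trial) |>
        dplyr::group_by(.data$cycle) |>
        dplyr::slice(2) |>
        dplyr::ungroup()
      purrr::map_dfr(names(windows), function(wn) {
        d <- dplyr::filter(pos2, .data$cycle %in% windows[[wn]]) |>
          dplyr::left_join(base, by = "object_id")
        tibble::tibble(
          window = wn,
          percent = mean((d$anticipatory_force_N - d$baseline) /
                           discrepancy_N * 100)
        )
      })
    }) |>
    dplyr::ungroup()

  wide <- tidyr::pivot_wider(per, names_from = "window",
                             values_from = "percent")
  run_t <- function(x, label) {
    if (sd(x) < 1e-12) {
      # all participants identical: t is 0 (or +/-Inf off zero)
      stat <- if (abs(mean(x)) < 1e-12) 0 else sign(mean(x)) * Inf
      tt <- list(statistic = stat, parameter = length(x) - 1,
                 p.value = if (stat == 0) 1 else 0)
    } else {
      tt <- t.test(x)
    }
    tibble::tibble(test = label, estimate = mean(x),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  }
  tests <- dplyr::bind_rows(
    run_t(wide$early, "early_vs_0"),
    run_t(wide$end, "end_vs_0"),
    run_t(wide$end - wide$early, "change_end_minus_early")
  )
  structure(list(per_participant = per, tests = tests,
                 discrepancy_N = discrepancy_N),
            class = "generalization_result")
}

#' Mixed-design ANOVA on log response times across task epochs
#'
#' Two-way repeated-measures ANOVA on log-transformed response times with a
#' between-subjects factor Group and a within-subjects factor Epoch (by
#' default four epochs splitting the training and test phases in half:
#' cycles 1-15, 16-30, 31-50, 51-70). Reported without sphericity
#' correction. Follow-up per-epoch one-tailed two-sample t-tests examine
#' whether the Group effect holds in each epoch individually.
#'
#' @param table Behavior tibble with a `group` column (two levels) and
#'   response times.
#' @param epochs Named list of cycle vectors.
#' @param followup_direction Alternative for per-epoch tests, in terms of
#'   the first group level minus the second; default `"less"` (first group
#'   faster).
#' @return A list of class `rt_anova_result`: `anova` (tidy F table),
#'   `followup` (per-epoch t-tests), `cell_means`.
#' @export
rt_epoch_anova <- function(table,
                           epochs = list(ep1 = 1:15, ep2 = 16:30,
                                         ep3 = 31:50, ep4 = 51:70),
                           followup_direction = "less") {
  if (!"group" %in% names(table)) {
    abort("`table` must contain a `group` column (two levels).")
  }
  if (any(table$response_time_ms <= 0, na.rm = TRUE)) {
    abort("Response times must be positive.")
  }
  cells <- purrr::map_dfr(names(epochs), function(en) {
    table |>
      dplyr::filter(.data$cycle %in% epochs[[en]],
                    !is.na(.data$response_time_ms)) |>
      dplyr::group_by(.data$participant_id, .data$group) |>
      dplyr::summarise(log_rt = mean(log(.data$response_time_ms)),
                       .groups = "drop") |>
      dplyr::mutate(epoch = en)
  })
  # participants are nested within groups; ids need only be unique per group
  cells$participant_id <- interaction(cells$group, cells$participant_id,
                                      drop = TRUE)
  counts <- dplyr::count(cells, .data$participant_id)
  if (dplyr::n_distinct(counts$n) != 1 ||
      counts$n[1] != length(epochs)) {
    abort("Unbalanced design: every participant needs every epoch.")
  }
  cells$group <- factor(cells$group)
  cells$epoch <- factor(cells$epoch, levels = names(epochs))
  fit <- aov(log_rt ~ group * epoch + Error(participant_id / epoch),
             data = cells)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: participant_id"]][[1]])
  within <- as.data.frame(sm[["Error: participant_id:epoch"]][[1]])
  row_of <- function(tab, pattern, effect) {
    i <- grep(pattern, trimws(rownames(tab)))[1]
    err <- grep("Residuals", trimws(rownames(tab)))[1]
    tibble::tibble(effect = effect,
                   df1 = tab$Df[i], df2 = tab$Df[err],
                   statistic = tab$`F value`[i],
                   p_value = tab$`Pr(>F)`[i])
  }
  anova_tab <- dplyr::bind_rows(
    row_of(between, "^group$", "group"),
    row_of(within, "^epoch$", "epoch"),
    row_of(within, "^group:epoch$", "group:epoch")
  )
  lv <- levels(cells$group)
  followup <- purrr::map_dfr(names(epochs), function(en) {
    d <- dplyr::filter(cells, .data$epoch == en)
    tt <- t.test(d$log_rt[d$group == lv[1]], d$log_rt[d$group == lv[2]],
                 alternative = followup_direction, var.equal = FALSE)
    tibble::tibble(epoch = en,
                   estimate = unname(tt$estimate[1] - tt$estimate[2]),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  })
  structure(list(anova = anova_tab, followup = followup,
                 cell_means = cells),
            class = "rt_anova_result")
}

#' Category switch-cost analysis of response times
#'
#' Response times grow with the force being prepared, so switch costs must
#' be assessed against a weight-matched prediction. A linear regression of
#' RT on scheduled weight (in N) is fitted over "non-switch" test-phase
#' trials -- excluding test-object trials and the trials immediately after
#' them. Predicted RT on switch trials is the non-switch mean plus the
#' slope times the force difference; the result reports observed minus
#' predicted RT for test-object trials and for immediately-following
#' trials, with per-participant t confidence intervals.
#'
#' @param table Single-condition behavior tibble with response times.
#' @return A list of class `switch_cost_result`: `slope_ms_per_N` and a
#'   tibble `costs` with observed-minus-predicted estimates and 95% CIs.
#' @export
switch_cost <- function(table) {
  assert_single_condition(table)
  test_id <- test_object_id(table)
  d <- table |>
    dplyr::filter(.data$phase == "test",
                  !is.na(.data$response_time_ms)) |>
    dplyr::arrange(.data$participant_id, .data$trial) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      is_test_obj = .data$object_id == test_id,
      after_test = dplyr::lag(.data$is_test_obj, default = FALSE),
      kind = dplyr::case_when(
        .data$is_test_obj ~ "switch_to_outlier",
        .data$after_test ~ "switch_from_outlier",
        TRUE ~ "non_switch")
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(weight_N = weight_to_force(.data$mass_g))
  ns <- dplyr::filter(d, .data$kind == "non_switch")
  if (nrow(ns) < 10) abort("Need at least 10 non-switch trials.")
  fit <- lm(response_time_ms ~ weight_N, data = ns)
  slope <- coef(fit)[["weight_N"]]
  ns_mean_rt <- mean(ns$response_time_ms)
  ns_mean_w <- mean(ns$weight_N)
  per <- d |>
    dplyr::filter(.data$kind != "non_switch") |>
    dplyr::group_by(.data$participant_id, .data$kind) |>
    dplyr::summarise(
      observed = mean(.data$response_time_ms),
      predicted = ns_mean_rt + slope * (mean(.data$weight_N) - ns_mean_w),
      .groups = "drop") |>
    dplyr::mutate(cost_ms = .data$observed - .data$predicted)
  costs <- per |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(
      estimate_ms = mean(.data$cost_ms),
      ci_lo = tryCatch(t.test(.data$cost_ms)$conf.int[1],
                       error = function(e) NA_real_),
      ci_hi = tryCatch(t.test(.data$cost_ms)$conf.int[2],
                       error = function(e) NA_real_),
      n = dplyr::n(), .groups = "drop")
  structure(list(slope_ms_per_N = slope, costs = costs,
                 per_participant = per),
            class = "switch_cost_result")
}

#' Two-sample comparison of end-of-test outlier forces between groups
#'
#' Pooled-variance two-sample t-test on per-participant mean anticipatory
#' force for the test object over the final 16 test cycles (used to compare
#' the gradual-ramp groups with their abrupt counterparts).
#'
#' @param table_a,table_b Single-condition behavior tibbles.
#' @return A one-row tibble with means, `statistic`, `df`, `p_value`.
#' @export
group_comparison <- function(table_a, table_b) {
  end_forces <- function(tab) {
    win <- tail(cycles_of(tab, "test"), 16)
    tab |>
      dplyr::filter(.data$cycle %in% win,
                    .data$object_id == test_object_id(tab)) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(f = mean(.data$anticipatory_force_N),
                       .groups = "drop") |>
      dplyr::pull("f")
  }
  a <- end_forces(table_a)
  b <- end_forces(table_b)
  tt <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 n_a = length(a), n_b = length(b))
}
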