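#' Exclusion configuration
#'
#' Bundles the trial- and participant-level exclusion settings. The
#' laboratory profile excludes anticipatory forces at or below 1 N or more
#' than 3.5 scaled median absolute deviations (MADs) from the participant's
#' per-object median, excludes response times more than 3.5 scaled MADs from
#' the per-object median after log transformation, and screens out
#' participants whose training forces lack a highly significant (alpha =
#' 0.01) positive correlation with object weight over the final 15 training
#' cycles. The web profile uses a 4-MAD criterion, no force floor, and a
#' milder (alpha = 0.10) correlation screen that must hold in both the final
#' five training cycles and the final five test cycles.
#'
#' @param profile `"lab"` or `"web"`.
#' @param mad_multiplier Multiplier on the scaled MAD.
#' @param force_floor_N Forces at or below this are excluded (`NA` for
#'   none).
#' @param nonlearner_alpha One-sided alpha for the learner screen.
#' @return A list of class `exclusion_config`.
#' @export
exclusion_config <- function(profile = c("lab", "web"),
                             mad_multiplier = NULL,
                             force_floor_N = NULL,
                             nonlearner_alpha = NULL) {
  profile <- match.arg(profile)
  defaults <- if (profile == "lab") {
    list(mad_multiplier = 3.5, force_floor_N = 1, nonlearner_alpha = 0.01)
  } else {
    list(mad_multiplier = 4, force_floor_N = NA_real_, nonlearner_alpha = 0.10)
  }
  out <- list(
    profile = profile,
    mad_multiplier = mad_multiplier %||% defaults$mad_multiplier,
    force_floor_N = force_floor_N %||% defaults$force_floor_N,
    nonlearner_alpha = nonlearner_alpha %||% defaults$nonlearner_alpha
  )
  stopifnot(out$mad_multiplier > 0,
            out$nonlearner_alpha > 0, out$nonlearner_alpha < 1)
  structure(out, class = "exclusion_config")
}

#' Robust outlier mask by scaled median absolute deviation
#'
#' Flags values more than `multiplier` scaled MADs (MAD times the
#' 1.4826 normal-consistency constant) from the median, optionally after a
#' log transformation. Cells whose MAD is zero produce no exclusions (a
#' degenerate, typically low-noise cell; excluding every non-median value
#' there would be catastrophic).
#'
#' @param values Numeric vector (one participant-by-object cell).
#' @param multiplier Multiplier on the scaled MAD.
#' @param log_transform Apply `log()` before computing deviations?
#' @return Logical mask, `TRUE` = flagged.
#' @export
mad_exclude <- function(values, multiplier = 3.5, log_transform = FALSE) {
  if (length(values) == 0) abort("`values` must be non-empty.")
  v <- if (log_transform) log(values) else values
  scaled_mad <- mad(v)  # stats::mad uses the 1.4826 constant by default
  if (scaled_mad == 0) return(rep(FALSE, length(values)))
  abs(v - median(v)) > multiplier * scaled_mad
}

#' Flag outlying trials in a behavior table
#'
#' Applies [mad_exclude()] per participant-by-object cell (pooled over all
#' cycles) to anticipatory forces (raw scale) and, when present, to response
#' times (log scale). Laboratory forces at or below the force floor are
#' flagged unconditionally.
#'
#' @param table A behavior tibble.
#' @param config An [exclusion_config()].
#' @return The table with logical columns `force_outlier` and `rt_outlier`.
#' @export
flag_outlier_trials <- function(table, config = exclusion_config("lab")) {
  has_rt <- "response_time_ms" %in% names(table) &&
    any(!is.na(table$response_time_ms))
  out <- table |>
    dplyr::group_by(.data$participant_id, .data$object_id) |>
    dplyr::mutate(
      force_outlier = mad_exclude(.data$anticipatory_force_N,
                                  config$mad_multiplier),
      rt_outlier = if (has_rt) {
        mad_exclude(.data$response_time_ms, config$mad_multiplier,
                    log_transform = TRUE)
      } else FALSE
    ) |>
    dplyr::ungroup()
  if (!is.na(config$force_floor_N)) {
    out$force_outlier <- out$force_outlier |
      out$anticipatory_force_N <= config$force_floor_N
  }
  out
}

#' Impute flagged trials from other participants
#'
#' Flagged anticipatory forces (or response times) are replaced by the mean
#' value produced on non-outlying trials by the other participants for the
#' same object, cycle and condition. Response times are averaged on the
#' original (ms) scale. If a cell has no donors the participant's own
#' non-flagged median for that object is used and a warning is raised.
#'
#' @param table Output of [flag_outlier_trials()].
#' @return The table with flagged values replaced, `imputed` flag set, and
#'   `excluded` marking rows that were flagged.
#' @export
impute_trials <- function(table) {
  need <- c("force_outlier", "rt_outlier")
  if (!all(need %in% names(table))) {
    abort("Run `flag_outlier_trials()` before `impute_trials()`.")
  }
  impute_one <- function(tab, value_col, flag_col) {
    vals <- tab[[value_col]]
    flags <- tab[[flag_col]]
    idx <- which(flags & !is.na(vals))
    for (i in idx) {
      donors <- which(
        !flags &
          tab$object_id == tab$object_id[i] &
          tab$cycle == tab$cycle[i] &
          tab$condition == tab$condition[i] &
          tab$participant_id != tab$participant_id[i]
      )
      if (length(donors)) {
        vals[i] <- mean(tab[[value_col]][donors])
      } else {
        own <- which(!flags &
                       tab$participant_id == tab$participant_id[i] &
                       tab$object_id == tab$object_id[i])
        warn(paste0("No donors for participant ", tab$participant_id[i],
                    ", object ", tab$object_id[i], ", cycle ", tab$cycle[i],
                    "; falling back to the participant's own cell median."))
        vals[i] <- median(tab[[value_col]][own])
      }
    }
    vals
  }
  out <- table
  out$anticipatory_force_N <-
    impute_one(table, "anticipatory_force_N", "force_outlier")
  if (any(table$rt_outlier)) {
    out$response_time_ms <-
      impute_one(table, "response_time_ms", "rt_outlier")
  }
  out$imputed <- table$force_outlier | table$rt_outlier
  out$excluded <- as.integer(out$imputed)
  out
}

#' Identify participants who learned the training weights
#'
#' A participant is retained when a one-sided Pearson test of anticipatory
#' force against scheduled weight over training-object trials rejects at
#' the configured alpha, in every required window. The laboratory profile
#' uses the final 15 cycles of the training phase; the web profile requires
#' the screen to pass in both the final five training cycles and the final
#' five test cycles. Conditions whose training phase contains only the test
#' object (`+Linear`, `++Linear`) are exempt. Participants with constant
#' forces (undefined correlation) are excluded.
#'
#' @param table A behavior tibble.
#' @param config An [exclusion_config()].
#' @return A tibble: `participant_id`, `condition`, `retained`, and the
#'   per-window one-sided p-values.
#' @export
learner_screen <- function(table, config = exclusion_config("lab")) {
  one_window <- function(d) {
    d <- dplyr::filter(d, .data$object_id != 3L)
    if (nrow(d) < 4 ||
        sd(d$anticipatory_force_N) == 0 || sd(d$mass_g) == 0) {
      return(NA_real_)
    }
    cor.test(d$anticipatory_force_N, weight_to_force(d$mass_g),
             alternative = "greater")$p.value
  }
  table |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      train_cycles <- sort(unique(d$cycle[d$phase == "training"]))
      single_object_training <-
        length(unique(d$object_id[d$phase == "training"])) == 1
      if (single_object_training) {
        return(tibble::tibble(retained = TRUE,
                              p_training = NA_real_, p_test = NA_real_))
      }
      if (config$profile == "lab") {
        win <- tail(train_cycles, 15)
        p1 <- one_window(dplyr::filter(d, .data$cycle %in% win))
        tibble::tibble(
          retained = !is.na(p1) && p1 < config$nonlearner_alpha,
          p_training = p1, p_test = NA_real_)
      } else {
        win1 <- tail(train_cycles, 5)
        test_cycles <- sort(unique(d$cycle[d$phase == "test"]))
        win2 <- tail(test_cycles, 5)
        p1 <- one_window(dplyr::filter(d, .data$cycle %in% win1))
        p2 <- one_window(dplyr::filter(d, .data$cycle %in% win2))
        tibble::tibble(
          retained = !is.na(p1) && !is.na(p2) &&
            p1 < config$nonlearner_alpha && p2 < config$nonlearner_alpha,
          p_training = p1, p_test = p2)
      }
    }) |>
    dplyr::ungroup()
}

#' Full preprocessing pipeline
#'
#' Flags and imputes outlying trials, screens out non-learner participants,
#' and returns the cleaned table together with an exclusions report.
#' Preprocessing is idempotent: applying it to its own output changes
#' nothing.
#'
#' @param table A behavior tibble.
#' @param config An [exclusion_config()]; defaults to the profile matching
#'   the table's `setting` column.
#' @return A list of class `preprocess_result`: `table` (cleaned rows of
#'   retained participants), `screen` (per-participant retention),
#'   `report` (tibble participant x rule x count).
#' @export
preprocess_behavior <- function(table, config = NULL) {
  config <- config %||%
    exclusion_config(if (identical(table$setting[1], "web")) "web" else "lab")
  flagged <- flag_outlier_trials(table, config)
  imputed <- impute_trials(flagged)
  screen <- learner_screen(imputed, config)
  keep <- screen$participant_id[screen$retained]
  report <- dplyr::bind_rows(
    flagged |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(rule = "force_outlier",
                       count = sum(.data$force_outlier), .groups = "drop"),
    flagged |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(rule = "rt_outlier",
                       count = sum(.data$rt_outlier), .groups = "drop"),
    tibble::tibble(participant_id = screen$participant_id,
                   rule = "nonlearner",
                   count = as.integer(!screen$retained))
  )
  cleaned <- imputed |>
    dplyr::filter(.data$participant_id %in% keep) |>
    dplyr::select(-"force_outlier", -"rt_outlier")
  structure(list(table = cleaned, screen = screen, report = report),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  n_flag <- sum(x$table$imputed)
  cat("<preprocess_result>\n")
  cat("  retained participants:", sum(x$screen$retained), "of",
      nrow(x$screen), "\n")
  cat("  imputed trials:", n_flag,
      sprintf("(%.2f%%)", 100 * n_flag / max(nrow(x$table), 1)), "\n")
  invisible(x)
}
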