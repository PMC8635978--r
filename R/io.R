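BEHAVIOR_REQUIRED_COLS <- c(
  "participant_id", "condition", "trial", "phase", "cycle", "object_id",
  "volume_cm3", "mass_g", "anticipatory_force_N"
)
BEHAVIOR_NUMERIC_COLS <- c(
  "participant_id", "trial", "cycle", "object_id", "volume_cm3", "mass_g",
  "anticipatory_force_N"
)

#' Read a behavior table from CSV
#'
#' Validates the documented schema (header required, UTF-8, decimal-point
#' numbers): required columns `participant_id`, `condition`, `trial`,
#' `phase`, `cycle`, `object_id`, `volume_cm3`, `mass_g`,
#' `anticipatory_force_N`; optional columns (e.g. `response_time_ms`,
#' `setting`, `model_type`, `excluded`, `analysis_excluded`) are preserved.
#'
#' @param path CSV file path.
#' @return A behavior tibble.
#' @export
read_behavior_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         locale = readr::locale(decimal_mark = "."))
  missing <- setdiff(BEHAVIOR_REQUIRED_COLS, names(tab))
  if (length(missing)) {
    abort(paste0("Behavior table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- BEHAVIOR_NUMERIC_COLS[
    !vapply(tab[BEHAVIOR_NUMERIC_COLS], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("Non-numeric values in column(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (!"setting" %in% names(tab)) tab$setting <- "lab"
  tab
}

#' Write a behavior table to CSV
#'
#' @param table Behavior tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_behavior_table <- function(table, path) {
  missing <- setdiff(BEHAVIOR_REQUIRED_COLS, names(table))
  if (length(missing)) {
    abort(paste0("Behavior table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_csv(table, path)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param conditions Character vector of condition names.
#' @param setting `"lab"` or `"web"`.
#' @param model_type `"family"` or `"map"`.
#' @param n_participants Cohort size per condition.
#' @param seed Integer seed (explicit; no wall-clock seeding).
#' @param analyses Subset of `c("famstats", "mixtures", "power")`.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param power_reps Replicates for the power analysis, if enabled.
#' @return A list of class `run_config`.
#' @export
run_config <- function(conditions = c("Linear+", "Linear++", "Uncorr+"),
                       setting = "lab",
                       model_type = "family",
                       n_participants = 14,
                       seed = 1L,
                       analyses = c("famstats", "mixtures"),
                       out_dir = NULL,
                       power_reps = 1000) {
  bad <- setdiff(conditions, condition_names(setting))
  if (length(bad)) {
    abort(paste0("Unknown ", setting, " condition(s): ",
                 paste(bad, collapse = ", ")))
  }
  bad <- setdiff(analyses, c("famstats", "mixtures", "power"))
  if (length(bad)) {
    abort(paste0("Unknown analysis toggle(s): ", paste(bad, collapse = ", ")))
  }
  if (n_participants < 2 && "famstats" %in% analyses) {
    abort("Group tests need at least 2 participants per condition.")
  }
  structure(list(conditions = conditions, setting = setting,
                 model_type = model_type, n_participants = n_participants,
                 seed = as.integer(seed), analyses = analyses,
                 out_dir = out_dir, power_reps = power_reps),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with fields matching [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the simulate -> preprocess -> analyze pipeline
#'
#' For each configured condition: simulates a cohort, preprocesses it, and
#' runs the configured analyses. With an output directory set, writes the
#' cleaned behavior tables, a tidy results CSV, a JSON summary and a run
#' manifest (config and seeds) for reproducibility.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `tables` (cleaned behavior
#'   tables by condition), `results` (tidy tibble: analysis, group,
#'   statistic, value, ci_lo, ci_hi, p), `mixtures`, `power`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tables <- list()
  rows <- list()
  mixtures <- list()
  for (i in seq_along(config$conditions)) {
    cn <- config$conditions[i]
    cond <- condition(cn, config$setting)
    raw <- simulate_cohort(cond, config$model_type, config$n_participants,
                           seed = derive_seed(config$seed, i))
    pre <- preprocess_behavior(raw)
    tab <- pre$table
    tables[[cn]] <- tab
    if (sum(pre$screen$retained) < 2) {
      abort(paste0("Condition ", cn, ": fewer than 2 retained ",
                   "participants; increase the cohort size."))
    }
    if ("famstats" %in% config$analyses) {
      ec <- endphase_correlation(tab)
      ol <- outlier_learning_test(tab)
      gen <- single_trial_generalization(tab)
      rows[[length(rows) + 1]] <- dplyr::bind_rows(
        tibble::tibble(analysis = "endphase_correlation", group = cn,
                       statistic = paste0("r_", ec$method), value = ec$r,
                       ci_lo = ec$ci_lo, ci_hi = ec$ci_hi, p = NA_real_),
        tibble::tibble(analysis = "outlier_learning", group = cn,
                       statistic = "mean_learning_N",
                       value = ol$mean_learning_N,
                       ci_lo = NA_real_, ci_hi = NA_real_,
                       p = ol$p_value),
        tibble::tibble(analysis = "generalization", group = cn,
                       statistic = gen$tests$test,
                       value = gen$tests$estimate,
                       ci_lo = NA_real_, ci_hi = NA_real_,
                       p = gen$tests$p_value)
      )
    }
    if ("mixtures" %in% config$analyses) {
      mi <- mixture_input(tab)
      if (nrow(mi) >= 5) {
        bm <- bimodality_analysis(mi$value,
                                  seed = derive_seed(config$seed, 100L + i))
        mixtures[[cn]] <- bm
        rows[[length(rows) + 1]] <- tibble::tibble(
          analysis = "bimodality", group = cn,
          statistic = c("delta_aic", "relative_likelihood"),
          value = c(bm$comparison$delta_aic,
                    bm$comparison$relative_likelihood),
          ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_)
      }
    }
  }
  power <- NULL
  if ("power" %in% config$analyses) {
    power <- power_for_n(n_reps = config$power_reps,
                         seed = derive_seed(config$seed, 999L))
    rows[[length(rows) + 1]] <- tibble::tibble(
      analysis = "power", group = "n=36", statistic = "power",
      value = power$power, ci_lo = power$ci_lo, ci_hi = power$ci_hi,
      p = NA_real_)
  }
  results <- dplyr::bind_rows(rows)
  out <- structure(list(tables = tables, results = results,
                        mixtures = mixtures, power = power,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline(out, config$out_dir)
  out
}

write_pipeline <- function(result, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory: ", out_dir))
  }
  for (cn in names(result$tables)) {
    fn <- file.path(out_dir,
                    paste0("behavior_", gsub("[^A-Za-z0-9]+", "_", cn),
                           ".csv"))
    write_behavior_table(result$tables[[cn]], fn)
  }
  readr::write_csv(result$results, file.path(out_dir, "results.csv"))
  summary <- list(
    conditions = result$config$conditions,
    setting = result$config$setting,
    model_type = result$config$model_type,
    n_participants = result$config$n_participants,
    seed = result$config$seed,
    results = result$results
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("famlift")),
    r_version = R.version.string,
    seed = result$config$seed,
    config_hash = rlang::hash(unclass(result$config)),
    timestamp = NA_character_  # deterministic outputs carry no wall-clock
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", length(x$tables), "condition(s),",
      nrow(x$results), "result rows\n")
  print(x$results, n = 20)
  invisible(x)
}
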