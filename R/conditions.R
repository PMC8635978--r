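#' Standard gravitational acceleration used throughout the task (m/s^2)
#'
#' @keywords internal
#' @noRd
GRAVITY <- 9.81

#' Convert an object mass to the force required to support it
#'
#' Masses are carried in grams throughout the package (matching the units in
#' which the task conditions are defined); forces are carried in newtons.
#' The conversion uses g = 9.81 m/s^2 exactly, and no rounding is applied --
#' round only at display.
#'
#' @param mass_g Numeric vector of masses in grams. Must be non-negative.
#' @return Numeric vector of forces in newtons.
#' @examples
#' weight_to_force(900)  # ~8.83 N, the mean training-object weight
#' weight_to_force(1500) # ~14.72 N
#' @export
weight_to_force <- function(mass_g) {
  if (!is.numeric(mass_g) || any(!is.finite(mass_g))) {
    abort("`mass_g` must be a finite numeric vector.")
  }
  if (any(mass_g < 0)) {
    abort("`mass_g` must be non-negative.")
  }
  mass_g / 1000 * GRAVITY
}

# Laboratory object geometry: five cylinders of common radius whose heights
# give equally spaced nominal volumes of 400..800 cm^3.
LAB_RADIUS_CM <- 4.61
LAB_HEIGHTS_CM <- c(6, 7.5, 9, 10.5, 12)
LAB_VOLUMES_CM3 <- c(400, 500, 600, 700, 800)

# Web object geometry: smaller cylinders; volumes are exact pi * r^2 * h.
WEB_RADIUS_CM <- 2
WEB_HEIGHTS_CM <- 3:7

LAB_TRAINING_MASSES_G <- c(600, 750, 1050, 1200)   # density 1.5 g/cm^3
WEB_TRAINING_MASSES_G <- c(300, 400, 600, 700)

#' Names of the available experimental conditions
#'
#' @param setting `"lab"` or `"web"`.
#' @return Character vector of condition names.
#' @export
condition_names <- function(setting = c("lab", "web")) {
  setting <- match.arg(setting)
  if (setting == "lab") {
    c("Linear+", "Linear++", "Uncorr+", "+Linear", "++Linear",
      "LinearUp", "LinearDown")
  } else {
    c("Linear+", "Linear++", "Linear-", "Linear--")
  }
}

#' Define an experimental condition
#'
#' Returns the full definition of one of the object-lifting conditions:
#' the object set, the scheduled masses, the phase structure (ordered phases
#' with cycle counts and trials per cycle), rest-break trial indices, and the
#' weight discrepancy of the outlier (test) object relative to the weight
#' predicted by the training-object family.
#'
#' Laboratory conditions use five cylinders with nominal volumes 400--800
#' cm^3; the four training objects (the two smallest and two largest) weigh
#' 600, 750, 1050 and 1200 g -- a constant density of 1.5 g/cm^3 -- and the
#' mid-size test object weighs 1200 g ("+" conditions) or 1500 g ("++"),
#' i.e. 300 g or 600 g more than the family-predicted 900 g. In the ramp
#' conditions (`LinearUp`, `LinearDown`) the test-object weight steps by
#' 50 g at trials 221, 261, 301, 341, 381 and 421 between 1200 and 1500 g.
#' Web conditions use training weights 300--700 g and test weights 700, 900,
#' 300 or 100 g.
#'
#' @param name Condition name; see [condition_names()].
#' @param setting `"lab"` or `"web"`.
#' @return An object of class `lift_condition`.
#' @export
condition <- function(name, setting = c("lab", "web")) {
  setting <- match.arg(setting)
  if (!name %in% condition_names(setting)) {
    abort(paste0("Unknown ", setting, " condition: '", name, "'. Available: ",
                 paste(condition_names(setting), collapse = ", ")))
  }

  if (setting == "lab") {
    phases <- switch(
      name,
      "Linear+" = ,
      "Linear++" = ,
      "Uncorr+" = tibble::tibble(
        phase = c("training", "test"),
        n_cycles = c(30L, 40L),
        trials_per_cycle = c(4L, 5L)
      ),
      "+Linear" = ,
      "++Linear" = tibble::tibble(
        phase = c("training", "test", "one_to_one"),
        n_cycles = c(30L, 40L, 10L),
        trials_per_cycle = c(1L, 5L, 8L)
      ),
      "LinearUp" = ,
      "LinearDown" = tibble::tibble(
        phase = c("training", "test"),
        n_cycles = c(30L, 68L),
        trials_per_cycle = c(4L, 5L)
      )
    )
    outlier_mass <- switch(name,
      "Linear+" = 1200, "Uncorr+" = 1200, "+Linear" = 1200,
      "Linear++" = 1500, "++Linear" = 1500,
      "LinearUp" = 1200, "LinearDown" = 1500)
    ramp <- NULL
    if (name %in% c("LinearUp", "LinearDown")) {
      ramp <- list(
        start_mass_g = outlier_mass,
        step_g = if (name == "LinearUp") 50 else -50,
        change_trials = c(221L, 261L, 301L, 341L, 381L, 421L),
        range_g = c(1200, 1500)
      )
    }
    rest_breaks <- switch(name,
      "+Linear" = , "++Linear" = c(90L, 190L),
      "LinearUp" = , "LinearDown" = c(60L, 120L, 220L, 300L, 380L),
      c(60L, 120L, 200L))
    out <- list(
      name = name,
      setting = setting,
      phases = phases,
      radius_cm = LAB_RADIUS_CM,
      heights_cm = LAB_HEIGHTS_CM,
      volumes_cm3 = LAB_VOLUMES_CM3,
      training_masses_g = LAB_TRAINING_MASSES_G,
      outlier_mass_g = outlier_mass,
      ramp = ramp,
      uncorrelated = identical(name, "Uncorr+"),
      max_abs_r = if (identical(name, "Uncorr+")) 0.3 else NA_real_,
      rest_breaks = rest_breaks
    )
  } else {
    phases <- tibble::tibble(
      phase = c("training", "test"),
      n_cycles = c(15L, 20L),
      trials_per_cycle = c(4L, 5L)
    )
    outlier_mass <- switch(name,
      "Linear+" = 700, "Linear++" = 900, "Linear-" = 300, "Linear--" = 100)
    out <- list(
      name = name,
      setting = setting,
      phases = phases,
      radius_cm = WEB_RADIUS_CM,
      heights_cm = WEB_HEIGHTS_CM,
      volumes_cm3 = pi * WEB_RADIUS_CM^2 * WEB_HEIGHTS_CM,
      training_masses_g = WEB_TRAINING_MASSES_G,
      outlier_mass_g = outlier_mass,
      ramp = NULL,
      uncorrelated = FALSE,
      max_abs_r = NA_real_,
      rest_breaks = integer(0)
    )
  }

  # Family-predicted mass at the test volume: the test object is always the
  # middle size, so the family prediction equals the mean training mass.
  family_mass <- mean(out$training_masses_g)
  final_mass <- if (is.null(out$ramp)) out$outlier_mass_g else {
    out$ramp$start_mass_g + out$ramp$step_g * length(out$ramp$change_trials)
  }
  out$family_expected_mass_g <- family_mass
  out$discrepancy_N <- weight_to_force(abs(final_mass - family_mass))
  out$outlier_sign <- sign(final_mass - family_mass)
  out$n_trials <- sum(out$phases$n_cycles * out$phases$trials_per_cycle)
  out$training_ids <- c(1L, 2L, 4L, 5L)
  out$test_id <- 3L
  structure(out, class = "lift_condition")
}

#' @export
print.lift_condition <- function(x, ...) {
  cat("<lift_condition> ", x$name, " (", x$setting, ")\n", sep = "")
  cat("  trials:", x$n_trials, " phases:",
      paste0(x$phases$phase, " (", x$phases$n_cycles, "x",
             x$phases$trials_per_cycle, ")", collapse = ", "), "\n")
  cat("  training masses (g):", paste(x$training_masses_g, collapse = ", "),
      " outlier (g):", x$outlier_mass_g,
      if (!is.null(x$ramp)) paste0(" (ramp ", x$ramp$step_g, " g/step)") else "",
      "\n")
  invisible(x)
}

#' Enumerate admissible training-mass assignments for an uncorrelated design
#'
#' In the Uncorr+ condition the four training masses are randomly assigned to
#' the four training volumes subject to the absolute Pearson correlation
#' between volume and mass not exceeding `max_abs_r`. This enumerates all 24
#' permutations and returns the admissible ones.
#'
#' @param volumes Training volumes (cm^3).
#' @param masses Training masses (g).
#' @param max_abs_r Inclusive bound on |Pearson r(volume, mass)|.
#' @return A tibble with one row per admissible permutation: list-column
#'   `masses` (mass order over `volumes`) and column `r`.
#' @export
admissible_mass_assignments <- function(volumes = c(400, 500, 700, 800),
                                        masses = c(600, 750, 1050, 1200),
                                        max_abs_r = 0.3) {
  perms <- all_permutations(length(masses))
  res <- purrr::map(seq_len(nrow(perms)), function(i) {
    m <- masses[perms[i, ]]
    tibble::tibble(masses = list(m), r = cor(volumes, m))
  })
  out <- dplyr::bind_rows(res)
  dplyr::filter(out, abs(.data$r) <= max_abs_r)
}

# All permutations of 1..n as a matrix (rows), n small.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
  unname(out)
}

#' Build the object set for a condition and participant
#'
#' Returns one row per carousel object with its geometry, nominal volume and
#' scheduled mass. For linear conditions masses are assigned by volume rank;
#' for the Uncorr+ condition the four training masses are a uniformly drawn
#' admissible permutation (|r(volume, mass)| <= 0.3), drawn from the
#' participant seed by rejection sampling. For ramp conditions the mass given
#' here is the test object's starting mass; per-trial resolution happens in
#' [generate_schedule()].
#'
#' @param condition A [condition()] object.
#' @param seed Integer seed (per participant).
#' @return A tibble: `object_id` (1..5, rank by volume), `radius_cm`,
#'   `height_cm`, `volume_cm3`, `mass_g`, `role` ("training"/"test").
#' @export
make_objects <- function(condition, seed = 1L) {
  stopifnot(inherits(condition, "lift_condition"))
  vols <- condition$volumes_cm3
  train_vols <- vols[condition$training_ids]
  masses_train <- condition$training_masses_g
  if (condition$uncorrelated) {
    masses_train <- withr::with_seed(seed, {
      repeat {
        m <- sample(condition$training_masses_g)
        if (abs(cor(train_vols, m)) <= condition$max_abs_r) break
      }
      m
    })
  }
  mass <- numeric(5)
  mass[condition$training_ids] <- masses_train
  mass[condition$test_id] <- condition$outlier_mass_g
  tibble::tibble(
    object_id = 1:5,
    radius_cm = condition$radius_cm,
    height_cm = condition$heights_cm,
    volume_cm3 = vols,
    mass_g = mass,
    role = ifelse(seq_len(5) == condition$test_id, "test", "training")
  )
}
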