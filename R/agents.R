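#' Parameters of the object-families learner
#'
#' A generative agent implementing the categorical (object-families)
#' hypothesis. The agent maintains a single family density estimate shared by
#' all objects classified as family members, plus individual mass memories
#' for objects classified as individuals:
#'
#' * The first object ever lifted founds the family: the density estimate is
#'   initialized to its observed density (before that lift, predictions come
#'   from the visual prior density).
#' * A member's predicted force is `density_estimate * volume * g`; after a
#'   member lift the density estimate moves toward the observed density by a
#'   delta rule with rate `family_learning_rate`, so learning generalizes to
#'   every member.
#' * Expulsion from the family requires accumulated evidence: the absolute
#'   discrepancies between observed weight and family prediction on the
#'   object's last `reclassify_window` member lifts are summed and divided
#'   by the window length (a fixed-size window, so a single aberrant lift
#'   cannot trigger expulsion; the evidence saturates after
#'   `reclassify_window` consistent lifts). When this evidence exceeds the
#'   participant's category boundary, the object is expelled and gets its
#'   own mass memory, initialized at the family-predicted mass and updated
#'   by a delta rule with rate `individual_learning_rate`. Expelled objects
#'   contribute nothing to the family estimate.
#' * The effective boundary for an object widens with the discrepancies the
#'   participant has already tolerated for it (an exponentially weighted
#'   mean with rate `boundary_broadening` added to the base threshold), so a
#'   gradually growing deviation broadens the category while an abrupt jump
#'   of the same final size triggers expulsion.
#' * With `hysteresis = TRUE` (default) an expelled object remains an
#'   individual even if its discrepancy later shrinks; with `FALSE` it
#'   rejoins the family once the family prediction is again within the
#'   boundary.
#'
#' @param prior_density Visual prior density (g/cm^3) used before the first
#'   lift of the founding object.
#' @param family_learning_rate Delta-rule rate for the family density, in
#'   (0, 1].
#' @param individual_learning_rate Delta-rule rate for individual mass
#'   memories, in (0, 1].
#' @param boundary_threshold_N Category boundary: force discrepancy (N) at
#'   which an object is expelled from the family.
#' @param reclassify_window Number of recent member lifts over which the
#'   discrepancy evidence is averaged before comparing to the boundary.
#' @param boundary_broadening Rate in [0, 1) of the exponentially weighted
#'   mean of tolerated discrepancies that widens the effective boundary;
#'   0 disables broadening.
#' @param hysteresis Do expelled objects remain individuals as their
#'   discrepancy shrinks?
#' @param motor_noise_sd_N SD of additive zero-mean motor noise on emitted
#'   forces (N).
#' @return A list of class `family_params`.
#' @export
family_params <- function(prior_density = 1,
                          family_learning_rate = 0.3,
                          individual_learning_rate = 0.8,
                          boundary_threshold_N = 5,
                          reclassify_window = 3,
                          boundary_broadening = 0.05,
                          hysteresis = TRUE,
                          motor_noise_sd_N = 1) {
  stopifnot(family_learning_rate > 0, family_learning_rate <= 1,
            individual_learning_rate > 0, individual_learning_rate <= 1,
            boundary_threshold_N > 0, motor_noise_sd_N >= 0,
            reclassify_window >= 1,
            boundary_broadening >= 0, boundary_broadening < 1)
  structure(as.list(environment()), class = "family_params")
}

#' Parameters of the associative-map learner
#'
#' A generative agent implementing the associative-map hypothesis: predicted
#' force is a normalized Gaussian-kernel expansion over object volume,
#' `F(V) = sum_i w_i phi_i(V) / sum_i phi_i(V)`, and after each lift the
#' kernel weights move toward the observed weight by a normalized delta
#' rule, `w_i <- w_i + rate * (w_obs - F(V)) * phi_i(V) / sum_j phi_j(V)`.
#' Overlapping kernels produce graded generalization and partial learning of
#' any outlier -- the discriminating prediction of the associative account.
#'
#' @param kernel_centers Kernel centers (cm^3); defaults to the volumes of
#'   the condition's five objects.
#' @param kernel_width Gaussian kernel SD (cm^3); defaults to 0.75 times
#'   the mean spacing of the centers, giving substantial but not complete
#'   interference between neighboring objects.
#' @param learning_rate Delta-rule rate in (0, 1].
#' @param prior_density Visual prior density (g/cm^3) used to initialize the
#'   kernel weights (`w_i = prior_density * center_i * g`).
#' @param motor_noise_sd_N SD of additive motor noise on emitted forces (N).
#' @return A list of class `associative_params`.
#' @export
associative_params <- function(kernel_centers = NULL,
                               kernel_width = NULL,
                               learning_rate = 0.5,
                               prior_density = 1,
                               motor_noise_sd_N = 1) {
  stopifnot(learning_rate >= 0, learning_rate <= 1, motor_noise_sd_N >= 0)
  if (!is.null(kernel_width)) stopifnot(kernel_width > 0)
  structure(as.list(environment()), class = "associative_params")
}

#' Response-time emission parameters
#'
#' Response times are generated as
#' `RT = base + slope * predicted_force + selection_cost * (n_categories - 1)
#' + noise`, where `n_categories` counts the memory categories currently
#' held (the family plus one per individual object; always 1 for the
#' associative agent). The slope default reflects the robust empirical
#' finding that producing larger anticipatory forces takes longer.
#'
#' @param base_ms Baseline response time (ms).
#' @param slope_ms_per_N Increase in RT per newton of predicted force.
#' @param selection_cost_ms Extra time per memory category beyond the first.
#' @param noise_sd_ms SD of additive RT noise (ms); RTs are floored at
#'   `floor_ms`.
#' @param floor_ms Minimum emitted RT (ms).
#' @return A list of class `rt_params`.
#' @export
rt_params <- function(base_ms = 500, slope_ms_per_N = 26.2,
                      selection_cost_ms = 40, noise_sd_ms = 80,
                      floor_ms = 150) {
  structure(as.list(environment()), class = "rt_params")
}

#' Simulate a single object-families participant
#'
#' Runs the [family_params()] agent over a trial schedule and returns one
#' behavior-table row per lift.
#'
#' @param params A [family_params()] object.
#' @param schedule A [generate_schedule()] tibble.
#' @param seed Integer seed for motor and RT noise.
#' @param participant_id Identifier stored in the output.
#' @param rt A [rt_params()] object, or `NULL` to omit response times.
#' @return A tibble with columns `participant_id`, `condition`,
#'   `model_type`, `trial`, `phase`, `cycle`, `object_id`, `volume_cm3`,
#'   `mass_g`, `anticipatory_force_N`, `response_time_ms`,
#'   `analysis_excluded`, `excluded`.
#' @export
simulate_family_participant <- function(params, schedule, seed = 1L,
                                        participant_id = 1L,
                                        rt = rt_params()) {
  stopifnot(inherits(params, "family_params"))
  n <- nrow(schedule)
  obj_ids <- sort(unique(schedule$object_id))
  idx <- function(o) match(o, obj_ids)
  nobj <- length(obj_ids)

  member <- rep(TRUE, nobj)
  m_hat <- rep(NA_real_, nobj)
  hist <- vector("list", nobj)
  e_ema <- rep(0, nobj)
  founded <- FALSE
  d_hat <- params$prior_density

  pred <- numeric(n)
  n_cat <- integer(n)
  for (t in seq_len(n)) {
    o <- idx(schedule$object_id[t])
    V <- schedule$volume_cm3[t]
    m <- schedule$mass_g[t]
    w <- weight_to_force(m)
    n_cat[t] <- 1L + sum(!member)

    if (!founded) {
      pred[t] <- weight_to_force(params$prior_density * V)
      d_hat <- m / V
      founded <- TRUE
      next
    }

    if (member[o]) {
      p <- weight_to_force(d_hat * V)
      pred[t] <- p
      e <- abs(w - p)
      hist[[o]] <- tail(c(hist[[o]], e), params$reclassify_window)
      evidence <- sum(hist[[o]]) / params$reclassify_window
      if (evidence > params$boundary_threshold_N + e_ema[o]) {
        member[o] <- FALSE
        m_hat[o] <- d_hat * V
        m_hat[o] <- m_hat[o] + params$individual_learning_rate * (m - m_hat[o])
      } else {
        lam <- params$boundary_broadening
        e_ema[o] <- (1 - lam) * e_ema[o] + lam * e
        d_hat <- d_hat + params$family_learning_rate * (m / V - d_hat)
      }
    } else {
      pred[t] <- weight_to_force(m_hat[o])
      m_hat[o] <- m_hat[o] + params$individual_learning_rate * (m - m_hat[o])
      if (!params$hysteresis &&
          abs(w - weight_to_force(d_hat * V)) <= params$boundary_threshold_N) {
        member[o] <- TRUE
        hist[[o]] <- NULL
        e_ema[o] <- 0
      }
    }
  }

  emit_rows(schedule, pred, n_cat, params$motor_noise_sd_N, seed,
            participant_id, "family", rt)
}

#' Simulate a single associative-map participant
#'
#' Runs the [associative_params()] agent over a trial schedule.
#'
#' @inheritParams simulate_family_participant
#' @param params An [associative_params()] object.
#' @return A behavior tibble; see [simulate_family_participant()].
#' @export
simulate_associative_participant <- function(params, schedule, seed = 1L,
                                             participant_id = 1L,
                                             rt = rt_params()) {
  stopifnot(inherits(params, "associative_params"))
  centers <- params$kernel_centers %||% sort(unique(schedule$volume_cm3))
  width <- params$kernel_width %||% (0.75 * mean(diff(sort(centers))))
  wts <- weight_to_force(params$prior_density * centers)

  n <- nrow(schedule)
  pred <- numeric(n)
  for (t in seq_len(n)) {
    V <- schedule$volume_cm3[t]
    w <- weight_to_force(schedule$mass_g[t])
    phi <- exp(-(V - centers)^2 / (2 * width^2))
    phi_n <- phi / sum(phi)
    p <- sum(wts * phi_n)
    pred[t] <- p
    wts <- wts + params$learning_rate * (w - p) * phi_n
  }
  emit_rows(schedule, pred, rep(1L, n), params$motor_noise_sd_N, seed,
            participant_id, "map", rt)
}

# Shared emission: add motor noise to internal predictions, generate RTs,
# assemble the behavior table.
emit_rows <- function(schedule, pred, n_cat, noise_sd, seed,
                      participant_id, model_type, rt) {
  n <- nrow(schedule)
  withr::with_seed(seed, {
    force <- pred + rnorm(n, 0, noise_sd)
    force <- pmax(force, 0.01)
    rt_ms <- if (is.null(rt)) rep(NA_real_, n) else {
      pmax(rt$base_ms + rt$slope_ms_per_N * pred +
             rt$selection_cost_ms * (n_cat - 1L) +
             rnorm(n, 0, rt$noise_sd_ms),
           rt$floor_ms)
    }
    tibble::tibble(
      participant_id = as.integer(participant_id),
      condition = attr(schedule, "condition_name") %||% NA_character_,
      setting = attr(schedule, "setting") %||% "lab",
      model_type = model_type,
      trial = schedule$trial,
      phase = schedule$phase,
      cycle = schedule$cycle,
      object_id = schedule$object_id,
      volume_cm3 = schedule$volume_cm3,
      mass_g = schedule$mass_g,
      anticipatory_force_N = force,
      response_time_ms = rt_ms,
      analysis_excluded = schedule$analysis_excluded,
      excluded = 0L
    )
  })
}

#' Default population-level calibration for a cohort
#'
#' Between-participant variability enters through the category boundary of
#' the family agent: thresholds are drawn from a normal distribution whose
#' mean and spread scale with the condition's training force range (the span
#' of family forces sets the natural scale of tolerable discrepancies). At
#' the laboratory scale this puts the mean boundary at about 5.0 N with SD
#' about 1.5 N, so that the two outlier discrepancies used in the task
#' (roughly 2.9 and 5.9 N) fall on opposite flanks of the boundary
#' distribution: small-discrepancy outliers are retained by most
#' participants while large-discrepancy outliers split the population into
#' learners and non-learners. Motor noise is 1 N in the laboratory setting
#' and 0.7 N in the web setting.
#'
#' In addition to trial-to-trial motor noise, each participant carries a
#' constant force bias (drawn from a zero-mean normal with SD
#' `participant_bias_sd_N`), reflecting stable individual over- or
#' under-estimation of the force scale.
#'
#' @param condition A [condition()] object.
#' @return A list with `threshold_mean_N`, `threshold_sd_N`,
#'   `motor_noise_sd_N`, `participant_bias_sd_N`.
#' @export
default_population <- function(condition) {
  span <- weight_to_force(diff(range(condition$training_masses_g)))
  list(
    threshold_mean_N = 0.85 * span,
    threshold_sd_N = 0.25 * span,
    motor_noise_sd_N = if (condition$setting == "web") 0.7 else 1,
    participant_bias_sd_N = 0.6
  )
}

#' Simulate a cohort of participants
#'
#' Draws per-participant category boundaries (family model) from the
#' population spread, runs the per-participant simulator with seeds derived
#' from the cohort seed by a splittable counter scheme (so a cohort can be
#' extended without reshuffling existing participants), and concatenates the
#' rows. For the Uncorr+ condition each participant receives their own
#' admissible random size-to-weight assignment.
#'
#' @param condition A [condition()] object.
#' @param model_type `"family"` or `"map"`.
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer cohort seed; all randomness derives from it.
#' @param population Population calibration, see [default_population()].
#' @param params Agent parameters ([family_params()] or
#'   [associative_params()]); the population threshold and noise settings
#'   are applied on top for the family model.
#' @param rt A [rt_params()] object or `NULL`.
#' @return A behavior tibble (one row per participant x trial).
#' @export
simulate_cohort <- function(condition,
                            model_type = c("family", "map"),
                            n_participants,
                            seed = 1L,
                            population = default_population(condition),
                            params = NULL,
                            rt = rt_params()) {
  model_type <- match.arg(model_type)
  stopifnot(n_participants >= 1)
  rows <- purrr::map(seq_len(n_participants), function(i) {
    pseed <- derive_seed(seed, i)
    # per-participant population draws use their own derived seed so that
    # extending the cohort never reshuffles existing participants
    draw <- withr::with_seed(derive_seed(pseed, 13L), {
      list(threshold = max(rnorm(1, population$threshold_mean_N,
                                 population$threshold_sd_N), 0.5),
           bias = rnorm(1, 0, population$participant_bias_sd_N %||% 0))
    })
    sched <- generate_schedule(condition, pseed)
    tab <- if (model_type == "family") {
      p <- params %||% family_params()
      p$boundary_threshold_N <- draw$threshold
      p$motor_noise_sd_N <- population$motor_noise_sd_N
      simulate_family_participant(p, sched, seed = derive_seed(pseed, 7L),
                                  participant_id = i, rt = rt)
    } else {
      p <- params %||% associative_params()
      p$motor_noise_sd_N <- population$motor_noise_sd_N
      simulate_associative_participant(p, sched,
                                       seed = derive_seed(pseed, 7L),
                                       participant_id = i, rt = rt)
    }
    tab$anticipatory_force_N <-
      pmax(tab$anticipatory_force_N + draw$bias, 0.01)
    tab
  })
  dplyr::bind_rows(rows)
}
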