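#' Spring-mass-damper parameters for the release phase
#'
#' The release phase is simulated as a point mass acted on by gravity and
#' attached to the (held-fixed) hand by a stiff damped spring. Two presets
#' match the task variants: the laboratory robot uses a 4000 N/m spring with
#' viscous damping 2 N s/m sampled at 5 kHz; the web variant uses spring
#' constant 1 and damping 0.01 (treated as SI units with masses in kg)
#' stepped at the 60 Hz frame rate, where only the qualitative behavior
#' (oscillation amplitude and decay growing with error) matters.
#'
#' @param object_mass_kg Object mass in kg.
#' @param stiffness Spring constant (N/m).
#' @param damping Viscous damping coefficient (N s/m).
#' @param gravity Gravitational acceleration magnitude (m/s^2).
#' @param dt Integration time step (s).
#' @param duration Simulated duration (s).
#' @return A list of class `spring_mass_params`.
#' @export
spring_mass_params <- function(object_mass_kg,
                               stiffness = 4000,
                               damping = 2,
                               gravity = GRAVITY,
                               dt = 2e-4,
                               duration = 2) {
  if (object_mass_kg <= 0) abort("`object_mass_kg` must be positive.")
  if (stiffness <= 0) abort("`stiffness` must be positive.")
  if (damping < 0) abort("`damping` must be non-negative.")
  if (dt <= 0) abort("`dt` must be positive.")
  if (duration <= 0) abort("`duration` must be positive.")
  structure(list(object_mass_kg = object_mass_kg, stiffness = stiffness,
                 damping = damping, gravity = gravity, dt = dt,
                 duration = duration),
            class = "spring_mass_params")
}

#' Web-task preset of the release-phase physics
#'
#' @inheritParams spring_mass_params
#' @export
web_spring_params <- function(object_mass_kg, duration = 10) {
  spring_mass_params(object_mass_kg, stiffness = 1, damping = 0.01,
                     dt = 1 / 60, duration = duration)
}

#' Simulate the object release phase
#'
#' Integrates the linear second-order system
#' `m x'' = (F_ant - m g) - k x - c x'` from rest at the release point
#' (open loop: no corrective response is modeled; the spring is preloaded so
#' the net force at t = 0 equals the anticipatory force minus the object
#' weight). The trace is a damped oscillation about the new equilibrium
#' `(F_ant - m g)/k`: an anticipatory force matching the object weight keeps
#' the object still, an underestimate drives it downward. A classical
#' fixed-step 4th-order Runge-Kutta scheme is used at the stated sample
#' rates.
#'
#' @param anticipatory_force Upward force applied at release (N).
#' @param params A [spring_mass_params()] object.
#' @return A tibble (class `release_trace`): `t_s`, `position_m` (vertical
#'   displacement from the release point), `force_N` (load force transmitted
#'   to the object).
#' @export
simulate_release <- function(anticipatory_force, params) {
  stopifnot(inherits(params, "spring_mass_params"))
  if (!is.finite(anticipatory_force)) {
    abort("`anticipatory_force` must be finite.")
  }
  m <- params$object_mass_kg
  k <- params$stiffness
  c_ <- params$damping
  f0 <- anticipatory_force - m * params$gravity

  accel <- function(x, v) (f0 - k * x - c_ * v) / m
  n <- floor(params$duration / params$dt)
  dt <- params$dt
  x <- numeric(n + 1)
  v <- numeric(n + 1)
  for (i in seq_len(n)) {
    x1 <- x[i]; v1 <- v[i]; a1 <- accel(x1, v1)
    x2 <- x1 + dt / 2 * v1; v2 <- v1 + dt / 2 * a1; a2 <- accel(x2, v2)
    x3 <- x1 + dt / 2 * v2; v3 <- v1 + dt / 2 * a2; a3 <- accel(x3, v3)
    x4 <- x1 + dt * v3;     v4 <- v1 + dt * a3;     a4 <- accel(x4, v4)
    x[i + 1] <- x1 + dt / 6 * (v1 + 2 * v2 + 2 * v3 + v4)
    v[i + 1] <- v1 + dt / 6 * (a1 + 2 * a2 + 2 * a3 + a4)
  }
  out <- tibble::tibble(
    t_s = seq(0, by = dt, length.out = n + 1),
    position_m = x,
    force_N = anticipatory_force - k * x - c_ * v
  )
  structure(out, class = c("release_trace", class(out)))
}

#' Laboratory per-trial score
#'
#' `score = max(0, 100 - 13 * |error|)` where `error` is the difference in
#' newtons between the anticipatory force and the object weight.
#'
#' @param error_N Force error (N), vectorized.
#' @return Score in points.
#' @export
lab_score <- function(error_N) {
  if (any(!is.finite(error_N))) abort("`error_N` must be finite.")
  pmax(0, 100 - 13 * abs(error_N))
}

#' Web per-trial score and time penalty
#'
#' Score is `max(0, 1 - e^2/2.25) * 100` and the release-phase duration
#' (inter-trial time penalty) is `min(0.4 e^2, 12)` seconds, where `e` is
#' the spring-length error in centimeters.
#'
#' @param error_cm Spring-length error (cm), vectorized.
#' @return A tibble with columns `score` and `penalty_s`.
#' @export
web_score_and_penalty <- function(error_cm) {
  if (any(!is.finite(error_cm))) abort("`error_cm` must be finite.")
  tibble::tibble(
    score = pmax(0, 1 - error_cm^2 / 2.25) * 100,
    penalty_s = pmin(0.4 * error_cm^2, 12)
  )
}

#' Adaptive tolerance-band state
#'
#' The laboratory task displays bars above and below the object; the
#' tolerated deviation adapts to performance between +/-2 and +/-13 mm.
#'
#' @param half_width_mm Current half-width of the tolerated band (mm).
#' @param success_streak Count of consecutive within-band trials.
#' @return A list of class `tolerance_state`.
#' @export
tolerance_state <- function(half_width_mm = 13, success_streak = 0) {
  if (half_width_mm < 2 || half_width_mm > 13) {
    abort("`half_width_mm` must lie in [2, 13].")
  }
  structure(list(half_width_mm = half_width_mm,
                 success_streak = success_streak),
            class = "tolerance_state")
}

#' Update the tolerance band after a trial
#'
#' The band grows 1 mm after a trial in which the object crossed a bar (cap
#' 13 mm) and shrinks 1 mm after five consecutive within-band trials (floor
#' 2 mm); either event resets the streak.
#'
#' @param state A [tolerance_state()].
#' @param crossed_bar Logical: did the object cross a bar this trial?
#' @return The updated `tolerance_state`.
#' @export
update_tolerance <- function(state, crossed_bar) {
  stopifnot(inherits(state, "tolerance_state"))
  if (isTRUE(crossed_bar)) {
    tolerance_state(min(state$half_width_mm + 1, 13), 0)
  } else {
    streak <- state$success_streak + 1
    if (streak >= 5) {
      tolerance_state(max(state$half_width_mm - 1, 2), 0)
    } else {
      tolerance_state(state$half_width_mm, streak)
    }
  }
}
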