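# Shared fixture builders -- all synthetic, generated at test time.

# Minimal hand-built behavior table: n_participants, forces supplied by
# `force_fun(participant, object_id, volume, mass, phase, cycle)`.
build_behavior_table <- function(condition_name = "Linear+",
                                 n_participants = 4,
                                 seed = 1,
                                 force_fun = NULL,
                                 rt_fun = NULL) {
  cond <- condition(condition_name)
  rows <- lapply(seq_len(n_participants), function(p) {
    sched <- generate_schedule(cond, seed + p)
    f <- if (is.null(force_fun)) {
      weight_to_force(sched$mass_g)
    } else {
      mapply(force_fun, p, sched$object_id, sched$volume_cm3,
             sched$mass_g, sched$phase, sched$cycle)
    }
    rt <- if (is.null(rt_fun)) NA_real_ else {
      mapply(rt_fun, p, sched$object_id, sched$volume_cm3, sched$mass_g,
             sched$phase, sched$cycle)
    }
    tibble::tibble(
      participant_id = p, condition = condition_name, setting = "lab",
      model_type = "fixture", trial = sched$trial, phase = sched$phase,
      cycle = sched$cycle, object_id = sched$object_id,
      volume_cm3 = sched$volume_cm3, mass_g = sched$mass_g,
      anticipatory_force_N = f, response_time_ms = rt,
      analysis_excluded = sched$analysis_excluded, excluded = 0L
    )
  })
  dplyr::bind_rows(rows)
}

# Closed-form solution of the underdamped driven spring-mass-damper used by
# simulate_release: m x'' = f0 - k x - c x', x(0) = x'(0) = 0.
analytic_release <- function(t, f0, m, k, c_) {
  xeq <- f0 / k
  w0 <- sqrt(k / m)
  zeta <- c_ / (2 * sqrt(k * m))
  stopifnot(zeta < 1)
  wd <- w0 * sqrt(1 - zeta^2)
  xeq * (1 - exp(-zeta * w0 * t) *
           (cos(wd * t) + zeta * w0 / wd * sin(wd * t)))
}

# Independent permutation enumerator (base R, recursion-free) used as the
# oracle for the uncorrelated mass-assignment count.
enumerate_permutations <- function(v) {
  n <- length(v)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  idx <- idx[apply(idx, 1, function(r) length(unique(r)) == n), ,
             drop = FALSE]
  lapply(seq_len(nrow(idx)), function(i) v[idx[i, ]])
}
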