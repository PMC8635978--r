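#' Generate a constrained pseudo-random trial schedule
#'
#' Builds the ordered trial sequence for a condition, reproducibly from a
#' seed. Constraints, by phase:
#'
#' * **training** (four-object conditions): each cycle is a permutation of
#'   the four training objects, and the first object of a cycle never repeats
#'   the last object of the previous cycle. In `+Linear`/`++Linear` the
#'   training phase is 30 lifts of the test object alone.
#' * **test**: the test object always opens each five-trial cycle; the four
#'   training objects follow in pseudo-random order, with each training
#'   object appearing in position 2 (immediately after the test object)
#'   exactly once in every block of four cycles.
#' * **one_to_one** (`+Linear`/`++Linear` only): ten cycles of eight trials;
#'   the test object is lifted four times per cycle and each training object
#'   once. Across the phase, consecutive test-object presentations occur
#'   exactly 13 times, and presentations separated by one, two or three
#'   intervening trials exactly 15, 8 and 3 times. Test-object trials that
#'   directly follow a test-object trial are flagged `analysis_excluded`.
#'
#' Ramp conditions resolve the test object's scheduled mass per trial index
#' (50 g steps at trials 221, 261, 301, 341, 381, 421). Rest-break markers
#' are set at the condition's printed trial indices.
#'
#' Constraints are satisfied by rejection sampling with a retry cap; the
#' result is deterministic given `(condition, seed)`.
#'
#' @param condition A [condition()] object.
#' @param seed Integer seed.
#' @param objects Object set from [make_objects()]; defaults to
#'   `make_objects(condition, seed)` so that one seed fixes both the
#'   (possibly participant-specific) mass assignment and the trial order.
#' @return A tibble of class `lift_schedule` with columns `trial`, `phase`,
#'   `cycle`, `object_id`, `volume_cm3`, `mass_g`, `rest_break_after`
#'   (0/1), `analysis_excluded` (0/1). Trial and cycle indices are 1-based;
#'   cycles number consecutively across phases.
#' @export
generate_schedule <- function(condition, seed = 1L,
                              objects = make_objects(condition, seed)) {
  stopifnot(inherits(condition, "lift_condition"))
  order_ids <- withr::with_seed(derive_seed(seed, 1L), {
    schedule_object_order(condition)
  })

  n <- length(order_ids$object_id)
  sched <- tibble::tibble(
    trial = seq_len(n),
    phase = order_ids$phase,
    cycle = order_ids$cycle,
    object_id = order_ids$object_id
  )
  sched <- dplyr::left_join(
    sched,
    dplyr::select(objects, "object_id", "volume_cm3", "mass_g"),
    by = "object_id"
  )

  # Ramp conditions: the test object's mass is a step function of trial index.
  if (!is.null(condition$ramp)) {
    ramp <- condition$ramp
    steps <- vapply(sched$trial,
                    function(t) sum(ramp$change_trials <= t), numeric(1))
    ramp_mass <- ramp$start_mass_g + ramp$step_g * steps
    ramp_mass <- pmin(pmax(ramp_mass, ramp$range_g[1]), ramp$range_g[2])
    is_test <- sched$object_id == condition$test_id
    sched$mass_g[is_test] <- ramp_mass[is_test]
  }

  sched$rest_break_after <- as.integer(sched$trial %in% condition$rest_breaks)

  # In the 1:1 phase, test-object lifts that immediately follow a test-object
  # lift are excluded from analysis.
  excl <- rep(FALSE, n)
  oto <- which(sched$phase == "one_to_one")
  if (length(oto)) {
    ids <- sched$object_id[oto]
    excl[oto] <- ids == condition$test_id &
      dplyr::lag(ids, default = -1L) == condition$test_id
  }
  sched$analysis_excluded <- as.integer(excl)

  structure(sched,
            class = c("lift_schedule", class(sched)),
            condition_name = condition$name,
            setting = condition$setting,
            seed = seed)
}

# Object presentation order for all phases; runs inside a seeded RNG context.
schedule_object_order <- function(condition) {
  phases <- condition$phases
  out <- list()
  cycle_offset <- 0L
  last_obj <- NA_integer_
  for (i in seq_len(nrow(phases))) {
    ph <- phases$phase[i]
    ncyc <- phases$n_cycles[i]
    tpc <- phases$trials_per_cycle[i]
    ids <- switch(
      ph,
      training = if (tpc == 1L) {
        list(object_id = rep(condition$test_id, ncyc),
             cycle = seq_len(ncyc))
      } else {
        training_order(condition$training_ids, ncyc, last_obj)
      },
      test = test_order(condition$training_ids, condition$test_id, ncyc),
      one_to_one = one_to_one_order(condition$training_ids,
                                    condition$test_id, ncyc)
    )
    if (is.null(ids$cycle)) {
      ids$cycle <- rep(seq_len(ncyc), each = tpc)
    }
    ids$cycle <- ids$cycle + cycle_offset
    ids$phase <- rep(ph, length(ids$object_id))
    out[[i]] <- ids
    cycle_offset <- cycle_offset + ncyc
    last_obj <- tail(ids$object_id, 1)
  }
  list(object_id = unlist(lapply(out, `[[`, "object_id")),
       cycle = unlist(lapply(out, `[[`, "cycle")),
       phase = unlist(lapply(out, `[[`, "phase")))
}

MAX_SCHEDULE_RETRIES <- 1e5

# Training phase: per-cycle permutations, no repeat across cycle boundaries.
training_order <- function(training_ids, n_cycles, last_obj = NA_integer_) {
  res <- integer(0)
  prev <- last_obj
  for (cyc in seq_len(n_cycles)) {
    for (k in seq_len(MAX_SCHEDULE_RETRIES)) {
      perm <- sample(training_ids)
      if (is.na(prev) || perm[1] != prev) break
      if (k == MAX_SCHEDULE_RETRIES) {
        abort("Could not satisfy training-order constraint (internal bug).")
      }
    }
    res <- c(res, perm)
    prev <- tail(perm, 1)
  }
  list(object_id = res)
}

# Test phase: test object first; each training object in position 2 exactly
# once per block of four cycles.
test_order <- function(training_ids, test_id, n_cycles) {
  res <- integer(0)
  cycles_left <- n_cycles
  block_sizes <- rep(4L, n_cycles %/% 4L)
  if (n_cycles %% 4L) block_sizes <- c(block_sizes, n_cycles %% 4L)
  for (bs in block_sizes) {
    pos2 <- sample(training_ids)[seq_len(bs)]
    for (j in seq_len(bs)) {
      rest <- sample(setdiff(training_ids, pos2[j]))
      res <- c(res, test_id, pos2[j], rest)
    }
  }
  list(object_id = res)
}

# 1:1 phase: construct the test-object gap pattern first (13 adjacent pairs,
# 15/8/3 pairs with 1/2/3 intervening trials), then check that every
# eight-trial cycle holds exactly four test-object lifts, then fill each
# cycle's remaining slots with a random order of the four training objects.
one_to_one_order <- function(training_ids, test_id, n_cycles) {
  stopifnot(n_cycles == 10L)
  gaps <- c(rep(0L, 13), rep(1L, 15), rep(2L, 8), rep(3L, 3))
  n_trials <- 8L * n_cycles
  for (k in seq_len(MAX_SCHEDULE_RETRIES)) {
    g <- sample(gaps)
    is_test <- logical(n_trials)
    pos <- 1L
    is_test[pos] <- TRUE
    ok <- TRUE
    for (gi in g) {
      pos <- pos + gi + 1L
      if (pos > n_trials) { ok <- FALSE; break }
      is_test[pos] <- TRUE
    }
    if (!ok || sum(is_test) != 4L * n_cycles) next
    per_cycle <- colSums(matrix(is_test, nrow = 8L))
    if (all(per_cycle == 4L)) {
      res <- integer(n_trials)
      res[is_test] <- test_id
      for (cyc in seq_len(n_cycles)) {
        idx <- (cyc - 1L) * 8L + 1:8
        slots <- idx[!is_test[idx]]
        res[slots] <- sample(training_ids)
      }
      return(list(object_id = res))
    }
  }
  abort("Could not satisfy 1:1-phase gap constraints (internal bug).")
}
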