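noiseless_family <- function(...) {
  family_params(motor_noise_sd_N = 0, ...)
}

test_that("a rate-1 noiseless family agent is exact from the second cycle", {
  sched <- generate_schedule(condition("Linear+"), 1)
  p <- noiseless_family(family_learning_rate = 1,
                        boundary_threshold_N = 10)
  tab <- simulate_family_participant(p, sched, seed = 1, rt = NULL)
  tr <- tab[tab$phase == "training" & tab$cycle > 1, ]
  expect_equal(tr$anticipatory_force_N, weight_to_force(tr$mass_g),
               tolerance = 1e-12)
})

test_that("a high-threshold agent never learns even the extreme outlier", {
  sched <- generate_schedule(condition("Linear++"), 2)
  p <- noiseless_family(boundary_threshold_N = 7)
  tab <- simulate_family_participant(p, sched, seed = 1, rt = NULL)
  out <- tab[tab$phase == "test" & tab$object_id == 3L, ]
  # predictions stay at the family value (~8.8 N), far below 14.72 N
  expect_true(all(out$anticipatory_force_N < 10.5))
  expect_lt(abs(mean(tail(out$anticipatory_force_N, 16)) - 8.83), 0.75)
})

test_that("a low-threshold agent expels and fully learns the outlier", {
  sched <- generate_schedule(condition("Linear+"), 3)
  p <- noiseless_family(boundary_threshold_N = 1.5,
                        boundary_broadening = 0)
  tab <- simulate_family_participant(p, sched, seed = 1, rt = NULL)
  out <- tab[tab$phase == "test" & tab$object_id == 3L, ]
  late_out <- tail(out$anticipatory_force_N, 16)
  expect_equal(late_out, rep(weight_to_force(1200), 16), tolerance = 1e-6)
  # after reclassification, outlier lifts stop shifting family predictions:
  # the trial after the outlier matches that object's own scheduled weight
  te <- tab[tab$phase == "test", ]
  late_cycles <- tail(unique(te$cycle), 16)
  pos2 <- do.call(rbind, lapply(late_cycles, function(cc) {
    te[te$cycle == cc, ][2, ]
  }))
  expect_equal(pos2$anticipatory_force_N, weight_to_force(pos2$mass_g),
               tolerance = 1e-6)
})

test_that("generalization is positive while the outlier is a member and drops after expulsion", {
  sched <- generate_schedule(condition("Linear++"), 4)
  p <- noiseless_family(boundary_threshold_N = 4, boundary_broadening = 0)
  tab <- simulate_family_participant(p, sched, seed = 1, rt = NULL)
  te <- tab[tab$phase == "test", ]
  cycles <- unique(te$cycle)
  shift <- vapply(cycles, function(cc) {
    r <- te[te$cycle == cc, ][2, ]  # trial right after the outlier
    r$anticipatory_force_N - weight_to_force(r$mass_g)
  }, numeric(1))
  # evidence accumulates over the outlier's first lifts: early shifts up
  expect_gt(mean(shift[1:2]), 0.5)
  # once expelled, outlier lifts no longer move the family estimate
  expect_lt(mean(abs(tail(shift, 16))), 0.05)
})

test_that("an assimilated individual is forgotten when its family arrives", {
  # reversed curriculum: the outlier is learned alone, then the family
  # pulls the shared density estimate back and the outlier is re-absorbed
  sched <- generate_schedule(condition("+Linear"), 5)
  p <- noiseless_family(boundary_threshold_N = 6)
  tab <- simulate_family_participant(p, sched, seed = 1, rt = NULL)
  tr_out <- tab[tab$phase == "training", ]
  expect_lt(abs(tail(tr_out$anticipatory_force_N, 1) -
                  weight_to_force(1200)), 1e-6)
  te_out <- tab[tab$phase == "test" & tab$object_id == 3L, ]
  expect_lt(mean(tail(te_out$anticipatory_force_N, 16)), 10)
})

test_that("the degenerate associative agent reduces to a lookup table", {
  sched <- generate_schedule(condition("Linear+"), 1)
  p <- associative_params(kernel_width = 1e-6, learning_rate = 1,
                          motor_noise_sd_N = 0)
  tab <- simulate_associative_participant(p, sched, seed = 1, rt = NULL)
  seen <- new.env()
  for (i in seq_len(nrow(tab))) {
    o <- as.character(tab$object_id[i])
    if (!is.null(seen[[o]])) {
      expect_equal(tab$anticipatory_force_N[i],
                   weight_to_force(tab$mass_g[i]), tolerance = 1e-9)
    }
    seen[[o]] <- TRUE
  }
})

test_that("a zero-rate associative agent never moves off its prior", {
  sched <- generate_schedule(condition("Linear+"), 1)
  p <- associative_params(learning_rate = 0, motor_noise_sd_N = 0,
                          prior_density = 1)
  tab <- simulate_associative_participant(p, sched, seed = 1, rt = NULL)
  # predictions never move: one constant value per object for all 320 trials
  per_obj <- tapply(tab$anticipatory_force_N, tab$object_id,
                    function(v) diff(range(v)))
  expect_true(all(per_obj < 1e-12))
})

test_that("overlapping kernels leave the outlier partially learned", {
  sched <- generate_schedule(condition("Linear+"), 2)
  p <- associative_params(motor_noise_sd_N = 0)
  tab <- simulate_associative_participant(p, sched, seed = 1, rt = NULL)
  out <- tab[tab$phase == "test" & tab$object_id == 3L, ]
  steady <- tail(out$anticipatory_force_N, 8)
  # converged to a narrow limit cycle strictly between family-predicted
  # (~9.1 N) and actual (11.77 N) weight
  expect_lt(diff(range(steady)), 0.2)
  expect_gt(mean(steady), 9.3)
  expect_lt(mean(steady), 11.7)
})

test_that("cohort simulation is deterministic and well formed", {
  cond <- condition("Linear+")
  a <- simulate_cohort(cond, "family", 5, seed = 99)
  b <- simulate_cohort(cond, "family", 5, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(cond, "family", 5, seed = 98)))
  expect_true(all(is.finite(a$anticipatory_force_N)))
  expect_true(all(a$anticipatory_force_N > 0))
  expect_equal(nrow(a), 5 * 320)
  expect_equal(unique(a$condition), "Linear+")
  # extending a cohort preserves the existing participants' rows
  c10 <- simulate_cohort(cond, "map", 10, seed = 99)
  c5 <- simulate_cohort(cond, "map", 5, seed = 99)
  expect_identical(c5, c10[c10$participant_id <= 5, ])
})

test_that("response times carry force scaling and selection costs", {
  cond <- condition("Uncorr+")
  tab <- simulate_cohort(cond, "family", 6, seed = 3)
  expect_true(all(tab$response_time_ms >= 150))
  lin <- simulate_cohort(condition("Linear+"), "family", 6, seed = 3)
  # multiple memory categories in the uncorrelated condition slow responses
  expect_gt(mean(tab$response_time_ms[tab$phase == "test"]),
            mean(lin$response_time_ms[lin$phase == "test"]))
})
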