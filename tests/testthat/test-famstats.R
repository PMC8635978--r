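test_that("a perfect force-weight mapping gives r = 1", {
  tab <- build_behavior_table(n_participants = 2)
  ec <- endphase_correlation(tab)
  expect_equal(ec$r[ec$method == "pooled"], 1)
})

test_that("Fisher-z intervals match the closed form", {
  # frozen from tanh(atanh(0.76) +/- 1.96 / sqrt(448 - 3))
  z <- atanh(0.76); h <- 1.96 / sqrt(445)
  expect_equal(round(tanh(z - h), 4), 0.7179)  # CI ~ [0.72, 0.80]
  expect_equal(round(tanh(z + h), 4), 0.7966)
  # and the function reproduces the formula on data with known pooled r
  set.seed(4)
  tab <- build_behavior_table(
    n_participants = 4,
    force_fun = function(p, o, v, m, ph, cyc)
      weight_to_force(m) + rnorm(1, 0, 1.5))
  ec <- endphase_correlation(tab)
  pooled <- ec[ec$method == "pooled", ]
  zz <- atanh(pooled$r); hh <- 1.96 / sqrt(pooled$n - 3)
  expect_equal(pooled$ci_lo, tanh(zz - hh))
  expect_equal(pooled$ci_hi, tanh(zz + hh))
})

test_that("uncorrelated forces give r near zero with a CI spanning zero", {
  set.seed(7)
  tab <- build_behavior_table(
    n_participants = 13,  # 13 x 8 cycles x 4 objects > 400 trials
    force_fun = function(p, o, v, m, ph, cyc) 9 + rnorm(1, 0, 1))
  ec <- endphase_correlation(tab)
  pooled <- ec[ec$method == "pooled", ]
  expect_gt(pooled$n, 400)
  expect_lt(abs(pooled$r), 0.15)
  expect_lt(pooled$ci_lo, 0)
  expect_gt(pooled$ci_hi, 0)
})

test_that("zero-variance windows are an error", {
  tab <- build_behavior_table(n_participants = 1,
                              force_fun = function(...) 8)
  expect_error(endphase_correlation(tab), "zero variance")
})

test_that("noiseless constant-density forces predict the family weight exactly", {
  tab <- build_behavior_table(
    n_participants = 2,
    force_fun = function(p, o, v, m, ph, cyc) weight_to_force(1.5 * v))
  fp <- family_predicted_weight(tab)
  expect_equal(fp$family_predicted_N, rep(weight_to_force(900), 2))
  expect_equal(round(fp$family_predicted_N[1], 2), 8.83)
})

test_that("the family prediction at the mean volume equals the mean force", {
  # exact algebraic identity of OLS, for arbitrary forces
  for (s in 1:20) {
    set.seed(s)
    tab <- build_behavior_table(
      n_participants = 1, seed = s,
      force_fun = function(p, o, v, m, ph, cyc) runif(1, 2, 15))
    fp <- family_predicted_weight(tab)
    win <- tail(sort(unique(tab$cycle[tab$phase == "test"])), 16)
    tr <- tab[tab$cycle %in% win & tab$object_id != 3L, ]
    # test volume 600 = mean of training volumes {400, 500, 700, 800}
    expect_equal(fp$family_predicted_N, mean(tr$anticipatory_force_N),
                 tolerance = 1e-10)
  }
})

test_that("a symmetric two-level force pattern predicts the midpoint", {
  tab <- build_behavior_table(
    n_participants = 1,
    force_fun = function(p, o, v, m, ph, cyc) if (v < 600) 9 else 11)
  fp <- family_predicted_weight(tab)
  expect_equal(fp$family_predicted_N, 10)
})

test_that("an outlier at the family prediction gives t = 0, p = 0.5", {
  # outlier force identical to each participant's own family prediction
  tab <- build_behavior_table(
    n_participants = 4,
    force_fun = function(p, o, v, m, ph, cyc)
      weight_to_force(1.5 * v) + p)  # participant offsets cancel
  res <- outlier_learning_test(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.5)
  expect_equal(res$direction, "greater")
})

test_that("outlier test direction follows the sign of the discrepancy", {
  web <- simulate_cohort(condition("Linear--", "web"), "family", 4,
                         seed = 2)
  res <- outlier_learning_test(web)
  expect_equal(res$direction, "less")
})

test_that("generalization percentages are exact for constructed shifts", {
  base_force <- function(p, o, v, m, ph, cyc) weight_to_force(1.5 * v)
  # post-outlier forces identical to baseline -> 0%
  tab0 <- build_behavior_table(n_participants = 3,
                               force_fun = base_force)
  g0 <- single_trial_generalization(tab0)
  expect_equal(g0$per_participant$percent,
               rep(0, nrow(g0$per_participant)))
  # uniform +2.943 N shift on position-2 trials in Linear+ -> 100%
  shift_fun <- function(shift) function(p, o, v, m, ph, cyc) {
    weight_to_force(1.5 * v) + shift
  }
  tab1 <- build_behavior_table(n_participants = 3,
                               force_fun = base_force)
  pos2 <- tab1$phase == "test" &
    ave(tab1$trial, tab1$participant_id, tab1$cycle,
        FUN = function(x) seq_along(x)) == 2
  tab1$anticipatory_force_N[pos2] <-
    tab1$anticipatory_force_N[pos2] + weight_to_force(300)
  g1 <- single_trial_generalization(tab1)
  expect_equal(g1$per_participant$percent[
    g1$per_participant$window == "end"], rep(100, 3))
  # the same absolute shift is only ~50% of the Linear++ discrepancy
  tab2 <- build_behavior_table("Linear++", n_participants = 3,
                               force_fun = base_force)
  pos2b <- tab2$phase == "test" &
    ave(tab2$trial, tab2$participant_id, tab2$cycle,
        FUN = function(x) seq_along(x)) == 2
  tab2$anticipatory_force_N[pos2b] <-
    tab2$anticipatory_force_N[pos2b] + 2.945
  g2 <- single_trial_generalization(tab2)
  expect_equal(g2$per_participant$percent[
    g2$per_participant$window == "end"],
    rep(100 * 2.945 / weight_to_force(600), 3))
  expect_equal(round(g2$per_participant$percent[1]), 50)
})

test_that("the mixed ANOVA matches a hand-computed sums-of-squares oracle", {
  # tiny balanced fixture: 2 groups x 3 participants x 2 epochs
  d <- tidyr::expand_grid(group = c("A", "B"), pid = 1:3,
                          epoch = c("e1", "e2"))
  set.seed(9)
  d$y <- round(rnorm(nrow(d), 7, 0.5), 3)
  tab <- tibble::tibble(
    participant_id = d$pid, group = d$group, cycle = ifelse(
      d$epoch == "e1", 1L, 2L),
    response_time_ms = exp(d$y))
  res <- rt_epoch_anova(tab, epochs = list(e1 = 1L, e2 = 2L))
  # oracle: explicit sums of squares for a two-way mixed design
  g <- 2; n <- 3; e <- 2
  mu <- mean(d$y)
  m_g <- tapply(d$y, d$group, mean)
  m_e <- tapply(d$y, d$epoch, mean)
  m_ge <- tapply(d$y, list(d$group, d$epoch), mean)
  m_s <- tapply(d$y, list(d$group, d$pid), mean)
  ss_g <- n * e * sum((m_g - mu)^2)
  ss_s <- e * sum((m_s - rep(m_g, each = 1))^2)  # subjects within groups
  ss_e <- g * n * sum((m_e - mu)^2)
  ss_ge <- n * sum((m_ge - outer(m_g, m_e, `+`) + mu)^2)
  ss_tot <- sum((d$y - mu)^2)
  ss_res <- ss_tot - ss_g - ss_s - ss_e - ss_ge
  f_g <- (ss_g / (g - 1)) / (ss_s / (g * (n - 1)))
  f_e <- (ss_e / (e - 1)) / (ss_res / (g * (n - 1) * (e - 1)))
  f_ge <- (ss_ge / ((g - 1) * (e - 1))) / (ss_res / (g * (n - 1) * (e - 1)))
  a <- res$anova
  expect_equal(a$statistic[a$effect == "group"], f_g, tolerance = 1e-10)
  expect_equal(a$statistic[a$effect == "epoch"], f_e, tolerance = 1e-10)
  expect_equal(a$statistic[a$effect == "group:epoch"], f_ge,
               tolerance = 1e-10)
  expect_equal(a$df1, c(1, 1, 1))
  expect_equal(a$df2, c(4, 4, 4))
})

test_that("null data give F ratios near one on average", {
  set.seed(11)
  fs <- replicate(120, {
    d <- tidyr::expand_grid(group = c("A", "B"), pid = 1:8,
                            epoch = 1:4)
    d$y <- rnorm(nrow(d))
    tab <- tibble::tibble(participant_id = d$pid, group = d$group,
                          cycle = d$epoch, response_time_ms = exp(d$y))
    res <- rt_epoch_anova(tab, epochs = list(e1 = 1L, e2 = 2L, e3 = 3L,
                                             e4 = 4L))
    res$anova$statistic
  })
  means <- rowMeans(fs)
  # E[F] = df2/(df2 - 2): ~1.17 for the group effect (df2 = 14), ~1.05
  # within; allow generous Monte-Carlo slack
  expect_true(all(means > 0.7 & means < 1.6))
})

test_that("a pure group offset moves only the group F", {
  d <- tidyr::expand_grid(group = c("A", "B"), pid = 1:10, epoch = 1:4)
  set.seed(12)
  d$y <- rnorm(nrow(d), 0, 0.3) + ifelse(d$group == "A", 0, 1.5)
  tab <- tibble::tibble(participant_id = d$pid, group = d$group,
                        cycle = d$epoch, response_time_ms = exp(d$y))
  res <- rt_epoch_anova(tab, epochs = list(e1 = 1L, e2 = 2L, e3 = 3L,
                                           e4 = 4L))
  a <- res$anova
  expect_gt(a$statistic[a$effect == "group"], 30)
  expect_lt(a$statistic[a$effect == "group:epoch"], 5)
})

test_that("the RT-weight slope is recovered exactly from noiseless data", {
  tab <- build_behavior_table(
    "Linear++", n_participants = 3,
    rt_fun = function(p, o, v, m, ph, cyc) 500 + 30 * weight_to_force(m))
  sc <- switch_cost(tab)
  expect_equal(sc$slope_ms_per_N, 30, tolerance = 1e-9)
  # RTs on switch trials follow the same line -> zero switch cost
  expect_equal(sc$costs$estimate_ms, c(0, 0), tolerance = 1e-9)
})

test_that("the weight-matched RT prediction adds slope times force difference", {
  # build data whose non-switch regression slope is exactly 26.2 ms/N
  tab <- build_behavior_table(
    "Linear++", n_participants = 3,
    rt_fun = function(p, o, v, m, ph, cyc) 600 + 26.2 * weight_to_force(m))
  sc <- switch_cost(tab)
  expect_equal(sc$slope_ms_per_N, 26.2, tolerance = 1e-9)
  per <- sc$per_participant
  outl <- per[per$kind == "switch_to_outlier", ]
  # predicted increment over the non-switch mean: 26.2 ms/N x 5.886 N,
  # printed as +154 ms
  ns_mean <- 600 + 26.2 * mean(weight_to_force(
    tab$mass_g[tab$phase == "test"][
      rep(c(FALSE, FALSE, TRUE, TRUE, TRUE), 40)]))
  expect_equal(round(mean(outl$predicted) - ns_mean), 154)
})

test_that("statistics are invariant to row order", {
  tab <- simulate_cohort(condition("Linear+"), "family", 5, seed = 31)
  set.seed(1)
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(outlier_learning_test(shuf), outlier_learning_test(tab))
  expect_equal(endphase_correlation(shuf)$r, endphase_correlation(tab)$r)
  g1 <- single_trial_generalization(tab)
  g2 <- single_trial_generalization(shuf)
  expect_equal(g2$tests, g1$tests)
})

test_that("group comparison uses a pooled-variance two-sample t", {
  a <- simulate_cohort(condition("LinearUp"), "family", 9, seed = 5)
  b <- simulate_cohort(condition("Linear++"), "family", 9, seed = 6)
  res <- group_comparison(a, b)
  expect_equal(res$df, 16)  # n_a + n_b - 2, matching the pooled test
  expect_lt(res$mean_a, res$mean_b)  # ramp group stays near the family
})
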