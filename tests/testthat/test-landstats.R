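covers9 <- c(19, 28, 34, 43, 50, 59, 63, 70, 83)

test_that("presence GLM: Wald z, location invariance, separation detection", {
  pres <- c(1, 1, 1, 1, 1, 1, 1, 0, 1)
  g <- glm_binomial_presence(pres, covers9)
  expect_false(g$separation_flag)
  expect_true(g$deviance <= g$null_deviance + 1e-9)
  # z statistic invariant under a constant shift of the covariate
  g2 <- glm_binomial_presence(pres, covers9 + 500)
  expect_equal(g$z, g2$z, tolerance = 1e-6)
  expect_equal(g$p, g2$p, tolerance = 1e-6)
  # a response that is a threshold on cover separates perfectly
  sep <- glm_binomial_presence(as.integer(covers9 <= 63), covers9)
  expect_true(sep$separation_flag)
  expect_true(is.na(sep$p))
  # constant response is degenerate, not an error
  dg <- glm_binomial_presence(rep(1, 9), covers9)
  expect_true(dg$separation_flag)
  expect_true(is.na(dg$p))
})

test_that("proportion GLM: scaling invariance and degenerate responses", {
  t1 <- table1()
  g <- glm_binomial_proportion(t1$assigned, t1$seedlings, covers9)
  expect_lt(g$slope, 0)
  g2 <- glm_binomial_proportion(2 * t1$assigned, 2 * t1$seedlings, covers9)
  expect_equal(g$slope, g2$slope, tolerance = 1e-8)
  full <- glm_binomial_proportion(t1$seedlings, t1$seedlings, covers9)
  expect_true(full$separation_flag)
  expect_true(is.na(full$p))
  expect_error(glm_binomial_proportion(c(1, 0, 2), c(1, 0, 5), c(10, 20, 30)),
               "totals")
})

test_that("Monte Carlo deviance test matches exact enumeration (presence)", {
  # the same-landscape presence null has only choose(9,2) = 36 distinct
  # placements of the two zeros; enumerate them as an independent oracle
  pres <- as.integer(table1()$same_landscape > 0)
  obs <- glm_binomial_presence(pres, covers9)$deviance
  combs <- combn(9, 2)
  devs <- apply(combs, 2, function(ix) {
    p <- rep(1, 9); p[ix] <- 0
    glm_binomial_presence(p, covers9)$deviance
  })
  p_exact <- mean(devs <= obs)
  mc <- suppressMessages(
    mc_glm_deviance_test(pres, NULL, covers9, n_rand = 999, seed = 17))
  se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(mc$p - p_exact), 2 * se + 1e-3)
  expect_gte(mc$p, 1 / 1000)
})

test_that("Monte Carlo deviance test limits: constant response gives p = 1", {
  mc <- mc_glm_deviance_test(rep(1, 9), NULL, covers9, n_rand = 99, seed = 1)
  expect_equal(mc$p, 1)
  mcp <- mc_glm_deviance_test(rep(2, 9), rep(10, 9), covers9,
                              n_rand = 99, seed = 1)
  expect_equal(mcp$p, 1)
})

test_that("R-squared randomization test behaves at its extremes", {
  y <- 2 * covers9 + 1
  mc <- mc_regression_r2_test(y, covers9, n_rand = 499, seed = 3)
  expect_equal(mc$observed_stat, 1)
  expect_equal(mc$p, 1 / 500)
  expect_error(mc_regression_r2_test(rep(1, 9), covers9), "constant")
  # joint permutation of (y, covers) leaves the p distribution unchanged
  set.seed(4)
  ord <- sample(9)
  y2 <- rnorm(9)
  p_a <- mc_regression_r2_test(y2, covers9, n_rand = 999, seed = 5)$p
  p_b <- mc_regression_r2_test(y2[ord], covers9[ord], n_rand = 999,
                               seed = 5)$p
  expect_lt(abs(p_a - p_b), 4 * sqrt(0.25 / 1000) + 1e-3)
})

test_that("landscape-level randomization keeps within-landscape structure", {
  # y depends on the landscape mean only; permuting covers at landscape
  # level must reproduce the same p as collapsing to landscape means
  set.seed(6)
  land <- rep(c("a", "b", "c", "d"), each = 5)
  cov <- rep(c(20, 40, 60, 80), each = 5)
  y <- rep(c(1, 2, 3, 4), each = 5) + rnorm(20, sd = 0.01)
  mc <- mc_regression_r2_test(y, cov, landscape_ids = land,
                              n_rand = 499, seed = 7)
  # perfect landscape-level relation: only the 4! = 24 arrangements exist,
  # and the observed one is (essentially uniquely) the best
  expect_lt(mc$p, 0.1)
  expect_gte(mc$p, 1 / 500)
})

test_that("log-distance mixed model: degenerate and invariance cases", {
  land <- rep(c("a", "b", "c"), each = 6)
  cov <- rep(c(20, 50, 80), each = 6)
  expect_error(lmm_log_distance(rexp(6) + 1, rep(50, 6), rep("a", 6)),
               "single landscape")
  same <- lmm_log_distance(rep(100, 18), cov, land)
  expect_equal(same$slope, 0)
  expect_equal(same$p, 1)
  set.seed(9)
  d <- exp(0.02 * cov + rnorm(18, sd = 0.3)) * 10
  f1 <- lmm_log_distance(d, cov, land)
  f2 <- lmm_log_distance(7 * d, cov, land)   # scale shifts intercept only
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
  expect_equal(f1$t, f2$t, tolerance = 1e-6)
  expect_true(f1$var_random >= 0 && f1$var_resid >= 0)
})

test_that("assignment summaries reproduce direct enumeration and the published ratio", {
  # published counts: 21 assigned of 271 seedlings = 7.75%
  t1 <- table1()
  expect_equal(round(100 * sum(t1$assigned) / sum(t1$seedlings), 2), 7.75)
  # synthetic run: counts equal direct enumeration of the assignment list
  sim <- simulate_dataset(small_sim_config(seed = 55))
  fr <- palmflow:::.augmented_adult_freqs(sim$dataset)
  crit <- simulate_critical_delta(fr, n_candidates = 40, n_sim = 300,
                                  seed = 56)
  asg <- assign_parents(sim$dataset, crit)
  summ <- summarize_assignments(asg, sim$dataset)
  ok <- !is.na(asg$parent_id)
  expect_equal(summ$per_site$assigned[summ$per_site$site_id == "Overall"],
               sum(ok))
  site_of <- setNames(sim$dataset$individuals$site_id,
                      sim$dataset$individuals$id)
  for (s in sim$dataset$sites$site_id) {
    sel <- ok & site_of[asg$offspring_id] == s
    row <- summ$per_site[summ$per_site$site_id == s, ]
    expect_equal(row$assigned, sum(sel))
    expect_equal(row$same_landscape,
                 sum(sel & site_of[asg$parent_id] == s, na.rm = TRUE))
  }
  # cross-landscape table distances are centroid distances in km
  if (nrow(summ$cross_landscape) > 0)
    expect_true(all(summ$cross_landscape$distance_km > 0.4))
  # empty assignments give all-zero summaries
  empty <- asg[0, ]
  z <- summarize_assignments(empty, sim$dataset)
  expect_true(all(z$per_site$assigned == 0))
  expect_equal(z$overall_percent_assigned, 0)
})
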