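test_that("an all-alive fixture reports zero death in every cohort", {
  sc <- cohort_scenario(S = 4, n11 = 30, n_ctrl_t = 12, n_ctrl_e = 12, seed = 61,
                        death_prob = c("1:1" = 0), division_rate = 0,
                        escape_rate = 0,
                        spontaneous_death = c(effector = 0, target = 0))
  rs <- render_scenario(sc)
  an <- analyze_stack(rs$stack, sc$design)
  co <- an$result$cohorts
  expect_true(all(co$target_death_pct[!is.na(co$target_death_pct)] == 0))
  expect_true(all(co$effector_death_pct[!is.na(co$effector_death_pct)] == 0))
  # stable no-death traps: endpoint/initial green within [0.9, 1.1]
  ng <- co$norm_end_green_mean[co$cohort == "1:1"]
  expect_gt(ng, 0.9); expect_lt(ng, 1.1)
})

test_that("control cohorts report near-baseline viability at the configured rates", {
  sc <- cohort_scenario(S = 6, n11 = 0, n_ctrl_t = 128, n_ctrl_e = 128,
                        seed = 62, division_rate = 0, escape_rate = 0,
                        spontaneous_death = c(effector = 0.01, target = 0.044))
  rs <- render_scenario(sc)
  an <- analyze_stack(rs$stack, sc$design)
  co <- an$result$cohorts
  vt <- co$target_viability_pct[co$cohort == "target_only_control"]
  ve <- co$effector_viability_pct[co$cohort == "effector_only_control"]
  expect_gte(vt, 93)
  expect_gte(ve, 93)
})

test_that("cytotoxicity fractions track the generating death probability", {
  sc <- cohort_scenario(S = 6, n11 = 213, n_ctrl_t = 20, n_ctrl_e = 20,
                        seed = 63, division_rate = 0, escape_rate = 0,
                        spontaneous_death = c(effector = 0, target = 0))
  rs <- render_scenario(sc)
  an <- analyze_stack(rs$stack, sc$design)
  co <- an$result$cohorts
  est <- co$target_death_pct[co$cohort == "1:1"]
  true_frac <- 100 * mean(!is.na(rs$truth$cells$death_h[
    rs$truth$cells$population == "target" &
      rs$truth$cells$trap %in% rs$truth$traps$trap[rs$truth$traps$k1 == 1 &
                                                     rs$truth$traps$k2 == 1]]))
  expect_equal(est, true_frac, tolerance = 1e-8)
  expect_lt(abs(est - 21.5), 3 * 100 * sqrt(0.215 * 0.785 / 213))
})

test_that("significance tiers map p-values at the conventional thresholds", {
  tier <- traparray:::.p_tier
  expect_equal(tier(0.01), "*")
  expect_equal(tier(0.001), "**")
  expect_equal(tier(0.00015), "***")
  expect_equal(tier(0.00005), "****")
  expect_equal(tier(0.5), "ns")
})

test_that("Dunn multiple-comparison z test matches an independent oracle", {
  vals <- c(1.1, 2.3, 1.9, 3.0, 2.2, 3.1, 2.7, 4.0, 5.5, 6.1, 5.9, 7.2)
  grp <- rep(c("a", "b", "c"), each = 4)
  d <- traparray:::.dunn_test(vals, grp)
  # frozen from independent rank arithmetic (scipy.stats)
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], -2.843684, tolerance = 1e-5)
  expect_equal(d$p[d$group1 == "a" & d$group2 == "c"], 0.0133786, tolerance = 1e-4)
  expect_equal(d$p[d$group1 == "a" & d$group2 == "b"], 0.980399, tolerance = 1e-4)
  expect_equal(d$p[d$group1 == "b" & d$group2 == "c"], 0.187343, tolerance = 1e-4)
})

test_that("cohort comparison finds no differences between identical cohorts", {
  set.seed(5)
  v <- rnorm(60)
  g <- rep(c("x", "y", "z"), 20)
  cmp <- compare_cohorts(v, g)
  expect_true(all(cmp$pairs$tier == "ns"))
})

test_that("cohort comparison separates distinct death probabilities", {
  set.seed(9)
  v <- c(rbinom(100, 1, 0.05), rbinom(100, 1, 0.40))
  g <- rep(c("low", "high"), each = 100)
  cmp <- compare_cohorts(v, g)
  expect_equal(cmp$method, "kruskal_dunn")  # binary data fails the normality gate
  expect_true(all(cmp$pairs$tier != "ns"))
  expect_lt(cmp$pairs$p[1], 0.0332)
})

test_that("undersized cohorts are skipped with a notice", {
  v <- c(rnorm(10), rnorm(10, 3), rnorm(2))
  g <- c(rep("a", 10), rep("b", 10), rep("tiny", 2))
  expect_message(cmp <- compare_cohorts(v, g), "tiny")
  expect_false("tiny" %in% c(cmp$pairs$group1, cmp$pairs$group2))
})
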