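test_that("Poisson pmf matches closed-form values and normalizes", {
  # high-precision direct evaluations of lambda^k e^-lambda / k!
  expect_equal(poisson_pmf(0.5, 1), 0.30326532985632, tolerance = 1e-10)
  expect_equal(poisson_pmf(0.83, 1), 0.36192090764687, tolerance = 1e-10)
  expect_identical(poisson_pmf(0, 0), 1)
  for (lam in c(0.1, 0.5, 1, 3, 10))
    expect_equal(sum(poisson_pmf(lam, 0:200)), 1, tolerance = 1e-12)
  expect_error(poisson_pmf(-1, 0))
  expect_error(poisson_pmf(0.5, 1.5))
})

test_that("empirical frequency and lambda estimation follow the tallies", {
  tab <- particle_table()
  expect_identical(tab$N_t, 1024L)
  # marginal zero-count frequency of the green population: 632/1024
  expect_equal(empirical_frequency(tab, 0, "green"), 632 / 1024, tolerance = 1e-12)
  expect_equal(round(100 * empirical_frequency(tab, 0, "green")), 62)
  expect_equal(empirical_frequency(tab, 1, "green"), 283 / 1024, tolerance = 1e-12)
  expect_equal(empirical_frequency(tab, 7, "green"), 0)
  expect_error(empirical_frequency(tab, 0, "magenta"))
  # weighted-sum oracle for the estimator
  counts <- matrix(0L, 5, 1); counts[, 1] <- c(616L, 307L, 77L, 19L, 5L)
  t2 <- occupancy_table(counts)
  expect_equal(estimate_lambda(t2, 1), 538 / 1024, tolerance = 1e-12)
  expect_equal(estimate_lambda(occupancy_table(matrix(10L, 1, 1)), 1), 0)
  expect_equal(estimate_lambda(occupancy_table(matrix(c(0L, 7L), 2, 1)), 1), 1)
})

test_that("double Poisson and dual frequency are products of marginals", {
  expect_equal(round(100 * double_poisson(loading_rate(0.5, 0.5), 1, 1), 1), 9.2)
  expect_equal(round(100 * double_poisson(loading_rate(0.83, 0.58), 1, 1), 1), 11.8)
  expect_identical(double_poisson(loading_rate(0, 0), 0, 0), 1)
  # marginalization identity
  for (l1 in c(0.3, 1, 2)) {
    r <- loading_rate(l1, 0.7)
    for (k1 in 0:4)
      expect_equal(sum(double_poisson(r, k1, 0:200)), poisson_pmf(l1, k1),
                   tolerance = 1e-12)
  }
  expect_equal(dual_frequency(0.3, 0.3), 0.09)
  expect_equal(dual_frequency(0.5, 0), 0)
  expect_equal(dual_frequency(1, 1), 1)
  expect_error(dual_frequency(1.2, 0.5))
})

test_that("cohort taxonomy partitions the occupancy lattice", {
  expect_equal(as.character(classify_cohort(0, 0)$category), "empty")
  expect_equal(as.character(classify_cohort(1, 1)$category), "singlet_1to1")
  expect_equal(as.character(classify_cohort(0, 3)$category), "target_only_control")
  expect_equal(as.character(classify_cohort(3, 0)$category), "effector_only_control")
  expect_equal(as.character(classify_cohort(2, 2)$category), "multiplet")
  expect_equal(as.character(classify_cohort(1, 2)$category), "multiplet")
  grid <- expand.grid(k1 = 0:6, k2 = 0:6)
  cl <- classify_cohort(grid$k1, grid$k2)
  expect_true(all(!is.na(cl$category)))    # every pair maps to one category
  expect_identical(cl$ratio, paste0(grid$k1, ":", grid$k2))
  expect_error(classify_cohort(-1, 0))
})

test_that("expected cohort counts conserve mass and match hand values", {
  e <- expected_cohort_counts(loading_rate(0.5, 0.5), 1024)
  expect_equal(sum(e$pairs$expected), 1024, tolerance = 1e-9)
  expect_equal(sum(e$cohorts), 1024, tolerance = 1e-9)
  expect_equal(unname(e$cohorts["singlet_1to1"]), 1024 * 0.0919698602929,
               tolerance = 1e-6)
  e2 <- expected_cohort_counts(loading_rate(0.83, 0.58), 1024)
  expect_equal(unname(e2$cohorts["singlet_1to1"]), 120.4, tolerance = 1e-3)
  e0 <- expected_cohort_counts(loading_rate(0, 0), 500)
  expect_equal(unname(e0$cohorts["empty"]), 500)
  expect_equal(sum(e0$cohorts) - e0$cohorts["empty"], 0, ignore_attr = TRUE)
})

test_that("chi-square goodness of fit behaves at both extremes", {
  # counts exactly proportional to Poisson(0.5) -> statistic ~ 0
  p <- dpois(0:5, 0.5); p[6] <- 1 - sum(p[1:5])
  counts <- matrix(round(1e6 * p), ncol = 1)
  g <- goodness_of_fit(occupancy_table(counts), 1)
  expect_lt(g$statistic, 0.01)
  expect_gt(g$p.value, 0.99)
  # all mass far from a Poisson shape -> tiny p
  bad <- matrix(c(500L, 0L, 0L, 0L, 0L, 500L), ncol = 1)
  gb <- goodness_of_fit(occupancy_table(bad), 1)
  expect_lt(gb$p.value, 1e-6)
  expect_error(goodness_of_fit(occupancy_table(matrix(100L, 1, 1)), 1))
})

test_that("goodness-of-fit rejection rate is calibrated near alpha", {
  set.seed(42)
  reject <- vapply(seq_len(400), function(i) {
    k <- rpois(1024, 0.5)
    counts <- matrix(tabulate(k + 1L, nbins = max(k) + 1L), ncol = 1)
    goodness_of_fit(occupancy_table(counts), 1)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.015)
  expect_lt(mean(reject), 0.095)
})

test_that("lambda optimization finds the analytic optimum and targets", {
  o <- optimize_lambda("singlet_1to1")
  expect_equal(o$rates$lambda1, 1, tolerance = 1e-3)
  expect_equal(o$value, exp(-2), tolerance = 1e-6)
  oe <- optimize_lambda("empty")
  expect_equal(oe$rates$lambda1, 0, tolerance = 1e-3)
  ot <- optimize_lambda(c(1, 1), target = 0.092, lambda2 = 0.5)
  expect_true(ot$feasible)
  expect_equal(ot$rates$lambda1, 0.5, tolerance = 5e-3)
  inf <- optimize_lambda(c(1, 1), target = 0.5, lambda2 = 0.5)
  expect_false(inf$feasible)
})

test_that("occupancy CSV round-trips and cohort tallies match the fixture", {
  tab <- particle_table()
  tmp <- tempfile(fileext = ".csv")
  write_occupancy_csv(tab, tmp)
  tab2 <- read_occupancy_csv(tmp, c("green", "red"))
  expect_identical(tab$counts, tab2$counts)
  coh <- tabulate_cohorts(tab)
  expect_equal(unname(coh["empty"]), 391)
  expect_equal(unname(coh["singlet_1to1"]), 105)
  expect_equal(unname(coh["target_only_control"]), 241)
  expect_equal(unname(coh["effector_only_control"]), 202)
  expect_equal(sum(coh), 1024)
})
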