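test_that("cells are conserved and capacity is respected", {
  d <- trap_design(S = 3)
  r0 <- simulate_loading(d, list(cell_lot(1, 0), cell_lot(2, 0)), sim_config(seed = 1))
  expect_equal(r0$occupancy$counts[1, 1], 32L)  # all traps empty
  expect_equal(r0$overflow_count, 0L)

  r <- simulate_loading(d, list(cell_lot(1, 100), cell_lot(2, 100)),
                        sim_config(seed = 2, trap_capacity = 1L))
  per <- r$per_trap
  expect_true(all(per[, 1] + per[, 2] <= 1))
  captured <- sum(per)
  expect_equal(captured + r$overflow_count, 200L)
  expect_equal(r$lambda_realized, c(sum(per[, 1]), sum(per[, 2])) / 32)
  expect_error(sim_config(trap_capacity = 0))
})

test_that("identical seed and config give bit-identical results", {
  d <- trap_design(S = 4)
  lots <- list(cell_lot(1, 40), cell_lot(2, 40))
  a <- simulate_loading(d, lots, sim_config(seed = 99))
  b <- simulate_loading(d, lots, sim_config(seed = 99))
  expect_identical(a, b)
  cpl <- sim_config(seed = 99, couple_hydraulics = TRUE)
  a2 <- simulate_loading(d, lots, cpl)
  b2 <- simulate_loading(d, lots, cpl)
  expect_identical(a2$per_trap, b2$per_trap)
})

test_that("uncoupled loading converges to Poisson occupancy (well-mixed limit)", {
  d <- trap_design(S = 8)
  for (lam in c(0.25, 0.5, 1.0)) {
    res <- simulate_replicates(d, list(cell_lot(1, round(lam * 1024)), cell_lot(2, 0)),
                               sim_config(seed = 7 + round(100 * lam), replicates = 20))
    pass <- vapply(res, function(r)
      goodness_of_fit(r$occupancy, 1)$p.value >= 0.01, logical(1))
    expect_gte(mean(pass), 0.95)
  }
})

test_that("replicate summary reproduces the analytic 1:1 singlet frequency", {
  d <- trap_design(S = 8)
  lots <- list(cell_lot(1, 512), cell_lot(2, 512))
  res <- simulate_replicates(d, lots, sim_config(seed = 17, replicates = 60))
  sm <- summarize_replicates(res)
  se <- sd(sm$pair_1to1) / sqrt(length(sm$pair_1to1))
  expect_lt(abs(mean(sm$pair_1to1) - 0.092), 3 * se + 0.002)
  # realized lambda is introduced/N_t minus rare capacity overflow
  expect_equal(mean(sm$lambda), 0.5, tolerance = 1e-3)
  # single replicate: zero spread
  s1 <- summarize_replicates(res[1])
  expect_equal(unname(s1$cohort_sd), rep(0, 5))
  expect_error(summarize_replicates(list()))
})

test_that("hydraulic coupling steers cells to empty traps (less overflow)", {
  d <- trap_design(S = 2)  # 16 traps
  lots <- list(cell_lot(1, 16), cell_lot(2, 16))
  ov <- vapply(1:10, function(s) {
    un <- simulate_loading(d, lots, sim_config(seed = s, trap_capacity = 2L))
    cp <- simulate_loading(d, lots, sim_config(seed = s, trap_capacity = 2L,
                                               couple_hydraulics = TRUE,
                                               occupancy_multiplier = 50))
    c(un$overflow_count, cp$overflow_count)
  }, numeric(2))
  expect_lte(mean(ov[2, ]), mean(ov[1, ]))
})

test_that("sequential and premixed lot ordering both conserve cells", {
  d <- trap_design(S = 3)
  lots <- list(cell_lot(1, 30), cell_lot(2, 30))
  for (mix in c("premixed", "sequential")) {
    r <- simulate_loading(d, lots, sim_config(seed = 5, mixing = mix))
    expect_equal(sum(r$per_trap) + r$overflow_count, 60L)
  }
})
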