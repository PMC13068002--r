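test_that("hydrostatic pressure is rho g h in both gravity conventions", {
  expect_equal(hydrostatic_pressure(998, 10.0, 0.10), 998)
  expect_equal(hydrostatic_pressure(998, 9.81, 0.10), 979.038, tolerance = 1e-6)
  expect_equal(hydrostatic_pressure(column_height = 0), 0)
  expect_error(hydrostatic_pressure(-1, 9.8, 0.1))
})

test_that("lumped flow relation and unit conversions reproduce bench values", {
  q <- total_flow(998, 1.48e13)
  expect_equal(q, 6.743243e-11, tolerance = 1e-6)
  expect_equal(flow_to_uL_min(q), 4.046, tolerance = 1e-3)
  expect_equal(total_flow(0, 1e13), 0)
  expect_equal(total_flow(2 * 998, 1.48e13), 2 * q)  # linearity
  expect_error(total_flow(998, 0))
  expect_equal(uL_min_to_flow(flow_to_uL_min(q)), q, tolerance = 1e-15)
})

test_that("branch flow splits the total over the last-stage channels", {
  d <- trap_design(S = 8)
  expect_equal(branch_flow(4.04, d), 4.04 / 256)
  expect_equal(round(branch_flow(4.04, d), 4), 0.0158)
  expect_equal(round(branch_flow(5, d), 4), 0.0195)
  expect_equal(branch_flow(0, d), 0)
})

test_that("rectangular-duct resistance has the right limits and scale", {
  # wide-channel limit: R -> 12 mu L / (w h^3)
  R <- segment_resistance(1e-3, 1e-3, 1e-5, 1e-3)
  expect_equal(R, 12e-3 * 1e-3 / (1e-3 * 1e-15), tolerance = 0.01)
  expect_equal(segment_resistance(2e-4, 30e-6, 35e-6),
               2 * segment_resistance(1e-4, 30e-6, 35e-6))  # linear in L
  # independent evaluation of the series formula (orientation h <= w)
  expect_equal(segment_resistance(100e-6, 35e-6, 30e-6, 1e-3),
               2.7605245e12, tolerance = 1e-6)
  # orientation convention: arguments commute
  expect_equal(segment_resistance(1e-4, 30e-6, 35e-6),
               segment_resistance(1e-4, 35e-6, 30e-6))
  expect_error(segment_resistance(0, 1e-6, 1e-6))
})

test_that("wall shear scales linearly and vanishes at zero flow", {
  expect_equal(wall_shear(0, 2e-6, 4e-6), 0)
  expect_equal(wall_shear(2e-12, 2e-6, 4e-6), 2 * wall_shear(1e-12, 2e-6, 4e-6))
})

test_that("loading time is volume over flow", {
  expect_equal(loading_time(10, 4.04), 2.475, tolerance = 1e-3)
  expect_equal(loading_time(0, 4.04), 0)
  expect_equal(loading_time(20, 4.04), 4.950, tolerance = 1e-3)
  expect_error(loading_time(10, 0))
})

test_that("network calibration reproduces the measured aggregate resistance", {
  net <- build_network(trap_design(S = 8))
  sol <- solve_flow(net, list(pressure = 998))
  expect_equal(sol$R_device, 1.48e13, tolerance = 1e-9)
  expect_equal(sol$total_flow, 998 / 1.48e13, tolerance = 1e-9)
  # empty symmetric device: every trap flow equals total / N
  expect_equal(sol$trap_flows, rep(sol$total_flow / 1024, 1024),
               tolerance = 1e-10)
  # symmetric last-stage flows
  expect_lt(diff(range(sol$leaf_flows)) / mean(sol$leaf_flows), 1e-10)
})

test_that("tree solver agrees with a dense Kirchhoff solve on the S=1 toy", {
  net <- build_network(trap_design(S = 1))  # 8 traps
  occ <- c(2L, rep(0L, 7))
  mult <- 10
  sol <- solve_flow(net, list(pressure = 998), occ, multiplier = mult)

  # independent oracle: nodal analysis with base::solve.
  # unknown pressures: junction n1, leaves n2 (traps 1-4), n3 (traps 5-8)
  r_path <- net$r_sub + net$r_trap * mult^occ
  g_in <- 1 / net$r_inlet
  g_s <- 1 / net$r_stage[1]
  gp <- 1 / r_path
  A <- matrix(0, 3, 3)
  b <- c(998 * g_in, 0, 0)
  A[1, 1] <- g_in + 2 * g_s; A[1, 2] <- -g_s; A[1, 3] <- -g_s
  A[2, 2] <- g_s + sum(gp[1:4]); A[2, 1] <- -g_s
  A[3, 3] <- g_s + sum(gp[5:8]); A[3, 1] <- -g_s
  p <- solve(A, b)
  oracle_flows <- c(p[2] * gp[1:4], p[3] * gp[5:8])
  expect_equal(sol$trap_flows, oracle_flows, tolerance = 1e-9)
  expect_equal(sol$total_flow, (998 - p[1]) * g_in, tolerance = 1e-9)

  # occupied trap starves, siblings gain, total drops below the empty device
  empty <- solve_flow(net, list(pressure = 998))
  expect_lt(sol$trap_flows[1], empty$trap_flows[1])
  expect_gt(sol$trap_flows[2], empty$trap_flows[2])
  expect_lt(sol$total_flow, empty$total_flow)

  # fixed-flow boundary: same total, higher inlet pressure, higher shear
  pump <- solve_flow(net, list(flow = empty$total_flow), occ, multiplier = mult)
  expect_equal(pump$total_flow, empty$total_flow)
  expect_gt(pump$inlet_pressure, 998)
  expect_gt(pump$trap_shear[1], sol$trap_shear[1])
})

test_that("flow conservation and monotone diversion hold across occupancies", {
  net <- build_network(trap_design(S = 3))  # 32 traps
  prev <- Inf
  for (m in c(1, 2, 5, 10, 100)) {
    occ <- rep(0L, 32); occ[7] <- 1L
    sol <- solve_flow(net, list(pressure = 998), occ, multiplier = m)
    # conservation: trap flows sum to the total
    expect_equal(sum(sol$trap_flows), sol$total_flow, tolerance = 1e-9)
    # per-leaf conservation
    leaf_sum <- tapply(sol$trap_flows, (seq_len(32) - 1) %/% 4, sum)
    expect_equal(as.numeric(leaf_sum), sol$leaf_flows, tolerance = 1e-9)
    # occupied-trap flow non-increasing in the multiplier
    expect_lte(sol$trap_flows[7], prev)
    prev <- sol$trap_flows[7]
  }
})

test_that("pump boundary needs at least the pipette pressure when occupied", {
  net <- build_network(trap_design(S = 2))
  base <- solve_flow(net, list(pressure = 998))
  for (n_occ in c(1, 5, 16)) {
    occ <- rep(0L, 16); occ[seq_len(n_occ)] <- 1L
    pip <- solve_flow(net, list(pressure = 998), occ)
    pump <- solve_flow(net, list(flow = base$total_flow), occ)
    expect_gte(pump$inlet_pressure, pip$inlet_pressure)
  }
})
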