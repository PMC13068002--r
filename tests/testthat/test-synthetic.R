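test_that("ground truth respects cohort-conditional death rules", {
  sc <- cohort_scenario(S = 4, death_prob = c("1:1" = 0), division_rate = 0,
                        escape_rate = 0,
                        spontaneous_death = c(effector = 0, target = 0))
  gt <- generate_ground_truth(sc)
  expect_equal(sum(!is.na(gt$cells$death_h)), 0)  # all probabilities zero
  expect_equal(nrow(gt$traps), sc$design$N)

  # contact-dependent deaths only in co-culture traps; controls spontaneous only
  sc2 <- cohort_scenario(S = 5, n11 = 60, n_ctrl_t = 30, n_ctrl_e = 30, seed = 3,
                         death_prob = c("1:1" = 1), division_rate = 0,
                         escape_rate = 0,
                         spontaneous_death = c(effector = 0, target = 0))
  gt2 <- generate_ground_truth(sc2)
  dead <- gt2$cells[!is.na(gt2$cells$death_h), ]
  expect_true(all(dead$population == "target"))
  expect_true(all(dead$trap %in% gt2$traps$trap[gt2$traps$k1 >= 1 & gt2$traps$k2 >= 1]))
  expect_equal(nrow(dead), 60)  # p = 1 in every 1:1 trap
  # event times lie on the frame grid
  expect_true(all(dead$death_h %in% gt2$frames_h))
})

test_that("singlet death fraction concentrates at the configured probability", {
  fr <- vapply(1:20, function(s) {
    sc <- cohort_scenario(S = 6, n11 = 213, n_ctrl_t = 0, n_ctrl_e = 0,
                          seed = 100 + s, division_rate = 0, escape_rate = 0,
                          spontaneous_death = c(effector = 0, target = 0))
    gt <- generate_ground_truth(sc)
    mean(!is.na(gt$cells$death_h[gt$cells$population == "target"]))
  }, numeric(1))
  se <- sqrt(0.215 * 0.785 / 213) / sqrt(20)
  expect_lt(abs(mean(fr) - 0.215), 3 * se)
})

test_that("generator output is bit-deterministic given the seed", {
  sc <- cohort_scenario(S = 3, n11 = 20, n_ctrl_t = 6, n_ctrl_e = 6, seed = 8)
  a <- generate_ground_truth(sc); b <- generate_ground_truth(sc)
  expect_identical(a, b)
  sa <- render_timelapse(a, sc); sb <- render_timelapse(b, sc)
  expect_identical(sa$data, sb$data)
  ca <- generate_calcium_traces(sc, n = c(responder = 5, non_responder = 5,
                                          death_signature = 5))
  cb <- generate_calcium_traces(sc, n = c(responder = 5, non_responder = 5,
                                          death_signature = 5))
  expect_identical(ca$traces, cb$traces)
})

test_that("rendered stack encodes the death optics (PI step, GFP decay, stable tracer)", {
  d <- trap_design(S = 2)
  occ <- cbind(k1 = rep(1L, 16), k2 = rep(1L, 16))
  sc <- scenario_config(design = d, occupancy = occ,
                        death_prob = c("1:1" = 1),
                        death_time_dist = c("8" = 1),
                        division_rate = 0, escape_rate = 0,
                        spontaneous_death = c(effector = 0, target = 0), seed = 4)
  gt <- generate_ground_truth(sc)
  st <- render_timelapse(gt, sc)
  frames <- st$frames_h
  i8 <- which(frames == 8); i0 <- 1L; iT <- length(frames)
  ch <- function(f, name) st$data[f, match(name, st$channels), , ]
  bg <- sc$noise_mean
  # red PI appears only from the death frame on
  expect_lt(max(ch(i8 - 1, "red")) - bg, 8 * sc$noise_sd)
  expect_gt(max(ch(i8, "red")) - bg, 100)
  # green decays after death: endpoint peak below half its initial value
  g0 <- max(ch(i0, "green")) - bg
  gT <- max(ch(iT, "green")) - bg
  expect_lt(gT, 0.5 * g0)
  # blue tracer persists within noise
  b0 <- max(ch(i0, "blue")) - bg
  bT <- max(ch(iT, "blue")) - bg
  expect_gt(bT, 0.8 * b0)
  # red and blue colocalize at the endpoint
  rmask <- ch(iT, "red") - bg > 100
  bmask <- ch(iT, "blue") - bg > 100
  expect_gt(sum(rmask & bmask) / sum(rmask), 0.5)
})

test_that("no-event renders are flat and empty traps are background", {
  sc <- cohort_scenario(S = 3, n11 = 12, n_ctrl_t = 6, n_ctrl_e = 6, seed = 9,
                        death_prob = c("1:1" = 0), division_rate = 0,
                        escape_rate = 0,
                        spontaneous_death = c(effector = 0, target = 0))
  rs <- render_scenario(sc)
  st <- rs$stack
  empty_traps <- rs$truth$traps$trap[rs$truth$traps$k1 == 0 & rs$truth$traps$k2 == 0]
  pitch <- st$pitch_px
  tr <- empty_traps[1]
  roi <- st$data[1, 1, , ((tr - 1) * pitch + 1):(tr * pitch)]
  expect_lt(abs(mean(roi) - sc$noise_mean), 3 * sc$noise_sd)
  # per-trap green intensity flat over time without bleach or deaths
  an <- analyze_stack(st, sc$design)
  occupied <- which(rs$truth$traps$k2 > 0)
  for (tr in occupied[1:5]) {
    g <- an$series[[tr]]$intensity[, "green"]
    expect_gt(min(g) / max(g), 0.85)
  }
})

test_that("ground truth serializes losslessly to JSON", {
  sc <- cohort_scenario(S = 3, n11 = 12, n_ctrl_t = 6, n_ctrl_e = 6, seed = 13,
                        division_rate = 0.2, escape_rate = 0.2)
  gt <- generate_ground_truth(sc)
  tmp <- tempfile(fileext = ".json")
  write_ground_truth(gt, tmp)
  gt2 <- read_ground_truth(tmp)
  expect_equal(gt2$cells, gt$cells)
  expect_equal(gt2$traps, gt$traps)
  expect_equal(gt2$frames_h, gt$frames_h)
})

test_that("calcium archetypes degenerate as configured", {
  sc <- cohort_scenario(S = 3, seed = 31)
  only_non <- generate_calcium_traces(sc, n = c(responder = 0, non_responder = 20,
                                                death_signature = 0))
  expect_true(all(only_non$labels$label == "non_responder"))
  # zero-amplitude responders are indistinguishable from non-responders
  flat <- generate_calcium_traces(sc, n = c(responder = 20, non_responder = 0,
                                            death_signature = 0),
                                  pulse_amplitude = c(0, 0))
  cl <- classify_traces(flat)
  expect_true(all(cl$label == "non_responder"))
})
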