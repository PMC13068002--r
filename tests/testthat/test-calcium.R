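test_that("normalization divides by the early-frame median", {
  tt <- seq(0, 100, by = 10)
  tr <- normalize_trace(tt, rep(50, 11))
  expect_equal(tr$norm, rep(1, 11))
  step <- normalize_trace(tt, c(rep(100, 6), rep(300, 5)))
  expect_equal(step$F0, 100)
  expect_equal(step$norm[8], 3)
  bad <- normalize_trace(tt, rep(0, 11))
  expect_false(bad$valid)
  expect_error(normalize_trace(1:5, 1:5))          # too short
  expect_error(normalize_trace(c(0, 1, 2, 4, 8, 16), rep(1, 6)))  # non-uniform
})

test_that("transient detection separates pulses from steps and noise", {
  tt <- seq(0, 1790, by = 10)
  set.seed(3)
  flat <- normalize_trace(tt, 100 + rnorm(length(tt), 0, 3))
  expect_equal(nrow(detect_transients(flat)), 0)
  # single gamma pulse at 600 s
  u <- (tt - 600) / 80
  pulse <- ifelse(u > 0, u * exp(1 - u), 0)
  resp <- normalize_trace(tt, 100 * (1 + 1.5 * pulse) + rnorm(length(tt), 0, 3))
  pk <- detect_transients(resp)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$onset_s - 600), 30)
  expect_equal(pk$amplitude, 1.5, tolerance = 0.15)
  # sustained step: no transient
  stepv <- 100 * (1 + 2 / (1 + exp(-(tt - 300) / 15))) + rnorm(length(tt), 0, 3)
  expect_equal(nrow(detect_transients(normalize_trace(tt, stepv))), 0)
})

test_that("trace taxonomy assigns the three archetypes", {
  tt <- seq(0, 1790, by = 10)
  set.seed(8)
  flat <- normalize_trace(tt, 100 + rnorm(length(tt), 0, 3))
  expect_equal(classify_trace(flat)$label, "non_responder")
  u <- (tt - 500) / 90
  resp <- normalize_trace(tt, 100 * (1 + 1.6 * pmax(u, 0) * exp(1 - pmax(u, 0))) +
                            rnorm(length(tt), 0, 3))
  expect_equal(classify_trace(resp)$label, "responder")
  # step-to-plateau near the start of the window
  stepv <- c(rep(100, 6), rep(320, length(tt) - 6)) + rnorm(length(tt), 0, 3)
  cls <- classify_trace(normalize_trace(tt, stepv))
  expect_equal(cls$label, "death_signature")
  expect_gt(cls$plateau_fraction, 0.5)
  # invalid trace is reported, not classified
  bad <- normalize_trace(tt, rep(0, length(tt)))
  expect_equal(classify_trace(bad)$label, "unclassified")
})

test_that("classification is invariant to uniform gain", {
  sc <- cohort_scenario(S = 3, seed = 77)
  cs <- generate_calcium_traces(sc, n = c(responder = 20, non_responder = 20,
                                          death_signature = 20))
  cl1 <- classify_traces(cs)
  scaled <- cs$traces
  scaled$intensity <- scaled$intensity * 7.3
  cl2 <- classify_traces(scaled)
  expect_equal(cl1$label, cl2$label)
})

test_that("archetype fixture is classified with at least 95% accuracy", {
  sc <- cohort_scenario(S = 3, seed = 21)
  cs <- generate_calcium_traces(sc)  # 100 per archetype at default SNR
  cl <- classify_traces(cs)
  m <- merge(cs$labels[, c("trap", "label")], cl[, c("trap", "label")], by = "trap")
  expect_gte(mean(m$label.x == m$label.y), 0.95)
})

test_that("response summaries report fractions, exclusions and discordance", {
  sc <- cohort_scenario(S = 3, seed = 78)
  cs <- generate_calcium_traces(sc, n = c(responder = 150, non_responder = 120,
                                          death_signature = 30))
  cl <- classify_traces(cs)
  s <- summarize_responses(cl)
  expect_equal(s$n, 300)
  expect_lt(abs(s$responder_frac - 0.5), 3 * sqrt(0.5 * 0.5 / 300))
  expect_lt(abs(s$death_signature_frac - 0.1), 3 * sqrt(0.1 * 0.9 / 300))
  # death-signature traces excluded from the responder denominator
  expect_gte(s$responder_frac_excl_death, s$responder_frac)
  # a trap holding one responder and one non-responder is discordant
  two <- rbind(
    cbind(data.frame(trap = 1, cell = 1),
          classify_trace(normalize_trace(seq(0, 100, 10), rep(100, 11)))),
    cbind(data.frame(trap = 1, cell = 2),
          classify_trace(normalize_trace(seq(0, 100, 10), rep(100, 11)))))
  two$label <- c("responder", "non_responder")
  s2 <- summarize_responses(two)
  expect_equal(s2$discordant_trap_frac, 1)
  # all-flat control: zero responders
  flatset <- generate_calcium_traces(sc, n = c(responder = 0, non_responder = 30,
                                               death_signature = 0))
  sf <- summarize_responses(classify_traces(flatset), "control")
  expect_equal(sf$responder_frac, 0)
})
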