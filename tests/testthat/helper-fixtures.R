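# Shared fixtures for the test suite. All image data is generated in code at
# test time; the only stored fixture is the small synthetic particle
# occupancy CSV in inst/extdata.

# Dual-colour particle occupancy table whose marginal and dual tallies match
# a published 1024-trap bead characterization (the off-diagonal split is a
# consistent synthetic reconstruction).
particle_table <- function() {
  read_occupancy_csv(system.file("extdata", "particle_occupancy_synthetic.csv",
                                 package = "traparray"),
                     population_labels = c("green", "red"))
}

# deterministic co-culture scenario on a small array: n11 1:1 traps,
# n_ctrl_t target-only, n_ctrl_e effector-only, rest empty
cohort_scenario <- function(S = 4L, n11 = 8L, n_ctrl_t = 4L, n_ctrl_e = 4L,
                            seed = 11L, ...) {
  design <- trap_design(S = S)
  n_empty <- design$N - n11 - n_ctrl_t - n_ctrl_e
  stopifnot(n_empty >= 0)
  occ <- cbind(k1 = c(rep(1L, n11), rep(0L, n_ctrl_t), rep(1L, n_ctrl_e),
                      rep(0L, n_empty)),
               k2 = c(rep(1L, n11), rep(1L, n_ctrl_t), rep(0L, n_ctrl_e),
                      rep(0L, n_empty)))
  scenario_config(design = design, occupancy = occ, seed = seed, ...)
}

# render a scenario and return ground truth + stack
render_scenario <- function(scenario) {
  truth <- generate_ground_truth(scenario)
  list(truth = truth, stack = render_timelapse(truth, scenario))
}
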