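# traparray

Analysis tools for single-cell pairing experiments in bifurcated
microfluidic trap arrays — the devices that co-seed an effector population
(e.g. NK cells) and a target population (e.g. tumour cells) into hundreds of
parallel traps in one step, then watch each pair by time-lapse microscopy.

Loading such a device is stochastic: the number of cells of population *i*
captured in a trap follows a Poisson law

&nbsp;&nbsp;&nbsp;&nbsp;*P*(λᵢ, k) = λᵢᵏ e^(−λᵢ) / k!,&nbsp;&nbsp;&nbsp;&nbsp;λᵢ = Nₚ,ᵢ / Nₜ,

and co-occupancy follows the double Poisson product
*P*(k₁ : k₂) = *P*(k₁) · *P*(k₂). One seeding therefore yields a mixture of
empty traps (0:0), single-population controls (≥1:0, 0:≥1), 1:1 singlets and
higher-order multiplets, with proportions tunable through λ. The package
implements:

* **Occupancy statistics** — pmf/estimators, cohort taxonomy, expected
  cohort yields, chi-square goodness of fit, and a λ design helper
  (`poisson_pmf`, `estimate_lambda`, `double_poisson`, `classify_cohort`,
  `expected_cohort_counts`, `goodness_of_fit`, `optimize_lambda`).
* **Hydraulic network model** — the `N = 4·2^S` bifurcation tree as a lumped
  Hagen–Poiseuille resistance network, calibrated to a measured aggregate
  resistance, with occupancy-dependent flow diversion under fixed-pressure
  (pipette) or fixed-flow (syringe pump) boundaries and per-filter shear
  estimates (`trap_design`, `build_network`, `solve_flow`,
  `hydrostatic_pressure`, `total_flow`, `branch_flow`, `loading_time`).
* **Monte-Carlo loading simulator** — seeded sequential cell routing down
  the tree, optionally hydraulically coupled, reproducing Poisson occupancy
  in the well-mixed limit (`simulate_loading`, `simulate_replicates`,
  `summarize_replicates`).
* **Synthetic data generator** — ground-truthed multi-channel time-lapse
  stacks (GFP + blue tracer targets, PI death marker, brightfield-proxy
  effectors, division/escape events, photobleaching) and three-archetype
  calcium traces (`scenario_config`, `generate_ground_truth`,
  `render_timelapse`, `generate_calcium_traces`).
* **Image pipeline** — straighten/crop stitched stacks, split into per-trap
  ROIs, count both populations, extract intensity traces, call deaths
  strictly by tracer+PI colocalization, apply division/escape exclusions,
  and summarise per-cohort cytotoxicity with ANOVA–Tukey or
  Kruskal–Wallis–Dunn significance testing (`analyze_stack` and the
  step-wise functions it wraps).
* **Calcium analysis** — F/F0 normalization, transient detection, and the
  responder / non-responder / death-signature taxonomy (`normalize_trace`,
  `detect_transients`, `classify_trace`, `summarize_responses`).

## Worked example

```r
library(traparray)

# Expected cohort yields for a 1024-trap device at lambda = 0.5 / 0.5
expected_cohort_counts(loading_rate(0.5, 0.5), N_t = 1024)
#> Expected cohort yields for N_t = 1024 traps (lambda1 = 0.5, lambda2 = 0.5):
#>                 empty effector_only_control   target_only_control
#>                 376.7                 244.4                 244.4
#>          singlet_1to1             multiplet
#>                  94.2                  64.4

# Hydrostatic loading: 10 cm column, measured device resistance
q <- total_flow(hydrostatic_pressure(998, 10.0, 0.10), 1.48e13)
flow_to_uL_min(q)          # 4.046 uL/min total
branch_flow(4.04, trap_design(S = 8))  # 0.0158 uL/min per last-stage channel

# Simulate a loading and check it against the Poisson model
res <- simulate_loading(trap_design(S = 8),
                        list(cell_lot(1, 512), cell_lot(2, 512)),
                        sim_config(seed = 1))
goodness_of_fit(res$occupancy, 1)
#> Poisson goodness of fit: X^2 = 0.241, df = 2, p = 0.8865 (lambda_hat = 0.5)

# Closed loop: synthetic 1:1 co-culture stack -> full pipeline
design <- trap_design(S = 4)
occ <- cbind(k1 = c(rep(1L, 40), rep(0L, 24)),
             k2 = c(rep(1L, 40), rep(0L, 10), rep(1L, 10), rep(0L, 4)))
sc <- scenario_config(design = design, occupancy = occ, seed = 11)
truth <- generate_ground_truth(sc)
stack <- render_timelapse(truth, sc)
analyze_stack(stack, design)$result
#> Per-cohort cytotoxicity (retained traps): per-cohort trap tallies,
#> target/effector death percentages and normalized endpoint intensities
```

The cohort summary lists, per effector-to-target cohort, the traps
assigned/excluded/retained, the target-death percentage among retained
traps (PI+tracer colocalization only — GFP loss alone never calls a death),
and the endpoint/initial green-intensity ratio.

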