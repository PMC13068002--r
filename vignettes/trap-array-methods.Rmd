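---
title: "Models and methods behind traparray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind traparray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traparray)
```

# The experimental system

A bifurcated trap-array chip splits an inlet channel in two at each of $S$
stages; after the last stage each channel opens into four sub-channels that
terminate in cell traps, giving $N = 4 \cdot 2^S$ traps ($N = 1024$ at
$S = 8$). Each trap ends in two or three filter constrictions narrower than
a cell, so cells are retained while medium passes. Seeding is driven
hydrostatically by the liquid column in a pipette tip; a mixed suspension of
an effector population (e.g. NK cells) and a target population (e.g.
GFP-expressing tumour cells) distributes stochastically over the traps.
The array is then imaged as a stitched panorama every 2 h for 14 h
(long-term cytotoxicity) or every 10 s for 30 min (calcium flux).

This vignette documents the models the package implements, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was open.

# Poisson occupancy model

Trap occupancy of each population is modelled as Poisson with rate
$\lambda_i = N_{p,i}/N_t$ (captured cells per trap); co-occupancy is the
product $P(k_1\!:\!k_2) = P(k_1)\,P(k_2)$, i.e. the populations load
independently. The pairing cohorts partition the occupancy lattice: empty
$(0\!:\!0)$, effector-only control $(\ge 1\!:\!0)$, target-only control
$(0\!:\!\ge 1)$, the 1:1 singlet, and multiplets (everything else doubly
occupied).

Design choices:

* **Tail aggregation.** Expected-count tables aggregate $k \ge k_{max}$
  (default 5) into one bin, so totals equal $N_t$ exactly and reporting
  matches the "$\ge 2$"-style classes used in array characterizations.
* **Goodness of fit.** The marginal tallies are tested against
  Poisson($\hat\lambda$) by chi-square with bins of expected count $< 5$
  merged upward and $df = \mathrm{bins} - 2$ (one df for totals, one for
  the estimated rate). A Monte-Carlo calibration test keeps the rejection
  rate near the nominal $\alpha$.
* **Two dual-frequency estimators.** The product rule
  $f(k_1\!:\!k_2) = f(k_1) f(k_2)$ and the direct tally
  $n_t(k_1\!:\!k_2)/N_t$ are both exposed; printed dual counts in the
  literature can be either, and the two differ at finite $N_t$.
* **$\lambda$ design helper.** `optimize_lambda()` uses a deterministic
  coarse grid plus golden-section refinement (via `optimize()`); the
  objectives are smooth and at most 2-D, so stochastic search is
  unnecessary. The symmetric 1:1 optimum is $\lambda = 1$ with probability
  $e^{-2}$.

# Lumped hydraulic model

The paper-scale device is characterised by closed-form relations — inlet
pressure $P = \rho g h$, total flow $Q = P/R$, per-branch flow $Q/2^S$ —
plus a full network model for occupancy effects. The network is a strict
series-parallel tree: an inlet segment, $S$ generations of channel segments
whose lengths halve per stage (distributing the 61.44 mm array span), four
trap sub-channels per last-stage channel, and a terminal filter edge per
trap (2–3 rectangular filter channels in parallel). Segment resistances use
the rectangular-duct series approximation
$R = 12 \mu L / (w h^3 (1 - 0.63\,h/w))$, $h \le w$.

Because per-segment lengths of the fabricated device are not published, the
network is calibrated by a single global scale factor so the empty-device
aggregate resistance equals the bench-measured $1.48 \times 10^{13}$
Pa s m$^{-3}$. Channel height uses the as-fabricated 35 µm (the 40 µm mask
height is also carried in the design object). Relative flow distributions
are therefore meaningful even though individual segment lengths are
nominal.

* **Occupancy.** A captured cell multiplies its trap's filter resistance by
  `occupancy_multiplier` (default 10 per cell). The value is a
  configuration choice — the diversion effect is qualitative in the source
  material — and all monotonicity properties hold for any multiplier > 1.
* **Boundaries.** Fixed inlet pressure models pipette drive; fixed inlet
  flow models a syringe pump. Under fixed pressure an occupied trap's flow
  and filter shear drop as flow diverts to empty neighbours; under fixed
  flow the inlet pressure rises instead and occupied-trap shear stays
  high. The solver is an exact $O(N)$ series-parallel collapse; tests check
  it against a dense Kirchhoff solve on an 8-trap toy.
* **Gravity.** $P = \rho g h$ with $g = 9.80665$ by default gives 979 Pa
  for $\rho = 998$, $h = 0.10$ m; the round figure 998 Pa quoted for this
  configuration corresponds to $g \approx 10$, so both conventions are
  accepted via the `gravity` argument and documented.
* **Units.** SI everywhere internally; µL/min only through
  `flow_to_uL_min()` / `uL_min_to_flow()` at the interface.

# Loading simulator

`simulate_loading()` routes cells one at a time from the inlet: at every
junction the branch is chosen with probability proportional to the current
branch flow, and at a terminal trap the cell is captured unless the trap is
at capacity. Uncoupled routing (equal splits, the well-mixed limit) is
equivalent to uniform trap choice and converges to Binomial
$(N_p, 1/N_t) \approx$ Poisson$(\lambda)$ occupancy; coupled routing
re-solves the subtree conductances after every capture (an $O(S)$
incremental update), steering later cells toward empty traps.

Choices: capture probability is 1 at a non-full trap (the filter geometry
guarantees capture; escape during the brief loading phase is not
simulated); trap capacity defaults to 6 cells; overflow cells are removed
and tallied rather than re-circulated (the physical fate of a cell reaching
a full trap is not documented; the choice is recorded in the result);
premixed lots interleave the populations by a seeded permutation, while
sequential lots run population 1 fully first. One root seed drives
deterministic per-replicate streams, and identical configurations are
bit-reproducible.

# Synthetic data generator

The generator is first-class, tested code: it produces the ground-truthed
inputs every downstream stage is validated against.

**Events.** Per-trap occupancies come from explicit tables, Poisson rates,
or a simulation result. In co-culture traps each target dies with the
cohort's probability (defaults: 0.215 for 1:1, 0.126 for 1:2, 0.267 for
2:1 — a dose-response in effector availability); control traps experience
only spontaneous baselines (defaults 0.01 effector, 0.044 target). Death
times are drawn from a discrete distribution on the 2-h frame grid weighted
toward 4–12 h. Division and escape are per-cell Bernoulli events (default
0.02) on interior frames; dead cells never divide or escape.

**Optics.** Cells render as Gaussian blobs (14 µm FWHM at 3 µm/pixel by
default). Targets carry green (GFP) and blue (a stable tracer); effectors
appear only in a brightfield-proxy channel (all cells appear there, as in
real brightfield). PI in the medium makes any dead cell step red at its
death frame; after target death the green decays exponentially (2 h
half-life) while the blue persists — dead targets remain rendered as
debris, because the filter constrictions retain lysed material. Escaping
cells shift half out of the band for one frame and vanish; divisions spawn
an adjacent equal-intensity blob placed deterministically at the free
position farthest from the trap's other cells. Background is Gaussian
noise (mean 100, sd 5; doubled for the brightfield proxy); optional global
rotation and per-frame photobleaching exercise the geometry pipeline.

**Calcium traces.** Three labelled archetypes on the 10 s / 30 min grid:
responders (1–3 gamma-shaped transients, amplitude 1–2 × baseline, rise
constant 60–120 s), non-responders (flat noise), and the death signature (a
logistic step within 1–5 min of loading to a sustained 2.5–3.5 × plateau).
A 5% linear bleach over the window is superimposed by default.

**What it does not emulate** — and hence what passing tests do not show
about real data: no optical PSF beyond Gaussian blobs, no focus drift or
stage jitter, no cell migration within the trap between frames, no
intensity heterogeneity between cells of a population, no segmentation-level
debris or clumps, and the brightfield proxy is a bright-blob stand-in for
real phase contrast. Pipeline accuracies measured on these fixtures are
upper bounds for real stacks.

# Image pipeline

* **Straightening.** The band tilt is estimated by maximising the sharpness
  (sum of squared row means) of the thresholded reference image over
  rotation angle — robust to the positions of individual cells — and the
  stack is rotated back and row-cropped to the band. Rotations below 0.1°
  are not applied, so aligned stacks pass through pixel-identical.
* **ROI grid.** The design pitch is verified against the autocorrelation of
  the column profile (>10% deviation is an error); the grid phase is the
  phase of the Fourier fundamental of the profile at the pitch frequency.
  ROI boxes are half-open, 0-based column intervals of one pitch —
  unambiguous round-tripping was the criterion for this convention.
* **Counting.** Cell centres are local maxima of the 3×3-smoothed,
  background-subtracted image above an 8×MAD noise floor, with a minimum
  mutual separation of half a cell diameter. Targets come from the
  pixelwise max of green and blue (so dead targets stay countable via the
  tracer); a brightfield spot within 2.9 px of a target spot is the same
  cell, the rest are effectors. Background is the per-band border-ring
  median (the top and bottom rows); mean ROI intensities are
  background-subtracted and clipped at zero.
* **Death calling.** Strictly dual-fluorescence: a PI-positive connected
  component overlapping the tracer mask by ≥ 0.5 (configurable) is a target
  death at its first such frame; PI without tracer is an effector death;
  GFP loss alone never calls a death. The per-frame colocalization tallies
  make death calling monotone, so no cell tracking is needed.
* **Exclusions.** Division: a count increase sustained for ≥ 2 consecutive
  frames (the persistence requirement rejects segmentation flicker).
  Escape: a count decrease with no new PI event in the surrounding frames.
  Also: PI-positive at frame 0 (pre-loaded dead) and saturated/merged ROIs
  (ambiguous count). Flags compose; retained + excluded = assigned per
  cohort, always.
* **Statistics.** Cohort outcomes are compared by one-way ANOVA + Tukey HSD
  when every cohort passes a Shapiro-Wilk gate at $\alpha = 0.05$,
  otherwise Kruskal-Wallis + Dunn's z-test with Bonferroni adjustment
  (Dunn's procedure is implemented in-package, tested against independent
  rank arithmetic). Tiers use the conventional thresholds (* < 0.0332,
  ** < 0.0021, *** < 0.0002, **** < 0.0001). Normalized intensity is
  per-trap endpoint/initial; both that ratio and the absolute intensities
  are reported because relative-vs-absolute drop conventions differ between
  studies.

# Calcium analysis

Traces are normalized to $F/F_0$ with $F_0$ the median of the first five
frames (50 s). Because traces are normalized, quiescent frames sit near 1:
baseline frames are those below $1 + 3\sigma$ with $\sigma$ estimated from
frame-to-frame differences, a linear fit through them is divided out
(conservative photobleach correction), and transients must exceed the
baseline by max(2 baseline sd, 0.2 $F/F_0$), have local prominence ≥ 0.2
(rejecting bumps on a decaying shoulder), and return toward baseline
(rejecting steps). The death signature is ≥ 50% of frames above 2× baseline
with no return; when the influx step falls inside the $F_0$ window the
classifier re-anchors on the lowest observed frames. Death-signature traces
are excluded from responder-fraction denominators, mirroring the exclusion
of compromised effectors. Thresholds are configuration-exposed defaults
chosen so the three archetypes separate cleanly at the generator's SNR; no
claim is made that they match any manual criteria.

# Problem sizes and determinism

The bundled tests and the acceptance script run at reduced scale as a
design choice: synthetic stacks use $S = 3$–$7$ devices (32–512 traps) at
3 µm/pixel with 8 frames, which preserves every structural property of the
full $S = 8$ panorama while keeping fixtures generatable in code at test
time. The Monte-Carlo loading checks use the full 1024-trap geometry (the
simulator is cheap). All randomness flows from explicit integer seeds
through deterministic derived streams; identical configurations reproduce
results bit-for-bit.

# Known limitations

* The hydraulic network is steady-state and lumped: no transients, no
  cell-deformation mechanics, no diffusive crosstalk between traps.
* The occupancy model assumes independent loading of the two populations;
  no covariance correction is applied to the dual-frequency product rule.
* Counting assumes cells at least half a diameter apart; heavily clumped
  multiplets would be flagged ambiguous rather than resolved.
* Within-trap association of deaths to individual cells is by count, not
  by a tracker; per-cell identity across frames is not maintained.
* The cell-line-specific calcium peak shapes (gradual vs spiked) are
  exported as features (amplitude, duration, rise) but no line-specific
  classifier is asserted.
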