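---
title: "Methods: motility, chemotaxis, and cytoskeletal biomechanics metrics"
author: "paccmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motility, chemotaxis, and cytoskeletal biomechanics metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paccmotion)
```

# Scope

`paccmotion` implements the quantitative side of a single-cell phenotyping
workflow used to characterise enlarged, stress-induced polyaneuploid
(PACC-state) cancer cells: per-cell trajectory metrics from time-lapse
tracking, circular statistics and a decision rule for chemotaxis in a serum
gradient, mean-squared-displacement (MSD) analysis of cytoskeleton-anchored
beads, magnetic-twisting-cytometry (MTC) stiffness, Hertz-model fitting of
AFM force–indentation curves, and the small arithmetic of expression
quantification (ΔΔCt, NanoString positive-control normalisation,
fluorescence summaries, positivity percentages). Everything upstream of
numbers — cell culture, imaging, segmentation, manual tracking — is out of
scope: the package consumes tables.

Because raw tracking and instrument data of this kind are rarely deposited,
the package ships synthetic-data generators with known ground truth for
every assay. They are first-class, tested code: all parameter-recovery and
calibration claims below are claims about these generators, evaluated by
the test suite and by `scripts/acceptance.R`.

# Trajectory metrics

A `trajectory` is a time-ordered list of (t, x, y) samples in minutes and
micrometres, optionally with a 2D cell area and exclusion flags. Metrics
are purely positional and never assume uniform sampling:

* **accumulated distance** — sum of consecutive segment lengths;
* **Euclidean distance** — first-to-last straight-line length;
* **directness** — Euclidean / accumulated; 1 means perfectly straight.

A cell that never moved has directness 0/0. We report that as *missing*
(`NA`), never 0 or 1, and drop it from cohort summaries — any imputation
would bias the cohort mean in an arbitrary direction. Cohort summaries are
always per-cell (one number per cell, as in dot plots), never per-step
pooling, so long tracks do not dominate.

The exclusion rule (`apply_exclusions`) removes cells flagged as divided,
apoptosed, or out-of-frame, and logs the count so reported cohort sizes
stay auditable. The rule is idempotent.

`regress_metric_vs_area` asks whether a motility metric is a cell-size
effect, by OLS of the per-cell metric on per-cell area; with slope and R²
near zero, size does not explain motility differences.

Coordinates are Cartesian with +y up. Tracking exports that use the image
convention (+y down) are flipped at the reader (`trajectory_dialect`,
`y_axis_direction = "image_down"`), so "up the gradient" means the same
thing regardless of source. The gradient axis convention is that the
declared axis points from the 0% toward the 20% serum reservoir; readers
must declare it, nothing is inferred.

# Chemotaxis statistics

Each cell contributes its *endpoint vector* — the displacement from its
first to its last sample, i.e. the endpoint of its spider-plot track.

**Forward migration indices.** Per cell, the endpoint component parallel
(or perpendicular) to the gradient axis divided by that cell's accumulated
distance; the cohort index is the arithmetic mean over cells. This is the
convention of the widely used ImageJ chemotaxis tooling. It follows
identically that per cell FMI∥² + FMI⊥² = directness², which the test
suite checks to 1e-9 as a cross-module identity.

**Rayleigh test.** Uniformity of endpoint angles, Z = n·R̄², with the
small-sample corrected p-value

p = exp(−Z)·[1 + (2Z − Z²)/(4n) − (24Z − 132Z² + 76Z³ − 9Z⁴)/(288n²)],

clamped to [0, 1]. This closed form is stated so results are exactly
reproducible elsewhere. Monte-Carlo calibration at n = 50 over 10,000 null
replicates keeps the empirical type-I error inside [0.04, 0.06].

**Rayleigh test for vector data.** The variant that also uses endpoint
distance. The literature names the test but not a unique recipe; we use
Moore's rank-based modification: magnitudes are replaced by ranks
(mid-ranks on ties, noted in the result), the statistic is the length of
the rank-weighted resultant of unit vectors normalised by n^{3/2}. The
null hypothesis is circular *uniformity* of directions, so the p-value is
obtained by seeded Monte-Carlo draws of the statistic with the observed
ranks paired against independently drawn uniform angles (10,000 draws by
default). We deliberately do not permute ranks against the observed
angles: that scheme tests independence of magnitude and direction, not
uniformity, and is blind to the most important alternative — all cells
moving the same way (the statistic is then invariant under the
permutation). The choice of variant is a documented design decision, not a
claim about what the original ImageJ implementation computed.

**Decision rule.** `classify_chemotaxis` declares a cohort chemotactic
only if (a) both circular tests are significant in the gradient arm and
nonsignificant in both uniform-media control arms; (b) the gradient arm's
∥FMI is significantly higher than each control's ∥FMI and than its own
⊥FMI (one-sided Mann–Whitney on per-cell components, consistent with the
workflow's global use of Mann–Whitney); and (c) the "close to zero" FMIs
(gradient ⊥, all control components) are within `near_zero_epsilon` of
zero. The tolerance defaults to 0.1 — no published threshold exists, so it
is an exposed parameter, not a constant. α defaults to the workflow-wide
0.05.

A structural property of this rule is worth stating plainly: it requires
four independent-ish hypothesis tests (two variants × two control arms) to
be *simultaneously* nonsignificant. With correctly calibrated tests at
α = 0.05 the probability of that joint event is at most (1 − 0.05)² ≈ 0.90
even if the two variants were perfectly correlated within an arm, and
≈ 0.84 at their actual correlation. Cohort-level "power" of the full rule
therefore plateaus around 0.84–0.87 regardless of how strong the gradient
response is; the test suite measures 0.835 at drift bias 0.4 with
60 cells/arm (every other criterion of the rule passes at rate 1.0 there,
and the false-verdict rate under the no-gradient null is below 1%). Making
the plateau higher would require deliberately conservative circular tests,
which would break their calibration. Power is monotone nondecreasing in
the drift bias, which the suite also checks.

# Synthetic migration model

No published model accompanies the assay, so the generator is the
package's own: a biased persistent random walk chosen for having exactly
two interpretable knobs beyond speed.

At each step the new heading is the angle of the resultant

w_prev·u(θ_prev) + w_grad·g + w_noise·u(η),  η ~ Uniform(−π, π],

with w_prev = `persistence` ∈ [0,1), w_grad = `drift_bias` ∈ [0,1],
w_noise = max(0, 1 − persistence − drift_bias), and g the unit gradient
axis. Limiting cases behave correctly: drift_bias = 1 with persistence = 0
gives a straight march up-gradient (directness exactly 1); both zero gives
an isotropic walk, whose cohort FMIs are zero in expectation (checked
within 3 standard errors at n = 500). Step lengths are zero-truncated
Gaussian speeds times the frame interval — the simplest distribution with
independent mean/SD knobs; a lognormal would add a shape assumption the
data cannot inform.

Defaults emulate the acquisition geometry of the assay: 49 frames at
30-minute cadence (24 h), starts scattered over a 500 µm field. Per-step
speeds are not published for this assay, so the defaults
(mean 0.8 µm/min, SD 0.4 µm/min, persistence 0.4) are realistic values for
adherent prostate-cancer epithelial cells, documented here as arbitrary
choices — they are *not* calibrated to any figure, and none of the
package's correctness claims depend on them.

Seeding: one master seed yields per-cell sub-seeds drawn sequentially, so
growing `n_cells` extends a cohort without reshuffling earlier cells, and
every generator is a pure function of its config (bitwise-reproducible).
The per-cell draw order (start, initial heading, speeds, noise angles) is
documented in `?simulate_trajectories` and pinned by a test against an
independent re-implementation.

What the generator does *not* emulate: cell–cell interactions, division or
death events (exclusion flags exist but are set by users, not simulated),
spatially varying gradients inside the chamber, or measurement noise of
the tracking itself. Passing tests therefore demonstrate correctness of
the estimators under a clean movement model, not robustness to real-world
tracking artefacts.

# Bead MSD and MTC stiffness

Bead tracks emulate spontaneous nanoscale displacements of RGD-coated
microbeads: 2D positions in nm at 12 frames/s for ~300 s, ~100 beads. For
`anomalous_exponent` α = 1 increments are iid Gaussian with per-coordinate
variance 2DΔt, so ensemble MSD(t) = 4Dt. For α ≠ 1 the track is exact
fractional Brownian motion (stationary increments, MSD = 4Dt^α), generated
by Cholesky factorisation of the fractional-Gaussian-noise covariance;
this costs O(frames²)–O(frames³), so long anomalous recordings should be
simulated at reduced duration (the suite uses tens of seconds).

`compute_msd` uses time-*and*-ensemble averaging over all overlapping
start times: the assay description does not fix the estimator, and
overlapping averaging maximises pair counts; for stationary-increment
processes (both generator regimes) it is unbiased. It is verified against
a naive triple-loop oracle to 1e-9, and the lag-zero point is included as
0 by convention. `fit_diffusion` reports slope/4 of the OLS line (with
intercept, which absorbs localisation-noise offsets in real data) and the
log–log slope for the anomalous exponent. With 1000 Brownian beads at
12 fps × 30 s the recovered D is within 10% of truth (R² > 0.99).

MTC stiffness is the ratio of specific-torque amplitude to bead
displacement amplitude (Pa/nm) under sinusoidal twisting. Amplitudes at
the driving frequency are extracted by least-squares regression on
sin(ωt), cos(ωt) and an offset — equivalent to the Fourier coefficient at
ω, phase-invariant by construction, and requiring at least two full
periods. Displacement amplitudes at or below a declared noise floor raise
an unmeasurable-stiffness error rather than returning an unbounded ratio.
No numeric moduli are published for this assay, so validation is
parameter recovery only (2% at 50 noisy periods).

# AFM Hertz fitting

For a conical tip, F = [2·E·tan(α) / (π(1 − ν²))]·δ², with α the tip
half-angle (35° default, stored in degrees and converted at the boundary)
and ν the Poisson ratio (0.5 for soft incompressible material; ν = 1 is a
degenerate-parameter error). Given δ², the model is linear in E, so the
least-squares optimum is closed form — identical to the nonlinear-fit
optimum, with no iteration or starting values. Negative estimates
(possible only under extreme noise) are clamped to zero with a warning.
An optional `max_indentation` cap restricts the fit to the force-setpoint
region of the instrument. Noiseless recovery is exact to 1e-9; with 5%
force noise the estimator is unbiased within 2% over 1000 replicates; the
fit is scale-equivariant (F → cF gives cÊ; δ → cδ gives Ê/c²).

Raw approach curves carry an unknown contact point. `estimate_contact_point`
fits a piecewise model — flat baseline before contact, Hertz parabola
after — by scanning every candidate sample and refining continuously
around the best one. Contact is declared only when the piecewise fit beats
an all-flat fit by an F-ratio of at least 20 (with 2 extra parameters);
below that, the curve is flagged "no detectable contact" and excluded,
which is the correct outcome for pure-noise curves. On synthetic curves a
50 nm offset is recovered within 5 nm at 2.5 nm sampling.

# Expression arithmetic

* **ΔΔCt**: ΔCt = Ct_target − Ct_housekeeping per condition,
  ΔΔCt = ΔCt_treated − ΔCt_control, fold = 2^(−ΔΔCt). Replicates missing
  any of the four Ct values are excluded with a warning. The summary fold
  is the geometric mean over replicates (means on the log2 scale), which
  is the unbiased scale for cycle-threshold noise; the arithmetic mean is
  also reported. The calculation is invariant to adding a constant to all
  four Ct values.
* **NanoString**: each sample is scaled by mean(positive-control totals) /
  (its positive-control total). The undetected rule (< 40 reads; exactly
  40 is kept) is applied to *raw* counts before scaling — the published
  order is ambiguous, but the rule speaks of transcript reads, which are
  raw. Samples with zero positive-control totals are excluded with an
  error record. Within-sample ratios of retained genes are preserved.
* **IntDen / MFI**: sum and mean of a cell's pixel intensities;
  MFI × pixel count ≡ IntDen. Exposure time is carried as metadata only —
  no cross-exposure rescaling is attempted, since intensities acquired at
  different exposures are not directly comparable.
* **Positivity**: 100·n⁺/n, reported exactly and rounded to integer
  percent as figure legends print it. Calling a cell positive is an input
  decision (scored upstream), not something inferred from intensities.
* **Anoikis / densitometry ratios**: simple guarded ratios with optional
  background subtraction and reference-lane normalisation.

# Pipeline, formats, reproducibility

`read_trajectories` consumes CSV/TSV tracking exports under a declared
`trajectory_dialect` (column mapping, pixel size, frame interval, y-axis
convention, gradient axis); malformed rows are dropped with line-numbered
warnings, non-monotone frames are data errors. `run_pipeline` chains
exclusions → metrics → spider coordinates → chemotaxis over the three
arms from a list or YAML config, writing per-cell CSVs, a JSON chemotaxis
report, and a run log with seeds, versions, and excluded-cell counts. All
randomness flows from config seeds; a rerun is byte-identical. Output
tables declare units in their headers. The package's functions (rather
than a shell executable) are the intended interface; `run_pipeline` is the
single entry point scripts should call.

# Problem sizes used by the checks

The shipped checks run at deliberately chosen desk scales: 1000
trajectories for the metric identities; 10,000 null replicates at n = 50
for Rayleigh calibration and 5000 for the vector variant (500 Monte-Carlo
draws per p-value); 200 three-arm replicates at 60 cells/arm for the
decision rule; 1000 beads × 30 s for diffusion recovery; 500–1000 noisy
force curves for Hertz bias. These sizes make Monte-Carlo error small
relative to every asserted tolerance while keeping a full run in about a
minute.

# Known limitations

* The migration generator's speed scale is arbitrary (nothing published
  to calibrate against); conclusions transfer only through the
  scale-invariant quantities (directness, FMI, angles).
* The vector-data Rayleigh variant is one defensible choice among several;
  p-values from other implementations of "Rayleigh test with vector data"
  need not match numerically.
* The chemotaxis decision rule's conjunction of null requirements caps its
  all-criteria pass rate near 0.84–0.87 (see above); users comparing
  cohorts should inspect the per-criterion trace, not only the boolean.
* MSD assumes a common, uniform time base across beads; tracks with
  dropped frames must be regularised upstream.
* Contact-point estimation assumes a single flat-then-Hertz transition;
  curves with adhesion dips or multiple contacts are out of scope (they
  will usually be flagged rather than mis-fit, but this is not
  guaranteed).
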