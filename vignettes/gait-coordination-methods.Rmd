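---
title: "Quantifying interlimb coordination: models, indices and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interlimb coordination: models, indices and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
library(dplyr)
```

# The measurement problem

Overground locomotion in a quadruped is scored from two kinds of raw data:
footfall event tables (one row per paw contact, with contact and lift-off
times, paw coordinates and a plantar/dorsal flag) and two-dimensional
joint-marker trajectories from sagittal cameras. From these, gaitphase
derives the quantities used to characterise interlimb coordination and its
disruption — by synaptic silencing of long propriospinal pathways, by spinal
cord injury, or by any comparable manipulation — together with the
statistics used to compare conditions.

# Interlimb phase and the irregularity criterion

For a limb pair, the **phase** of a step is the fraction of the leading
limb's stride at which the trailing limb makes initial contact:

$$\varphi = \frac{t^{*} - t_i}{t_{i+1} - t_i}, \qquad t_i \le t^{*} < t_{i+1},$$

where $t_i, t_{i+1}$ are consecutive initial contacts of the lead limb and
$t^{*}$ the first trailing-limb contact inside that stride.
$\varphi = 0.5$ is alternation; $\varphi = 0$ (equivalently 1) is synchrony.
The left hindlimb leads every pair that involves a hindlimb; the left
forelimb leads the forelimb pair. One phase is produced per lead stride, the
first trailing contact winning if several fall inside the stride — this
matches one-point-per-step phase plotting and makes the estimator
well-defined without a tie rule.

Circular phases are plotted linearly after reduction mod 1
(`transform_phase()`), a bijection of $[0,1)$ that leaves alternation at 0.5
and puts synchrony at the two ends. No richer transformation is applied: the
identity-mod-1 reading is documented and testable, and every downstream
statistic that genuinely needs circularity (means, dispersions, two-sample
comparison) is computed on the circle, not the line.

**Irregular steps.** Control timepoints define, per limb pair, a center and
spread (`control_bounds()`). A step is *irregular* when its wrap-aware
distance to the center, $\min(|\Delta|, 1 - |\Delta|)$, exceeds twice the
control SD (`classify_irregular()`): the shaded "outside normal
variability" band of linear phase plots. Two estimators of the spread are
provided:

* `linear` (default): arithmetic mean and SD of the transformed phases.
  This matches the linear plots and the "mean ± 2 SD" language used with
  them, and behaves well for alternating pairs whose phases cluster near
  0.5.
* `circular`: circular mean direction and circular SD
  $\sqrt{-2\ln R}/2\pi$ cycles. This is the right choice for pairs whose
  phases cluster at the 0/1 seam (synchronous pairs such as the
  heterolateral hindlimb–forelimb pair): the linear mean of values near 0
  *and* near 1 lands meaninglessly in the middle and inflates the SD until
  nothing is ever classed irregular. The distance test itself is always
  wrap-aware, so the circular method makes classification fully seam-proof.

Control bounds are computed per pair from the control timepoints named in
the run configuration, pooled across those timepoints, and never pooled
across pairs. Per-timepoint (unpooled) bounds can be obtained by naming a
single control timepoint.

Counts of irregular steps per timepoint feed a **two-proportion z test**
(below), reproducing the per-step proportion comparisons printed alongside
phase plots.

# Spatiotemporal gait indices

A stride runs from one initial contact of a limb to its next; stance is
contact to lift-off, swing the remainder, duty cycle stance over stride,
speed the stride displacement over stride time (`build_step_cycles()`).
Stride distance is the Euclidean XY displacement. Cycles inherit the
plantar/dorsal flag of their initiating contact; dorsal cycles are retained
and flagged, never silently dropped, since post-injury analyses include
them.

Two regression families describe the speed dependence of these indices
(`fit_speed_relationship()`):

* exponential decay $y = a e^{-b v} + c$ for stance and stride time. The
  floor $c$ is retained because stance time does not approach zero at high
  speed; the fit uses multi-start Levenberg–Marquardt with decay-rate starts
  $\{0.005, 0.02, 0.08\}$ rescaled to the observed speed range, keeping the
  three-parameter fit reliable without hand-tuned initial values;
* straight lines for stride distance and stride frequency, with per-point
  95% prediction-interval half-widths from the standard formula.

$R^2 = 1 - SS_{res}/SS_{tot}$ in both families, and each family recovers
its own noiseless data with $R^2 = 1$ (a property the test suite asserts).
Speed is per-stride instantaneous speed averaged over a pass, hindlimb
cycles by default (switchable), since the underlying convention in the
source material is not fully specified.

# Intralimb coordination

The hindlimb is reduced to a three-segment, two-angle chain: the proximal
angle at the hip (iliac crest–hip–ankle) and the distal angle at the ankle
(hip–ankle–toe), computed per frame as planar vertex angles and averaged
*as angles* across cameras — matching the "2D average angles" convention
and making the result invariant to per-camera rigid motions.

Within each step cycle the windowed global extrema give peak extension and
flexion, ties resolved to the earliest frame; excursion is max − min.
Derivative-based peak detection was rejected deliberately: at the frame
rates and noise levels typical of marker digitisation, windowed extrema are
robust and correspond directly to the "maximum and minimum angles"
definition.

The **intralimb phase** relates the peak timing of the two angles. The lead
angle is whichever peaks first in the cycle; with $t_\ell$ its peak,
$t_{\ell}'$ its peak in the next cycle and $t_s$ the other angle's peak,
$\psi = (t_s - t_\ell)/(t_{\ell}' - t_\ell)$. "Onset of the second angle"
is read as the second angle's *peak* time: the procedure that determines
the first angle's maximum and then locates the second angle within the
peak-to-peak window only has the second peak available as a well-defined
event; a trough-based alternative is exposed by computing on negated
angles. Because 0 and 1 both mean in-phase, $\psi$ is folded onto
$[0.5, 1]$ ($\psi' = \psi$ if $\psi \ge 0.5$, else $1 - \psi$), making the
in-phase neighbourhood — raw values running 0.9 through 1.0 to 0.1 —
contiguous, with 1 = in-phase and 0.5 = anti-phase. The fold is idempotent.

# Gross coordination indices

With placements ordered in time within a pass (`index_report()`):

* **RI** (regularity index): % of *plantar* placements participating in a
  normal four-limb step-sequence pattern;
* **CPI** (coordinated pattern index): the same over *all* cycles, dorsal
  included — coordination credit independent of plantar ability;
* **PSI**: hindlimb plantar steps as % of forelimb plantar steps (uncapped:
  the definition does not bound it above 100);
* **DSI**: dorsal hindlimb steps as % of all hindlimb steps — zero in
  uninjured animals — and its left/right **sidedness** split, which sums to
  100 whenever dorsal steps exist.

The "normal" pattern set is stated in the literature to contain four
orders without being enumerated; the default here is the two alternate and
two cruciate sequences familiar from footprint/CatWalk analysis, with the
rotary pair available (`normal_step_patterns(include_rotary = TRUE)`) and
the whole set swappable. Matching is greedy, left-to-right,
non-overlapping, earliest start first — the simplest deterministic rule,
and the one that gives RI = 100 on perfectly patterned passes. CPI uses the
same pattern set as RI; nothing in the definitions suggests otherwise.

BBB scores and ladder foot-slip counts are *inputs* (the rubric itself is
out of scope). `bbb_beyond_control()` counts test scores strictly above the
control maximum by default (the shaded-region rule for raw-score plots),
with a mean + 2 SD alternative; `ladder_summary()` keeps left and right
hindlimbs separate by design, so per-limb recovery remains visible.

# Postural stability

Three paw-placement geometry metrics (`posture_metrics()`): **gait angle**,
**diagonal length** (left hindlimb to right forelimb, consistent with the
left-hindlimb lead convention) and **rear track width**
$|y_{LH} - y_{RH}|$.

The gait-angle construction in the source material names the Pythagorean
theorem but leaves the vertex ambiguous. The default here is
$\theta = \arctan(|\Delta y| / |\Delta x|)$ between the progression axis
and the line from a reference hindlimb contact to the intervening
contralateral contact — the only reading whose magnitude (~30–35° given
~10–12 cm strides and ~4.5 cm track widths) matches the printed group
means. A three-point vertex-angle alternative ships behind
`definition = "vertex"`.

# The statistical layer

**Two-proportion z.** For counts $x_1/n_1$ and $x_2/n_2$,
$z = (\hat p_2 - \hat p_1)/SE$ with either the pooled
($\hat p\hat q(1/n_1 + 1/n_2)$, $\hat p$ the combined proportion) or the
unpooled ($\hat p_1\hat q_1/n_1 + \hat p_2\hat q_2/n_2$) variance, two-tailed
normal p. Both variants are first-class because the published per-step
comparisons this package validates against are internally inconsistent:
recomputing every printed z from its printed counts shows most pre-injury
overground and swim captions reproducing at two decimals under the
*unpooled* formula while the post-injury and BBB captions (and the Sylgard
hindlimb comparisons) reproduce under the *pooled* formula — and six
printed values reproduce under neither, so they are excluded from the
validation table (`ldpn_count_table()`). The default is the classical
pooled variant; the variant used is always recorded in the output. No
continuity correction is applied by default, because the printed values
reproduce without one; a flag provides it.

**Circular descriptives.** `circular_summary()` gives the mean direction,
resultant length $R$ and circular SD $\sqrt{-2 \ln R}/2\pi$ cycles, with an
explicit `mean_defined` flag when $R = 0$ rather than an arbitrary answer.

**Watson's two-sample $U^2$** tests whether two circular samples share a
common distribution of directions:

$$U^2 = \frac{n_1 n_2}{N^2}\left[\sum_k d_k^2 - \frac{(\sum_k d_k)^2}{N}\right],
\qquad d_k = \frac{i_k}{n_1} - \frac{j_k}{n_2},$$

over the $N = n_1 + n_2$ pooled ordered points. Cross-sample ties are
handled by replacing each $d$ within a tie group by the group mean — a
deterministic rule that makes the statistic symmetric in the samples,
invariant to the within-tie ordering, and exactly zero for identical
multisets. Significance is judged against the asymptotic 5% critical value
0.1869, and `u2_null_quantile()` can recalibrate that constant by
Monte-Carlo simulation under a common-uniform null (5,000 replicates at
$n_1 = n_2 = 100$ lands within ±0.01 of it). The implementation is checked
against a brute-force counting oracle on hundreds of random small
instances.

Paired t-tests and mixed-model/repeated-measures ANOVA that accompany the
indices in group-level reporting are deliberately left to standard
routines (`t.test()`, `lme4`/`lmerTest`); they are not re-derived here.

# The synthetic gait generator

Because no deposited recordings exist at desk scale, the generator
(`simulate_pass()`, `simulate_cohort()`) produces footfall streams with the
statistical structure the analysis assumes, plus a latent ground-truth
ledger for parameter-recovery testing.

* **Phase model.** Trailing-limb contacts are placed at a drawn phase of
  the lead stride: a von Mises draw (mean 0.5 cycles for the left–right and
  homolateral pairs, 0.0 for the heterolateral pair, per the
  synchronous/alternate coupling geometry of quadrupedal walking) mixed
  with a uniform "irregular" component of weight $p_{unif}$. This is the
  simplest two-knob model that reproduces both tight control clustering and
  condition-dependent spread; the defaults ($\kappa = 50$ control vs
  $\kappa = 2$ silenced, $p_{unif} = 0.02$ vs $0.10$) are testing
  conditions chosen to mirror the qualitative control/silenced contrast,
  not estimates of real animals — per-step phase variance is not reported
  beyond figure scatter, so no such estimate exists to copy.
* **Construction guarantees recovery.** Because trailing contacts are built
  from the lead stride and the drawn phase, the analysis-side phase formula
  recovers the latent value *exactly* in the noiseless case; the test suite
  asserts agreement to machine precision.
* **Spatiotemporal structure.** Per-step speeds are Gaussian
  (67 ± 19 cm/s, the scale of overground passes in this preparation);
  stance follows $a e^{-bv} + c$ with $a = 0.3$ s, $b = 0.02$ per cm/s,
  $c = 0.05$ s, giving stance times of 0.12–0.19 s over the speed range,
  and swing is 0.094 ± 0.008 s — group-mean scales for this preparation.
  X advances by speed × stride; Y sits at ± track width/2 (4.55 ± 0.45 cm)
  plus placement noise; dorsal flags are Bernoulli per hindlimb step.
* **Kinematics.** Marker chains realise cosine angle waveforms periodic
  with the step cycle: configured excursions (45° proximal, 90° distal,
  matching reported group averages), distal peak lagging the proximal by
  0.12 cycles (folded intralimb phase 0.88, the in-phase regime), two
  cameras with independent noise on the second.
* **Seeding.** One global seed, hashed per (animal, pass, condition), so
  adding animals or passes never perturbs other units' draws, and equal
  seeds give byte-identical fixture files (checksums in the
  `write_fixtures()` manifest).
* **Swim-style data** reuse the same phase machinery with no dorsal flags
  and no meaningful coordinates; hindlimb-only phase analysis runs
  unchanged on them.

What the generator does *not* emulate: forward dynamics, measurement jitter
on contact times, missed or mislabelled contacts, within-pass speed drift,
or any lesion model. Passing recovery tests therefore demonstrates the
correctness of the estimators on data satisfying the model's assumptions,
not robustness to the full messiness of video-scored recordings.

The forelimb pair is generated *emergently* (the right forelimb through the
heterolateral draw, the left through the homolateral draw) rather than from
its own latent phase, mirroring the kinematic chain of real data; its
configured mean is used only for analysis defaults.

# Numerical choices and degenerate inputs

* Phases live in $[0,1)$ everywhere; all distances on the circle are
  wrap-aware.
* `circular_summary()` flags $R = 0$ instead of returning an arbitrary
  mean; `control_bounds()` with fewer than two values, zero-length strides,
  non-monotonic contacts, lift-off at or after the next contact, dorsal
  forelimb rows, and out-of-range BBB scores are all hard, named errors
  with row context.
* A limb with a single contact yields zero cycles, silently; the trailing
  incomplete cycle is dropped without disturbing earlier cycles.
* Plateaued extrema resolve to the earliest frame; cycle windows with fewer
  than three frames are errors.
* The pipeline's per-timepoint z test degrades to an `NA` row (not an
  abort) when both arms are at a boundary — e.g. zero irregular steps
  everywhere — since the comparison is then vacuous.
* The exponential fit refuses degenerate designs (all speeds equal) and
  reports non-convergence from every start as an error rather than
  returning a silent local optimum.

# Problem sizes

The shipped tests and the acceptance script use cohorts of 2–8 animals,
2–10 passes and 5–200 steps per pass: 10,000 lead strides for
parameter-recovery checks (circular mean within 3 SE, irregular fraction
within 3 Monte-Carlo SEs of the analytic von Mises tail mass, stance-decay
parameters within 1% on noiseless data), 5,000 replicates for the $U^2$
null calibration, and 512 steps for the two-condition separation property.
These sizes were chosen so every documented property is measurable with
comfortable statistical margins while the whole suite runs in about a
minute.

# Known limitations

* The irregularity criterion inherits the linear-SD convention of the
  source plots; for synchrony-centred pairs use the circular method (see
  above) or the bounds are conservative to the point of vacuity.
* RI/CPI depend on the pattern-set choice; the default set is a documented
  convention, not a ground truth, and is configurable for a reason.
* The gait-angle definition is a disambiguation of an under-specified
  construction; both readings are shipped.
* Watson's $U^2$ tie handling matters only for coarsely quantised phases;
  at video frame rates ties across samples are rare.
* The generator's independence assumptions (no serial correlation between
  successive phases within a pass) are a simplification; real gait shows
  step-to-step correlation that would narrow, not widen, confidence in the
  recovered means.
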