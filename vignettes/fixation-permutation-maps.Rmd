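---
title: "Fixation-density maps and cluster-corrected permutation contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation-density maps and cluster-corrected permutation contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixmapr)
```

## The problem

Where people fixate on a face is routinely read as a marker of which facial
information they use. That reading assumes fixation patterns are driven by
the stimulus and the task — but the pre-stimulus *start position* of the
eyes (left of, right of, above, below, or on the face) is a purely
visuomotor factor that can reshape the whole scanpath. Quantifying that
influence requires comparing two-dimensional fixation distributions between
conditions, with inference that respects the spatial structure of gaze data:
fixation densities are not normal at any pixel, and pixel-wise testing
invites a multiple-comparison problem that grows with raster resolution.

`fixmapr` implements the full analysis chain for such experiments:

1. **Face-anchored geometry.** Seven rectangular AOIs per face (left/right
   eye, bridge of nose, left/right half-nose, left/right half-mouth), in
   degrees of visual angle with y increasing downward. The lateral start
   positions are the circumcenters of the same-side eye / half-nose /
   half-mouth AOI centers; the upper (lower) start lies on the perpendicular
   bisector of the two eye (mouth) centers at a distance fixed to the mean
   of the two lateral circumradii; the center start is the half-nose
   midpoint. Faces are aligned to the across-face average AOI layout by
   translation only (the closed-form least-squares translation is the mean
   of the per-label center differences).
2. **Spatial density maps.** Each analysed fixation contributes an isotropic
   Gaussian with sd 0.3 degrees, evaluated at pixel centers; fixations carry
   equal weight (no duration weighting). Maps are averaged across trials
   within participant, then across participants, so unequal trial counts do
   not reweight participants.
3. **Permutation inference.** Condition contrasts are tested by a Monte
   Carlo permutation test that exchanges *fixation locations* — not pixels —
   and only within matching ordinal positions (fixation 1 with fixation 1,
   and so on) for each participant. Each permutation yields a resampled
   group difference map; pixel p-values place the observed map within that
   resampled distribution, separately for positively and negatively signed
   pixels.
4. **Cluster correction.** A subset of resampled maps get their own
   statistical maps; the maximum suprathreshold cluster size per map forms a
   null distribution, and observed clusters smaller than its upper
   `cluster_alpha` tail are eliminated. Because locations rather than
   pixels are exchanged, raster resolution does not inflate the effective
   number of tests, and the cluster null is recomputed for whatever grid is
   chosen.

## The permutation model in detail

Let $A$ and $B$ be the contrasted conditions. The null hypothesis is that,
for every ordinal position $k$, the distribution of fixation locations at
ordinal $k$ is the same in $A$ and $B$. Under this null the pooled
locations within each (participant × ordinal) stratum are exchangeable, so
a permutation reassigns them to conditions uniformly at random while
preserving each condition's count in the stratum. Non-location fields
(durations, trial structure) stay put.

With trial-mean and participant-mean averaging, the group difference map is
linear in the fixations: fixation $i$ of participant $s$ in condition $c$
contributes its kernel times $\pm 1 / (n_{\text{trials}}(s,c) \cdot
n_{\text{participants}})$. The implementation exploits this by evaluating
every fixation's truncated kernel once into a sparse basis matrix; each
permutation is then a signed reweighting and a single sparse
matrix-by-vector product, which is what makes hundreds of simulated
experiments with hundreds of iterations each tractable.

For a pixel with observed value $v \ge 0$ and $N$ resampled maps, $p =
(\#\{v^\* \ge v\} + 1)/(N + 1)$; negative pixels use the lower tail. The
add-one convention counts the observed map within its own reference
distribution, so $p \ge 1/(N+1)$ and each one-sided tail is valid (never
anticonservative) at any $N$; ties count toward the null. Note that
because the two signed tails are each thresholded at `pixel_alpha` with no
further two-sidedness adjustment, the *union* of signed suprathreshold
pixels can reach twice `pixel_alpha` per pixel under the null; family-wise
control of the final maps is unaffected because the cluster null applies
the identical rule to the resampled maps. The same rule is
applied to the resampled maps used for the cluster null: every map —
observed or resampled — is ranked within the full stack of $N + 1$ maps.
Under the null this makes the observed map exchangeable with the resampled
ones, which is exactly the property the max-cluster-size argument needs.
A `leave_self_out` flag switches to referencing each resampled map against
the other maps only, for comparison.

Both signed tails are thresholded at `pixel_alpha` each with no further
two-sidedness adjustment, and the cluster null records the maximum cluster
size over both signs, so family-wise control covers the signed map as a
whole.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sigma` | 0.3 deg | density-kernel sd per fixation |
| `cell` | 0.05 deg/px (0.1 for repeated calibration runs) | raster resolution |
| `pad` | 1 deg | grid margin beyond the image bounds |
| `n_iterations` | 10,400 | permutation iterations |
| `n_cluster_maps` | 2,600 | resampled maps given their own statistical map |
| `pixel_alpha` | 0.01 | uncorrected pixel threshold |
| `cluster_alpha` | 0.05 | cluster-size threshold |
| `connectivity` | 8 | pixel adjacency for clusters (4 available) |
| `k` | 5 | fixations analysed per trial |

The iteration defaults mirror the full-scale analysis the package is built
around; calibration and tests scale them down together (500 / 125), which
changes Monte Carlo precision but not validity — the add-one guarantee
holds at any iteration count.

## Numerical choices

* **Kernel truncation.** Kernels are cut at 4 sd for speed; a single
  fixation's map mass is then 1 to within about $6 \times 10^{-5}$, and the
  declared normalisation tolerance is $10^{-3}$. The default 1-degree grid
  padding keeps nearly all mass of fixations clamped to the image edge
  (one-sided tail beyond 1 degree at sd 0.3 is $4 \times 10^{-4}$).
* **Degeneracy.** The circumcenter solver rejects anchor triples whose
  triangle area is below $10^{-9}$ deg²; the vertical-start solver rejects
  target distances not exceeding half the anchor separation. The synthetic
  face generator resamples jittered faces that trip either gate.
* **Branch selection.** The perpendicular bisector yields two candidate
  vertical starts. The upper start takes the solution farther from the
  mouth midpoint, the lower the one farther from the eye midpoint. This
  feature-relative rule needs no orientation flag and reduces to
  "forehead side" / "chin side" for upright faces; it is this package's
  choice where convention does not settle the matter.
* **Ties and discreteness.** Suprathreshold masks are computed from
  per-pixel order statistics of the map stack (`v` strictly greater than
  the $(m+1)$-th largest value, with $m$ the largest count passing
  `pixel_alpha`), which reproduces the counting rule exactly, ties
  included. The cluster survival threshold is the nearest-rank
  $(1-\texttt{cluster\_alpha})$ quantile of the null maximum sizes, and
  clusters at least that large survive.
* **AOI assignment.** Rectangles are closed; points on shared edges go to
  the higher-priority label (eyes before nose before mouth, left to right).
* **Latency from fixation records.** If a fixation row spans stimulus onset
  (onset ≤ 0), the latency to the first saccade is that row's end.
  Otherwise — as in the synthetic reports, which contain only on-face
  fixations — it is the ordinal-1 onset minus a nominal 25 ms saccade
  flight time. Event-level saccade tables are not consumed.
* **Short trials.** Trials with fewer than `k` fixations are retained with
  the fixations they have (the relative-frequency denominator still counts
  `k` possible fixations per trial); `strict = TRUE` drops them instead.
* **d′.** Hit/false-alarm rates of 0 or 1 are replaced by $1/(2N)$ and
  $1 - 1/(2N)$ before the z-transform.

## The synthetic generator

`generator_config()` parameterises a simulated start-position experiment:
jittered copies of a canonical 10-degree-forehead face layout stand in for
photographs; the first fixation is Gaussian about the face center with a
`kappa` = 0.5 deg bias toward the start position; fixations 2 onward draw
from a landmark mixture over the seven AOI centers (weights favouring the
eye region), tilted away from the start side and shifted `delta` = 1.0 deg
toward the opposite side; first fixations are shorter (240 vs 330 ms) and
center-start first saccades slower (300 vs 180 ms); an equal-variance
signal-detection observer with criterion 0 produces old/new responses. The
study-scale defaults are 20 participants, 80 faces and 4 study trials per
orientation × start cell. Magnitudes the emulated design does not pin down
(`kappa`, `delta`, scatter, timing means) are declared once here and are
free parameters, not estimates.

What the generator does *not* emulate: saccade kinematics and undershoot,
blinks, calibration drift, pupil artifacts, inter-face appearance
variation beyond AOI jitter, or any coupling between gaze and recognition
success. Passing tests therefore certify the statistical machinery —
geometry, densities, exchangeability, error control, power — on data with
the assumed structure, not the ecological validity of any particular
human dataset.

`generate_null_dataset()` equalises every condition-specific term, so the
two condition labels are exchangeable by construction; it is the ground
truth for the error-rate calibration. `generate_effect_dataset()` plants a
known opposite-side shift on fixations 2–5 of one condition for power
analysis, with `planted_region()` giving the analytic location of the
planted difference.

## Calibration results and problem sizes

The repeated-run harness (`run_null_calibration()`, `run_power_analysis()`)
uses 20 participants, 8 trials per condition, 500 iterations, 125
cluster-null maps and a 0.1 deg/px grid — sizes chosen so a hundred
end-to-end simulated experiments complete in minutes while each run still
has realistic fixation counts (1,280 analysed fixations). The package's
tests assert, on these runs, that the family-wise rate of surviving
clusters under the null is compatible with the nominal 0.05, that each
signed tail's face-region pixel rate respects its add-one bound of
$5/501$ up to the Monte Carlo error of the 100-run mean (and that the
union stays above 0.003, i.e. the test is not vacuously conservative),
and that a planted 1.5-degree shift is recovered as a correctly-signed
surviving cluster in at least 90% of runs. The union of the two signed
tails sits near twice the per-tail level by construction (previous
section), which the calibration output makes visible by reporting the
tails separately. `scripts/acceptance.R` recomputes the two error rates
from scratch. On toy problems with eight exchangeable assignments the
Monte Carlo p-values are checked against exhaustive enumeration.

## Known limitations

* Alignment is translation-only by design; faces differing in scale or
  rotation are not normalised. A consequence worth knowing: when faces
  differ in shape, the fixations of one trial all inherit that face's
  residual (non-translational) layout deviation, so locations are mildly
  correlated *across* ordinal positions within a trial. The permutation
  scheme exchanges locations independently per ordinal stratum and
  therefore does not preserve that dependence; in simulations with
  0.15-degree AOI jitter this inflates the uncorrected per-tail pixel rate
  on the order of 10% (it does not break the cluster-level correction, which
  applies the identical rule to its null maps). The error-rate calibration
  therefore uses identical faces, making stratum locations exactly
  exchangeable — the null the pixel test is actually about — and analyses
  of heterogeneous faces should read uncorrected pixel maps with this
  caveat in mind.
* The cluster statistic is size in pixels; cluster-mass and
  random-field-theory alternatives are out of scope.
* The nearest-rank survival rule inherits the mild discreteness of a
  finite cluster-null sample (125 values at the calibration scale).
* Latencies derived from fixation reports are only as good as the
  flight-time convention above; with raw saccade events they should be
  recomputed upstream.
* Repeated-measures ANOVAs and t-tests on the emitted summaries are left
  to general statistics software; the package produces the per-cell tables
  those tests consume.
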