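# fixmapr

Spatial statistics for face-viewing eye-tracking experiments in which the
pre-stimulus **start position** of the eyes is manipulated relative to the
face. Fixation locations are widely read as markers of which facial
information observers use; `fixmapr` implements the analysis chain needed to
ask how much of a fixation pattern is instead produced by where the eyes
started — a non-stimulus, non-task visuomotor factor.

## What it computes

* **Face-anchored geometry** (degrees of visual angle, y downward): seven
  rectangular AOIs per face (left/right eye, nose bridge, half-noses,
  half-mouths); the five start positions derived from them — the lateral
  starts are circumcenters of the same-side eye/half-nose/half-mouth AOI
  centers, the upper/lower starts sit on the eye/mouth perpendicular
  bisectors at the mean lateral circumradius, the center start is the
  half-nose midpoint; translation-only least-squares alignment of every
  face to the average AOI layout.
* **Spatial fixation-density maps**: each of the first five fixations per
  trial contributes an isotropic Gaussian, σ = 0.3°, evaluated on a regular
  raster; trial-mean then participant-mean averaging; per-participant
  condition differences.
* **Monte Carlo permutation inference**: the null hypothesis is that the
  distribution of fixation locations of each *ordinal* fixation is the same
  across conditions, so locations are exchanged only within
  (participant × ordinal) strata. Pixel p-values use the add-one
  convention, `p = (#{resampled ≥ v} + 1) / (N + 1)` for positive pixels
  (lower tail for negative); because locations rather than pixels are
  permuted, raster resolution does not inflate the multiple-comparison
  burden.
* **Max-cluster-size FWER correction**: a subset of resampled maps receive
  their own statistical maps; the distribution of their largest
  suprathreshold cluster (p < 0.01, 8-connectivity) yields a nearest-rank
  95% survival threshold for the observed clusters.
* **A synthetic scanpath generator** reproducing the statistical structure
  such experiments report — first fixations near the face center with a
  slight toward-start bias, fixations 2–5 biased to the opposite side,
  shorter first fixations, slower first saccades from a central start, and
  an equal-variance signal-detection old/new observer — so every stage is
  verifiable end to end without human data.

## Worked example

The `analysis/` scripts run the whole study pipeline on a simulated
experiment (20 participants, 80 faces, 2 orientations × 5 starts × 2
phases). `Rscript analysis/01_simulate.R` writes the raw artifacts, then
`Rscript analysis/02_preprocess.R` prints:

```
dropped 986 fixations beyond the fifth; 606 trials had < 5
latency to first saccade: center 298 ms vs peripheral 182 ms
fixation duration: ordinal 1 240 ms vs ordinals 2-5 329 ms
mean d-prime 1.07 (true generator value 1.00)
```

— the center start delays the first saccade by ~120 ms and the first
fixation is ~90 ms shorter than later ones, the two timing signatures the
pipeline is built to summarise. `Rscript analysis/03_density_maps.R` builds
the aligned density maps (eyes sit near y = −2°, y increases downward):

```
start left  :  400 fixations, density peak at (+3.23, -2.17) deg
start right :  400 fixations, density peak at (-2.27, -1.92) deg
start upper :  400 fixations, density peak at (-1.22, -0.82) deg
start lower :  400 fixations, density peak at (-1.17, -2.57) deg
```

Each start's density peaks on the **opposite** side of the face.
`analysis/04_contrasts.R` then runs the permutation contrasts (fixations
2–5, 500 iterations, 125 cluster-null maps):

```
right_vs_left                 3 cluster(s), 2 surviving (threshold 155 px)
    negative cluster, 2752 px, centered at x = +3.06 deg
    positive cluster, 2611 px, centered at x = -2.88 deg
upright_vs_inverted           7 cluster(s), 0 surviving (threshold 121 px)
```

The right-start advantage (positive) survives on the *left* half of the
face and vice versa — the opposite-side effect — while the
upright-vs-inverted contrast, a true null for this generator once the
inverted maps are flip-aligned, correctly yields no surviving clusters.
`analysis/05_calibration.R` estimates the machinery's error rates on null
and planted-effect data, and `analysis/06_averaging_artifact.R` shows why
averaging across opposed starts regresses fixation locations to a
face-center point where almost no fixation actually lands.

In code, a minimal contrast on your own data looks like:

```r
library(fixmapr)
fx    <- read_fixation_report("fixation_report.tsv")
faces <- read_aoi_file("aois.tsv")
fx <- select_first_k(fx, k = 5)
fx <- drop_first_and_center(fx)           # fixations 2-5, peripheral starts
fx <- clamp_to_image(fx, faces[[1]])
fx <- align_fixations(fx, faces)
res <- run_contrast(fx,
                    grid = default_grid(faces[[1]], cell = 0.05),
                    spec = permutation_spec(seed = 1),
                    condition_col = "start_position",
                    levels = c("right", "left"))
res$clusters                               # sizes, signs, survival
```

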