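# Calibration and power harness: repeated end-to-end runs of the
# permutation + cluster-correction pipeline on synthetic null or
# planted-effect data, summarising family-wise and pixel-level error rates.

#' Configuration for a calibration-scale experiment
#'
#' Desk-scale settings for repeated end-to-end runs: 20 participants, 8
#' trials per contrasted condition, 500 permutation iterations with 125
#' cluster-null maps, and a 0.1 deg/px grid.
#'
#' @param n_participants,trials_per_cell synthetic-experiment size.
#' @param n_iterations,n_cluster_maps permutation settings.
#' @param cell grid resolution in deg/px.
#' @param pixel_alpha,cluster_alpha significance thresholds.
#' @return list with `config_args`, `spec_args`, `cell`.
#' @export
calibration_settings <- function(n_participants = 20, trials_per_cell = 8,
                                 n_iterations = 500, n_cluster_maps = 125,
                                 cell = 0.1,
                                 pixel_alpha = 0.01, cluster_alpha = 0.05) {
  # jitter_sd = 0: the error-rate calibration must satisfy the test's own
  # exchangeability unit (fixation locations within participant x ordinal).
  # With per-face shape jitter, fixations of one trial share the face's
  # residual non-translational jitter, which correlates locations across
  # ordinal strata and mildly inflates the uncorrected pixel rate (see the
  # methods vignette); identical faces make stratum locations exactly
  # exchangeable, which is the null the calibration is about.
  list(config_args = list(n_participants = n_participants,
                          trials_per_cell = trials_per_cell,
                          jitter_sd = 0),
       spec_args = list(n_iterations = n_iterations,
                        n_cluster_maps = n_cluster_maps,
                        pixel_alpha = pixel_alpha,
                        cluster_alpha = cluster_alpha),
       cell = cell)
}

# Shared plumbing: simulate (null or planted), preprocess (first five,
# drop first fixation, clamp, align), and run the contrast.
calibration_run <- function(seed, settings, delta = 0,
                            direction = c(-1, 0)) {
  cfg <- do.call(generator_config,
                 c(settings$config_args, list(seed = seed)))
  ds <- if (delta == 0) generate_null_dataset(cfg)
        else generate_effect_dataset(cfg, delta = delta,
                                     direction = direction)
  fx <- select_first_k(ds$fixations, k = 5)
  fx <- drop_first_and_center(fx, drop_first = TRUE, drop_center = FALSE)
  fx <- clamp_to_image(fx, canonical_face())
  fx <- align_fixations(fx, ds$faces)
  grid <- default_grid(canonical_face(), cell = settings$cell)
  spec <- do.call(permutation_spec,
                  c(settings$spec_args,
                    list(seed = derive_seed(seed, 99))))
  res <- run_contrast(fx, grid, spec)
  list(result = res, dataset = ds, grid = grid)
}

#' Repeated null runs: FWER and pixel-level type-I calibration
#'
#' For each seed, generates an exchangeable-null dataset (two conditions
#' with identical per-ordinal fixation distributions), runs the full
#' permutation + max-cluster-size pipeline, and records (i) whether any
#' cluster survived correction and (ii) the fraction of face-region pixels
#' declared significant at the uncorrected pixel threshold.
#'
#' @param n_runs number of independent seeded runs.
#' @param settings a [calibration_settings()].
#' @param seed master seed; run `r` uses a stream derived from it.
#' @param verbose print a progress line every 10 runs.
#' @return data.frame with one row per run: `seed`, `any_surviving`,
#'   `n_surviving`, `sig_fraction_face`, `max_true_cluster`.
#' @export
run_null_calibration <- function(n_runs = 100,
                                 settings = calibration_settings(),
                                 seed = 1L, verbose = FALSE) {
  face <- canonical_face()
  fr <- face_region(face)
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run <- calibration_run(derive_seed(seed, 7, r), settings)
    res <- run$result
    g <- grid_centers(run$grid)
    in_face <- outer(g$x >= fr[1] & g$x <= fr[3],
                     g$y >= fr[2] & g$y <= fr[4], `&`)
    sig <- res$pmap$p < res$spec$pixel_alpha
    out[[r]] <- data.frame(
      seed = derive_seed(seed, 7, r),
      any_surviving = any(res$clusters$survives),
      n_surviving = sum(res$clusters$survives),
      sig_fraction_face = mean(sig[in_face]),
      # the two signed tails separately: each is a valid one-sided test
      sig_fraction_face_pos = mean(sig[in_face] & res$pmap$sign[in_face] > 0),
      sig_fraction_face_neg = mean(sig[in_face] & res$pmap$sign[in_face] < 0),
      max_true_cluster = if (nrow(res$clusters)) max(res$clusters$size) else 0)
    if (verbose && r %% 10 == 0)
      message(sprintf("null calibration: %d/%d runs, FWER so far %.3f",
                      r, n_runs,
                      mean(vapply(out[seq_len(r)], `[[`, TRUE,
                                  "any_surviving"))))
  }
  do.call(rbind, out)
}

#' Expected planted-effect region
#'
#' The analytic mean difference map implied by the generator: the landmark
#' mixture shifted by `delta` along `direction` minus the unshifted mixture,
#' each landmark smoothed by the combined scatter + kernel sd.  The planted
#' region is where this expected difference exceeds `frac` of its maximum.
#'
#' @param config a [generator_config()].
#' @param delta,direction planted shift (deg) and unit direction.
#' @param grid a [grid_spec()].
#' @param sigma density-kernel sd (deg).
#' @param frac region threshold as a fraction of the peak difference.
#' @return logical matrix (`n_x` x `n_y`), `TRUE` inside the planted region.
#' @export
planted_region <- function(config, delta, direction, grid, sigma = 0.3,
                           frac = 0.5) {
  direction <- direction / sqrt(sum(direction^2))
  cen <- aoi_centers(canonical_face())
  s <- sqrt(config$scatter_sd^2 + sigma^2)
  g <- grid_centers(grid)
  acc <- matrix(0, grid$n_x, grid$n_y)
  for (l in seq_len(nrow(cen))) {
    w <- config$landmark_weights[[cen$label[l]]]
    shifted <- outer(stats::dnorm(g$x, cen$x[l] + delta * direction[1], s),
                     stats::dnorm(g$y, cen$y[l] + delta * direction[2], s))
    plain <- outer(stats::dnorm(g$x, cen$x[l], s),
                   stats::dnorm(g$y, cen$y[l], s))
    acc <- acc + w * (shifted - plain)
  }
  acc >= frac * max(acc)
}

#' Repeated planted-effect runs: power of the corrected maps
#'
#' For each seed, plants an opposite-side mean shift of `delta` degrees on
#' fixations 2-5 of one condition, runs the full pipeline, and records
#' whether a surviving cluster of the correct sign overlaps the planted
#' region.
#'
#' @param n_runs number of independent seeded runs.
#' @param delta planted shift in degrees (default 1.5).
#' @param direction unit direction of the planted shift.
#' @param settings a [calibration_settings()].
#' @param seed master seed.
#' @param verbose print progress.
#' @return data.frame per run: `seed`, `recovered` (surviving,
#'   correct-signed, overlapping cluster), `any_surviving`,
#'   `max_surviving_size`.
#' @export
run_power_analysis <- function(n_runs = 50, delta = 1.5,
                               direction = c(-1, 0),
                               settings = calibration_settings(),
                               seed = 1L, verbose = FALSE) {
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run <- calibration_run(derive_seed(seed, 11, r), settings,
                           delta = delta, direction = direction)
    res <- run$result
    cfg <- run$dataset$config
    region <- planted_region(cfg, delta, direction, run$grid)
    region_idx <- which(region)
    surv <- res$clusters[res$clusters$survives, , drop = FALSE]
    # planted shift moves condition A density toward `direction`, so the
    # recovering cluster must be positive (A > B) inside the region
    recovered <- FALSE
    for (ci in seq_len(nrow(surv))) {
      if (surv$sign[ci] == 1L &&
          length(intersect(surv$pixels[[ci]], region_idx)))
        recovered <- TRUE
    }
    out[[r]] <- data.frame(
      seed = derive_seed(seed, 11, r),
      recovered = recovered,
      any_surviving = nrow(surv) > 0,
      max_surviving_size = if (nrow(surv)) max(surv$size) else 0)
    if (verbose && r %% 10 == 0)
      message(sprintf("power: %d/%d runs, recovery so far %.2f",
                      r, n_runs,
                      mean(vapply(out[seq_len(r)], `[[`, TRUE, "recovered"))))
  }
  do.call(rbind, out)
}
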