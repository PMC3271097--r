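test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_participants = 3, trials_per_cell = 2,
                          n_faces = 6, seed = 77)
  d1 <- generate_null_dataset(cfg)
  d2 <- generate_null_dataset(cfg)
  expect_identical(d1$fixations, d2$fixations)
  expect_equal(lapply(d1$faces, aoi_centers), lapply(d2$faces, aoi_centers))
  b1 <- generate_behavior(cfg, n_trials = 40)
  b2 <- generate_behavior(cfg, n_trials = 40)
  expect_identical(b1, b2)
})

test_that("zero jitter reproduces the canonical face; faces average back to it", {
  cfg0 <- generator_config(n_faces = 3, jitter_sd = 0, seed = 1)
  for (f in generate_faces(cfg0))
    expect_equal(aoi_centers(f)[, c("x", "y")],
                 aoi_centers(canonical_face())[, c("x", "y")],
                 tolerance = 1e-12)
  # with 80 jittered faces the reference frame approaches the canonical
  # layout: each mean center has se jitter_sd / sqrt(2 * 80)
  cfg <- generator_config(n_faces = 80, jitter_sd = 0.15, seed = 4)
  rf <- reference_frame(generate_faces(cfg))
  canon <- aoi_centers(canonical_face())
  se <- 0.15 / sqrt(2 * 80)
  expect_true(all(abs(rf$x - canon$x) < 4 * se))
  expect_true(all(abs(rf$y - canon$y) < 4 * se))
})

test_that("trial model: unbiased when kappa = delta = 0, signed bias otherwise", {
  f <- canonical_face()
  cen <- aoi_centers(f)
  n <- 1200
  cfg0 <- generator_config(kappa = 0, delta = 0, weight_tilt = 0)
  cond_r <- list(orientation = "upright", start = "right", phase = "study")
  set.seed(42)
  first <- t(replicate(n, {
    tr <- generate_trial(cfg0, cond_r, f, n_fix = 2)
    c(tr$x[1], tr$y[1], tr$x[2], tr$y[2])
  }))
  ctr <- center_start(f)
  se1 <- cfg0$sigma1 / sqrt(n)
  expect_lt(abs(mean(first[, 1]) - ctr[["x"]]), 3 * se1)
  expect_lt(abs(mean(first[, 2]) - ctr[["y"]]), 3 * se1)
  # ordinal-2 mean equals the unshifted mixture mean
  mix_mean_x <- sum(cfg0$landmark_weights * cen$x)
  se2 <- sqrt(cfg0$scatter_sd^2 + sum(cfg0$landmark_weights *
                                        (cen$x - mix_mean_x)^2)) / sqrt(n)
  expect_lt(abs(mean(first[, 3]) - mix_mean_x), 3 * se2)

  # kappa > 0: first fixations for a right start sit right of a left start
  cfgk <- generator_config(kappa = 0.5, delta = 0, weight_tilt = 0)
  set.seed(43)
  x_r <- replicate(n, generate_trial(cfgk, cond_r, f, n_fix = 1)$x[1])
  cond_l <- list(orientation = "upright", start = "left", phase = "study")
  x_l <- replicate(n, generate_trial(cfgk, cond_l, f, n_fix = 1)$x[1])
  expect_gt(mean(x_r) - mean(x_l), 0)
  # delta > 0: later fixations flip to the side opposite the start
  cfgd <- generator_config(kappa = 0, delta = 1, weight_tilt = 0)
  set.seed(44)
  x2_r <- replicate(n, generate_trial(cfgd, cond_r, f, n_fix = 2)$x[2])
  x2_l <- replicate(n, generate_trial(cfgd, cond_l, f, n_fix = 2)$x[2])
  expect_lt(mean(x2_r) - mean(x2_l), 0)
})

test_that("null datasets have exchangeable conditions per ordinal", {
  n_seeds <- 40
  pvals <- c()
  for (s in seq_len(n_seeds)) {
    cfg <- generator_config(n_participants = 4, trials_per_cell = 6,
                            n_faces = 8, seed = 1000 + s)
    ds <- generate_null_dataset(cfg)
    fx <- ds$fixations[ds$fixations$ordinal <= 3, ]
    for (o in c(1, 3)) {
      a <- fx[fx$condition == "A" & fx$ordinal == o, ]
      b <- fx[fx$condition == "B" & fx$ordinal == o, ]
      pvals <- c(pvals,
                 suppressWarnings(ks.test(a$x, b$x)$p.value),
                 suppressWarnings(ks.test(a$y, b$y)$p.value))
    }
  }
  # 160 KS tests at alpha = 0.01 under a true null: expect ~1.6 failures
  expect_lt(mean(pvals < 0.01), 0.05)
})

test_that("planted effect reduces to the null at delta = 0 and shifts the mean by delta", {
  cfg <- generator_config(n_participants = 4, trials_per_cell = 4,
                          n_faces = 6, seed = 55)
  eff0 <- generate_effect_dataset(cfg, delta = 0)
  null <- generate_null_dataset(cfg)
  expect_identical(eff0$fixations, null$fixations)

  cfg2 <- generator_config(n_participants = 10, trials_per_cell = 20,
                           n_faces = 10, seed = 56)
  delta <- 1.5
  eff <- generate_effect_dataset(cfg2, delta = delta, direction = c(-1, 0))
  fx <- eff$fixations[eff$fixations$ordinal %in% 2:5, ]
  xa <- fx$x[fx$condition == "A"]
  xb <- fx$x[fx$condition == "B"]
  se <- sqrt(var(xa) / length(xa) + var(xb) / length(xb))
  expect_lt(abs((mean(xa) - mean(xb)) + delta), 3 * se)
})

test_that("trial structure: 1-10 fixations, consecutive ordinals, fewer at test", {
  cfg <- generator_config(n_participants = 2, trials_per_cell = 3,
                          n_faces = 4, seed = 8)
  ds <- generate_dataset(cfg)
  per_trial <- split(ds$fixations$ordinal, ds$fixations$trial_id)
  for (o in per_trial) {
    expect_true(length(o) >= 1 && length(o) <= 10)
    expect_identical(sort(o), seq_along(o))
  }
  n_fix <- tapply(ds$fixations$ordinal, ds$fixations$trial_id, length)
  phase <- tapply(ds$fixations$phase, ds$fixations$trial_id, `[`, 1)
  expect_true(all(n_fix[phase == "study"] >= cfg$min_fix_study))
  expect_true(all(n_fix[phase == "test"] >= cfg$min_fix_test))
  expect_lt(mean(n_fix[phase == "test"]), mean(n_fix[phase == "study"]))
})

test_that("signal-detection observer matches its closed form", {
  cfg0 <- generator_config(n_participants = 1, dprime_true = 0, seed = 31)
  b0 <- generate_behavior(cfg0, n_trials = 4000)
  hr <- mean(b0$response[b0$truth == "old"] == "old")
  far <- mean(b0$response[b0$truth == "new"] == "old")
  expect_lt(abs(hr - far), 4 * sqrt(0.25 / 2000 + 0.25 / 2000))
  cfg1 <- generator_config(n_participants = 1, dprime_true = 1, seed = 32)
  b1 <- generate_behavior(cfg1, n_trials = 10000)
  hr1 <- mean(b1$response[b1$truth == "old"] == "old")
  expect_lt(abs(hr1 - pnorm(0.5)), 4 * sqrt(pnorm(0.5) * pnorm(-0.5) / 5000))
})
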