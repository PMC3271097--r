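test_that("label permutation preserves stratum location pools and swaps uniformly", {
  fx <- toy_exchangeable_data()
  set.seed(5)
  pooled <- function(d) {
    key <- paste(d$participant_id, d$ordinal)
    lapply(split(paste(d$x, d$y), key), sort)
  }
  before <- pooled(fx)
  swaps <- 0
  n_draws <- 400
  for (i in seq_len(n_draws)) {
    perm <- permute_labels(fx)
    expect_identical(pooled(perm), before)
    # stratum (p2, 1) has one fixation per condition: did it swap?
    if (perm$x[5] == fx$x[6]) swaps <- swaps + 1
  }
  # each (1,1) stratum swaps with probability 1/2
  expect_lt(abs(swaps / n_draws - 0.5), 3 * sqrt(0.25 / n_draws))
})

test_that("pixel p-values follow the add-one two-tailed counting rule", {
  # true exceeds all 9 resampled values -> p = 1/10
  res <- matrix(1:9, nrow = 1)
  out <- pixel_pvalues(10, res)
  expect_equal(out$p, 0.1)
  expect_equal(out$sign, 1)
  # true at the median -> p ~ 0.5
  expect_equal(pixel_pvalues(5, res)$p, 6 / 10)
  # negative pixels use the lower tail
  expect_equal(pixel_pvalues(-10, -res)$p, 0.1)
  expect_error(pixel_pvalues(1, matrix(0, 1, 0)), "no resampled")
})

test_that("thresholding is monotone in alpha and respects signs", {
  pmap <- list(p = matrix(c(0.001, 0.5, 0.009, 1), 2, 2),
               sign = matrix(c(1, 1, -1, -1), 2, 2))
  m1 <- threshold_map(pmap, 0.01)
  expect_equal(as.vector(m1), c(1, 0, -1, 0))
  # at alpha = 1 every pixel with p < 1 passes (the threshold is strict)
  m_all <- threshold_map(pmap, 1)
  expect_true(all(m_all[pmap$p < 1] != 0))
  all1 <- list(p = matrix(1, 3, 3), sign = matrix(1, 3, 3))
  expect_true(all(threshold_map(all1, 0.01) == 0))
  m_small <- threshold_map(pmap, 0.005)
  expect_true(all(m_small[m1 == 0] == 0))
})

test_that("cluster labelling matches a flood-fill oracle at both connectivities", {
  # single pixel
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  cl <- label_clusters(m)
  expect_equal(cl$size, 1)
  # two diagonal pixels: one cluster under 8-connectivity, two under 4
  m2 <- matrix(0L, 5, 5); m2[2, 2] <- 1L; m2[3, 3] <- 1L
  expect_equal(nrow(label_clusters(m2, 8)), 1)
  expect_equal(nrow(label_clusters(m2, 4)), 2)
  set.seed(19)
  for (conn in c(8, 4)) {
    for (rep in 1:10) {
      m3 <- matrix(sample(c(-1L, 0L, 1L), 400, TRUE,
                          prob = c(0.15, 0.7, 0.15)), 20, 20)
      got <- label_clusters(m3, conn)
      oracle <- floodfill_clusters(m3, conn)
      expect_equal(nrow(got), length(oracle))
      got_sets <- lapply(got$pixels, sort)
      ora_sets <- lapply(oracle, `[[`, "pixels")
      expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                      vapply(ora_sets, paste, "", collapse = ","))
      # sign coherence inside every cluster
      for (i in seq_len(nrow(got)))
        expect_true(all(m3[got$pixels[[i]]] == got$sign[i]))
    }
  }
})

test_that("cluster correction applies the nearest-rank survival threshold", {
  cl <- data.frame(id = 1:3, sign = c(1L, -1L, 1L), size = c(25, 19, 18))
  cl$pixels <- I(list(1:25, 26:44, 45:62))
  out <- cluster_correct(cl, null_sizes = 1:20, cluster_alpha = 0.05)
  expect_equal(attr(out, "size_threshold"), 19)
  expect_equal(out$survives, c(TRUE, TRUE, FALSE))
  # a cluster larger than every null max always survives
  out2 <- cluster_correct(cl[1, ], null_sizes = rep(3, 100))
  expect_true(out2$survives)
})

test_that("run_contrast is deterministic and consistent with the direct p-value route", {
  fx <- toy_exchangeable_data()
  grid <- grid_spec(-2, -1.5, 0.5, 8, 6)
  spec <- permutation_spec(n_iterations = 400, n_cluster_maps = 50,
                           seed = 99)
  r1 <- run_contrast(fx, grid, spec)
  r2 <- run_contrast(fx, grid, spec)
  expect_identical(r1$pmap, r2$pmap)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)
  expect_identical(r1$clusters$size, r2$clusters$size)

  # dual route: the same permutations via the in-memory stream, p-values
  # via the exposed counting rule
  rdm <- resampled_difference_maps(fx, grid, n = 400, include_true = TRUE,
                                   seed = 99)
  v_true <- rdm$maps[, 1]
  expect_equal(as.vector(r1$true_map$values), v_true)
  pm <- pixel_pvalues(v_true, rdm$maps[, -1])
  expect_equal(as.vector(r1$pmap$p), pm$p)
  expect_identical(as.vector(threshold_map(list(p = pm$p, sign = pm$sign),
                                           spec$pixel_alpha)),
                   as.vector(r1$mask))
  # p-values never fall below the add-one floor
  expect_true(all(r1$pmap$p >= 1 / (spec$n_iterations + 1)))
})

test_that("self-contrasts of duplicated data produce a zero map and no clusters", {
  base <- toy_exchangeable_data()
  dup <- base[base$condition == "A", ]
  dup2 <- dup
  dup2$condition <- "B"
  dup2$trial_id <- paste0(dup2$trial_id, "x")
  fx <- rbind(dup, dup2)
  grid <- grid_spec(-2, -1.5, 0.5, 8, 6)
  res <- run_contrast(fx, grid,
                      permutation_spec(n_iterations = 200,
                                       n_cluster_maps = 40, seed = 3))
  expect_lt(max(abs(res$true_map$values)), 1e-12)
  expect_false(any(res$clusters$survives))
})

test_that("participants missing a condition are excluded with a warning", {
  fx <- toy_exchangeable_data()
  fx$condition[fx$participant_id == "p2"] <- "A"
  grid <- grid_spec(-2, -1.5, 0.5, 8, 6)
  expect_warning(
    res <- run_contrast(fx, grid,
                        permutation_spec(n_iterations = 50,
                                         n_cluster_maps = 10, seed = 1)),
    "missing a condition.*p2")
  expect_equal(res$n_participants, 1)
})

test_that("resampled maps of exchangeable data are centered on zero", {
  cfg <- generator_config(n_participants = 4, trials_per_cell = 4,
                          n_faces = 4, seed = 61)
  ds <- generate_null_dataset(cfg)
  fx <- drop_first_and_center(select_first_k(ds$fixations, 5), TRUE, FALSE)
  fx <- align_fixations(clamp_to_image(fx, canonical_face()), ds$faces)
  grid <- default_grid(canonical_face(), cell = 0.25)
  rdm <- resampled_difference_maps(fx, grid, n = 300, include_true = FALSE,
                                   seed = 12)
  mu <- rowMeans(rdm$maps)
  se <- apply(rdm$maps, 1, sd) / sqrt(300)
  active <- se > 0
  expect_gt(mean(abs(mu[active]) < 3 * se[active]), 0.98)
})
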