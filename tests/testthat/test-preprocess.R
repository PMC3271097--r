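make_report <- function() {
  cfg <- generator_config(n_participants = 2, trials_per_cell = 2,
                          n_faces = 4, seed = 17)
  generate_dataset(cfg)
}

test_that("fixation reports round-trip and validate their schema", {
  ds <- make_report()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_report(ds$fixations, path)
  back <- read_fixation_report(path)
  expect_equal(back[, names(ds$fixations)], ds$fixations,
               tolerance = 1e-12, ignore_attr = TRUE)

  # missing column -> schema error
  broken <- ds$fixations
  broken$ordinal <- NULL
  p2 <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(broken, p2, sep = "\t")
  expect_error(read_fixation_report(p2), "missing required columns.*ordinal")

  # empty file with header -> empty frame
  p3 <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(ds$fixations[0, ], p3, sep = "\t")
  expect_equal(nrow(read_fixation_report(p3)), 0)

  # unparseable numeric -> row dropped with line numbers
  txt <- readLines(path)
  txt[3] <- sub("^([^\t]*\t[^\t]*\t[^\t]*\t[^\t]*\t[^\t]*\t[^\t]*\t[^\t]*\t)[^\t]*",
                "\\1oops", txt[3])
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(txt, p4)
  expect_warning(out <- read_fixation_report(p4), "dropping 1 unparseable")
  expect_equal(nrow(out), nrow(ds$fixations) - 1)
})

test_that("first-k selection truncates, counts, and is idempotent", {
  ds <- make_report()
  fx <- ds$fixations
  k5 <- select_first_k(fx, 5)
  expect_true(all(k5$ordinal <= 5))
  n_per <- tapply(fx$ordinal, fx$trial_id, length)
  expect_equal(attr(k5, "n_removed"), sum(pmax(0, n_per - 5)))
  again <- select_first_k(k5, 5)
  expect_equal(again$ordinal, k5$ordinal)
  expect_equal(attr(again, "n_removed"), 0L)
  strict <- select_first_k(fx, 5, strict = TRUE)
  n_strict <- tapply(strict$ordinal, strict$trial_id, length)
  expect_true(all(n_strict == 5))
})

test_that("first-fixation and center-start filters remove exactly their rows", {
  ds <- make_report()
  fx <- ds$fixations
  expect_identical(drop_first_and_center(fx, FALSE, FALSE), fx)
  nf <- drop_first_and_center(fx, TRUE, FALSE)
  expect_true(all(nf$ordinal >= 2))
  expect_equal(nrow(fx) - nrow(nf), sum(fx$ordinal == 1))
  nc <- drop_first_and_center(fx, FALSE, TRUE)
  expect_equal(nrow(fx) - nrow(nc), sum(fx$start_position == "center"))
})

test_that("clamping projects to the nearest boundary point", {
  b <- c(0, 0, 10, 12)
  fx <- data.frame(x = c(-1, 5, 11, -2), y = c(5, 6, 13, -3))
  cl <- clamp_to_image(fx, b)
  expect_equal(cl$x, c(0, 5, 10, 0))
  expect_equal(cl$y, c(5, 6, 12, 0))
  expect_equal(attr(cl, "clamped_fraction"), 0.75)
  ctr <- c(5, 6)
  d0 <- sqrt((fx$x - ctr[1])^2 + (fx$y - ctr[2])^2)
  d1 <- sqrt((cl$x - ctr[1])^2 + (cl$y - ctr[2])^2)
  expect_true(all(d1 <= d0 + 1e-12))
})

test_that("AOI assignment matches a brute-force containment scan", {
  f <- canonical_face()
  expect_equal(assign_aoi(-2, -2, f), "left_eye")
  # shared edge between the nose halves: left_nose has priority
  expect_equal(assign_aoi(0, 0.2, f), "left_nose")
  set.seed(91)
  x <- runif(5000, -6, 6)
  y <- runif(5000, -7, 7)
  got <- assign_aoi(x, y, f)
  labels <- c("left_eye", "mid_eye", "right_eye", "left_nose",
              "right_nose", "left_mouth", "right_mouth")
  brute <- vapply(seq_along(x), function(i) {
    for (lab in labels) {
      a <- f$aois[[lab]]
      if (x[i] >= a$x_min && x[i] <= a$x_max &&
          y[i] >= a$y_min && y[i] <= a$y_max) return(lab)
    }
    "outside"
  }, character(1))
  expect_identical(got, brute)
})

test_that("relative frequencies use the trials-times-k denominator and sum to 1", {
  f <- canonical_face()
  fx <- data.frame(
    participant_id = "p1", trial_id = rep(c("t1", "t2"), each = 5),
    phase = "study", orientation = "upright", start_position = "left",
    face_id = "c", ordinal = rep(1:5, 2),
    x = 0, y = 0, onset_ms = 0, duration_ms = 100,
    stringsAsFactors = FALSE)
  # 3 fixations in the left eye, the rest elsewhere on the face
  fx$x <- c(-2, -2, -2, 0, 0, 0, 0, 0, 0, 0)
  fx$y <- c(-2, -2, -2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2)
  tab <- relative_frequencies(fx, faces = list(c = f))
  expect_equal(tab$rel_freq[tab$aoi == "left_eye"], 0.3)
  expect_equal(sum(tab$rel_freq), 1)
  # all-outside data: outside row carries everything
  fx2 <- fx
  fx2$x <- 5; fx2$y <- -6
  tab2 <- relative_frequencies(fx2, faces = list(c = f))
  expect_equal(tab2$rel_freq[tab2$aoi == "outside"], 1)
  expect_equal(sum(tab2$rel_freq[tab2$aoi != "outside"]), 0)
  # invariant to row order
  tab3 <- relative_frequencies(fx[sample(nrow(fx)), ], faces = list(c = f))
  expect_equal(tab3, tab)
})

test_that("latency uses the onset-spanning fixation else the flight-corrected onset", {
  # fixation spanning stimulus onset: latency is its end
  fx <- data.frame(trial_id = "t1", ordinal = 1:2, x = 0, y = 0,
                   onset_ms = c(0, 250), duration_ms = c(220, 300))
  expect_equal(latency_to_first_saccade(fx)$latency_ms, 220)
  # on-face records only: onset minus flight time; shift-invariant given
  # the spanning convention
  fx2 <- data.frame(trial_id = "t1", ordinal = 1:2, x = 0, y = 0,
                    onset_ms = c(205, 500), duration_ms = c(250, 300))
  expect_equal(latency_to_first_saccade(fx2, flight_ms = 25)$latency_ms, 180)
})

test_that("timing profiles recover the generator's latency and duration structure", {
  cfg <- generator_config(n_participants = 6, trials_per_cell = 6,
                          n_faces = 6, seed = 23)
  ds <- generate_dataset(cfg)
  prof <- duration_profile(select_first_k(ds$fixations, 5))
  lat <- prof$latency
  lat_c <- lat$latency_mean_ms[lat$start_position == "center"]
  lat_p <- lat$latency_mean_ms[lat$start_position != "center"]
  expect_gt(mean(lat_c), mean(lat_p))
  expect_lt(abs(mean(lat_c) - cfg$lat_mean_center), 4 * cfg$lat_sd /
              sqrt(length(lat_c) * cfg$trials_per_cell * 2))
  dur <- prof$durations
  d1 <- dur$duration_mean_ms[dur$ordinal == 1]
  d25 <- dur$duration_mean_ms[dur$ordinal %in% 2:5]
  expect_gt(mean(d25) - mean(d1),
            0.5 * (cfg$dur_mean_later - cfg$dur_mean_first))
  # constant durations pass through exactly
  fxc <- data.frame(participant_id = "p", trial_id = "t", phase = "study",
                    orientation = "upright", start_position = "left",
                    face_id = "f", ordinal = 1:3, x = 0, y = 0,
                    onset_ms = c(200, 500, 800), duration_ms = 275)
  expect_true(all(duration_profile(fxc)$durations$duration_mean_ms == 275))
})

test_that("d-prime matches its closed form and corrects extreme rates", {
  # hit rate pnorm(0.5), fa rate pnorm(-0.5) -> d' = 1 exactly
  expect_equal(dprime(6915, 3085, 3085, 6915), 1, tolerance = 1e-3)
  expect_equal(dprime(50, 50, 50, 50), 0)
  expect_error(dprime(0, 0, 5, 5), "zero trials")
  # perfect hits with N = 10: rate replaced by 1 - 1/20
  expect_equal(dprime(10, 0, 5, 5), qnorm(0.95) - qnorm(0.5))
})
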