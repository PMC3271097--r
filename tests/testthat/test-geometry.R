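test_that("circumcenter is equidistant, handles symmetry and degeneracy", {
  expect_equal(unname(circumcenter(c(0, 0), c(4, 0), c(0, 4))), c(2, 2))
  expect_error(circumcenter(c(0, 0), c(2, 0), c(4, 0), face_id = "f1"),
               "degenerate geometry.*f1")
  set.seed(11)
  n_ok <- 0
  while (n_ok < 25) {
    p <- matrix(runif(6, -5, 5), 3, 2)
    area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                  (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    if (area < 1e-6) next
    n_ok <- n_ok + 1
    cc <- circumcenter(p[1, ], p[2, ], p[3, ])
    d <- sqrt((cc[1] - p[, 1])^2 + (cc[2] - p[, 2])^2)
    expect_lt(max(d) - min(d), 1e-7 * max(d))
  }
})

test_that("start positions satisfy their defining equidistance constraints", {
  cfg <- generator_config(n_faces = 15, jitter_sd = 0.2, seed = 5)
  faces <- generate_faces(cfg)
  for (f in faces) {
    sp <- start_positions(f)
    ctr <- aoi_centers(f)
    pt <- function(l) unlist(ctr[ctr$label == l, c("x", "y")])
    at <- function(p) unlist(sp[sp$position == p, c("x", "y")])
    dist <- function(a, b) sqrt(sum((a - b)^2))
    for (side in c("left", "right")) {
      p <- at(side)
      d3 <- c(dist(p, pt(paste0(side, "_eye"))),
              dist(p, pt(paste0(side, "_nose"))),
              dist(p, pt(paste0(side, "_mouth"))))
      expect_lt(max(d3) - min(d3), 1e-9)
    }
    r_mean <- (dist(at("left"), pt("left_eye")) +
                 dist(at("right"), pt("right_eye"))) / 2
    expect_lt(abs(dist(at("upper"), pt("left_eye")) - r_mean), 1e-9)
    expect_lt(abs(dist(at("upper"), pt("right_eye")) - r_mean), 1e-9)
    expect_lt(abs(dist(at("lower"), pt("left_mouth")) - r_mean), 1e-9)
    expect_lt(abs(dist(at("lower"), pt("right_mouth")) - r_mean), 1e-9)
    expect_equal(at("center"),
                 (pt("left_nose") + pt("right_nose")) / 2,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("vertical start selects the feature-away branch and flags infeasible distances", {
  f <- canonical_face()
  # eyes at (+/-2, -2): upper start at distance 3 sits sqrt(5) above them
  up <- vertical_start(f, "upper", 3)
  expect_equal(unname(up), c(0, -2 - sqrt(5)), tolerance = 1e-12)
  lo <- vertical_start(f, "lower", 3)
  expect_equal(unname(lo), c(0, 2.6 + sqrt(9 - 1.1^2)), tolerance = 1e-12)
  expect_error(vertical_start(f, "upper", 2), "infeasible distance")
  # inversion moves the forehead below the eyes; the rule follows the face
  fi <- invert_geometry(f)
  up_i <- vertical_start(fi, "upper", 3)
  expect_gt(up_i[["y"]], aoi_center(fi$aois$left_eye)[["y"]])
})

test_that("mirror flip swaps left and right start positions exactly", {
  cfg <- generator_config(n_faces = 5, jitter_sd = 0.2, seed = 9)
  for (f in generate_faces(cfg)) {
    sp <- start_positions(f)
    spm <- start_positions(mirror_geometry(f, axis_x = 0))
    expect_equal(spm$x[spm$position == "left"],
                 -sp$x[sp$position == "right"], tolerance = 1e-9)
    expect_equal(spm$y[spm$position == "left"],
                 sp$y[sp$position == "right"], tolerance = 1e-9)
    expect_equal(spm$x[spm$position == "upper"],
                 -sp$x[sp$position == "upper"], tolerance = 1e-9)
  }
})

test_that("inversion preserves pairwise AOI distances and is an involution", {
  cfg <- generator_config(n_faces = 4, jitter_sd = 0.25, seed = 3)
  for (f in generate_faces(cfg)) {
    fi <- invert_geometry(f)
    expect_equal(fi$orientation, "inverted")
    d0 <- dist(as.matrix(aoi_centers(f)[, c("x", "y")]))
    d1 <- dist(as.matrix(aoi_centers(fi)[, c("x", "y")]))
    expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
    back <- invert_geometry(fi)
    expect_equal(aoi_centers(back), aoi_centers(f), tolerance = 1e-12)
    # AOI centered on the axis is fixed
    mid_y <- (f$image_bounds[2] + f$image_bounds[4]) / 2
    a <- aoi_rect("mid_eye", -1, mid_y - 0.5, 1, mid_y + 0.5)
    f2 <- f
    f2$aois$mid_eye <- a
    expect_equal(aoi_center(invert_geometry(f2)$aois$mid_eye),
                 aoi_center(a), tolerance = 1e-12)
  }
})

test_that("alignment translation is the closed-form SSD minimiser", {
  f <- canonical_face()
  ctr <- aoi_centers(f)
  expect_equal(alignment_translation(ctr, ctr), c(dx = 0, dy = 0))
  shifted <- ctr
  shifted$x <- shifted$x + 1
  shifted$y <- shifted$y - 2
  expect_equal(alignment_translation(shifted, ctr), c(dx = -1, dy = 2))
  bad <- ctr[7:1, ]
  expect_error(alignment_translation(bad, ctr), "label-mismatch")
  set.seed(21)
  for (i in 1:20) {
    fc <- ctr
    fc$x <- fc$x + rnorm(7, 0, 1)
    fc$y <- fc$y + rnorm(7, 0, 1)
    t_cf <- alignment_translation(fc, ctr)
    t_grid <- grid_translation(fc, ctr)
    expect_lt(max(abs(t_cf - t_grid)), 0.002)
  }
})

test_that("reference frame is the per-label mean of AOI centers", {
  f <- canonical_face()
  expect_equal(reference_frame(list(f)), aoi_centers(f))
  cfg <- generator_config(n_faces = 6, jitter_sd = 0.2, seed = 13)
  faces <- generate_faces(cfg)
  rf <- reference_frame(faces)
  brute_x <- rowMeans(sapply(faces, function(g) aoi_centers(g)$x))
  brute_y <- rowMeans(sapply(faces, function(g) aoi_centers(g)$y))
  expect_equal(rf$x, unname(brute_x))
  expect_equal(rf$y, unname(brute_y))
})

test_that("AOI files round-trip and start positions export", {
  cfg <- generator_config(n_faces = 3, seed = 2)
  faces <- generate_faces(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_aoi_file(faces, path)
  back <- read_aoi_file(path)
  expect_equal(names(back), names(faces))
  for (id in names(faces))
    expect_equal(aoi_centers(back[[id]]), aoi_centers(faces[[id]]),
                 tolerance = 1e-9)
  csv <- withr::local_tempfile(fileext = ".csv")
  tab <- write_start_positions(faces, csv)
  expect_equal(nrow(tab), 15)
  expect_true(file.exists(csv))
})
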