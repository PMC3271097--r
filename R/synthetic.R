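# Synthetic scanpath generator.
#
# Emulates the statistical structure of a start-position face-recognition
# experiment: five feature-anchored start positions, first fixations near the
# face center with a slight bias toward the start position, later fixations
# drawn from a landmark-anchored mixture pushed toward the opposite side of
# the face, shorter first fixations, longer first-saccade latencies for the
# center start, and an equal-variance signal-detection old/new observer.

#' Canonical face AOI layout
#'
#' A seven-AOI layout for a frontal face scaled to a 10 deg forehead width
#' (eye centers 4 deg apart, mouth 4.6 deg below the eyes), in degrees with
#' y increasing downward and the origin at the face center.  Used as the
#' template from which synthetic faces are jittered.
#'
#' @param face_id identifier for the constructed geometry.
#' @return a `face_geometry`.
#' @export
canonical_face <- function(face_id = "canonical") {
  aois <- list(
    aoi_rect("left_eye",   -3.2, -2.6, -0.8, -1.4),
    aoi_rect("mid_eye",    -0.8, -2.6,  0.8, -1.4),
    aoi_rect("right_eye",   0.8, -2.6,  3.2, -1.4),
    aoi_rect("left_nose",  -1.5, -0.8,  0.0,  1.2),
    aoi_rect("right_nose",  0.0, -0.8,  1.5,  1.2),
    aoi_rect("left_mouth", -2.2,  2.0,  0.0,  3.2),
    aoi_rect("right_mouth", 0.0,  2.0,  2.2,  3.2))
  face_geometry(face_id, aois, image_bounds = c(-5.5, -6.5, 5.5, 6.5),
                orientation = "upright")
}

#' Bounding box of the facial features
#'
#' The rectangle spanned by the seven AOI rectangles of a face; used as the
#' "face region" when summarising pixel-level error rates.
#'
#' @param geometry a `face_geometry`.
#' @return numeric `c(x_min, y_min, x_max, y_max)` in degrees.
#' @export
face_region <- function(geometry) {
  xs <- range(unlist(lapply(geometry$aois, function(a) c(a$x_min, a$x_max))))
  ys <- range(unlist(lapply(geometry$aois, function(a) c(a$y_min, a$y_max))))
  c(xs[1], ys[1], xs[2], ys[2])
}

#' Generator configuration
#'
#' Full parameterization of the synthetic experiment.  Defaults mirror the
#' study design being emulated: 20 participants, 2 (orientation) x 5 (start)
#' cells with 4 study trials each (40 study faces), 80 faces, and timing /
#' spatial parameters chosen as plausible for face viewing (values the source
#' design does not pin down are declared here once).
#'
#' @param n_participants number of participants.
#' @param trials_per_cell study-phase trials per orientation x start cell.
#' @param n_faces number of face stimuli.
#' @param jitter_sd sd (deg) of the i.i.d. Gaussian jitter applied to the
#'   canonical AOI corners per face.
#' @param kappa toward-start bias of the first fixation (deg).
#' @param delta opposite-side shift of fixations 2-5 (deg).
#' @param sigma1 scatter sd of the first fixation about the face center (deg).
#' @param scatter_sd scatter sd of later fixations about their landmark (deg).
#' @param weight_tilt exponential tilt of landmark weights away from the
#'   start side (0 = no tilt).
#' @param landmark_weights base mixture weights over the 7 AOI landmarks
#'   (must sum to 1); default favours the eye region.
#' @param dur_mean_first,dur_mean_later,dur_sd fixation-duration model (ms);
#'   first fixations are shorter.
#' @param lat_mean_peripheral,lat_mean_center,lat_sd latency-to-first-saccade
#'   model (ms); the center start is slower.
#' @param saccade_flight_ms nominal saccade flight time between first-saccade
#'   onset and the first on-face fixation (ms).
#' @param min_fix_study,min_fix_test,max_fix,fix_geom_p fixation-count model:
#'   counts are `min + rgeom(fix_geom_p)` truncated at `max_fix` (fewer
#'   fixations at test, where presentation is brief).
#' @param dprime_true true sensitivity of the simulated old/new observer.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 20,
                             trials_per_cell = 4,
                             n_faces = 80,
                             jitter_sd = 0.15,
                             kappa = 0.5,
                             delta = 1.0,
                             sigma1 = 0.9,
                             scatter_sd = 0.8,
                             weight_tilt = 0.3,
                             landmark_weights = c(
                               left_eye = 0.22, mid_eye = 0.16,
                               right_eye = 0.22, left_nose = 0.11,
                               right_nose = 0.11, left_mouth = 0.09,
                               right_mouth = 0.09),
                             dur_mean_first = 240, dur_mean_later = 330,
                             dur_sd = 60,
                             lat_mean_peripheral = 180, lat_mean_center = 300,
                             lat_sd = 40,
                             saccade_flight_ms = 25,
                             min_fix_study = 5, min_fix_test = 3,
                             max_fix = 10, fix_geom_p = 0.5,
                             dprime_true = 1.0,
                             seed = 1L) {
  stopifnot(length(landmark_weights) == 7,
            all(names(landmark_weights) == AOI_LABELS) ||
              setequal(names(landmark_weights), AOI_LABELS),
            all(landmark_weights > 0),
            abs(sum(landmark_weights) - 1) < 1e-8,
            jitter_sd >= 0, sigma1 > 0, scatter_sd > 0, dur_sd > 0,
            lat_sd > 0, min_fix_study >= 1, max_fix >= min_fix_study,
            fix_geom_p > 0, fix_geom_p <= 1)
  cfg <- as.list(environment())
  cfg$landmark_weights <- landmark_weights[AOI_LABELS]
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>",
      x$n_participants, "participants,",
      x$trials_per_cell, "trials/cell,", x$n_faces, "faces\n")
  cat(sprintf("  kappa = %.2f deg, delta = %.2f deg, scatter = %.2f deg, seed = %d\n",
              x$kappa, x$delta, x$scatter_sd, as.integer(x$seed)))
  invisible(x)
}

# Deterministic sub-seed derivation so per-participant (and per-stage)
# streams are reproducible independently of each other. Kept below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in idx) s <- (s * 48271 + as.double(k)) %% 2147483629
  as.integer(s + 1)
}

#' Generate jittered synthetic faces
#'
#' Each face is the canonical layout with i.i.d. Gaussian jitter on every
#' rectangle corner, standing in for distinct photographs.  Faces whose
#' jittered anchors are degenerate (collinear lateral anchors or an
#' infeasible vertical-start distance) are resampled, up to a retry bound.
#'
#' @param config a [generator_config()].
#' @param seed optional seed override (defaults to a stream derived from
#'   `config$seed`).
#' @return named list of `face_geometry` objects (`"f001"`, ...).
#' @export
generate_faces <- function(config, seed = derive_seed(config$seed, 1)) {
  template <- canonical_face()
  set.seed(seed)
  out <- vector("list", config$n_faces)
  for (i in seq_len(config$n_faces)) {
    id <- sprintf("f%03d", i)
    for (try in 1:20) {
      aois <- lapply(template$aois, function(a) {
        j <- stats::rnorm(4, 0, config$jitter_sd)
        x <- sort(c(a$x_min + j[1], a$x_max + j[2]))
        y <- sort(c(a$y_min + j[3], a$y_max + j[4]))
        # keep jittered rectangles inside the image bounds
        ib <- template$image_bounds
        aoi_rect(a$label, max(x[1], ib[1]), max(y[1], ib[2]),
                 min(x[2], ib[3]), min(y[2], ib[4]))
      })
      g <- face_geometry(id, aois, template$image_bounds, "upright")
      ok <- tryCatch({ start_positions(g); TRUE },
                     error = function(e) FALSE)
      if (ok) break
      if (try == 20)
        stop("generate_faces: could not generate a non-degenerate face '",
             id, "' in 20 attempts; reduce jitter_sd")
    }
    out[[i]] <- g
  }
  names(out) <- vapply(out, function(f) f$face_id, character(1))
  out
}

# unit vector from the face center toward a start position; zero start
# direction (used by null datasets) gives c(0, 0)
start_direction <- function(geometry, start) {
  if (identical(start, "none")) return(c(0, 0))
  sp <- start_positions(geometry)
  p <- unlist(sp[sp$position == start, c("x", "y")])
  ctr <- center_start(geometry)
  v <- p - ctr
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0) else v / n
}

#' Generate one trial's fixation sequence
#'
#' The first fixation lands near the face center with a `kappa`-deg bias
#' toward the start position; fixations 2 onward are drawn from the
#' landmark-anchored mixture with weights tilted away from the start side
#' and every landmark shifted `delta` deg toward the opposite side.
#' Durations and the first-saccade latency follow the configured models.
#' Inverted trials are generated in the inverted face frame.
#'
#' @param config a [generator_config()].
#' @param condition list with elements `orientation` (`"upright"` /
#'   `"inverted"`), `start` (`"left"`, `"right"`, `"upper"`, `"lower"`,
#'   `"center"`, or `"none"` for a start-agnostic trial), `phase`
#'   (`"study"` / `"test"`).
#' @param face a `face_geometry` (upright; inversion is applied here).
#' @param n_fix optional fixation count override.
#' @return data.frame with columns `ordinal`, `x`, `y`, `onset_ms`,
#'   `duration_ms`, plus attribute `latency_ms` (first-saccade latency).
#' @export
generate_trial <- function(config, condition, face, n_fix = NULL) {
  geom <- if (condition$orientation == "inverted") invert_geometry(face)
          else face
  ctr <- center_start(geom)
  u <- start_direction(geom, condition$start)
  cen <- aoi_centers(geom)

  if (is.null(n_fix)) {
    minf <- if (identical(condition$phase, "test")) config$min_fix_test
            else config$min_fix_study
    n_fix <- min(minf + stats::rgeom(1, config$fix_geom_p), config$max_fix)
  }

  lat_mean <- if (identical(condition$start, "center")) config$lat_mean_center
              else config$lat_mean_peripheral
  latency <- max(80, stats::rnorm(1, lat_mean, config$lat_sd))

  # landmark weights tilted away from the start side
  proj <- (cen$x - ctr[[1]]) * u[1] + (cen$y - ctr[[2]]) * u[2]
  w <- config$landmark_weights * exp(-config$weight_tilt * proj)
  w <- w / sum(w)

  lm <- c(1L, sample.int(7, n_fix - 1L, replace = TRUE, prob = w))
  mx <- c(ctr[[1]] + config$kappa * u[1],
          cen$x[lm[-1]] - config$delta * u[1])
  my <- c(ctr[[2]] + config$kappa * u[2],
          cen$y[lm[-1]] - config$delta * u[2])
  sds <- c(config$sigma1, rep(config$scatter_sd, n_fix - 1L))
  x <- stats::rnorm(n_fix, mx, sds)
  y <- stats::rnorm(n_fix, my, sds)
  dur <- pmax(50, stats::rnorm(n_fix,
                               c(config$dur_mean_first,
                                 rep(config$dur_mean_later, n_fix - 1L)),
                               config$dur_sd))
  onset <- latency + config$saccade_flight_ms +
    c(0, cumsum(dur[-n_fix] + config$saccade_flight_ms))
  out <- data.frame(ordinal = seq_len(n_fix), x = x, y = y,
                    onset_ms = onset, duration_ms = dur)
  attr(out, "latency_ms") <- latency
  out
}

# internal: build a full fixation report for arbitrary condition cells.
# cells: data.frame(orientation, start, phase, condition) where `condition`
# is the label used by downstream contrasts; trials_per_cell trials per cell
# and participant.
build_dataset <- function(config, cells, trials_per_cell, faces,
                          delta_by_condition = NULL) {
  res <- vector("list", config$n_participants)
  face_ids <- names(faces)
  for (p in seq_len(config$n_participants)) {
    set.seed(derive_seed(config$seed, 2, p))
    rows <- list()
    trial_id <- 0L
    pid <- sprintf("p%02d", p)
    for (ci in seq_len(nrow(cells))) {
      cond <- as.list(cells[ci, ])
      cfg_c <- config
      if (!is.null(delta_by_condition))
        cfg_c$delta <- delta_by_condition[[cond$condition]]
      for (t in seq_len(trials_per_cell)) {
        trial_id <- trial_id + 1L
        fid <- face_ids[[sample.int(length(face_ids), 1)]]
        tr <- generate_trial(cfg_c, cond, faces[[fid]])
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid,
          trial_id = sprintf("%s_t%03d", pid, trial_id),
          phase = cond$phase, orientation = cond$orientation,
          start_position = cond$start, condition = cond$condition,
          face_id = fid, tr,
          stringsAsFactors = FALSE)
      }
    }
    res[[p]] <- do.call(rbind, rows)
  }
  fx <- do.call(rbind, res)
  rownames(fx) <- NULL
  fx
}

#' Generate a full synthetic experiment
#'
#' Fixation report over the full factorial design (orientation x start x
#' phase), the jittered face set, and the behavioral response table.
#'
#' @param config a [generator_config()].
#' @return list with elements `fixations` (data.frame in the fixation-report
#'   dialect), `faces` (list of `face_geometry`), `behavior` (old/new
#'   response table), `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  faces <- generate_faces(config)
  cells <- expand.grid(orientation = c("upright", "inverted"),
                       start = c("left", "right", "upper", "lower", "center"),
                       phase = c("study", "test"),
                       stringsAsFactors = FALSE)
  cells$condition <- paste(cells$orientation, cells$start, cells$phase,
                           sep = ".")
  fx <- build_dataset(config, cells, config$trials_per_cell, faces)
  beh <- generate_behavior(config)
  list(fixations = fx, faces = faces, behavior = beh, config = config)
}

#' Generate an exchangeable-null dataset
#'
#' Two condition labels (`"A"`, `"B"`) whose fixation-generating
#' distributions are identical per ordinal: the toward-start and
#' opposite-side terms are equalised (no start direction enters the spatial
#' model), so condition labels are exchangeable by construction.  Used to
#' calibrate the permutation and cluster machinery.
#'
#' @param config a [generator_config()]; `trials_per_cell` trials per
#'   condition and participant.
#' @return list with `fixations`, `faces`, `config`.
#' @export
generate_null_dataset <- function(config = generator_config()) {
  faces <- generate_faces(config)
  cells <- data.frame(orientation = "upright", start = "none",
                      phase = "study", condition = c("A", "B"),
                      stringsAsFactors = FALSE)
  fx <- build_dataset(config, cells, config$trials_per_cell, faces)
  list(fixations = fx, faces = faces, config = config)
}

#' Generate a planted-effect dataset
#'
#' Identical to [generate_null_dataset()] except that condition `"A"`'s
#' fixations 2 onward receive an additional mean shift of `delta` degrees
#' along `direction` (default: leftward, emulating the opposite-side
#' advantage for a right start position).  `delta = 0` reduces exactly to
#' the null dataset.
#'
#' @param config a [generator_config()].
#' @param delta planted shift in degrees.
#' @param direction unit-norm length-2 direction of the shift.
#' @return list with `fixations`, `faces`, `config`, `delta`, `direction`.
#' @export
generate_effect_dataset <- function(config = generator_config(),
                                    delta = 1.5,
                                    direction = c(-1, 0)) {
  direction <- direction / sqrt(sum(direction^2))
  faces <- generate_faces(config)
  cells <- data.frame(orientation = "upright", start = "none",
                      phase = "study", condition = c("A", "B"),
                      stringsAsFactors = FALSE)
  fx <- build_dataset(config, cells, config$trials_per_cell, faces)
  sel <- fx$condition == "A" & fx$ordinal >= 2
  fx$x[sel] <- fx$x[sel] + delta * direction[1]
  fx$y[sel] <- fx$y[sel] + delta * direction[2]
  list(fixations = fx, faces = faces, config = config,
       delta = delta, direction = direction)
}

#' Generate old/new recognition behavior
#'
#' Equal-variance signal-detection observer with sensitivity
#' `config$dprime_true` and criterion 0: hit probability
#' `pnorm(dprime/2)`, false-alarm probability `pnorm(-dprime/2)`.
#'
#' @param config a [generator_config()].
#' @param n_trials trials per participant (half old, half new).
#' @param seed optional seed override.
#' @return data.frame with columns `participant_id`, `trial`, `truth`
#'   (`"old"`/`"new"`), `response`, `rt_ms`.
#' @export
generate_behavior <- function(config, n_trials = 80,
                              seed = derive_seed(config$seed, 3)) {
  set.seed(seed)
  d <- config$dprime_true
  out <- lapply(seq_len(config$n_participants), function(p) {
    truth <- rep(c("old", "new"), length.out = n_trials)
    p_yes <- ifelse(truth == "old", stats::pnorm(d / 2), stats::pnorm(-d / 2))
    resp <- ifelse(stats::runif(n_trials) < p_yes, "old", "new")
    data.frame(participant_id = sprintf("p%02d", p),
               trial = seq_len(n_trials), truth = truth, response = resp,
               rt_ms = stats::rlnorm(n_trials, log(900), 0.3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
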