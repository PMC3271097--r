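# Ingest fixation reports, apply trial/fixation filters, assign AOIs, and
# compute relative-frequency, timing and behavioral summaries.

FIXREPORT_COLUMNS <- c("participant_id", "trial_id", "phase", "orientation",
                       "start_position", "face_id", "ordinal", "x", "y",
                       "onset_ms", "duration_ms")

#' Read a tab-delimited fixation report
#'
#' One row per fixation, with named columns `participant_id`, `trial_id`,
#' `phase`, `orientation`, `start_position`, `face_id`, `ordinal`, `x`, `y`,
#' `onset_ms`, `duration_ms` (the dialect exported by common eye-tracker
#' analysis software).  Extra columns are kept.  Rows whose numeric fields do
#' not parse are dropped with a warning naming their line numbers; trials
#' with non-monotone fixation onsets raise a warning.
#'
#' @param path file path.
#' @return data.frame of typed fixation records.
#' @export
read_fixation_report <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  miss <- setdiff(FIXREPORT_COLUMNS, names(dt))
  if (length(miss))
    stop("read_fixation_report: missing required columns: ",
         paste(miss, collapse = ", "))
  df <- as.data.frame(dt)
  if (nrow(df) == 0) return(df)
  for (col in c("ordinal", "x", "y", "onset_ms", "duration_ms"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- !stats::complete.cases(df[, c("ordinal", "x", "y", "onset_ms",
                                       "duration_ms")])
  if (any(bad)) {
    warning("read_fixation_report: dropping ", sum(bad),
            " unparseable row(s) at line(s) ",
            paste(utils::head(which(bad) + 1L, 20), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  df$ordinal <- as.integer(df$ordinal)
  mono <- vapply(split(df$onset_ms[order(df$trial_id, df$ordinal)],
                       df$trial_id[order(df$trial_id, df$ordinal)]),
                 function(o) all(diff(o) >= 0), logical(1))
  if (any(!mono))
    warning("read_fixation_report: non-monotone onsets within trial(s): ",
            paste(utils::head(names(mono)[!mono], 5), collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write a fixation report
#' @param fixations data.frame of fixation records.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_fixation_report <- function(fixations, path) {
  data.table::fwrite(fixations, path, sep = "\t")
  invisible(path)
}

#' Keep only the first k fixations of every trial
#'
#' Equalises the data contributed per trial by truncating each trial to
#' ordinals `<= k`.  Trials with fewer than `k` fixations are retained with
#' their available fixations (set `strict = TRUE` to drop them instead);
#' counts of removed fixations and short trials are attached as attributes
#' `n_removed` and `n_short_trials`.
#'
#' @param fixations fixation data.frame.
#' @param k maximum ordinal to keep (default 5).
#' @param strict drop trials with fewer than `k` fixations.
#' @return filtered data.frame.
#' @export
select_first_k <- function(fixations, k = 5, strict = FALSE) {
  keep <- fixations$ordinal <= k
  out <- fixations[keep, , drop = FALSE]
  n_fix <- tapply(out$ordinal, out$trial_id, length)
  short <- names(n_fix)[n_fix < k]
  if (strict && length(short))
    out <- out[!(out$trial_id %in% short), , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_short_trials") <- length(short)
  rownames(out) <- NULL
  out
}

#' Drop the first fixation and/or center-start trials
#'
#' The first fixation is heavily constrained by the start position and the
#' center start shows qualitatively different timing, so density contrasts
#' typically exclude both.
#'
#' @param fixations fixation data.frame.
#' @param drop_first remove ordinal-1 rows.
#' @param drop_center remove trials with `start_position == "center"`.
#' @return filtered data.frame.
#' @export
drop_first_and_center <- function(fixations, drop_first = TRUE,
                                  drop_center = TRUE) {
  keep <- rep(TRUE, nrow(fixations))
  if (drop_first) keep <- keep & fixations$ordinal != 1L
  if (drop_center) keep <- keep & fixations$start_position != "center"
  out <- fixations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clamp out-of-image fixations to the nearest image edge
#'
#' Fixations falling outside the stimulus image are projected (L2) to the
#' nearest boundary point so every analysed fixation carries equal weight.
#' The clamped fraction is attached as attribute `clamped_fraction`.
#'
#' @param fixations fixation data.frame (columns `x`, `y`).
#' @param bounds numeric `c(x_min, y_min, x_max, y_max)` in degrees, or a
#'   `face_geometry` whose image bounds are used.
#' @return data.frame with clamped coordinates.
#' @export
clamp_to_image <- function(fixations, bounds) {
  if (inherits(bounds, "face_geometry")) bounds <- bounds$image_bounds
  stopifnot(length(bounds) == 4)
  x <- pmin(pmax(fixations$x, bounds[1]), bounds[3])
  y <- pmin(pmax(fixations$y, bounds[2]), bounds[4])
  clamped <- x != fixations$x | y != fixations$y
  out <- fixations
  out$x <- x
  out$y <- y
  attr(out, "clamped_fraction") <-
    if (nrow(out)) mean(clamped) else 0
  out
}

#' Assign fixations to AOIs
#'
#' Returns the label of the (closed) AOI rectangle containing each point,
#' or `"outside"`.  Points on shared edges are resolved by the declared
#' priority order (eyes before nose before mouth, left to right).
#'
#' @param x,y fixation coordinates in the face's frame (deg).
#' @param geometry a `face_geometry`.
#' @return character vector of labels.
#' @export
assign_aoi <- function(x, y, geometry) {
  out <- rep("outside", length(x))
  for (lab in rev(AOI_PRIORITY)) {   # highest priority applied last
    a <- geometry$aois[[lab]]
    inside <- x >= a$x_min & x <= a$x_max & y >= a$y_min & y <= a$y_max
    out[inside] <- lab
  }
  out
}

#' Relative fixation frequencies per AOI
#'
#' For each participant x condition cell, the number of fixations landing
#' in each AOI (or outside all of them) divided by the number of *possible*
#' fixations, `trials x k`.  Cells where every trial contributes exactly
#' `k` fixations therefore sum to 1 across the 7 AOIs plus `outside`.
#'
#' @param fixations fixation data.frame (already truncated with
#'   [select_first_k()]); must contain an `aoi` column (from
#'   [assign_aoi()]) or the face geometries must be supplied.
#' @param faces optional named list of `face_geometry` used to assign AOIs
#'   per face when no `aoi` column is present.
#' @param cell_cols columns defining a condition cell.
#' @param k possible fixations per trial (denominator), default 5.
#' @return data.frame with columns `participant_id`, the cell columns,
#'   `aoi`, `n`, `rel_freq`.
#' @export
relative_frequencies <- function(fixations, faces = NULL,
                                 cell_cols = c("orientation",
                                               "start_position", "phase"),
                                 k = 5) {
  fx <- fixations
  if (is.null(fx$aoi)) {
    if (is.null(faces))
      stop("relative_frequencies: provide an 'aoi' column or 'faces'")
    fx$aoi <- NA_character_
    for (fid in unique(fx$face_id)) {
      sel <- fx$face_id == fid
      g <- faces[[fid]]
      if (fx$orientation[sel][1] == "inverted") g <- invert_geometry(g)
      fx$aoi[sel] <- assign_aoi(fx$x[sel], fx$y[sel], g)
    }
  }
  dt <- data.table::as.data.table(fx)
  levels <- c(AOI_LABELS, "outside")
  cell_by <- c("participant_id", cell_cols)
  denom <- dt[, list(n_trials = data.table::uniqueN(trial_id)), by = cell_by]
  counts <- dt[, list(n = .N), by = c(cell_by, "aoi")]
  grid <- denom[, c(cell_by, "n_trials"), with = FALSE]
  full <- grid[, list(aoi = levels), by = c(cell_by, "n_trials")]
  out <- merge(full, counts, by = c(cell_by, "aoi"), all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  out$rel_freq <- out$n / (out$n_trials * k)
  out$aoi <- factor(out$aoi, levels = levels)
  data.table::setorderv(out, c(cell_by, "aoi"))
  as.data.frame(out)
}

#' Latency to the first saccade
#'
#' Time from stimulus onset (t = 0) to the first saccade of each trial,
#' recovered from fixation-level data: if a trial contains a fixation row
#' spanning stimulus onset (`onset_ms <= 0`), the latency is that row's end
#' (`onset + duration`); otherwise the first on-face fixation's onset minus
#' a nominal saccade flight time.  Trials with no post-stimulus fixation
#' yield `NA`.
#'
#' @param fixations fixation data.frame.
#' @param flight_ms nominal saccade flight time (ms), matching the
#'   synthetic generator's default.
#' @return data.frame with one row per trial: `trial_id`, `latency_ms`.
#' @export
latency_to_first_saccade <- function(fixations, flight_ms = 25) {
  dt <- data.table::as.data.table(fixations)
  lat <- dt[, {
    o <- order(ordinal)
    on <- onset_ms[o]; du <- duration_ms[o]
    if (!length(on)) list(latency_ms = NA_real_)
    else if (on[1] <= 0) list(latency_ms = on[1] + du[1])
    else list(latency_ms = on[1] - flight_ms)
  }, by = "trial_id"]
  as.data.frame(lat)
}

#' Timing summaries per condition cell
#'
#' Per participant x condition cell: mean latency to first saccade, and
#' mean/sd fixation duration per ordinal, with trial counts.
#'
#' @param fixations fixation data.frame.
#' @param cell_cols columns defining a condition cell.
#' @param flight_ms see [latency_to_first_saccade()].
#' @return list of data.frames `latency` (participant, cell, mean latency,
#'   n trials) and `durations` (participant, cell, ordinal, mean, sd, n).
#' @export
duration_profile <- function(fixations,
                             cell_cols = c("orientation", "start_position",
                                           "phase"),
                             flight_ms = 25) {
  dt <- data.table::as.data.table(fixations)
  cell_by <- c("participant_id", cell_cols)
  lat <- latency_to_first_saccade(fixations, flight_ms)
  tr <- unique(dt[, c("trial_id", cell_by), with = FALSE])
  lat <- merge(data.table::as.data.table(lat), tr, by = "trial_id")
  lat_sum <- lat[, list(latency_mean_ms = mean(latency_ms, na.rm = TRUE),
                        n_trials = .N), by = cell_by]
  dur <- dt[, list(duration_mean_ms = mean(duration_ms),
                   duration_sd_ms = stats::sd(duration_ms),
                   n = .N),
            by = c(cell_by, "ordinal")]
  data.table::setorderv(dur, c(cell_by, "ordinal"))
  list(latency = as.data.frame(lat_sum), durations = as.data.frame(dur))
}

#' Signal-detection sensitivity d-prime
#'
#' `qnorm(hit rate) - qnorm(false-alarm rate)` with the standard extreme-rate
#' correction: rates of 0 and 1 are replaced by `1/(2N)` and `1 - 1/(2N)`
#' of their own trial class.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative counts;
#'   each class (old, new) must contain at least one trial.
#' @return d-prime (numeric scalar).
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  stopifnot(hits >= 0, misses >= 0, false_alarms >= 0,
            correct_rejections >= 0)
  n_old <- hits + misses
  n_new <- false_alarms + correct_rejections
  if (n_old == 0 || n_new == 0)
    stop("dprime: zero trials in the old or new class")
  clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  hr <- clamp(hits / n_old, n_old)
  far <- clamp(false_alarms / n_new, n_new)
  stats::qnorm(hr) - stats::qnorm(far)
}

#' Per-participant d-prime table from a behavior table
#'
#' @param behavior data.frame with columns `participant_id`, `truth`,
#'   `response` (values `"old"`/`"new"`) and optionally `rt_ms`.
#' @return data.frame with `participant_id`, `dprime`, hit/FA rates, and
#'   mean correct RT when available.
#' @export
dprime_table <- function(behavior) {
  out <- lapply(split(behavior, behavior$participant_id), function(b) {
    h <- sum(b$truth == "old" & b$response == "old")
    m <- sum(b$truth == "old" & b$response == "new")
    fa <- sum(b$truth == "new" & b$response == "old")
    cr <- sum(b$truth == "new" & b$response == "new")
    data.frame(participant_id = b$participant_id[1],
               dprime = dprime(h, m, fa, cr),
               hit_rate = h / (h + m), fa_rate = fa / (fa + cr),
               rt_correct_ms = if (!is.null(b$rt_ms))
                 mean(b$rt_ms[b$response == b$truth]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
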