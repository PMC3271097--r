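# Spatial fixation-density maps on a regular grid over the aligned-face
# frame.  Each fixation contributes an isotropic Gaussian (sd `sigma`,
# default 0.3 deg) evaluated at pixel centers, so a map's mass
# (sum(values) * cell^2) equals its fixation count up to kernel truncation.

#' Grid specification
#'
#' A regular raster over the aligned-face frame.  Pixel `(i, j)` (1-based)
#' has center `(x_min + (i - 0.5) cell, y_min + (j - 0.5) cell)`; map values
#' are stored as an `n_x` x `n_y` matrix indexed `[i, j]`.
#'
#' @param x_min,y_min lower-left corner (deg).
#' @param cell pixel size (deg); must be positive.
#' @param n_x,n_y pixel counts.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(x_min, y_min, cell, n_x, n_y) {
  stopifnot(cell > 0, n_x >= 1, n_y >= 1)
  structure(list(x_min = x_min, y_min = y_min, cell = cell,
                 n_x = as.integer(n_x), n_y = as.integer(n_y)),
            class = "grid_spec")
}

#' Default grid over a face's image bounds
#'
#' The image bounding box padded by `pad` degrees on every side so edge
#' fixations keep (nearly) all their kernel mass, rasterised at `cell`
#' deg/pixel.  All downstream statistics are resolution-robust because the
#' cluster null is recomputed per grid.
#'
#' @param bounds numeric `c(x_min, y_min, x_max, y_max)` or a
#'   `face_geometry`.
#' @param cell pixel size in deg (default 0.05).
#' @param pad padding in deg (default 1).
#' @return a [grid_spec()].
#' @export
default_grid <- function(bounds, cell = 0.05, pad = 1) {
  if (inherits(bounds, "face_geometry")) bounds <- bounds$image_bounds
  x_min <- bounds[1] - pad
  y_min <- bounds[2] - pad
  n_x <- ceiling((bounds[3] + pad - x_min) / cell)
  n_y <- ceiling((bounds[4] + pad - y_min) / cell)
  grid_spec(x_min, y_min, cell, n_x, n_y)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, %.3f deg/px, origin (%.2f, %.2f)\n",
              x$n_x, x$n_y, x$cell, x$x_min, x$y_min))
  invisible(x)
}

#' Pixel-center coordinates of a grid
#' @param grid a `grid_spec`.
#' @return list with numeric vectors `x` (length `n_x`) and `y` (`n_y`).
#' @export
grid_centers <- function(grid) {
  list(x = grid$x_min + (seq_len(grid$n_x) - 0.5) * grid$cell,
       y = grid$y_min + (seq_len(grid$n_y) - 0.5) * grid$cell)
}

#' Align fixations to the common reference frame
#'
#' Translates each fixation by its face's [alignment_translation()] so maps
#' for different faces can be summed meaningfully.  Translation-only, so all
#' within-trial distances are preserved.
#'
#' @param fixations fixation data.frame with a `face_id` column.
#' @param faces named list of `face_geometry` (in the frame the fixations
#'   were recorded in, i.e. inverted geometry for inverted trials).
#' @param reference reference centers from [reference_frame()]; defaults to
#'   the average over `faces`.
#' @return the data.frame with translated `x`, `y`.
#' @export
align_fixations <- function(fixations, faces,
                            reference = reference_frame(faces)) {
  out <- fixations
  for (fid in unique(out$face_id)) {
    t <- alignment_translation(aoi_centers(faces[[fid]]), reference)
    sel <- out$face_id == fid
    out$x[sel] <- out$x[sel] + t[["dx"]]
    out$y[sel] <- out$y[sel] + t[["dy"]]
  }
  out
}

# Evaluate the truncated Gaussian patch of one fixation on the grid.
# Returns NULL when the patch misses the grid, else list(ix, iy, vals).
gaussian_patch <- function(gx, gy, x, y, grid, sigma, trunc) {
  r <- trunc * sigma
  # 1e-9 guard keeps boundary-pixel inclusion reflection-symmetric
  ix <- which(gx >= x - r - 1e-9 & gx <= x + r + 1e-9)
  iy <- which(gy >= y - r - 1e-9 & gy <= y + r + 1e-9)
  if (!length(ix) || !length(iy)) return(NULL)
  vx <- stats::dnorm(gx[ix], x, sigma)
  vy <- stats::dnorm(gy[iy], y, sigma)
  list(ix = ix, iy = iy, vals = outer(vx, vy))
}

#' Spatial fixation-density map
#'
#' Sums, over fixations, an isotropic Gaussian pdf (sd `sigma`) evaluated at
#' pixel centers.  Fixations carry equal weight (no duration weighting).
#' Units are density per deg^2, so `sum(values) * cell^2` equals the
#' fixation count up to kernel truncation (kernels are cut at
#' `trunc = 4` sigma for speed; declared normalisation tolerance 1e-3).
#'
#' @param fixations fixation data.frame (already clamped and aligned), or
#'   `NULL`/empty for a zero map.
#' @param grid a [grid_spec()].
#' @param sigma kernel sd in degrees (default 0.3).
#' @param trunc truncation radius in sds (default 4).
#' @return an object of class `density_map`: list with `grid`, `values`
#'   (`n_x` x `n_y` matrix), `n_fixations`.
#' @export
density_map <- function(fixations, grid, sigma = 0.3, trunc = 4) {
  g <- grid_centers(grid)
  vals <- matrix(0, grid$n_x, grid$n_y)
  n <- if (is.null(fixations)) 0L else nrow(fixations)
  if (n) {
    for (i in seq_len(n)) {
      p <- gaussian_patch(g$x, g$y, fixations$x[i], fixations$y[i],
                          grid, sigma, trunc)
      if (!is.null(p))
        vals[p$ix, p$iy] <- vals[p$ix, p$iy] + p$vals
    }
  }
  structure(list(grid = grid, values = vals, n_fixations = n,
                 sigma = sigma),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d px, %d fixations, mass %.4f\n",
              x$grid$n_x, x$grid$n_y, x$n_fixations, map_mass(x)))
  invisible(x)
}

#' Total mass of a density map
#' @param map a `density_map` (or matrix with a grid argument).
#' @param grid grid when `map` is a bare matrix.
#' @return `sum(values) * cell^2`.
#' @export
map_mass <- function(map, grid = NULL) {
  if (inherits(map, "density_map")) sum(map$values) * map$grid$cell^2
  else sum(map) * grid$cell^2
}

#' Average density maps across trials then participants
#'
#' Unweighted mean over trials within each participant, then unweighted
#' mean over participants (so participants with unequal trial counts carry
#' equal weight).
#'
#' @param maps list of `density_map`s (one per trial).
#' @param participant_ids character vector parallel to `maps`.
#' @return a `density_map` whose `n_fixations` is the total count.
#' @export
group_average <- function(maps, participant_ids) {
  stopifnot(length(maps) == length(participant_ids), length(maps) >= 1)
  by_p <- split(maps, participant_ids)
  pmaps <- lapply(by_p, function(ms)
    Reduce(`+`, lapply(ms, `[[`, "values")) / length(ms))
  avg <- Reduce(`+`, pmaps) / length(pmaps)
  structure(list(grid = maps[[1]]$grid, values = avg,
                 n_fixations = sum(vapply(maps, `[[`, 0, "n_fixations")),
                 sigma = maps[[1]]$sigma),
            class = "density_map")
}

#' Participant-wise difference of two sets of density maps
#'
#' For each participant, (trial-mean map of A) minus (trial-mean map of B),
#' then averaged across participants.
#'
#' @param maps_A,maps_B lists of per-trial `density_map`s.
#' @param participants_A,participants_B participant ids parallel to the
#'   map lists; every participant must appear on both sides.
#' @return an object of class `difference_map` (`grid`, `values`).
#' @export
difference_map <- function(maps_A, maps_B, participants_A, participants_B) {
  pa <- split(maps_A, participants_A)
  pb <- split(maps_B, participants_B)
  common <- intersect(names(pa), names(pb))
  if (!length(common)) stop("difference_map: no shared participants")
  diffs <- lapply(common, function(p) {
    ma <- Reduce(`+`, lapply(pa[[p]], `[[`, "values")) / length(pa[[p]])
    mb <- Reduce(`+`, lapply(pb[[p]], `[[`, "values")) / length(pb[[p]])
    ma - mb
  })
  structure(list(grid = maps_A[[1]]$grid,
                 values = Reduce(`+`, diffs) / length(diffs),
                 n_participants = length(common)),
            class = "difference_map")
}

#' Flip a map or fixations about a horizontal axis
#'
#' Used to align inverted-face data with upright-face data before
#' subtraction.  `flip` twice is the identity and mass is conserved.
#'
#' @param x a `density_map`, `difference_map`, or fixation data.frame.
#' @param axis_y reflection axis in degrees; for maps defaults to the grid's
#'   vertical center.
#' @return object of the same type, reflected.
#' @export
flip_vertical <- function(x, axis_y = NULL) {
  if (is.data.frame(x)) {
    if (is.null(axis_y)) stop("flip_vertical: axis_y required for fixations")
    x$y <- 2 * axis_y - x$y
    return(x)
  }
  grid <- x$grid
  if (!is.null(axis_y)) {
    center <- grid$y_min + grid$n_y * grid$cell / 2
    if (abs(axis_y - center) > grid$cell / 2 + 1e-9)
      stop("flip_vertical: map flips are about the grid's vertical center; ",
           "re-grid first")
  }
  x$values <- x$values[, rev(seq_len(grid$n_y)), drop = FALSE]
  x
}

#' Marginal profiles of a map
#'
#' Summations of the spatial density across each dimension: the x-profile
#' sums over rows of constant x (scaled by `cell` so that
#' `sum(profile) * cell` equals the map mass), likewise the y-profile.
#'
#' @param map a `density_map` or `difference_map`.
#' @return list with data.frames `x` (`x`, `density`) and `y`
#'   (`y`, `density`).
#' @export
profile_plots <- function(map) {
  g <- grid_centers(map$grid)
  list(x = data.frame(x = g$x,
                      density = rowSums(map$values) * map$grid$cell),
       y = data.frame(y = g$y,
                      density = colSums(map$values) * map$grid$cell))
}

#' Write a map as TSV with a JSON sidecar describing the grid
#'
#' @param map a `density_map` or `difference_map`.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  utils::write.table(map$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(map$grid), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a density or significance map as a PNG heatmap
#'
#' Colorscale runs from zero (transparent) to `zmax`; difference maps are
#' drawn on a symmetric red/blue scale.
#'
#' @param map a `density_map` or `difference_map` (or signed mask matrix
#'   with `grid`).
#' @param path output PNG path.
#' @param zmax color scale maximum; defaults to the observed maximum.
#' @param grid grid when `map` is a bare matrix.
#' @return `path`, invisibly.
#' @export
plot_map_png <- function(map, path, zmax = NULL, grid = NULL) {
  if (is.matrix(map)) {
    vals <- map
  } else {
    vals <- map$values
    grid <- map$grid
  }
  g <- grid_centers(grid)
  grDevices::png(path, width = 640, height = 640 * grid$n_y / grid$n_x)
  op <- graphics::par(mar = c(3, 3, 1, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  signed <- any(vals < 0)
  if (signed) {
    m <- if (is.null(zmax)) max(abs(vals)) else zmax
    if (m == 0) m <- 1
    breaks <- seq(-m, m, length.out = 65)
    cols <- grDevices::hcl.colors(64, "Blue-Red 3")
  } else {
    m <- if (is.null(zmax)) max(vals) else zmax
    if (m == 0) m <- 1
    breaks <- seq(0, m, length.out = 65)
    cols <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE, alpha = 0.9)
    cols[1] <- grDevices::adjustcolor("white", alpha.f = 0) # zero transparent
  }
  graphics::image(g$x, rev(-g$y), vals[, rev(seq_along(g$y)), drop = FALSE],
                  breaks = breaks, col = cols, useRaster = TRUE,
                  xlab = "x (deg)", ylab = "y (deg)")
  invisible(path)
}
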