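# Face-anchored geometry: AOI rectangles, start positions, alignment.
#
# Coordinate convention used throughout the package: degrees of visual angle,
# origin at the screen/face center, x increasing rightward and y increasing
# DOWNWARD (image convention).  All geometry is continuous; pixelization only
# happens in the density module.

AOI_LABELS <- c("left_eye", "mid_eye", "right_eye",
                "left_nose", "right_nose", "left_mouth", "right_mouth")

# Tie-break priority for fixations on shared AOI edges: eye region over nose
# over mouth, left-to-right within a region (declared constant).
AOI_PRIORITY <- AOI_LABELS

#' Construct an AOI rectangle
#'
#' One rectangular area of interest over a facial feature, in degrees of
#' visual angle (screen frame, y increasing downward).
#'
#' @param label one of `"left_eye"`, `"mid_eye"`, `"right_eye"`,
#'   `"left_nose"`, `"right_nose"`, `"left_mouth"`, `"right_mouth"`.
#' @param x_min,y_min,x_max,y_max rectangle bounds in degrees;
#'   `x_min < x_max`, `y_min < y_max`.
#' @return an object of class `aoi_rect`.
#' @export
aoi_rect <- function(label, x_min, y_min, x_max, y_max) {
  label <- match.arg(label, AOI_LABELS)
  stopifnot(is.numeric(x_min), is.numeric(x_max), is.numeric(y_min),
            is.numeric(y_max))
  if (!(x_min < x_max) || !(y_min < y_max))
    stop("aoi_rect: degenerate rectangle for label '", label,
         "' (need x_min < x_max and y_min < y_max)")
  structure(list(label = label, x_min = x_min, y_min = y_min,
                 x_max = x_max, y_max = y_max),
            class = "aoi_rect")
}

#' Center of an AOI rectangle
#' @param rect an `aoi_rect`.
#' @return numeric length-2 vector `c(x, y)`.
#' @export
aoi_center <- function(rect) {
  c(x = (rect$x_min + rect$x_max) / 2, y = (rect$y_min + rect$y_max) / 2)
}

#' Construct a face geometry
#'
#' A face is described by its seven feature AOIs (both eyes, bridge of the
#' nose, the two nose halves, the two mouth halves), the image bounds the
#' face is displayed in, and its orientation.
#'
#' @param face_id identifier (character or integer).
#' @param aois list of exactly seven [aoi_rect()]s, one per label.
#' @param image_bounds numeric length-4 `c(x_min, y_min, x_max, y_max)` in
#'   degrees; every AOI must lie within it.
#' @param orientation `"upright"` or `"inverted"`.
#' @return an object of class `face_geometry`.
#' @export
face_geometry <- function(face_id, aois,
                          image_bounds,
                          orientation = c("upright", "inverted")) {
  orientation <- match.arg(orientation)
  labels <- vapply(aois, function(a) a$label, character(1))
  if (!setequal(labels, AOI_LABELS) || anyDuplicated(labels))
    stop("face_geometry: face '", face_id,
         "' must have each of the 7 AOI labels exactly once")
  names(aois) <- labels
  aois <- aois[AOI_LABELS]
  stopifnot(length(image_bounds) == 4)
  ib <- as.numeric(image_bounds)
  for (a in aois) {
    if (a$x_min < ib[1] - 1e-9 || a$y_min < ib[2] - 1e-9 ||
        a$x_max > ib[3] + 1e-9 || a$y_max > ib[4] + 1e-9)
      stop("face_geometry: AOI '", a$label, "' of face '", face_id,
           "' outside image bounds")
  }
  structure(list(face_id = face_id, aois = aois, image_bounds = ib,
                 orientation = orientation),
            class = "face_geometry")
}

#' @export
print.face_geometry <- function(x, ...) {
  cat("<face_geometry> face", x$face_id, "(", x$orientation, ")\n")
  cat("  image bounds [deg]:", paste(signif(x$image_bounds, 4), collapse = ", "), "\n")
  ctr <- aoi_centers(x)
  for (i in seq_len(nrow(ctr)))
    cat(sprintf("  %-11s center (%6.2f, %6.2f)\n",
                ctr$label[i], ctr$x[i], ctr$y[i]))
  invisible(x)
}

#' AOI centers of a face
#' @param geometry a `face_geometry`.
#' @return data.frame with columns `label`, `x`, `y` (deg), in canonical
#'   label order.
#' @export
aoi_centers <- function(geometry) {
  ctr <- t(vapply(geometry$aois, aoi_center, numeric(2)))
  data.frame(label = AOI_LABELS, x = ctr[, 1], y = ctr[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Circumcenter of three points
#'
#' The unique point equidistant from three non-collinear points, via the
#' closed-form perpendicular-bisector intersection.  Used for the lateral
#' start positions, which sit equidistant from the same-side eye, half-nose
#' and half-mouth AOI centers.
#'
#' @param p1,p2,p3 numeric length-2 points `c(x, y)` in degrees.
#' @param face_id optional identifier used in the degeneracy error message.
#' @return numeric length-2 point equidistant (to ~1e-9 deg) from the inputs.
#' @export
circumcenter <- function(p1, p2, p3, face_id = NULL) {
  ax <- p1[[1]]; ay <- p1[[2]]
  bx <- p2[[1]]; by <- p2[[2]]
  cx <- p3[[1]]; cy <- p3[[2]]
  # twice the signed area; degeneracy gate on |area| < 1e-9 deg^2
  area2 <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  if (abs(area2) / 2 < 1e-9)
    stop("degenerate geometry: collinear anchor centers",
         if (!is.null(face_id)) paste0(" for face '", face_id, "'") else "")
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(x = ux, y = uy)
}

#' Lateral (left/right) start position
#'
#' The point equidistant from the centers of the same-side eye, half-nose and
#' half-mouth AOIs.
#'
#' @param geometry a `face_geometry`.
#' @param side `"left"` or `"right"`.
#' @return numeric length-2 point in degrees.
#' @export
lateral_start <- function(geometry, side = c("left", "right")) {
  side <- match.arg(side)
  ctr <- aoi_centers(geometry)
  anchors <- paste0(side, c("_eye", "_nose", "_mouth"))
  p <- lapply(anchors, function(l) unlist(ctr[ctr$label == l, c("x", "y")]))
  circumcenter(p[[1]], p[[2]], p[[3]], face_id = geometry$face_id)
}

#' Vertical (upper/lower) start position
#'
#' The point on the perpendicular bisector of two anchor centers (the two
#' eyes for the upper start, the two mouth halves for the lower start) at a
#' given distance from each.  Of the two bisector solutions the upper start
#' takes the one on the forehead side of the eyes (farther from the mouth)
#' and the lower start the one on the chin side of the mouth (farther from
#' the eyes); the rule is expressed feature-relative so it is unaffected by
#' image inversion.
#'
#' @param geometry a `face_geometry`.
#' @param which `"upper"` or `"lower"`.
#' @param target_distance distance in degrees from the start position to each
#'   anchor center; must exceed half the anchor separation.
#' @return numeric length-2 point in degrees.
#' @export
vertical_start <- function(geometry, which = c("upper", "lower"),
                           target_distance) {
  which <- match.arg(which)
  ctr <- aoi_centers(geometry)
  pt <- function(l) unlist(ctr[ctr$label == l, c("x", "y")])
  anchors <- if (which == "upper") c("left_eye", "right_eye")
             else c("left_mouth", "right_mouth")
  away_from <- if (which == "upper") (pt("left_mouth") + pt("right_mouth")) / 2
               else (pt("left_eye") + pt("right_eye")) / 2
  p <- pt(anchors[1]); q <- pt(anchors[2])
  m <- (p + q) / 2
  half <- sqrt(sum((q - p)^2)) / 2
  if (target_distance <= half + 1e-12)
    stop("infeasible distance: target_distance (", signif(target_distance, 6),
         ") must exceed half the anchor separation (", signif(half, 6),
         ") for face '", geometry$face_id, "'")
  h <- sqrt(target_distance^2 - half^2)
  dirv <- (q - p) / (2 * half)
  normal <- c(-dirv[2], dirv[1])
  cand <- rbind(m + h * normal, m - h * normal)
  d2 <- rowSums((cand - matrix(away_from, 2, 2, byrow = TRUE))^2)
  out <- cand[which.max(d2), ]
  names(out) <- c("x", "y")
  out
}

#' Center start position
#'
#' Midpoint of the two half-nose AOI centers.
#'
#' @param geometry a `face_geometry`.
#' @return numeric length-2 point in degrees.
#' @export
center_start <- function(geometry) {
  ctr <- aoi_centers(geometry)
  pt <- function(l) unlist(ctr[ctr$label == l, c("x", "y")])
  out <- (pt("left_nose") + pt("right_nose")) / 2
  names(out) <- c("x", "y")
  out
}

#' All five start positions of a face
#'
#' Left and right starts are circumcenters of their same-side anchor AOIs;
#' the upper/lower anchor distance is constrained to the mean of the left
#' and right circumradii; the center start is the half-nose midpoint.
#'
#' @param geometry a `face_geometry`.
#' @return data.frame with columns `position` (left, right, upper, lower,
#'   center), `x`, `y` in degrees.
#' @export
start_positions <- function(geometry) {
  ctr <- aoi_centers(geometry)
  pt <- function(l) unlist(ctr[ctr$label == l, c("x", "y")])
  left <- lateral_start(geometry, "left")
  right <- lateral_start(geometry, "right")
  r_left <- sqrt(sum((left - pt("left_eye"))^2))
  r_right <- sqrt(sum((right - pt("right_eye"))^2))
  d <- (r_left + r_right) / 2
  upper <- vertical_start(geometry, "upper", d)
  lower <- vertical_start(geometry, "lower", d)
  center <- center_start(geometry)
  out <- rbind(left, right, upper, lower, center)
  data.frame(position = c("left", "right", "upper", "lower", "center"),
             x = out[, 1], y = out[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Average AOI layout across faces
#'
#' The common reference frame used for alignment: the per-label mean of AOI
#' centers across a set of faces.
#'
#' @param faces list of `face_geometry` objects.
#' @return data.frame with columns `label`, `x`, `y` (deg).
#' @export
reference_frame <- function(faces) {
  stopifnot(length(faces) >= 1)
  mats <- lapply(faces, function(f) as.matrix(aoi_centers(f)[, c("x", "y")]))
  avg <- Reduce(`+`, mats) / length(mats)
  data.frame(label = AOI_LABELS, x = avg[, 1], y = avg[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Translation aligning a face to the reference frame
#'
#' The translation minimising the sum of squared differences between a
#' face's AOI centers and the reference centers; under translation-only this
#' is in closed form the mean of (reference - face) over the seven centers.
#'
#' @param face_centers,reference_centers data.frames with columns `label`,
#'   `x`, `y` (label-matched; as returned by [aoi_centers()] /
#'   [reference_frame()]).
#' @return named numeric `c(dx, dy)`: add to face coordinates to land in the
#'   reference frame.
#' @export
alignment_translation <- function(face_centers, reference_centers) {
  if (nrow(face_centers) != nrow(reference_centers) ||
      !all(face_centers$label == reference_centers$label))
    stop("alignment_translation: label-mismatched center lists")
  c(dx = mean(reference_centers$x - face_centers$x),
    dy = mean(reference_centers$y - face_centers$y))
}

#' Invert a face geometry
#'
#' Reflect every AOI (and the image bounds) about a horizontal axis,
#' flipping the orientation flag.  Double inversion is the identity.
#'
#' @param geometry a `face_geometry`.
#' @param axis_y reflection axis in degrees; defaults to the vertical center
#'   of the image bounds (how inverted stimuli are constructed).
#' @return the inverted `face_geometry`.
#' @export
invert_geometry <- function(geometry,
                            axis_y = (geometry$image_bounds[2] +
                                      geometry$image_bounds[4]) / 2) {
  refl <- function(y) 2 * axis_y - y
  aois <- lapply(geometry$aois, function(a) {
    y1 <- refl(a$y_min); y2 <- refl(a$y_max)
    aoi_rect(a$label, a$x_min, min(y1, y2), a$x_max, max(y1, y2))
  })
  ib <- geometry$image_bounds
  yb <- sort(refl(ib[c(2, 4)]))
  face_geometry(geometry$face_id, aois,
                image_bounds = c(ib[1], yb[1], ib[3], yb[2]),
                orientation = if (geometry$orientation == "upright")
                  "inverted" else "upright")
}

#' Mirror-flip a face geometry left-right
#'
#' Reflect about a vertical axis, swapping the left/right AOI labels (as
#' when stimulus images are randomly left-right flipped).
#'
#' @param geometry a `face_geometry`.
#' @param axis_x reflection axis in degrees; defaults to the horizontal
#'   center of the image bounds.
#' @return the flipped `face_geometry`.
#' @export
mirror_geometry <- function(geometry,
                            axis_x = (geometry$image_bounds[1] +
                                      geometry$image_bounds[3]) / 2) {
  refl <- function(x) 2 * axis_x - x
  swap <- c(left_eye = "right_eye", mid_eye = "mid_eye",
            right_eye = "left_eye", left_nose = "right_nose",
            right_nose = "left_nose", left_mouth = "right_mouth",
            right_mouth = "left_mouth")
  aois <- lapply(geometry$aois, function(a) {
    x1 <- refl(a$x_min); x2 <- refl(a$x_max)
    aoi_rect(unname(swap[a$label]), min(x1, x2), a$y_min, max(x1, x2), a$y_max)
  })
  ib <- geometry$image_bounds
  xb <- sort(refl(ib[c(1, 3)]))
  face_geometry(geometry$face_id, aois,
                image_bounds = c(xb[1], ib[2], xb[2], ib[4]),
                orientation = geometry$orientation)
}

#' Read AOI rectangle files
#'
#' Tab-delimited dialect, one rectangle per row:
#' `face_id  label  x_min  y_min  x_max  y_max` (degrees).
#'
#' @param path file path.
#' @param image_bounds bounds to attach to every face, or `NULL` to use the
#'   bounding box of each face's AOIs.
#' @param orientation orientation flag for the constructed geometries.
#' @return named list of `face_geometry` objects.
#' @export
read_aoi_file <- function(path, image_bounds = NULL, orientation = "upright") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("face_id", "label")))
  need <- c("face_id", "label", "x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("read_aoi_file: missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(as.data.frame(dt), dt$face_id), function(d) {
    aois <- lapply(seq_len(nrow(d)), function(i)
      aoi_rect(d$label[i], d$x_min[i], d$y_min[i], d$x_max[i], d$y_max[i]))
    ib <- if (is.null(image_bounds))
      c(min(d$x_min), min(d$y_min), max(d$x_max), max(d$y_max))
    else image_bounds
    face_geometry(d$face_id[1], aois, ib, orientation)
  })
  out[unique(dt$face_id)]
}

#' Write AOI rectangle files
#' @param faces list of `face_geometry` objects.
#' @param path output path (tab-delimited, see [read_aoi_file()]).
#' @return `path`, invisibly.
#' @export
write_aoi_file <- function(faces, path) {
  rows <- do.call(rbind, lapply(faces, function(f) {
    do.call(rbind, lapply(f$aois, function(a)
      data.frame(face_id = f$face_id, label = a$label,
                 x_min = a$x_min, y_min = a$y_min,
                 x_max = a$x_max, y_max = a$y_max,
                 stringsAsFactors = FALSE)))
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}

#' Export start positions for a set of faces
#' @param faces list of `face_geometry` objects.
#' @param path output CSV path (`face_id, position, x, y`).
#' @return the table, invisibly.
#' @export
write_start_positions <- function(faces, path) {
  tab <- do.call(rbind, lapply(faces, function(f) {
    sp <- start_positions(f)
    cbind(face_id = f$face_id, sp)
  }))
  data.table::fwrite(tab, path)
  invisible(tab)
}
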