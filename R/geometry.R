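#' Root-hair geometry
#'
#' Describes a root hair as a tube of given radius along the +x axis,
#' capped by a hemisphere at the tip. The hair occupies
#' `0 <= x <= tip_position`, `|y| <= radius`, with the hemispherical cap
#' over the last `radius` micrometres. For `stage = "growing"` the tip
#' advances at `growth_rate`.
#'
#' @param stage Developmental stage: `"bulge"`, `"growing"` or `"mature"`.
#' @param shank_length Length of the cylindrical shank, um.
#' @param radius Hair radius, um.
#' @param growth_rate Tip advance rate, um/min (forced to 0 for bulge and
#'   mature stages unless given explicitly).
#' @return An object of class `root_hair_geometry`.
#' @export
#' @examples
#' g <- root_hair_geometry("growing")
#' in_hair(g, x = 5, y = 0)
root_hair_geometry <- function(stage = c("growing", "bulge", "mature"),
                               shank_length = NULL, radius = 4,
                               growth_rate = NULL) {
  stage <- match.arg(stage)
  if (is.null(shank_length)) {
    shank_length <- switch(stage, bulge = 2, growing = 40, mature = 80)
  }
  if (is.null(growth_rate)) {
    growth_rate <- if (stage == "growing") 1.941 else 0
  }
  if (radius <= 0) rlang::abort("radius must be positive")
  if (shank_length < 0) rlang::abort("shank_length must be non-negative")
  if (growth_rate < 0) rlang::abort("growth_rate must be non-negative")
  structure(
    list(stage = stage, shank_length = shank_length, radius = radius,
         tip_position = shank_length + radius, growth_rate = growth_rate),
    class = "root_hair_geometry"
  )
}

#' @export
print.root_hair_geometry <- function(x, ...) {
  cat("<root_hair_geometry> stage:", x$stage,
      " shank:", x$shank_length, "um  radius:", x$radius,
      "um  tip at:", x$tip_position, "um  growth:", x$growth_rate, "um/min\n")
  invisible(x)
}

#' Tip position at a given time
#' @param geometry A [root_hair_geometry()].
#' @param t Time, s.
#' @return Tip x-coordinate, um.
#' @export
tip_at <- function(geometry, t = 0) {
  geometry$tip_position + geometry$growth_rate / 60 * t
}

#' Test whether points lie inside the root-hair domain
#'
#' @param geometry A [root_hair_geometry()].
#' @param x,y Coordinates, um (vectorized).
#' @param t Time, s (tip advances for growing hairs).
#' @return Logical vector.
#' @export
in_hair <- function(geometry, x, y, t = 0) {
  tip <- tip_at(geometry, t)
  r <- geometry$radius
  cap_centre <- tip - r
  in_shank <- x >= 0 & x <= cap_centre & abs(y) <= r
  in_cap <- x > cap_centre & (x - cap_centre)^2 + y^2 <= r^2
  in_shank | in_cap
}

#' Axis coordinate frame of a root hair
#'
#' Arc-length parameterization of an axis polyline whose first point is
#' the tip; `distance_below_tip()` maps arbitrary (x, y) positions to
#' their arc-length distance below the tip (projection onto the axis).
#'
#' @param axis_polyline Numeric matrix or data frame with columns x, y
#'   (um), ordered from the tip towards the base.
#' @return An object of class `axis_frame`.
#' @export
#' @examples
#' af <- axis_frame(cbind(x = c(44, 0), y = c(0, 0)))
#' distance_below_tip(af, x = c(44, 34), y = c(0, 0))
axis_frame <- function(axis_polyline) {
  p <- as.matrix(axis_polyline)[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  if (nrow(p) < 2) rlang::abort("axis polyline needs at least 2 points")
  seg <- diff(p)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) rlang::abort("axis polyline has zero-length segments")
  structure(
    list(points = p, seg_len = len, cum_len = c(0, cumsum(len)),
         tip_point = p[1, ]),
    class = "axis_frame"
  )
}

#' Axis frame of a synthetic root hair
#'
#' Straight axis from the tip to the base along y = 0.
#' @param geometry A [root_hair_geometry()].
#' @param t Time, s.
#' @return An [axis_frame()].
#' @export
geometry_axis <- function(geometry, t = 0) {
  tip <- tip_at(geometry, t)
  axis_frame(cbind(x = c(tip, 0), y = c(0, 0)))
}

#' Arc-length distance below the tip
#'
#' Projects points onto the axis polyline and returns their arc-length
#' distance from the tip (>= 0; the tip itself maps to 0).
#'
#' @param axis An [axis_frame()].
#' @param x,y Coordinates, um (vectorized).
#' @return Numeric vector of distances, um.
#' @export
distance_below_tip <- function(axis, x, y) {
  p <- axis$points
  n_seg <- nrow(p) - 1
  out <- rep(Inf, length(x))
  arc <- numeric(length(x))
  best <- rep(Inf, length(x))
  for (s in seq_len(n_seg)) {
    a <- p[s, ]; b <- p[s + 1, ]
    ab <- b - a
    L2 <- sum(ab^2)
    tt <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / L2
    tt <- pmin(1, pmax(0, tt))
    px <- a[1] + tt * ab[1]
    py <- a[2] + tt * ab[2]
    d2 <- (x - px)^2 + (y - py)^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    arc[upd] <- axis$cum_len[s] + tt[upd] * sqrt(L2)
  }
  arc
}

#' Zone of points relative to the tip
#'
#' @param axis An [axis_frame()].
#' @param x,y Coordinates, um.
#' @param apical_length Apical zone length below the tip, um (default 10).
#' @return Character vector, `"apical"` or `"subapical"`.
#' @export
zone_of <- function(axis, x, y, apical_length = 10) {
  d <- distance_below_tip(axis, x, y)
  ifelse(d <= apical_length, "apical", "subapical")
}

#' Pixel-wise zone mask for a frame
#'
#' Labels every in-hair pixel apical (within `apical_length` of the tip
#' along the axis) or subapical (the rest of the hair), and flags the
#' tip-ROI (within `tip_roi_length` of the tip) used to define the counted
#' endosome population.
#'
#' @param frame_shape Integer vector `c(n_row, n_col)` of the image.
#' @param axis An [axis_frame()] in the image coordinate system.
#' @param pixel_size Pixel size, um/px.
#' @param apical_length Apical zone length, um (default 10).
#' @param tip_roi_length Tip-ROI length, um (default 30).
#' @param hair_mask Optional logical matrix marking in-hair pixels; when
#'   `NULL` all pixels are considered in-hair.
#' @param origin Physical coordinate (um) of the image corner before pixel
#'   (1,1), `c(x0, y0)`.
#' @return A `region_mask` object: list with `labels` (character matrix:
#'   "apical" / "subapical" / "outside"), `tip_roi` (logical matrix),
#'   `axis`, `apical_length`, `tip_roi_length`, `pixel_size`.
#' @export
make_zone_mask <- function(frame_shape, axis, pixel_size,
                           apical_length = 10, tip_roi_length = 30,
                           hair_mask = NULL, origin = c(0, 0)) {
  nr <- frame_shape[1]; nc <- frame_shape[2]
  xs <- origin[1] + (seq_len(nc) - 0.5) * pixel_size
  ys <- origin[2] + (seq_len(nr) - 0.5) * pixel_size
  xg <- matrix(xs, nr, nc, byrow = TRUE)
  yg <- matrix(ys, nr, nc)
  if (min(axis$points[, 1]) < min(xs) - pixel_size ||
      max(axis$points[, 1]) > max(xs) + pixel_size) {
    rlang::abort("axis polyline extends outside the frame")
  }
  d <- matrix(distance_below_tip(axis, as.vector(xg), as.vector(yg)), nr, nc)
  labels <- ifelse(d <= apical_length, "apical", "subapical")
  if (!is.null(hair_mask)) labels[!hair_mask] <- "outside"
  tip_roi <- d <= tip_roi_length
  if (!is.null(hair_mask)) tip_roi <- tip_roi & hair_mask
  structure(
    list(labels = labels, tip_roi = tip_roi, axis = axis,
         apical_length = apical_length, tip_roi_length = tip_roi_length,
         pixel_size = pixel_size, origin = origin),
    class = "region_mask"
  )
}

#' Root-hair growth rate from tip positions
#'
#' Least-squares linear fit of tip arc-length position against time;
#' the slope is reported in um/min. Standard acquisition for this
#' measurement is one frame per 60 s over 20 min.
#'
#' @param tip_positions Data frame with columns `t` (s) and `tip` (um), or
#'   two numeric vectors via `t`/`tip`.
#' @param t,tip Alternative vector interface.
#' @return A `growth_fit` object; `coef()`-style access via
#'   `$rate_um_min`, plus [generics::tidy()] and [generics::glance()]
#'   methods.
#' @export
#' @examples
#' gf <- growth_rate(tibble::tibble(t = 0:20 * 60, tip = 10 + 1.941 / 60 * (0:20 * 60)))
#' gf$rate_um_min
growth_rate <- function(tip_positions = NULL, t = NULL, tip = NULL) {
  if (!is.null(tip_positions)) {
    t <- tip_positions[["t"]]
    tip <- tip_positions[["tip"]]
  }
  if (length(t) < 2) rlang::abort("need at least 2 tip positions")
  if (any(diff(t) <= 0)) rlang::abort("sampling times must be strictly increasing")
  fit <- stats::lm(tip ~ t)
  rate <- unname(coef(fit)[2]) * 60
  structure(
    list(fit = fit, rate_um_min = rate, n = length(t),
         duration_s = max(t) - min(t)),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> rate:", signif(x$rate_um_min, 4), "um/min over",
      x$n, "time points (", x$duration_s, "s )\n")
  invisible(x)
}
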