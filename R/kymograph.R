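# Kymographs: intensity sampled along a polyline vs time; ridge tracing,
# steepest-slope speed extraction and movement classification.

bilinear_sample <- function(m, rx, cx) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(rx); c0 <- floor(cx)
  fr <- rx - r0; fc <- cx - c0
  r0 <- pmin(nr - 1L, pmax(1L, r0)); c0 <- pmin(nc - 1L, pmax(1L, c0))
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# Greedy piecewise-linear segmentation of a (t, s) series: segments grow
# while the least-squares residual RMS stays below rms_tol (um).
pwl_segments <- function(t, s, rms_tol = 0.26, min_pts = 5L) {
  n <- length(t)
  out <- list()
  i <- 1L
  while (i <= n - 1L) {
    St <- 0; Ss <- 0; Stt <- 0; Sts <- 0; Sss <- 0; k <- 0
    j <- i
    best_j <- i
    while (j <= n) {
      St <- St + t[j]; Ss <- Ss + s[j]
      Stt <- Stt + t[j]^2; Sts <- Sts + t[j] * s[j]; Sss <- Sss + s[j]^2
      k <- k + 1
      if (k >= 2) {
        vt <- Stt - St^2 / k
        if (vt > 0) {
          b <- (Sts - St * Ss / k) / vt
          sse <- Sss - Ss^2 / k - b^2 * vt
          rms <- sqrt(max(0, sse) / k)
          if (rms > rms_tol && k >= max(3L, min_pts)) break
        }
      }
      best_j <- j
      j <- j + 1L
    }
    ii <- i:best_j
    k2 <- length(ii)
    if (k2 >= 2) {
      tt <- t[ii] - mean(t[ii]); ss <- s[ii]
      vt <- sum(tt^2)
      slope <- if (vt > 0) sum(tt * ss) / vt else 0
      fitted <- mean(ss) + slope * tt
      rms <- sqrt(mean((ss - fitted)^2))
      out[[length(out) + 1L]] <- tibble::tibble(
        t_start = t[ii[1]], t_end = t[ii[k2]],
        n_pts = k2, slope = slope,
        extent = abs(s[ii[k2]] - s[ii[1]]), rms = rms)
    }
    if (best_j >= n) break
    i <- best_j
  }
  if (!length(out)) {
    return(tibble::tibble(t_start = numeric(), t_end = numeric(),
                          n_pts = integer(), slope = numeric(),
                          extent = numeric(), rms = numeric()))
  }
  purrr::list_rbind(out)
}

#' Build a kymograph along a polyline
#'
#' Each column is the image intensity sampled (bilinear) along the
#' rasterized polyline, one column per frame; for line widths above 1 px
#' the intensity is averaged across the width perpendicular to the line.
#' The sampling step along the line is one pixel.
#'
#' @param stack An `image_stack`.
#' @param line Polyline in um (matrix/data frame with columns x, y) in
#'   the stack's coordinate system.
#' @param width Line width in px (odd; default 1).
#' @return A `kymograph` object: list with `values` (distance x time),
#'   `distance` (um along the line), `times` (s), `pixel_size`,
#'   `frame_interval`, `line`, `width`.
#' @export
build_kymograph <- function(stack, line, width = 1L) {
  if (width %% 2 == 0) rlang::abort("line width must be odd")
  px <- attr(stack, "pixel_size") %||% 1
  dt <- attr(stack, "frame_interval") %||% 1
  origin <- attr(stack, "origin") %||% c(0, 0)
  p <- as.matrix(line)[, 1:2, drop = FALSE]
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nt <- dim(stack)[3]
  lim_x <- origin[1] + c(0, nc * px)
  lim_y <- origin[2] + c(0, nr * px)
  bad <- p[, 1] < lim_x[1] | p[, 1] > lim_x[2] |
         p[, 2] < lim_y[1] | p[, 2] > lim_y[2]
  if (any(bad)) {
    rlang::abort(paste0("line exits the image at (",
                        paste(signif(p[which(bad)[1], ], 4), collapse = ", "),
                        ") um"))
  }
  # rasterize at one-pixel steps
  seg <- diff(p)
  seg_len <- sqrt(rowSums(seg^2))
  arc <- c(0, cumsum(seg_len))
  total <- sum(seg_len)
  s_steps <- seq(0, total, by = px)
  pts <- vapply(s_steps, function(s) {
    k <- max(1L, findInterval(s, arc, rightmost.closed = TRUE))
    k <- min(k, nrow(seg))
    f <- (s - arc[k]) / seg_len[k]
    p[k, ] + f * seg[k, ]
  }, numeric(2))
  pts <- t(pts)
  # unit normals per sample
  dirs <- vapply(s_steps, function(s) {
    k <- min(max(1L, findInterval(s, arc, rightmost.closed = TRUE)), nrow(seg))
    seg[k, ] / seg_len[k]
  }, numeric(2))
  dirs <- t(dirs)
  normals <- cbind(-dirs[, 2], dirs[, 1])
  offs <- (seq_len(width) - (width + 1) / 2) * px
  vals <- matrix(0, length(s_steps), nt)
  for (k in seq_len(nt)) {
    m <- stack[, , k]
    acc <- 0
    for (o in offs) {
      qx <- pts[, 1] + o * normals[, 1]
      qy <- pts[, 2] + o * normals[, 2]
      cxp <- (qx - origin[1]) / px + 0.5
      ryp <- (qy - origin[2]) / px + 0.5
      if (width == 1L) {
        acc <- acc + m[cbind(pmin(nr, pmax(1L, round(ryp))),
                             pmin(nc, pmax(1L, round(cxp))))]
      } else {
        acc <- acc + bilinear_sample(m, ryp, cxp)
      }
    }
    vals[, k] <- acc / width
  }
  structure(list(values = vals, distance = s_steps,
                 times = (seq_len(nt) - 1) * dt, pixel_size = px,
                 frame_interval = dt, line = p, width = width),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat("<kymograph>", nrow(x$values), "positions x", ncol(x$values),
      "frames,", signif(max(x$distance), 4), "um along line\n")
  invisible(x)
}

#' Trace ridge lines in a kymograph
#'
#' Per-column local maxima above an adaptive background threshold
#' (median + 4 MAD by default) are linked greedily across columns
#' (nearest neighbour within `max_jump` px, gaps up to 2 columns).
#'
#' @param k A `kymograph`.
#' @param max_jump Maximum ridge displacement between columns, px.
#' @param thresh Absolute intensity threshold; `NULL` = median + 4 MAD.
#' @param min_cols Minimum ridge length in columns.
#' @return List of tibbles (t, d_um) — one per ridge.
#' @export
trace_ridges <- function(k, max_jump = 6, thresh = NULL, min_cols = 5L) {
  v <- k$values
  if (is.null(thresh)) {
    thresh <- stats::median(v) + 4 * stats::mad(v)
  }
  nper <- ncol(v)
  maxima <- purrr::map(seq_len(nper), function(j) {
    col <- v[, j]
    n <- length(col)
    if (n < 3) return(integer(0))
    idx <- which(col[2:(n - 1)] >= col[1:(n - 2)] &
                 col[2:(n - 1)] >= col[3:n] &
                 col[2:(n - 1)] > thresh) + 1L
    idx
  })
  ridges <- list()       # finished
  active <- list()       # each: list(rows, cols, last_row, last_col)
  for (j in seq_len(nper)) {
    mx <- maxima[[j]]
    used <- rep(FALSE, length(mx))
    if (length(active)) {
      ord <- order(vapply(active, function(a) -a$last_col, numeric(1)))
      for (ai in ord) {
        a <- active[[ai]]
        if (j - a$last_col > 3L) next
        cand <- which(!used & abs(mx - a$last_row) <= max_jump * (j - a$last_col))
        if (!length(cand)) next
        pick <- cand[which.min(abs(mx[cand] - a$last_row))]
        used[pick] <- TRUE
        a$rows <- c(a$rows, mx[pick]); a$cols <- c(a$cols, j)
        a$last_row <- mx[pick]; a$last_col <- j
        active[[ai]] <- a
      }
    }
    # retire stale ridges
    if (length(active)) {
      stale <- vapply(active, function(a) j - a$last_col > 3L, logical(1))
      ridges <- c(ridges, active[stale])
      active <- active[!stale]
    }
    for (ii in which(!used)) {
      active[[length(active) + 1L]] <-
        list(rows = mx[ii], cols = j, last_row = mx[ii], last_col = j)
    }
  }
  ridges <- c(ridges, active)
  ridges <- purrr::keep(ridges, ~ length(.x$cols) >= min_cols)
  purrr::map(ridges, function(a) {
    tibble::tibble(t = k$times[a$cols], d_um = k$distance[a$rows])
  })
}

#' Maximum speed from a kymograph
#'
#' Ridge lines are traced, each ridge is fitted piecewise-linearly, and
#' the maximum absolute segment slope is returned in um/s. A purely
#' vertical (stationary) ridge yields 0; a featureless kymograph yields
#' `NA`.
#'
#' @param k A `kymograph` (>= 5 columns).
#' @param max_jump Ridge-linking jump limit, px per column.
#' @param min_extent Minimum spatial extent (um) of a segment to count
#'   as movement.
#' @return Maximum speed, um/s (NA if no ridge found).
#' @export
max_speed_from_kymograph <- function(k, max_jump = 6, min_extent = 0.5) {
  if (ncol(k$values) < 5) rlang::abort("kymograph needs at least 5 columns")
  ridges <- trace_ridges(k, max_jump = max_jump)
  if (!length(ridges)) return(NA_real_)
  best <- 0
  for (r in ridges) {
    seg <- pwl_segments(r$t, r$d_um, rms_tol = 1.5 * k$pixel_size, min_pts = 5L)
    if (!nrow(seg)) next
    seg <- seg[seg$extent >= min_extent, , drop = FALSE]
    if (nrow(seg)) best <- max(best, max(abs(seg$slope)))
  }
  best
}

#' Classify movement from a kymograph
#'
#' A ridge segment qualifies as continuous movement when its straight-
#' line fit residual is below 1 px RMS and its spatial extent is at least
#' `continuous_min_length` (default 15 um). The kymograph is labelled
#' continuous if any segment qualifies.
#'
#' @param k A `kymograph`.
#' @param continuous_min_length Minimum straight-run extent, um.
#' @param max_jump Ridge-linking jump limit, px per column.
#' @return Tibble: label ("continuous"/"discontinuous"),
#'   qualifying_run_length (um; longest straight run).
#' @export
classify_movement <- function(k, continuous_min_length = 15, max_jump = 6) {
  ridges <- trace_ridges(k, max_jump = max_jump)
  run <- classify_runs(purrr::map(ridges, ~ list(t = .x$t, s = .x$d_um)),
                       k$pixel_size)
  tibble::tibble(
    label = if (run >= continuous_min_length) "continuous" else "discontinuous",
    qualifying_run_length = run)
}

# longest straight (rms < 1 px) run over a list of (t, s) traces
classify_runs <- function(traces, pixel_size) {
  best <- 0
  for (r in traces) {
    seg <- pwl_segments(r$t, r$s, rms_tol = pixel_size, min_pts = 5L)
    ok <- seg$extent[seg$rms < pixel_size]
    if (length(ok)) best <- max(best, ok)
  }
  best
}

#' Classify a track's movement pattern
#'
#' Applies the kymograph continuous/discontinuous criterion to a
#' trajectory's axial position series (the trajectory is its own ridge
#' trace in (distance-below-tip, time) space).
#'
#' @param track Track tibble rows for one track.
#' @param axis An [axis_frame()].
#' @param continuous_min_length Minimum straight-run extent, um.
#' @param pixel_size Residual tolerance scale (1 px), um.
#' @return Tibble: label, qualifying_run_length.
#' @export
classify_track_movement <- function(track, axis, continuous_min_length = 15,
                                    pixel_size = 0.26) {
  tr <- dplyr::arrange(tibble::as_tibble(track), .data$frame)
  s_pos <- distance_below_tip(axis, tr$x_um, tr$y_um)
  run <- classify_runs(list(list(t = tr$t, s = s_pos)), pixel_size)
  tibble::tibble(
    label = if (run >= continuous_min_length) "continuous" else "discontinuous",
    qualifying_run_length = run)
}
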