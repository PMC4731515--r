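# Frame-to-frame optimal-assignment linking, gap closing, path-length
# filtering, speed profiles and stop/go segmentation.

#' Linking parameters
#'
#' @param max_displacement Maximum displacement per frame, um (gate for
#'   the assignment).
#' @param max_gap Maximum number of missed frames closed by linear
#'   interpolation (interpolated spots are flagged `inferred` and are
#'   excluded from intensity-based analyses).
#' @param min_path_length Minimum trajectory path length, um; shorter
#'   trajectories are excluded (default 5 um).
#' @param filter_on `"path_length"` (default; matches filtering whole
#'   trajectories) or `"net_displacement"`.
#' @return A `linking_params` list.
#' @export
linking_params <- function(max_displacement = 2, max_gap = 1,
                           min_path_length = 5,
                           filter_on = c("path_length", "net_displacement")) {
  if (max_displacement <= 0) rlang::abort("max_displacement must be positive")
  if (max_gap < 0) rlang::abort("max_gap must be >= 0")
  if (min_path_length < 0) rlang::abort("min_path_length must be >= 0")
  structure(list(max_displacement = max_displacement, max_gap = max_gap,
                 min_path_length = min_path_length,
                 filter_on = match.arg(filter_on)),
            class = "linking_params")
}

#' Link spots into trajectories
#'
#' Frame-to-frame assignment minimizing total squared displacement
#' (optimal bipartite assignment, Jonker-Volgenant) subject to the
#' `max_displacement` gate; unmatched spots start or end tracks. Track
#' ends are then joined to later track starts across gaps of up to
#' `max_gap` frames (greedy ascending-displacement matching, gate scaled
#' by the gap length), with missing frames filled by linear interpolation
#' flagged `inferred`.
#'
#' @param spots Spot tibble ([dog_detect()] format: frame, t, x_um, y_um,
#'   intensity, ...).
#' @param params A [linking_params()].
#' @return Track tibble: track_id, frame, t, x_um, y_um, intensity,
#'   inferred.
#' @export
link_spots <- function(spots, params = linking_params()) {
  empty <- tibble::tibble(track_id = integer(), frame = integer(),
                          t = numeric(), x_um = numeric(), y_um = numeric(),
                          intensity = numeric(), inferred = logical())
  s <- tibble::as_tibble(spots)
  if (!nrow(s)) return(empty)
  if (!"intensity" %in% names(s)) s$intensity <- NA_real_
  s <- dplyr::arrange(s, .data$frame)
  s$track_id <- NA_integer_
  frames <- sort(unique(s$frame))
  gate <- params$max_displacement^2
  next_id <- 1L
  idx_by_frame <- split(seq_len(nrow(s)), s$frame)
  prev_idx <- idx_by_frame[[as.character(frames[1])]]
  s$track_id[prev_idx] <- seq_along(prev_idx)
  next_id <- length(prev_idx) + 1L
  for (fi in seq_along(frames)[-1]) {
    cur_idx <- idx_by_frame[[as.character(frames[fi])]]
    contiguous <- frames[fi] == frames[fi - 1] + 1L
    if (contiguous && length(prev_idx) && length(cur_idx)) {
      dx <- outer(s$x_um[prev_idx], s$x_um[cur_idx], "-")
      dy <- outer(s$y_um[prev_idx], s$y_um[cur_idx], "-")
      cost <- dx^2 + dy^2
      m <- lap_match_gated(cost, gate)
      for (i in seq_along(prev_idx)) {
        if (!is.na(m[i])) s$track_id[cur_idx[m[i]]] <- s$track_id[prev_idx[i]]
      }
    }
    new <- cur_idx[is.na(s$track_id[cur_idx])]
    if (length(new)) {
      s$track_id[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  s$inferred <- FALSE
  if (params$max_gap > 0) s <- close_gaps(s, params)
  out <- dplyr::arrange(
    dplyr::select(s, "track_id", "frame", "t", "x_um", "y_um",
                  "intensity", "inferred"),
    .data$track_id, .data$frame)
  tibble::as_tibble(out)
}

# Join track ends to later track starts across short gaps.
close_gaps <- function(s, params) {
  repeat {
    info <- dplyr::summarise(
      dplyr::group_by(s, .data$track_id),
      f0 = min(.data$frame), f1 = max(.data$frame),
      x0 = .data$x_um[which.min(.data$frame)],
      y0 = .data$y_um[which.min(.data$frame)],
      x1 = .data$x_um[which.max(.data$frame)],
      y1 = .data$y_um[which.max(.data$frame)],
      .groups = "drop")
    ends <- info; starts <- info
    cand <- tidyr::crossing(e = seq_len(nrow(ends)), b = seq_len(nrow(starts)))
    cand <- dplyr::filter(
      cand,
      starts$f0[.data$b] - ends$f1[.data$e] - 1L >= 1L,
      starts$f0[.data$b] - ends$f1[.data$e] - 1L <= params$max_gap)
    if (!nrow(cand)) return(s)
    gap_n <- starts$f0[cand$b] - ends$f1[cand$e]
    d2 <- (starts$x0[cand$b] - ends$x1[cand$e])^2 +
          (starts$y0[cand$b] - ends$y1[cand$e])^2
    lim2 <- (params$max_displacement * gap_n)^2
    cand <- cand[d2 <= lim2, , drop = FALSE]
    d2 <- d2[d2 <= lim2]
    if (!nrow(cand)) return(s)
    # greedy matching by ascending displacement
    ord <- order(d2)
    changed <- FALSE
    touched <- integer(0)
    for (ci in ord) {
      ei <- cand$e[ci]; bi <- cand$b[ci]
      e_id <- info$track_id[ei]; b_id <- info$track_id[bi]
      if (e_id == b_id || e_id %in% touched || b_id %in% touched) next
      touched <- c(touched, e_id, b_id)
      f1 <- info$f1[ei]; f0 <- info$f0[bi]
      dt_per <- (s$t[s$track_id == b_id & s$frame == f0] -
                 s$t[s$track_id == e_id & s$frame == f1]) / (f0 - f1)
      miss <- seq(f1 + 1L, f0 - 1L)
      frac <- (miss - f1) / (f0 - f1)
      fill <- tibble::tibble(
        frame = miss,
        t = s$t[s$track_id == e_id & s$frame == f1] + (miss - f1) * dt_per,
        x_um = info$x1[ei] + frac * (info$x0[bi] - info$x1[ei]),
        y_um = info$y1[ei] + frac * (info$y0[bi] - info$y1[ei]),
        intensity = NA_real_, track_id = e_id, inferred = TRUE)
      s <- dplyr::bind_rows(s, fill)
      s$track_id[s$track_id == b_id] <- e_id
      changed <- TRUE
    }
    if (!changed) return(s)
  }
}

#' Per-track summaries
#'
#' @param tracks Track tibble from [link_spots()].
#' @param axis Optional [axis_frame()]; when given, `max_speed` is the
#'   steepest piecewise-linear slope of the track's axial position (the
#'   kymograph-ridge estimator), otherwise a windowed-regression velocity
#'   maximum is used.
#' @param window Regression window (frames) for the windowed estimator.
#' @return Tibble: track_id, n_spots, t_start, t_end, path_length,
#'   net_displacement, max_speed, mean_speed.
#' @export
track_summary <- function(tracks, axis = NULL, window = 5L) {
  tr <- dplyr::arrange(tibble::as_tibble(tracks), .data$track_id, .data$frame)
  if (!nrow(tr)) {
    return(tibble::tibble(track_id = integer(), n_spots = integer(),
                          t_start = numeric(), t_end = numeric(),
                          path_length = numeric(),
                          net_displacement = numeric(),
                          max_speed = numeric(), mean_speed = numeric()))
  }
  dplyr::summarise(
    dplyr::group_by(tr, .data$track_id),
    n_spots = dplyr::n(),
    t_start = min(.data$t), t_end = max(.data$t),
    path_length = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
    net_displacement = sqrt((dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
                            (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2),
    max_speed = track_max_speed(.data$t, .data$x_um, .data$y_um,
                                axis = axis, window = window),
    mean_speed = {
      dtt <- diff(.data$t)
      if (length(dtt)) mean(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2) / dtt)
      else NA_real_
    },
    .groups = "drop")
}

# Maximum speed of one trajectory. With an axis frame the trajectory is
# projected to arc-length position and segmented piecewise-linearly (the
# same estimator used on kymograph ridges); otherwise speed is the
# magnitude of a windowed least-squares velocity.
track_max_speed <- function(t, x, y, axis = NULL, window = 5L) {
  n <- length(t)
  if (n < 2) return(NA_real_)
  if (!is.null(axis)) {
    s_pos <- distance_below_tip(axis, x, y)
    seg <- pwl_segments(t, s_pos, rms_tol = 0.26, min_pts = max(3L, window))
    if (!nrow(seg)) return(0)
    return(max(abs(seg$slope)))
  }
  if (n < window + 1) {
    return(max(sqrt(diff(x)^2 + diff(y)^2) / diff(t)))
  }
  sp <- vapply(seq_len(n - window + 1L), function(i) {
    ii <- i:(i + window - 1L)
    tt <- t[ii] - mean(t[ii])
    den <- sum(tt^2)
    vx <- sum(tt * x[ii]) / den
    vy <- sum(tt * y[ii]) / den
    sqrt(vx^2 + vy^2)
  }, numeric(1))
  max(sp)
}

#' Filter tracks by trajectory length
#'
#' Retains tracks whose path length (or net displacement, see
#' [linking_params()]) is at least `min_path_length`; the count of
#' removed tracks is attached as attribute `n_removed`. Idempotent.
#'
#' @param tracks Track tibble.
#' @param params A [linking_params()].
#' @return Filtered track tibble.
#' @export
filter_tracks <- function(tracks, params = linking_params()) {
  tr <- tibble::as_tibble(tracks)
  if (!nrow(tr)) {
    attr(tr, "n_removed") <- 0L
    return(tr)
  }
  su <- track_summary(tr)
  metric <- if (params$filter_on == "path_length") su$path_length
            else su$net_displacement
  keep_ids <- su$track_id[metric >= params$min_path_length]
  out <- dplyr::filter(tr, .data$track_id %in% keep_ids)
  attr(out, "n_removed") <- nrow(su) - length(keep_ids)
  out
}

#' Frame-to-frame speed profile of one track
#'
#' @param track Track tibble rows for a single track (>= 2 spots).
#' @return Tibble (t, speed): speed over each consecutive frame pair,
#'   stamped at the interval end time.
#' @export
speed_profile <- function(track) {
  tr <- dplyr::arrange(tibble::as_tibble(track), .data$frame)
  if (nrow(tr) < 2) rlang::abort("speed profile needs at least 2 spots")
  if (length(unique(tr$track_id)) > 1) {
    rlang::abort("speed_profile expects a single track")
  }
  dtt <- diff(tr$t)
  tibble::tibble(t = tr$t[-1],
                 speed = sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / dtt)
}

#' Segment a speed profile into stop and go phases
#'
#' Contiguous runs with speed below `v_stop` lasting at least `min_phase`
#' are labelled stop; everything else is go. The phases partition the
#' profile's time span.
#'
#' @param profile Tibble (t, speed) from [speed_profile()].
#' @param v_stop Stop-phase speed cutoff, um/s (default 0.5).
#' @param min_phase Minimum stop-phase duration, s (default 0.3).
#' @return Tibble: phase ("stop"/"go"), t_start, t_end.
#' @export
segment_stop_go <- function(profile, v_stop = 0.5, min_phase = 0.3) {
  pr <- tibble::as_tibble(profile)
  if (!nrow(pr)) rlang::abort("empty speed profile")
  slow <- pr$speed < v_stop
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  t0 <- if (nrow(pr) >= 2) pr$t[1] - (pr$t[2] - pr$t[1]) else pr$t[1]
  seg_start <- ifelse(starts == 1L, t0, pr$t[pmax(1L, starts - 1L)])
  seg_end <- pr$t[ends]
  lab <- ifelse(r$values & (seg_end - seg_start) >= min_phase, "stop", "go")
  out <- tibble::tibble(phase = lab, t_start = seg_start, t_end = seg_end)
  # merge adjacent phases with equal labels
  if (nrow(out) > 1) {
    grp <- cumsum(c(TRUE, out$phase[-1] != out$phase[-nrow(out)]))
    out <- dplyr::summarise(dplyr::group_by(out, grp = grp),
                            phase = dplyr::first(.data$phase),
                            t_start = min(.data$t_start),
                            t_end = max(.data$t_end), .groups = "drop")
    out$grp <- NULL
  }
  out
}
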