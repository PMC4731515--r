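# Pairwise endosome interactions: dancing (transient synchronized
# close-range movement) and clustering/fusion (track merge with a
# sustained summed-intensity increase).

#' Interaction detection parameters
#'
#' @param d_interact Physical-interaction distance, um (default 1.0).
#' @param d_dance Outer synchrony envelope for dancing windows, um
#'   (default 2.0).
#' @param min_dance_duration Minimum dancing duration, s (default 5;
#'   deliberately below the observed 10-35 s range so the range is a
#'   measured output, not a prior).
#' @param sync_min Minimum displacement synchrony (Pearson correlation of
#'   displacement vectors pooled over x and y), default 0.5.
#' @param sync_lag Time lag over which synchrony displacements are taken,
#'   s (default 0.3; longer lags suppress localization noise).
#' @param fusion_persistence Minimum duration of the sustained intensity
#'   increase for clustering/fusion, s (default 20).
#' @param fusion_intensity_ratio_tol Relative tolerance on the
#'   product-vs-member-sum intensity match (default 0.3).
#' @return An `interaction_params` list.
#' @export
interaction_params <- function(d_interact = 1, d_dance = 2,
                               min_dance_duration = 5, sync_min = 0.5,
                               sync_lag = 0.3, fusion_persistence = 20,
                               fusion_intensity_ratio_tol = 0.3) {
  if (d_interact > d_dance) rlang::abort("d_interact must be <= d_dance")
  if (min_dance_duration <= 0) rlang::abort("min_dance_duration must be > 0")
  if (fusion_persistence <= 0) rlang::abort("fusion_persistence must be > 0")
  structure(list(d_interact = d_interact, d_dance = d_dance,
                 min_dance_duration = min_dance_duration,
                 sync_min = sync_min, sync_lag = sync_lag,
                 fusion_persistence = fusion_persistence,
                 fusion_intensity_ratio_tol = fusion_intensity_ratio_tol),
            class = "interaction_params")
}

#' Distance between two tracks over their common frames
#'
#' @param tracks Track tibble.
#' @param pair Two track ids.
#' @return Tibble (frame, t, distance): Euclidean distance between the
#'   sub-pixel positions at each common frame.
#' @export
pairwise_distance_series <- function(tracks, pair) {
  tr <- tibble::as_tibble(tracks)
  a <- dplyr::filter(tr, .data$track_id == pair[1])
  b <- dplyr::filter(tr, .data$track_id == pair[2])
  j <- dplyr::inner_join(a, b, by = "frame", suffix = c("_a", "_b"))
  if (nrow(j) < 2) rlang::abort("tracks share fewer than 2 frames")
  j <- dplyr::arrange(j, .data$frame)
  tibble::tibble(frame = j$frame, t = j$t_a,
                 distance = sqrt((j$x_um_a - j$x_um_b)^2 +
                                 (j$y_um_a - j$y_um_b)^2))
}

# Pooled Pearson correlation of displacement vectors of two aligned
# position series. Displacements are taken over `lag` frames (~0.3 s)
# rather than single frames so that localization noise does not swamp
# the common motion signal.
displacement_sync <- function(xa, ya, xb, yb, lag = 3L) {
  lag <- max(1L, min(lag, length(xa) - 2L))
  da <- c(diff(xa, lag = lag), diff(ya, lag = lag))
  db <- c(diff(xb, lag = lag), diff(yb, lag = lag))
  if (length(da) < 4 || stats::sd(da) == 0 || stats::sd(db) == 0) return(NA_real_)
  stats::cor(da, db)
}

# Sustained summed-intensity increase check used to route candidate
# windows to fusion rather than dancing: TRUE if the combined intensity
# stays >= (1 + tol) x the pre-window baseline for at least
# `persistence` seconds within the window.
sustained_intensity_increase <- function(t, inten_sum, baseline, tol,
                                         persistence) {
  if (!length(t) || is.na(baseline) || baseline <= 0) return(FALSE)
  high <- inten_sum >= (1 + tol) * baseline
  if (!any(high)) return(FALSE)
  r <- rle(high)
  ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1) + 1L)
  dur <- t[ends] - t[starts]
  any(r$values & dur >= persistence)
}

#' Detect dancing-endosome events
#'
#' For every overlapping track pair, finds maximal windows in which the
#' pair distance stays at or below `d_dance`, the displacement synchrony
#' over the window is at least `sync_min`, and the window lasts at least
#' `min_dance_duration`. Windows whose combined intensity shows a
#' sustained (>= `fusion_persistence`) increase are routed to
#' clustering/fusion and are not dancing. A physical interaction is
#' flagged when the distance stays below `d_interact` for at least 1 s.
#'
#' @param tracks Track tibble (calibrated, um).
#' @param params An [interaction_params()].
#' @param axis Optional [axis_frame()] for zone assignment (zone of the
#'   mean member position at window start).
#' @param apical_length Apical zone length, um.
#' @return Tibble of events: event_id, type, track_a, track_b, t_start,
#'   t_end, min_distance, sync_score, physical_interaction, zone.
#' @export
detect_dancing <- function(tracks, params = interaction_params(),
                           axis = NULL, apical_length = 10) {
  tr <- dplyr::arrange(tibble::as_tibble(tracks), .data$track_id, .data$frame)
  ids <- unique(tr$track_id)
  out <- list()
  if (length(ids) >= 2) {
    by_id <- split(tr, tr$track_id)
    # candidate pairs: bounding boxes closer than d_dance
    bb <- dplyr::summarise(dplyr::group_by(tr, .data$track_id),
                           x0 = min(.data$x_um), x1 = max(.data$x_um),
                           y0 = min(.data$y_um), y1 = max(.data$y_um),
                           f0 = min(.data$frame), f1 = max(.data$frame),
                           .groups = "drop")
    for (i in seq_along(ids)[-length(ids)]) {
      for (jj in (i + 1):length(ids)) {
        bi <- bb[i, ]; bj <- bb[jj, ]
        if (bi$f1 < bj$f0 || bj$f1 < bi$f0) next
        gx <- max(bi$x0, bj$x0) - min(bi$x1, bj$x1)
        gy <- max(bi$y0, bj$y0) - min(bi$y1, bj$y1)
        if (max(gx, 0)^2 + max(gy, 0)^2 > params$d_dance^2) next
        a <- by_id[[as.character(ids[i])]]
        b <- by_id[[as.character(ids[jj])]]
        m <- dplyr::inner_join(a, b, by = "frame", suffix = c("_a", "_b"))
        if (nrow(m) < 3) next
        m <- dplyr::arrange(m, .data$frame)
        d <- sqrt((m$x_um_a - m$x_um_b)^2 + (m$y_um_a - m$y_um_b)^2)
        close <- d <= params$d_dance
        if (!any(close)) next
        r <- rle(close)
        ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1) + 1L)
        for (w in which(r$values)) {
          ii <- starts[w]:ends[w]
          dur <- m$t_a[ii[length(ii)]] - m$t_a[ii[1]]
          if (dur < params$min_dance_duration) next
          lag <- max(1L, round(params$sync_lag /
                               max(stats::median(diff(m$t_a)), 1e-9)))
          sync <- displacement_sync(m$x_um_a[ii], m$y_um_a[ii],
                                    m$x_um_b[ii], m$y_um_b[ii], lag = lag)
          if (is.na(sync) || sync < params$sync_min) next
          # fusion routing: sustained combined-intensity increase
          isum <- m$intensity_a[ii] + m$intensity_b[ii]
          pre <- which(m$frame < m$frame[ii[1]])
          baseline <- if (length(pre)) {
            stats::median(m$intensity_a[pre] + m$intensity_b[pre], na.rm = TRUE)
          } else stats::median(isum[seq_len(max(1, min(5, length(isum))))],
                               na.rm = TRUE)
          if (!all(is.na(isum)) &&
              sustained_intensity_increase(m$t_a[ii], isum, baseline,
                                           params$fusion_intensity_ratio_tol,
                                           params$fusion_persistence)) next
          # a dancing event must come within the physical-interaction
          # distance at some time
          if (min(d[ii]) >= params$d_interact) next
          phys_frames <- d[ii] < params$d_interact
          phys <- {
            rr <- rle(phys_frames)
            ee <- cumsum(rr$lengths); ss <- c(1L, head(ee, -1) + 1L)
            any(rr$values & (m$t_a[ii][ee] - m$t_a[ii][ss]) >= 1)
          }
          zone <- if (!is.null(axis)) {
            zone_of(axis, mean(c(m$x_um_a[ii[1]], m$x_um_b[ii[1]])),
                    mean(c(m$y_um_a[ii[1]], m$y_um_b[ii[1]])), apical_length)
          } else NA_character_
          out[[length(out) + 1L]] <- tibble::tibble(
            type = "dancing", track_a = ids[i], track_b = ids[jj],
            t_start = m$t_a[ii[1]], t_end = m$t_a[ii[length(ii)]],
            min_distance = min(d[ii]), sync_score = sync,
            physical_interaction = phys, zone = zone)
        }
      }
    }
  }
  res <- if (length(out)) purrr::list_rbind(out) else
    tibble::tibble(type = character(), track_a = integer(),
                   track_b = integer(), t_start = numeric(),
                   t_end = numeric(), min_distance = numeric(),
                   sync_score = numeric(), physical_interaction = logical(),
                   zone = character())
  dplyr::mutate(res, event_id = dplyr::row_number(), .before = 1)
}

#' Detect clustering/fusion events
#'
#' Looks for track-merge topology: a track ending within `d_interact` of
#' a track that continues (or starts) at the next frames, where the
#' continuing track's intensity matches the summed pre-merge member
#' intensities within `fusion_intensity_ratio_tol` and the increase is
#' sustained for at least `fusion_persistence` seconds. Pre-merge
#' intensities are medians over the ~3 s before the merge excluding the
#' last second (where the detection windows already overlap);
#' `intensity_ratio` is the sustained product intensity relative to the
#' first member's pre-merge intensity.
#'
#' @param tracks Track tibble with per-spot intensities (interpolated
#'   spots are excluded from the intensity measurements).
#' @param params An [interaction_params()].
#' @param axis Optional [axis_frame()] for zone assignment.
#' @param apical_length Apical zone length, um.
#' @return Tibble of events: event_id, type, track_a, track_b,
#'   product_track, t_start, t_end, intensity_ratio, zone. `track_b` is
#'   the merge partner (which may continue as `product_track`).
#' @export
detect_cluster_fusion <- function(tracks, params = interaction_params(),
                                  axis = NULL, apical_length = 10) {
  tr <- dplyr::arrange(tibble::as_tibble(tracks), .data$track_id, .data$frame)
  if (!"inferred" %in% names(tr)) tr$inferred <- FALSE
  empty <- tibble::tibble(event_id = integer(), type = character(),
                          track_a = integer(), track_b = integer(),
                          product_track = integer(), t_start = numeric(),
                          t_end = numeric(), intensity_ratio = numeric(),
                          zone = character())
  if (!nrow(tr)) return(empty)
  su <- dplyr::summarise(dplyr::group_by(tr, .data$track_id),
                         f0 = min(.data$frame), f1 = max(.data$frame),
                         .groups = "drop")
  last_frame <- max(tr$frame)
  dt_med <- stats::median(diff(sort(unique(tr$t))))
  by_id <- split(tr, tr$track_id)
  pre_int <- function(id, f_ref) {
    d <- by_id[[as.character(id)]]
    sel <- d$frame < f_ref - round(1 / dt_med) &
           d$frame >= f_ref - round(3 / dt_med) & !d$inferred
    if (!any(sel)) sel <- d$frame < f_ref & !d$inferred
    stats::median(d$intensity[sel], na.rm = TRUE)
  }
  out <- list()
  used_members <- integer(0)
  enders <- su[su$f1 < last_frame, ]
  for (k in seq_len(nrow(enders))) {
    id_a <- enders$track_id[k]
    if (id_a %in% used_members) next
    a <- by_id[[as.character(id_a)]]
    fe <- enders$f1[k]
    ax <- a$x_um[a$frame == fe]; ay <- a$y_um[a$frame == fe]
    # partner: any other track alive at fe+1 within d_interact
    nxt <- dplyr::filter(tr, .data$frame == fe + 1L, .data$track_id != id_a)
    if (!nrow(nxt)) next
    dd <- sqrt((nxt$x_um - ax)^2 + (nxt$y_um - ay)^2)
    if (min(dd) > params$d_interact) next
    id_p <- nxt$track_id[which.min(dd)]
    p <- by_id[[as.character(id_p)]]
    p_f0 <- min(p$frame)
    continuing <- p_f0 <= fe
    id_b <- id_p
    # member intensities before the merge
    i_a <- pre_int(id_a, fe + 1L)
    i_b <- if (continuing) pre_int(id_p, fe + 1L) else {
      # product is a new track: second member must also end here, nearby
      cand <- su[su$f1 >= fe - 1L & su$f1 <= fe &
                 su$track_id != id_a & su$track_id != id_p, ]
      found <- NA_integer_
      for (cid in cand$track_id) {
        cdat <- by_id[[as.character(cid)]]
        cx <- cdat$x_um[which.max(cdat$frame)]
        cy <- cdat$y_um[which.max(cdat$frame)]
        if (sqrt((cx - ax)^2 + (cy - ay)^2) <= 2 * params$d_interact) {
          found <- cid; break
        }
      }
      if (is.na(found)) next
      id_b <- found
      pre_int(found, fe + 1L)
    }
    if (is.na(i_a) || is.na(i_b)) next
    # product intensity sustained over the persistence window
    post <- dplyr::filter(p, .data$frame > fe, !.data$inferred)
    if (!nrow(post)) next
    t_merge <- min(post$t)
    span <- max(post$t) - t_merge
    if (span < params$fusion_persistence) next
    win <- dplyr::filter(post, .data$t <= t_merge + params$fusion_persistence)
    i_post <- stats::median(win$intensity, na.rm = TRUE)
    tol <- params$fusion_intensity_ratio_tol
    if (is.na(i_post) || i_post < (1 - tol) * (i_a + i_b) ||
        i_post > (1 + tol) * (i_a + i_b)) next
    ref <- if (id_a < id_b) i_a else i_b
    zone <- if (!is.null(axis)) {
      zone_of(axis, ax, ay, apical_length)
    } else NA_character_
    used_members <- c(used_members, id_a, id_b)
    out[[length(out) + 1L]] <- tibble::tibble(
      type = "cluster_fusion", track_a = min(id_a, id_b),
      track_b = max(id_a, id_b), product_track = id_p,
      t_start = t_merge, t_end = max(post$t),
      intensity_ratio = i_post / ref, zone = zone)
  }
  res <- if (length(out)) purrr::list_rbind(out) else empty[, -1]
  dplyr::mutate(res, event_id = dplyr::row_number(), .before = 1)
}

#' Classify the tracked population
#'
#' Labels every track `clustered` if it participates in any
#' clustering/fusion event (as member or product), else `dancing` if it
#' participates in any dancing event, else `individual` (fusion takes
#' precedence). The countable population size is the number of spots in
#' the first frame within the tip-ROI.
#'
#' @param tracks Track tibble.
#' @param dancing_events,fusion_events Event tibbles from
#'   [detect_dancing()] / [detect_cluster_fusion()].
#' @param axis Optional [axis_frame()]; with `tip_roi_length` defines the
#'   counted population.
#' @param tip_roi_length Tip-ROI length, um (default 30).
#' @return Tibble (class, n) over classes individual/dancing/clustered,
#'   with attribute `population_size`.
#' @export
classify_population <- function(tracks, dancing_events, fusion_events,
                                axis = NULL, tip_roi_length = 30) {
  tr <- tibble::as_tibble(tracks)
  ids <- unique(tr$track_id)
  clustered <- unique(c(fusion_events$track_a, fusion_events$track_b,
                        fusion_events$product_track))
  dancing <- setdiff(unique(c(dancing_events$track_a, dancing_events$track_b)),
                     clustered)
  cls <- dplyr::case_when(ids %in% clustered ~ "clustered",
                          ids %in% dancing ~ "dancing",
                          TRUE ~ "individual")
  out <- dplyr::count(
    tibble::tibble(class = factor(cls, c("individual", "dancing", "clustered"))),
    .data$class, .drop = FALSE, name = "n")
  out$class <- as.character(out$class)
  pop <- if (nrow(tr)) {
    first <- dplyr::filter(tr, .data$frame == min(.data$frame))
    if (!is.null(axis)) {
      sum(distance_below_tip(axis, first$x_um, first$y_um) <= tip_roi_length)
    } else nrow(first)
  } else 0L
  attr(out, "population_size") <- pop
  out
}

#' Event rates per root-hair zone
#'
#' @param events Event tibble (needs `type` and `zone` columns).
#' @param observation_duration Observation time, s (> 0).
#' @param zones Zones to report (default apical and subapical).
#' @return Tibble: zone, type, n_events, rate (events/s), including
#'   zero rows for absent combinations.
#' @export
event_rates <- function(events, observation_duration,
                        zones = c("apical", "subapical")) {
  if (observation_duration <= 0) rlang::abort("observation_duration must be > 0")
  types <- c("dancing", "cluster_fusion")
  grid <- tidyr::crossing(zone = zones, type = types)
  ev <- tibble::as_tibble(events)
  counts <- if (nrow(ev)) dplyr::count(ev, .data$zone, .data$type, name = "n_events")
            else tibble::tibble(zone = character(), type = character(),
                                n_events = integer())
  out <- dplyr::left_join(grid, counts, by = c("zone", "type"))
  out$n_events[is.na(out$n_events)] <- 0L
  dplyr::mutate(out, rate = .data$n_events / observation_duration)
}
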