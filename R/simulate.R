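# Ground-truthed synthetic endosome populations.
#
# Motion kinds:
#   continuous   - constant-speed excursions along the hair axis with
#                  lane-keeping lateral wobble; reflects at the hair ends.
#   stop_and_go  - alternating go (speed v) and stop (jitter only) phases
#                  with durations ~ U(0.5*tau, 1.5*tau).
#   dancing_pair - two particles sharing a slowly moving centroid; their
#                  separation relaxes to d_eq as an Ornstein-Uhlenbeck
#                  process during the dancing window, approached/left at
#                  ~4 um/s.
#   cluster_fusion - one particle converges on a second; at the fusion
#                  time both end and a product particle continues with the
#                  summed intensity and volume-conserving diameter.

default_motion_model <- function(preset, frame_interval) {
  list(v = preset$v_max, tau_go = 1.5, tau_stop = 1.5,
       jitter_sigma = 0.02, d_eq = 0.8, T_dance = NA_real_,
       relax_time = 2)
}

clamp_to_hair <- function(geometry, x, y, t, margin = 0.3) {
  tip <- tip_at(geometry, t)
  x <- pmin(tip - margin, pmax(margin, x))
  r <- geometry$radius
  cc <- tip - r
  half <- ifelse(x > cc, sqrt(pmax(0, r^2 - (x - cc)^2)), r)
  lim <- pmax(0.05, half - margin)
  y <- pmin(lim, pmax(-lim, y))
  list(x = x, y = y)
}

# Alternating go/stop phase labels for n frames.
phase_states <- function(n_frames, dt, tau_go, tau_stop) {
  states <- character(0)
  cur <- sample(c("go", "stop"), 1)
  while (length(states) < n_frames) {
    tau <- if (cur == "go") tau_go else tau_stop
    dur <- stats::runif(1, 0.5 * tau, 1.5 * tau)
    states <- c(states, rep(cur, max(1L, round(dur / dt))))
    cur <- if (cur == "go") "stop" else "go"
  }
  states[seq_len(n_frames)]
}

# Single-particle walk; go steps have length exactly v*dt (direction
# wobbles to keep the particle near its lane), stop steps are jitter.
sim_walk <- function(n_frames, dt, x0, y0, v, geometry, kind,
                     tau_go, tau_stop, jitter) {
  states <- if (kind == "continuous") rep("go", n_frames)
            else phase_states(n_frames, dt, tau_go, tau_stop)
  x <- numeric(n_frames); y <- numeric(n_frames)
  # confine to the cylindrical shank so wall reflections preserve the
  # go-phase step length exactly
  x[1] <- min(tip_at(geometry, 0) - geometry$radius, max(0.7, x0))
  y[1] <- y0
  dir <- sample(c(-1, 1), 1)
  lane <- y0
  for (i in seq_len(n_frames)[-1]) {
    t_i <- (i - 1) * dt
    xmax <- tip_at(geometry, t_i) - geometry$radius
    if (states[i] == "go") {
      dy <- -0.2 * (y[i - 1] - lane) + stats::rnorm(1, 0, jitter)
      cap <- 0.3 * v * dt
      dy <- max(-cap, min(cap, dy))
      dx <- dir * sqrt(max(0, (v * dt)^2 - dy^2))
      nx <- x[i - 1] + dx
      if (nx > xmax) { nx <- 2 * xmax - nx; dir <- -dir }
      if (nx < 0.7) { nx <- 1.4 - nx; dir <- -dir }
      x[i] <- nx
      y[i] <- y[i - 1] + dy
    } else {
      x[i] <- x[i - 1] + stats::rnorm(1, 0, jitter)
      y[i] <- y[i - 1] + stats::rnorm(1, 0, jitter)
    }
    cl <- clamp_to_hair(geometry, x[i], y[i], t_i)
    x[i] <- cl$x; y[i] <- cl$y
  }
  list(x = x, y = y, state = states)
}

# Tip-enriched initial axial position.
draw_x0 <- function(n, geometry, tip_enrichment, margin = 1) {
  tip <- tip_at(geometry, 0)
  lo <- margin; hi <- tip - margin
  if (hi <= lo) return(rep((lo + hi) / 2, n))
  xs <- numeric(0)
  w_max <- tip_enrichment
  while (length(xs) < n) {
    cand <- stats::runif(2 * n + 8, lo, hi)
    w <- 1 + (tip_enrichment - 1) * exp(-(tip - cand) / 10)
    keep <- stats::runif(length(cand)) * w_max < w
    xs <- c(xs, cand[keep])
  }
  xs[seq_len(n)]
}

# Confined stop-and-go 1D walk used for dancing-pair centroids: moves at
# speed v during go phases, reflecting at [lo, hi]; y holds the lane.
dancing_centroid_walk <- function(n_frames, dt, x0, y0, v, lo, hi, tau) {
  x <- numeric(n_frames); x[1] <- min(hi, max(lo, x0))
  dir <- sample(c(-1, 1), 1)
  for (i in seq_len(n_frames)[-1]) {
    nx <- x[i - 1] + dir * v * dt
    if (nx > hi) { nx <- 2 * hi - nx; dir <- -dir }
    if (nx < lo) { nx <- 2 * lo - nx; dir <- -dir }
    x[i] <- nx
  }
  list(x = x, y = rep(y0, n_frames), state = rep("go", n_frames))
}

empty_particles <- function() {
  tibble::tibble(particle_id = integer(), frame = integer(), t = numeric(),
                 x = numeric(), y = numeric(), intensity = numeric(),
                 apparent_diameter = numeric(), motion_state = character())
}

empty_events <- function() {
  tibble::tibble(event_id = integer(), type = character(),
                 member_ids = character(), product_id = integer(),
                 t_start = numeric(), t_end = numeric())
}

#' Simulate a ground-truthed endosome population
#'
#' Generates per-particle, per-frame ground-truth positions, intensities
#' and apparent diameters, plus an event log of dancing windows and
#' clustering/fusion times, for a mixture of motion kinds set by the
#' marker preset. Deterministic given `seed`.
#'
#' The mixture is assigned deterministically: `round(continuous_fraction *
#' n_particles)` particles are continuous; dancing and fusion pairs are
#' carved from the remainder (counts default to `round(rate * duration)`
#' from the preset); all remaining particles are stop-and-go.
#'
#' @param geometry A [root_hair_geometry()].
#' @param preset A one-row preset tibble ([get_preset()]) or a marker name.
#' @param n_particles Number of particles (>= 0).
#' @param duration Movie duration, s (> 0). Frames are sampled every
#'   `frame_interval` seconds, `round(duration / frame_interval)` frames.
#' @param motion_overrides Optional named list overriding motion
#'   parameters (`kind`, `v`, `tau_go`, `tau_stop`, `jitter_sigma`,
#'   `d_eq`, `T_dance`, `relax_time`). Setting `kind` forces every
#'   particle to that motion kind.
#' @param seed Integer seed; identical seeds give identical output.
#' @param frame_interval Frame interval, s (default 0.1).
#' @param n_dancing_pairs,n_fusion_pairs Optional explicit pair counts.
#' @param particle_intensities Optional numeric vector of per-particle
#'   intensities (recycled); default lognormal(meanlog 0, sdlog 0.3).
#' @param dance_durations,fusion_times Optional explicit dancing durations
#'   (s) / fusion times (s), one per pair; defaults: durations
#'   ~ U(10, 35) s, fusion at 35% of the movie.
#' @return An `endosome_truth` object: list with tibbles `particles`
#'   (particle_id, frame, t, x, y, intensity, apparent_diameter,
#'   motion_state) and `events` (event_id, type, member_ids, product_id,
#'   t_start, t_end); geometry, preset and frame interval as attributes.
#' @export
#' @examples
#' truth <- simulate_population(root_hair_geometry("growing"),
#'                              get_preset("RabA1d"), n_particles = 4,
#'                              duration = 5, seed = 1)
#' dplyr::count(truth$particles, particle_id)
simulate_population <- function(geometry, preset, n_particles, duration,
                                motion_overrides = NULL, seed = 1,
                                frame_interval = 0.1,
                                n_dancing_pairs = NULL,
                                n_fusion_pairs = NULL,
                                particle_intensities = NULL,
                                dance_durations = NULL,
                                fusion_times = NULL) {
  if (is.character(preset)) preset <- get_preset(preset)
  if (!inherits(geometry, "root_hair_geometry")) {
    rlang::abort("geometry must be a root_hair_geometry object")
  }
  if (duration <= 0) rlang::abort("duration must be positive")
  if (n_particles < 0) rlang::abort("n_particles must be >= 0")
  dt <- frame_interval
  n_frames <- max(1L, round(duration / dt))
  mm <- default_motion_model(preset, dt)
  mm[names(motion_overrides)] <- motion_overrides
  forced_kind <- motion_overrides$kind

  # --- mixture assignment (deterministic) -------------------------------
  if (!is.null(forced_kind)) {
    n_cont <- if (forced_kind == "continuous") n_particles else 0L
    nd <- if (forced_kind == "dancing_pair") n_particles %/% 2L else 0L
    nf <- if (forced_kind == "cluster_fusion") n_particles %/% 2L else 0L
    n_sg <- n_particles - n_cont - 2L * nd - 2L * nf
  } else {
    if (!is.null(n_dancing_pairs) && n_dancing_pairs > 0 && n_particles < 2) {
      rlang::abort("dancing pairs require at least 2 particles")
    }
    n_cont <- as.integer(round(preset$continuous_fraction * n_particles))
    nd <- n_dancing_pairs %||% round(preset$dancing_rate * duration)
    nf <- n_fusion_pairs %||% round(preset$fusion_rate * duration)
    nd <- as.integer(nd); nf <- as.integer(nf)
    avail <- n_particles - n_cont
    if (2L * (nd + nf) > avail) {
      rlang::warn("not enough non-continuous particles for requested pairs; reducing")
      while (2L * (nd + nf) > avail && nf > 0L) nf <- nf - 1L
      while (2L * (nd + nf) > avail && nd > 0L) nd <- nd - 1L
    }
    n_sg <- avail - 2L * (nd + nf)
  }


  if (n_particles == 0L) {
    out <- list(particles = empty_particles(), events = empty_events())
    return(structure(out, class = "endosome_truth", geometry = geometry,
                     preset = preset, frame_interval = dt,
                     duration = duration, seed = seed))
  }

  with_seed(seed, {
    tvec <- (seq_len(n_frames) - 1) * dt
    inten <- if (is.null(particle_intensities)) {
      stats::rlnorm(n_particles, 0, 0.3)
    } else rep_len(particle_intensities, n_particles)
    diam <- pmax(60, stats::rnorm(n_particles, preset$apparent_diameter_mean,
                                  preset$apparent_diameter_sd))
    x0 <- draw_x0(n_particles, geometry, preset$tip_enrichment)
    y0 <- stats::runif(n_particles, -(geometry$radius - 1), geometry$radius - 1)

    rows <- list(); events <- list()
    next_id <- n_particles + 1L
    ev_id <- 0L
    pid <- 0L

    mk_rows <- function(id, frames, w, state) {
      tibble::tibble(particle_id = id, frame = frames, t = frames * dt,
                     x = w$x, y = w$y, intensity = inten_of(id),
                     apparent_diameter = diam_of(id), motion_state = state)
    }
    # product particles get intensities/diameters appended
    inten_extra <- numeric(0); diam_extra <- numeric(0)
    inten_of <- function(id) if (id <= n_particles) inten[id] else inten_extra[id - n_particles]
    diam_of <- function(id) if (id <= n_particles) diam[id] else diam_extra[id - n_particles]

    # --- singles: continuous then stop_and_go ---------------------------
    # individual speeds scatter around the preset mean (between-particle
    # variability of the reported marker speeds) unless overridden
    v_fixed <- !is.null(motion_overrides$v)
    v_sd <- if ("v_sd" %in% names(preset)) preset$v_sd else 0
    singles <- c(rep("continuous", n_cont), rep("stop_and_go", n_sg))
    for (k in seq_along(singles)) {
      pid <- pid + 1L
      v_k <- if (v_fixed || v_sd == 0) mm$v else
        max(0.5, stats::rnorm(1, mm$v, v_sd))
      w <- sim_walk(n_frames, dt, x0[pid], y0[pid], v_k, geometry,
                    singles[k], mm$tau_go, mm$tau_stop, mm$jitter_sigma)
      rows[[length(rows) + 1L]] <-
        mk_rows(pid, 0:(n_frames - 1L), w, w$state)
    }

    # --- dancing pairs --------------------------------------------------
    sep_rest <- 1.5          # resting half-separation, um
    h_eq <- mm$d_eq / 2
    appr_rate <- 2           # half-separation closure rate, um/s (4 um/s pairwise)
    t_app <- (sep_rest - h_eq) / appr_rate
    sigma_h <- 0.075 * sqrt(2 / mm$relax_time)
    for (k in seq_len(nd)) {
      ida <- pid + 1L; idb <- pid + 2L; pid <- pid + 2L
      Td <- if (!is.null(dance_durations)) dance_durations[k] else stats::runif(1, 10, 35)
      Td <- min(Td, duration - 2 * t_app - 1)
      lo <- t_app + 0.2
      hi <- max(lo, duration - Td - t_app - 0.2)
      ts <- stats::runif(1, lo, hi)
      te <- ts + Td
      cy0 <- stats::runif(1, -(geometry$radius - 2.6), geometry$radius - 2.6)
      # each pair's centroid is confined to its own stretch of the hair
      # (dancing pairs travel short distances); slots keep pairs apart
      tip0 <- tip_at(geometry, 0)
      slot_w <- (tip0 - 6) / max(1L, nd)
      cx0 <- 3 + (k - 0.5) * slot_w
      v_c <- stats::runif(1, 0.6, 1.1)
      cen <- dancing_centroid_walk(n_frames, dt, cx0, cy0, v_c,
                                   lo = max(1.5, cx0 - 5),
                                   hi = min(tip0 - 1.5, cx0 + 5))
      ang <- stats::runif(1, 0, 2 * pi)
      e <- c(cos(ang), sin(ang))
      h <- numeric(n_frames)
      for (i in seq_len(n_frames)) {
        ti <- tvec[i]
        h[i] <- if (ti < ts - t_app) sep_rest
          else if (ti < ts) sep_rest - appr_rate * (ti - (ts - t_app))
          else if (ti <= te) NA            # OU, filled below
          else if (ti < te + t_app) h_eq + appr_rate * (ti - te)
          else sep_rest
      }
      in_dance <- is.na(h)
      idx <- which(in_dance)
      if (length(idx)) {
        hh <- h_eq
        for (i in idx) {
          hh <- hh - (hh - h_eq) * dt / mm$relax_time +
            sigma_h * sqrt(dt) * stats::rnorm(1)
          h[i] <- max(0.05, hh)
        }
      }
      na <- list(x = cen$x + h * e[1] + stats::rnorm(n_frames, 0, 0.01),
                 y = cen$y + h * e[2] + stats::rnorm(n_frames, 0, 0.01))
      nb <- list(x = cen$x - h * e[1] + stats::rnorm(n_frames, 0, 0.01),
                 y = cen$y - h * e[2] + stats::rnorm(n_frames, 0, 0.01))
      ca <- clamp_to_hair(geometry, na$x, na$y, tvec)
      cb <- clamp_to_hair(geometry, nb$x, nb$y, tvec)
      st <- ifelse(in_dance, "dancing", "go")
      rows[[length(rows) + 1L]] <- mk_rows(ida, 0:(n_frames - 1L), ca, st)
      rows[[length(rows) + 1L]] <- mk_rows(idb, 0:(n_frames - 1L), cb, st)
      ev_id <- ev_id + 1L
      events[[ev_id]] <- tibble::tibble(
        event_id = ev_id, type = "dancing",
        member_ids = paste(ida, idb, sep = ","), product_id = NA_integer_,
        t_start = ts, t_end = te)
    }

    # --- fusion pairs ---------------------------------------------------
    for (k in seq_len(nf)) {
      ida <- pid + 1L; idb <- pid + 2L; pid <- pid + 2L
      # default fusion times are staggered so events stay separable
      tf <- if (!is.null(fusion_times)) fusion_times[k] else
        max(1, (0.25 + 0.3 * (k - 1) / max(1L, nf)) * duration)
      k_fuse <- min(n_frames - 1L, max(1L, round(tf / dt)))
      tf <- k_fuse * dt
      # B rests at P; A approaches from 4 um away at speed v;
      # fusion sites sit in separate stretches of the hair
      py <- stats::runif(1, -(geometry$radius - 2), geometry$radius - 2)
      tip0 <- tip_at(geometry, 0)
      fslot <- (tip0 - 10) / max(1L, nf)
      px <- min(tip0 - 5, max(5, 5 + (k - 0.5) * fslot +
                                stats::runif(1, -fslot / 4, fslot / 4)))
      d0 <- 4
      t_go <- d0 / mm$v
      ang <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(ang), sin(ang))
      a0 <- c(px + d0 * u[1], py + d0 * u[2])
      cl <- clamp_to_hair(geometry, a0[1], a0[2], 0, margin = 0.5)
      a0 <- c(cl$x, cl$y); d0v <- a0 - c(px, py)
      mem_idx <- seq_len(k_fuse)           # frames 0..k_fuse-1
      ta <- tvec[mem_idx]
      fr_go <- ta >= tf - t_go
      frac <- pmax(0, pmin(1, (tf - ta) / t_go))
      ax <- ifelse(fr_go, px + d0v[1] * frac, a0[1]) +
        stats::rnorm(k_fuse, 0, mm$jitter_sigma)
      ay <- ifelse(fr_go, py + d0v[2] * frac, a0[2]) +
        stats::rnorm(k_fuse, 0, mm$jitter_sigma)
      bx <- px + cumsum(stats::rnorm(k_fuse, 0, mm$jitter_sigma))
      by <- py + cumsum(stats::rnorm(k_fuse, 0, mm$jitter_sigma))
      ca <- clamp_to_hair(geometry, ax, ay, ta)
      cb <- clamp_to_hair(geometry, bx, by, ta)
      sta <- ifelse(fr_go, "go", "stop")
      rows[[length(rows) + 1L]] <- mk_rows(ida, mem_idx - 1L, ca, sta)
      rows[[length(rows) + 1L]] <- mk_rows(idb, mem_idx - 1L, cb, rep("stop", k_fuse))
      # product
      prod_id <- next_id; next_id <- next_id + 1L
      inten_extra <- c(inten_extra, inten_of(ida) + inten_of(idb))
      diam_extra <- c(diam_extra,
                      (diam_of(ida)^3 + diam_of(idb)^3)^(1 / 3))
      n_post <- n_frames - k_fuse
      wp <- sim_walk(n_post, dt, cb$x[k_fuse], cb$y[k_fuse], mm$v, geometry,
                     "stop_and_go", mm$tau_go, mm$tau_stop, mm$jitter_sigma)
      stp <- wp$state; stp[1] <- "fused"
      rows[[length(rows) + 1L]] <- mk_rows(prod_id, k_fuse:(n_frames - 1L), wp, stp)
      ev_id <- ev_id + 1L
      events[[ev_id]] <- tibble::tibble(
        event_id = ev_id, type = "cluster_fusion",
        member_ids = paste(ida, idb, sep = ","), product_id = prod_id,
        t_start = tf, t_end = (n_frames - 1L) * dt)
    }

    particles <- dplyr::arrange(purrr::list_rbind(rows),
                                .data$particle_id, .data$frame)
    events_tbl <- if (length(events)) purrr::list_rbind(events) else empty_events()
    structure(list(particles = particles, events = events_tbl),
              class = "endosome_truth", geometry = geometry, preset = preset,
              frame_interval = dt, duration = duration, seed = seed)
  })
}

#' @export
print.endosome_truth <- function(x, ...) {
  cat("<endosome_truth>", length(unique(x$particles$particle_id)),
      "particles,", nrow(x$events), "events,",
      if (nrow(x$particles)) max(x$particles$frame) + 1 else 0, "frames @",
      attr(x, "frame_interval"), "s\n")
  invisible(x)
}
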