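# Parameter-recovery experiments: the full image-based analysis chain is
# run against the generator's ground truth. These are the quantitative
# validation entry points used by the test suite and the acceptance
# script, and the templates to adapt for real movies.

#' Maximum-speed recovery through the full image chain
#'
#' Simulates mature-hair movies of particles moving at the preset's
#' reported speed (continuous for early markers, stop-and-go for late
#' markers), renders them with spinning-disc optics, detects spots,
#' links tracks, filters by the 5 um rule and extracts each track's
#' maximum speed with the kymograph steepest-slope estimator; returns
#' the mean per-track maximum speed. Particles are spread across
#' several movies to keep the spot density in the regime where linking
#' identities are reliable.
#'
#' @param preset_name Marker preset.
#' @param n_particles Total particles across movies (default 20).
#' @param per_movie Particles per movie (default 5).
#' @param duration Movie duration, s (default 20: 200 frames at 0.1 s).
#' @param frame_interval s/frame.
#' @param seed Integer seed.
#' @param min_track_duration Minimum track duration entering the speed
#'   summary, s (a maximum-speed estimate needs at least one resolved
#'   go phase).
#' @return One-row tibble: preset, v_true, mean_max_speed, n_tracks.
#' @export
speed_recovery <- function(preset_name, n_particles = 20, per_movie = 5,
                           duration = 20, frame_interval = 0.1, seed = 1,
                           min_track_duration = 2) {
  pr <- get_preset(preset_name)
  kind <- if (pr$endosome_class == "early") "continuous" else "stop_and_go"
  geom <- root_hair_geometry("mature")
  axis <- geometry_axis(geom)
  det <- detection_params(dog_threshold = NULL, use_median_filter = FALSE)
  lp <- linking_params(max_displacement = 1.2 * pr$v_max * frame_interval,
                       max_gap = 2)
  n_movies <- ceiling(n_particles / per_movie)
  sus <- purrr::map(seq_len(n_movies), function(r) {
    tr <- simulate_population(geom, pr, per_movie, duration,
                              motion_overrides = list(kind = kind,
                                                      v = pr$v_max),
                              seed = seed + r,
                              frame_interval = frame_interval)
    stk <- render_movie(tr, optics_config("spinning_disc",
                                          frame_interval = frame_interval,
                                          seed = seed + 500L + r))
    sp <- detect_stack(stk, det)
    tk <- filter_tracks(link_spots(sp, lp), lp)
    track_summary(tk, axis = axis)
  })
  su <- dplyr::filter(purrr::list_rbind(sus),
                      .data$t_end - .data$t_start >= min_track_duration)
  tibble::tibble(preset = preset_name, v_true = pr$v_max,
                 mean_max_speed = mean(su$max_speed), n_tracks = nrow(su))
}

#' Continuous/discontinuous class recovery through the full image chain
#'
#' Simulates populations at the preset's continuous fraction, runs the
#' image chain, and classifies every classifiable track (path length at
#' least `continuous_min_length`; shorter trajectories cannot exhibit a
#' qualifying run and are indeterminate).
#'
#' @param preset_name Marker preset.
#' @param n_particles Total particles (default 50).
#' @param per_movie Particles per movie (default 10).
#' @param duration Movie duration, s.
#' @param seed Integer seed.
#' @param continuous_min_length Qualifying straight-run length, um.
#' @return One-row tibble: preset, true_fraction, percent_continuous,
#'   n_classifiable.
#' @export
movement_class_recovery <- function(preset_name, n_particles = 50,
                                    per_movie = 10, duration = 20,
                                    seed = 1,
                                    continuous_min_length = 15) {
  pr <- get_preset(preset_name)
  geom <- root_hair_geometry("mature")
  axis <- geometry_axis(geom)
  det <- detection_params(dog_threshold = NULL, use_median_filter = FALSE)
  lp <- linking_params(
    max_displacement = 1.2 * (pr$v_max + 2 * pr$v_sd) * 0.1, max_gap = 2)
  n_movies <- ceiling(n_particles / per_movie)
  labs <- character(0)
  for (r in seq_len(n_movies)) {
    tr <- simulate_population(geom, pr, per_movie, duration,
                              seed = seed + r,
                              n_dancing_pairs = 0, n_fusion_pairs = 0)
    stk <- render_movie(tr, optics_config("spinning_disc",
                                          seed = seed + 500L + r))
    sp <- detect_stack(stk, det)
    tk <- filter_tracks(link_spots(sp, lp), lp)
    if (!nrow(tk)) next
    su <- track_summary(tk)
    keep <- su$track_id[su$path_length >= continuous_min_length]
    for (id in keep) {
      labs <- c(labs, classify_track_movement(
        tk[tk$track_id == id, ], axis, continuous_min_length)$label)
    }
  }
  tibble::tibble(preset = preset_name,
                 true_fraction = pr$continuous_fraction,
                 percent_continuous = 100 * mean(labs == "continuous"),
                 n_classifiable = length(labs))
}

#' Size recovery through SIM rendering and FWHM profiling
#'
#' Draws apparent diameters from the preset's size distribution, renders
#' them as SIM-mode spots (early) or rings (late), measures each with
#' [fwhm_profile()] and summarizes.
#'
#' @param preset_name Marker preset.
#' @param n Number of particles (defaults: 76 for early presets, 62 for
#'   late, matching the reference sample sizes).
#' @param seed Integer seed.
#' @return One-row tibble: preset, generator_mean_nm, drawn_mean_nm,
#'   measured_mean_nm, n.
#' @export
size_recovery <- function(preset_name, n = NULL, seed = 1) {
  pr <- get_preset(preset_name)
  if (is.null(n)) n <- if (pr$endosome_class == "early") 76L else 62L
  d <- with_seed(seed, pmax(
    if (pr$endosome_class == "early") 100 else 150,
    stats::rnorm(n, pr$apparent_diameter_mean, pr$apparent_diameter_sd)))
  side <- ceiling(sqrt(n))
  grid <- tibble::tibble(
    x = (rep(seq_len(side), length.out = n)) * 2.5,
    y = (rep(seq_len(side), each = side, length.out = n)) * 2.5,
    diameter_nm = d, class = pr$endosome_class)
  fr <- render_sim_frame(grid, optics_config("sim"))
  got <- purrr::map_dbl(seq_len(n), function(i) {
    fwhm_profile(fr, c(grid$x[i], grid$y[i]))$fwhm_nm
  })
  tibble::tibble(preset = preset_name,
                 generator_mean_nm = pr$apparent_diameter_mean,
                 drawn_mean_nm = mean(d),
                 measured_mean_nm = mean(got), n = n)
}

#' Root-hair growth-rate recovery
#'
#' Samples tip positions of a growing synthetic hair (60 s interval over
#' 20 min by default) with Gaussian tip-localization noise and fits the
#' elongation rate.
#'
#' @param seed Integer seed.
#' @param rate True growth rate, um/min (default: the growing-stage
#'   geometry default, 1.941).
#' @param n_points Number of samples (default 21).
#' @param interval Sampling interval, s (default 60).
#' @param noise_sd Tip localization noise, um (default 0.2).
#' @return One-row tibble: true_rate, recovered_rate (um/min).
#' @export
growth_rate_recovery <- function(seed = 1, rate = NULL, n_points = 21,
                                 interval = 60, noise_sd = 0.2) {
  geom <- root_hair_geometry("growing", growth_rate = rate)
  tt <- (seq_len(n_points) - 1) * interval
  tips <- with_seed(seed,
                    tip_at(geom, tt) + stats::rnorm(n_points, 0, noise_sd))
  fit <- growth_rate(tibble::tibble(t = tt, tip = tips))
  tibble::tibble(true_rate = geom$growth_rate,
                 recovered_rate = fit$rate_um_min)
}

#' Dancing-event detection benchmark against the generator event log
#'
#' Simulates late-endosome movies containing scripted dancing pairs with
#' durations drawn from the observed 10-35 s range among stop-and-go and
#' continuous distractors, detects dancing events on the ground-truth
#' tracks with localization noise added, and scores recall, precision
#' and duration accuracy against the generator event log.
#'
#' @param n_events Total scripted dancing events (default 50).
#' @param pairs_per_movie Dancing pairs per movie (default 5).
#' @param seed Integer seed.
#' @param noise_sd Localization noise, um.
#' @return One-row tibble: n_events, n_detected, n_false, recall,
#'   precision, max_duration_error_s, frac_duration_in_range.
#' @export
dancing_recovery <- function(n_events = 50, pairs_per_movie = 5, seed = 1,
                             noise_sd = 0.03) {
  geom <- root_hair_geometry("growing", shank_length = 60)
  pr <- get_preset("FYVE")
  n_movies <- ceiling(n_events / pairs_per_movie)
  n_det <- 0L; n_fp <- 0L; n_true <- 0L
  dur_err <- numeric(0); in_range <- logical(0)
  for (r in seq_len(n_movies)) {
    tr <- simulate_population(geom, pr, 2L * pairs_per_movie + 6L, 45,
                              seed = seed + r,
                              n_dancing_pairs = pairs_per_movie,
                              n_fusion_pairs = 0)
    tk <- truth_to_tracks(tr, noise_sd = noise_sd, seed = seed + 500L + r)
    ev <- detect_dancing(tk, interaction_params())
    tp <- do.call(rbind, lapply(strsplit(tr$events$member_ids, ","),
                                as.integer))
    n_true <- n_true + nrow(tp)
    for (i in seq_len(nrow(ev))) {
      m <- which(tp[, 1] == pmin(ev$track_a[i], ev$track_b[i]) &
                 tp[, 2] == pmax(ev$track_a[i], ev$track_b[i]))
      dur <- ev$t_end[i] - ev$t_start[i]
      if (length(m)) {
        n_det <- n_det + 1L
        dur_err <- c(dur_err, abs(dur - (tr$events$t_end[m] -
                                         tr$events$t_start[m])))
        in_range <- c(in_range, dur >= 10 - 1 & dur <= 35 + 1)
      } else n_fp <- n_fp + 1L
    }
  }
  tibble::tibble(n_events = n_true, n_detected = n_det, n_false = n_fp,
                 recall = n_det / n_true,
                 precision = n_det / max(1L, n_det + n_fp),
                 max_duration_error_s = max(dur_err, 0),
                 frac_duration_in_range = mean(in_range))
}

#' Clustering/fusion detection benchmark
#'
#' Simulates movies with scripted fusion events (intensity-conserving
#' merges), detects them on the ground-truth tracks with localization
#' noise, and additionally checks that a constructed 5 s transient
#' co-localization is not called a fusion.
#'
#' @param n_events Total scripted fusions (default 30).
#' @param per_movie Fusion pairs per movie (default 3).
#' @param seed Integer seed.
#' @param noise_sd Localization noise, um.
#' @return One-row tibble: n_events, n_detected, recall,
#'   n_false_from_transient.
#' @export
fusion_recovery <- function(n_events = 30, per_movie = 3, seed = 1,
                            noise_sd = 0.03) {
  geom <- root_hair_geometry("growing", shank_length = 60)
  pr <- get_preset("FYVE")
  n_movies <- ceiling(n_events / per_movie)
  n_det <- 0L; n_true <- 0L
  for (r in seq_len(n_movies)) {
    tr <- simulate_population(geom, pr, 4L * per_movie, 60,
                              seed = seed + r,
                              n_dancing_pairs = 0,
                              n_fusion_pairs = per_movie)
    tk <- truth_to_tracks(tr, noise_sd = noise_sd, seed = seed + 500L + r)
    ev <- detect_cluster_fusion(tk, interaction_params())
    tevs <- tr$events[tr$events$type == "cluster_fusion", ]
    tp <- do.call(rbind, lapply(strsplit(tevs$member_ids, ","), as.integer))
    n_true <- n_true + nrow(tp)
    for (i in seq_len(nrow(ev))) {
      m <- which(tp[, 1] == pmin(ev$track_a[i], ev$track_b[i]) &
                 tp[, 2] == pmax(ev$track_a[i], ev$track_b[i]))
      if (length(m)) n_det <- n_det + 1L
    }
  }
  # transient co-localization control: A vanishes into B for 5 s, then a
  # new track appears; the summed intensity is not sustained
  nA <- 100L; nB <- 400L
  a <- tibble::tibble(track_id = 1L, frame = 0:(nA - 1L),
                      t = (0:(nA - 1L)) * 0.1, x_um = 5, y_um = 0,
                      intensity = 100, inferred = FALSE)
  b <- tibble::tibble(track_id = 2L, frame = 0:(nB - 1L),
                      t = (0:(nB - 1L)) * 0.1, x_um = 5.3, y_um = 0.2,
                      intensity = c(rep(150, nA), rep(250, 50),
                                    rep(150, nB - nA - 50L)),
                      inferred = FALSE)
  cc <- tibble::tibble(track_id = 3L, frame = (nA + 50L):(nB - 1L),
                       t = ((nA + 50L):(nB - 1L)) * 0.1, x_um = 5.1,
                       y_um = 0, intensity = 100, inferred = FALSE)
  fp <- nrow(detect_cluster_fusion(dplyr::bind_rows(a, b, cc),
                                   interaction_params()))
  tibble::tibble(n_events = n_true, n_detected = n_det,
                 recall = n_det / n_true, n_false_from_transient = fp)
}
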