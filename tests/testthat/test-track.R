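# Linking, the 5 um filter, speed profiles and stop/go segmentation.

spot_row <- function(frame, x, y, t = frame * 0.1, intensity = 1) {
  tibble::tibble(frame = as.integer(frame), t = t, x_um = x, y_um = y,
                 intensity = intensity, quality = 1)
}

test_that("a lone particle forms a single track", {
  sp <- dplyr::bind_rows(spot_row(0, 0, 0), spot_row(1, 0.5, 0),
                         spot_row(2, 1.0, 0))
  tk <- link_spots(sp, linking_params(max_displacement = 2))
  expect_equal(dplyr::n_distinct(tk$track_id), 1)
  expect_equal(nrow(tk), 3)
})

test_that("parallel movers keep their identities", {
  sp <- purrr::list_rbind(purrr::map(0:5, function(f) {
    dplyr::bind_rows(spot_row(f, f * 1.0, 0), spot_row(f, f * 1.0, 5))
  }))
  tk <- link_spots(sp, linking_params(max_displacement = 2))
  expect_equal(dplyr::n_distinct(tk$track_id), 2)
  for (id in unique(tk$track_id)) {
    expect_equal(stats::sd(tk$y_um[tk$track_id == id]), 0)
  }
})

test_that("a jump beyond the gate terminates the track", {
  sp <- dplyr::bind_rows(spot_row(0, 0, 0), spot_row(1, 3, 0))
  tk <- link_spots(sp, linking_params(max_displacement = 2, max_gap = 0))
  expect_equal(dplyr::n_distinct(tk$track_id), 2)
})

test_that("frame-to-frame assignment cost equals the brute-force minimum", {
  set.seed(21)
  for (rep in 1:8) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    p1 <- cbind(runif(n1, 0, 6), runif(n1, 0, 6))
    p2 <- cbind(runif(n2, 0, 6), runif(n2, 0, 6))
    cost <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
    gate <- 2^2
    m <- lap_match_gated(cost, gate)
    expect_equal(matching_cost(cost, m, gate),
                 brute_match_cost(cost, gate), tolerance = 1e-10)
  }
})

test_that("gap closing interpolates missing frames and flags them", {
  sp <- dplyr::bind_rows(spot_row(0, 0, 0), spot_row(1, 0.5, 0),
                         spot_row(3, 1.5, 0), spot_row(4, 2.0, 0))
  tk <- link_spots(sp, linking_params(max_displacement = 1, max_gap = 1))
  expect_equal(dplyr::n_distinct(tk$track_id), 1)
  expect_equal(sum(tk$inferred), 1)
  filled <- tk[tk$frame == 2L, ]
  expect_equal(filled$x_um, 1.0)
  expect_true(is.na(filled$intensity))
})

test_that("the 5 um rule excludes 4.9 and retains 5.1", {
  short <- make_track(1, x = seq(0, 4.9, length.out = 50), y = rep(0, 50))
  long <- make_track(2, x = seq(0, 5.1, length.out = 50), y = rep(0, 50))
  tk <- dplyr::bind_rows(short, long)
  out <- filter_tracks(tk, linking_params(min_path_length = 5))
  expect_equal(unique(out$track_id), 2)
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("filter_tracks is idempotent and handles empty input", {
  tk <- make_track(1, x = seq(0, 8, length.out = 30), y = rep(0, 30))
  once <- filter_tracks(tk, linking_params())
  twice <- filter_tracks(once, linking_params())
  expect_equal(as.data.frame(once), as.data.frame(twice))
  expect_equal(nrow(filter_tracks(tk[0, ], linking_params())), 0)
})

test_that("speed profiles report displacement over time", {
  still <- make_track(1, x = rep(2, 20), y = rep(1, 20))
  pr <- speed_profile(still)
  expect_true(all(pr$speed == 0))
  mover <- make_track(2, x = seq(0, 9.5, by = 0.5), y = rep(0, 20))
  pr2 <- speed_profile(mover)
  expect_equal(unique(round(pr2$speed, 9)), 5.0)
  expect_error(speed_profile(make_track(3, x = 1, y = 1)), "2 spots")
})

test_that("stop/go segmentation recovers phase structure", {
  # constant motion: a single go phase
  pr <- tibble::tibble(t = seq(0.1, 2, by = 0.1), speed = 5)
  seg <- segment_stop_go(pr, v_stop = 0.5)
  expect_equal(seg$phase, "go")
  # all-stop profile
  pr0 <- tibble::tibble(t = seq(0.1, 2, by = 0.1), speed = 0)
  expect_equal(segment_stop_go(pr0)$phase, "stop")
  # alternating profile with known switch times
  tt <- seq(0.1, 6, by = 0.1)
  sp <- ifelse(tt <= 2 | tt > 4, 5, 0.05)
  seg3 <- segment_stop_go(tibble::tibble(t = tt, speed = sp),
                          v_stop = 0.5, min_phase = 0.3)
  expect_equal(seg3$phase, c("go", "stop", "go"))
  expect_lt(abs(seg3$t_start[2] - 2), 0.2 + 1e-9)
  expect_lt(abs(seg3$t_end[2] - 4), 0.2 + 1e-9)
})

test_that("stop/go segmentation matches the generator event schedule", {
  geom <- root_hair_geometry("growing")
  tr <- simulate_population(geom, get_preset("FYVE"), 1, 10, seed = 31,
                            motion_overrides = list(kind = "stop_and_go"),
                            n_dancing_pairs = 0, n_fusion_pairs = 0)
  p <- tr$particles
  tk <- truth_to_tracks(tr, noise_sd = 0)
  seg <- segment_stop_go(speed_profile(tk), v_stop = 0.5, min_phase = 0.3)
  # true switch times from the state sequence
  st <- rle(p$motion_state)
  true_sw <- p$t[cumsum(st$lengths)[-length(st$lengths)]]
  det_sw <- sort(c(seg$t_start[-1]))
  for (sw in det_sw) {
    expect_lt(min(abs(true_sw - sw)), 0.2 + 1e-9)  # within 2 frames
  }
})

test_that("recovered track max speed matches the configured go speed", {
  geom <- root_hair_geometry("mature")
  axis <- geometry_axis(geom)
  tr <- simulate_population(geom, get_preset("RabA1d"), 30, 10, seed = 33,
                            motion_overrides = list(kind = "continuous",
                                                    v = 8.7))
  tk <- truth_to_tracks(tr, noise_sd = 0.03, seed = 34)
  su <- track_summary(tk, axis = axis)
  expect_equal(nrow(su), 30)
  expect_lt(abs(mean(su$max_speed) - 8.7) / 8.7, 0.05)
})
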