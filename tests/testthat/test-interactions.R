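# Dancing and clustering/fusion detection, population composition, rates.

test_that("pairwise distances are exact on constructed tracks", {
  a <- make_track(1, x = seq(0, 5, length.out = 20), y = rep(0, 20))
  b <- make_track(2, x = seq(0, 5, length.out = 20), y = rep(0, 20))
  ds <- pairwise_distance_series(dplyr::bind_rows(a, b), c(1, 2))
  expect_true(all(ds$distance == 0))
  b2 <- make_track(2, x = seq(0, 5, length.out = 20), y = rep(1.5, 20))
  ds2 <- pairwise_distance_series(dplyr::bind_rows(a, b2), c(1, 2))
  expect_true(all(abs(ds2$distance - 1.5) < 1e-12))
})

test_that("the 1 um threshold crossing lands on the constructed frame", {
  # converging tracks: distance decreases by 0.2 um per frame from 3 um
  n <- 21
  a <- make_track(1, x = rep(0, n), y = rep(0, n))
  b <- make_track(2, x = 3 - 0.2 * (0:(n - 1)), y = rep(0, n))
  ds <- pairwise_distance_series(dplyr::bind_rows(a, b), c(1, 2))
  # crossing below 1 um at frame 11 (distance 3 - 0.2*10.x)
  expect_equal(min(ds$frame[ds$distance < 1]), 11L)
  expect_error(pairwise_distance_series(
    dplyr::bind_rows(a, dplyr::mutate(b, frame = frame + 100L)), c(1, 2)),
    "fewer than 2")
})

test_that("distant independent walkers produce no dancing events", {
  set.seed(51)
  a <- make_track(1, x = cumsum(rnorm(120, 0, 0.1)),
                  y = cumsum(rnorm(120, 0, 0.1)))
  b <- make_track(2, x = 20 + cumsum(rnorm(120, 0, 0.1)),
                  y = cumsum(rnorm(120, 0, 0.1)))
  ev <- detect_dancing(dplyr::bind_rows(a, b), interaction_params())
  expect_equal(nrow(ev), 0)
})

test_that("a generated dancing pair is recovered with its duration", {
  geom <- root_hair_geometry("growing", shank_length = 40)
  tr <- simulate_population(geom, get_preset("FYVE"), 2, 20, seed = 53,
                            motion_overrides = list(kind = "dancing_pair"),
                            dance_durations = 12)
  tk <- truth_to_tracks(tr, noise_sd = 0.03, seed = 54)
  ev <- detect_dancing(tk, interaction_params())
  expect_equal(nrow(ev), 1)
  expect_lt(abs((ev$t_end - ev$t_start) - 12), 1)
  expect_lt(ev$min_distance, 1)
  expect_true(ev$physical_interaction)
})

test_that("sustained summed-intensity increase routes a pair to fusion, not dancing", {
  # pair at constant 0.8 um whose combined intensity doubles for 25 s
  n <- 400
  inten <- c(rep(1, 100), rep(2, 300))      # doubles at t = 10 s for 30 s
  a <- make_track(1, x = seq(0, 8, length.out = n), y = rep(0, n),
                  intensity = inten)
  b <- make_track(2, x = seq(0, 8, length.out = n), y = rep(0.8, n),
                  intensity = inten)
  ev <- detect_dancing(dplyr::bind_rows(a, b), interaction_params())
  expect_equal(nrow(ev), 0)
  # without the increase the same pair is dancing
  a2 <- make_track(1, x = seq(0, 8, length.out = n), y = rep(0, n))
  b2 <- make_track(2, x = seq(0, 8, length.out = n), y = rep(0.8, n))
  ev2 <- detect_dancing(dplyr::bind_rows(a2, b2), interaction_params())
  expect_equal(nrow(ev2), 1)
})

test_that("track sets without merges give no fusion events", {
  a <- make_track(1, x = seq(0, 8, length.out = 100), y = rep(0, 100))
  b <- make_track(2, x = seq(8, 0, length.out = 100), y = rep(3, 100))
  ev <- detect_cluster_fusion(dplyr::bind_rows(a, b), interaction_params())
  expect_equal(nrow(ev), 0)
})

test_that("a scripted 100+150 fusion yields one event with ratio 2.5", {
  geom <- root_hair_geometry("growing", shank_length = 40)
  tr <- simulate_population(geom, get_preset("FYVE"), 2, 50, seed = 55,
                            motion_overrides = list(kind = "cluster_fusion"),
                            particle_intensities = c(100, 150),
                            fusion_times = 15)
  tk <- truth_to_tracks(tr, noise_sd = 0.02, seed = 56)
  ev <- detect_cluster_fusion(tk, interaction_params())
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$intensity_ratio - 2.5), 0.1)
  expect_equal(sort(c(ev$track_a, ev$track_b)), c(1, 2))
})

test_that("5 s transient co-localization is not a fusion", {
  # track A ends while B continues with elevated intensity for only 5 s,
  # then a new track C appears where A vanished
  nA <- 100; nB <- 400
  a <- make_track(1, x = rep(5, nA), y = rep(0, nA), intensity = 100)
  b_int <- c(rep(150, nA), rep(250, 50), rep(150, nB - nA - 50))
  b <- make_track(2, x = rep(5.3, nB), y = rep(0.2, nB), intensity = b_int)
  c_tr <- make_track(3, x = rep(5.1, nB - nA - 50), y = rep(0, nB - nA - 50),
                     intensity = 100)
  c_tr$frame <- c_tr$frame + nA + 50L
  c_tr$t <- c_tr$t + (nA + 50) * 0.1
  ev <- detect_cluster_fusion(dplyr::bind_rows(a, b, c_tr),
                              interaction_params())
  expect_equal(nrow(ev), 0)
})

test_that("population composition counts with fusion precedence", {
  tracks <- purrr::list_rbind(purrr::map(1:10, function(i) {
    make_track(i, x = seq(0, 6, length.out = 50) + i, y = rep(i, 50))
  }))
  dancing <- tibble::tibble(event_id = 1L, type = "dancing", track_a = 1L,
                            track_b = 2L, t_start = 0, t_end = 10,
                            min_distance = 0.5, sync_score = 0.9,
                            physical_interaction = TRUE, zone = "apical")
  fusion <- tibble::tibble(event_id = 1L, type = "cluster_fusion",
                           track_a = 3L, track_b = 4L, product_track = 4L,
                           t_start = 5, t_end = 30, intensity_ratio = 2.5,
                           zone = "subapical")
  pop <- classify_population(tracks, dancing, fusion)
  expect_equal(pop$n[pop$class == "individual"], 6L)
  expect_equal(pop$n[pop$class == "dancing"], 2L)
  expect_equal(pop$n[pop$class == "clustered"], 2L)
  # a track in both a dancing and a fusion event counts as clustered
  dancing2 <- dplyr::mutate(dancing, track_a = 3L)
  pop2 <- classify_population(tracks, dancing2, fusion)
  expect_equal(pop2$n[pop2$class == "dancing"], 1L)
  expect_equal(pop2$n[pop2$class == "clustered"], 2L)
  # no events -> all individual
  pop3 <- classify_population(tracks, dancing[0, ], fusion[0, ])
  expect_equal(pop3$n[pop3$class == "individual"], 10L)
})

test_that("event rates divide zone counts by the observation time", {
  ev <- tibble::tibble(type = rep("dancing", 4), zone = rep("apical", 4))
  r <- event_rates(ev, observation_duration = 20)
  expect_equal(r$rate[r$zone == "apical" & r$type == "dancing"], 0.2)
  expect_equal(r$rate[r$zone == "subapical" & r$type == "dancing"], 0)
  expect_equal(nrow(r), 4)
  expect_error(event_rates(ev, 0), "observation_duration")
  r0 <- event_rates(ev[0, ], 10)
  expect_true(all(r0$rate == 0))
})

test_that("events are assigned to zones by their start position", {
  axis <- axis_frame(cbind(x = c(44, 0), y = c(0, 0)))
  expect_equal(zone_of(axis, 44 - 8, 0), "apical")
  expect_equal(zone_of(axis, 44 - 12, 0), "subapical")
})

test_that("no window is labelled both dancing and fusion", {
  geom <- root_hair_geometry("growing", shank_length = 60)
  tr <- simulate_population(geom, get_preset("FYVE"), 12, 50, seed = 57,
                            n_dancing_pairs = 2, n_fusion_pairs = 1)
  tk <- truth_to_tracks(tr, noise_sd = 0.03, seed = 58)
  ip <- interaction_params()
  dd <- detect_dancing(tk, ip)
  ff <- detect_cluster_fusion(tk, ip)
  if (nrow(dd) && nrow(ff)) {
    for (i in seq_len(nrow(dd))) {
      for (j in seq_len(nrow(ff))) {
        same_pair <- setequal(c(dd$track_a[i], dd$track_b[i]),
                              c(ff$track_a[j], ff$track_b[j]))
        overlap <- dd$t_start[i] < ff$t_end[j] && ff$t_start[j] < dd$t_end[i]
        expect_false(same_pair && overlap)
      }
    }
  }
  succeed()
})

test_that("raising d_interact never loses dancing events", {
  geom <- root_hair_geometry("growing", shank_length = 60)
  tr <- simulate_population(geom, get_preset("FYVE"), 10, 45, seed = 59,
                            n_dancing_pairs = 3, n_fusion_pairs = 0)
  tk <- truth_to_tracks(tr, noise_sd = 0.03, seed = 60)
  n1 <- nrow(detect_dancing(tk, interaction_params(d_interact = 0.9)))
  n2 <- nrow(detect_dancing(tk, interaction_params(d_interact = 1.5)))
  expect_gte(n2, n1)
})
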