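# Ground-truth generator: mixtures, events, conservation laws, geometry.

geom <- root_hair_geometry("growing")

test_that("empty population gives empty tables", {
  tr <- simulate_population(geom, get_preset("RabA1d"), 0, 10, seed = 1)
  expect_equal(nrow(tr$particles), 0)
  expect_equal(nrow(tr$events), 0)
  expect_named(tr$particles,
               c("particle_id", "frame", "t", "x", "y", "intensity",
                 "apparent_diameter", "motion_state"))
})

test_that("invalid inputs are rejected", {
  expect_error(simulate_population(geom, get_preset("FYVE"), 4, -1),
               "duration")
  expect_error(simulate_population(geom, get_preset("FYVE"), 1, 10,
                                   n_dancing_pairs = 1),
               "at least 2")
})

test_that("same seed gives identical output, different seed differs", {
  a <- simulate_population(geom, get_preset("FYVE"), 6, 5, seed = 7)
  b <- simulate_population(geom, get_preset("FYVE"), 6, 5, seed = 7)
  c <- simulate_population(geom, get_preset("FYVE"), 6, 5, seed = 8)
  expect_identical(a$particles, b$particles)
  expect_identical(a$events, b$events)
  expect_false(identical(a$particles$x, c$particles$x))
})

test_that("motion-kind mixture is assigned deterministically and exactly", {
  tr <- simulate_population(geom, get_preset("RabA1d"), 10, 5, seed = 3)
  kinds <- dplyr::summarise(
    dplyr::group_by(tr$particles, .data$particle_id),
    cont = all(.data$motion_state == "go"))
  expect_equal(sum(kinds$cont), 8)   # 0.8 * 10
  tr2 <- simulate_population(geom, get_preset("FYVE"), 10, 5, seed = 3,
                             n_dancing_pairs = 0, n_fusion_pairs = 0)
  kinds2 <- dplyr::summarise(
    dplyr::group_by(tr2$particles, .data$particle_id),
    cont = all(.data$motion_state == "go"))
  expect_equal(sum(kinds2$cont), 4)  # 0.4 * 10
})

test_that("all ground-truth positions lie inside the root hair", {
  for (preset in c("RabA1d", "FYVE")) {
    n <- if (preset == "RabA1d") 30 else 12
    tr <- simulate_population(geom, get_preset(preset), n, 8, seed = 5,
                              n_dancing_pairs = 2, n_fusion_pairs = 1)
    p <- tr$particles
    expect_true(all(in_hair(geom, p$x, p$y, p$t)))
  }
})

test_that("go-phase step length matches the configured speed", {
  tr <- simulate_population(geom, get_preset("FYVE"), 20, 15, seed = 9,
                            motion_overrides = list(kind = "stop_and_go",
                                                    v = 5.5),
                            n_dancing_pairs = 0, n_fusion_pairs = 0)
  st <- dplyr::mutate(
    dplyr::group_by(tr$particles, .data$particle_id),
    step = sqrt((.data$x - dplyr::lag(.data$x))^2 +
                (.data$y - dplyr::lag(.data$y))^2))
  # wall reflections fold the sampled displacement; measure free motion
  wall_hi <- tip_at(geom, 0) - geom$radius
  st <- st[st$x > 0.7 + 0.6 & st$x < wall_hi - 0.6, ]
  go <- st[st$motion_state == "go" & !is.na(st$step), ]
  expect_gt(nrow(go), 1000)
  speeds <- go$step / 0.1
  se <- stats::sd(speeds) / sqrt(nrow(go))
  expect_lt(abs(mean(speeds) - 5.5), 3 * se + 1e-6)
})

test_that("dancing durations stay within the observed 10-35 s range", {
  tr <- simulate_population(geom, get_preset("FYVE"), 14, 45, seed = 13,
                            n_dancing_pairs = 4, n_fusion_pairs = 0)
  durs <- tr$events$t_end - tr$events$t_start
  expect_equal(nrow(tr$events), 4)
  expect_true(all(durs >= 10 & durs <= 35))
})

test_that("dancing windows keep pairs near the equilibrium separation", {
  tr <- simulate_population(geom, get_preset("FYVE"), 7, 40, seed = 17,
                            n_dancing_pairs = 2, n_fusion_pairs = 0)
  for (k in seq_len(nrow(tr$events))) {
    ids <- as.integer(strsplit(tr$events$member_ids[k], ",")[[1]])
    a <- tr$particles[tr$particles$particle_id == ids[1], ]
    b <- tr$particles[tr$particles$particle_id == ids[2], ]
    sel <- a$t >= tr$events$t_start[k] & a$t <= tr$events$t_end[k]
    sep <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)[sel]
    # d_eq = 0.8 um, OU separation sd ~ 0.15 um
    expect_gte(mean(sep <= 0.8 + 3 * 0.15), 0.9)
  }
})

test_that("fusion conserves intensity exactly and diameter by volume", {
  tr <- simulate_population(geom, get_preset("FYVE"), 2, 40, seed = 19,
                            motion_overrides = list(kind = "cluster_fusion"),
                            particle_intensities = c(100, 150),
                            fusion_times = 10)
  ev <- tr$events
  expect_equal(ev$type, "cluster_fusion")
  p <- tr$particles
  prod_id <- ev$product_id
  members <- as.integer(strsplit(ev$member_ids, ",")[[1]])
  i_prod <- unique(p$intensity[p$particle_id == prod_id])
  i_mem <- vapply(members, function(id) unique(p$intensity[p$particle_id == id]),
                  numeric(1))
  expect_equal(i_prod, sum(i_mem))          # 100 + 150 = 250, pre-noise
  expect_equal(i_prod, 250)
  d_mem <- vapply(members,
                  function(id) unique(p$apparent_diameter[p$particle_id == id]),
                  numeric(1))
  d_prod <- unique(p$apparent_diameter[p$particle_id == prod_id])
  expect_equal(d_prod, (d_mem[1]^3 + d_mem[2]^3)^(1 / 3))
  # members end exactly when the product starts
  f_end <- max(p$frame[p$particle_id %in% members])
  f_start <- min(p$frame[p$particle_id == prod_id])
  expect_equal(f_start, f_end + 1L)
})

test_that("particle frames are contiguous between birth and death", {
  tr <- simulate_population(geom, get_preset("FYVE"), 10, 30, seed = 23,
                            n_dancing_pairs = 1, n_fusion_pairs = 1)
  by_id <- split(tr$particles$frame, tr$particles$particle_id)
  for (fr in by_id) {
    expect_equal(fr, seq(min(fr), max(fr)))
  }
})
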