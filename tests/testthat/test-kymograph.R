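# Kymograph construction, ridge slopes, movement classification.

# Movie of particles moving along the row y = 0 of a straight hair.
make_axis_movie <- function(xs_by_frame, pixel_size = 0.26,
                            frame_interval = 0.1, ny = 21, nx = 160,
                            amplitude = 100) {
  n <- length(xs_by_frame)
  frames <- lapply(seq_len(n), function(k) {
    m <- matrix(0, ny, nx)
    for (x in xs_by_frame[[k]]) {
      cx <- x / pixel_size + 0.5
      cy <- (ny + 1) / 2
      ix <- pmax(1, floor(cx - 4)):pmin(nx, ceiling(cx + 4))
      gx <- exp(-((ix - cx)^2) / (2 * 0.9^2))
      gy <- exp(-((seq_len(ny) - cy)^2) / (2 * 0.9^2))
      m[, ix] <- m[, ix] + amplitude * (gy %o% gx)
    }
    m
  })
  structure(array(unlist(frames), dim = c(ny, nx, n)),
            class = c("image_stack", "array"), pixel_size = pixel_size,
            frame_interval = frame_interval,
            origin = c(0, -(ny / 2) * pixel_size))
}

test_that("temporally constant stacks give identical kymograph columns", {
  stk <- make_axis_movie(rep(list(c(5, 15)), 8))
  k <- build_kymograph(stk, cbind(x = c(1, 28), y = c(0, 0)))
  expect_true(all(apply(k$values, 1, function(r) max(r) - min(r)) < 1e-9))
})

test_that("width-1 kymographs equal nearest-pixel samples", {
  stk <- make_axis_movie(rep(list(c(10)), 3))
  k <- build_kymograph(stk, cbind(x = c(1, 28), y = c(0, 0)), width = 1L)
  # the line runs along image row 11 (y = 0)
  cols <- round((k$distance + 1) / 0.26 + 0.5)
  expect_equal(k$values[, 1], stk[11, cols, 1])
})

test_that("lines leaving the image are rejected with coordinates", {
  stk <- make_axis_movie(rep(list(5), 3))
  expect_error(build_kymograph(stk, cbind(x = c(0, 50), y = c(0, 0))),
               "exits the image")
  expect_error(build_kymograph(stk, cbind(x = c(1, 20), y = c(0, 0)),
                               width = 2L), "odd")
})

test_that("a moving particle produces a ridge of its speed", {
  xs <- lapply(0:49, function(k) 4 + k * 0.1 * 5)   # 5 um/s
  stk <- make_axis_movie(xs)
  k <- build_kymograph(stk, cbind(x = c(1, 30), y = c(0, 0)))
  v <- max_speed_from_kymograph(k)
  expect_lt(abs(v - 5) / 5, 0.1)
  # weighted-least-squares oracle on per-column argmax
  am <- apply(k$values, 2, which.max)
  fit <- stats::lm(k$distance[am] ~ k$times)
  expect_lt(abs(abs(unname(coef(fit)[2])) - v) / 5, 0.1)
})

test_that("a stationary particle yields zero maximum speed", {
  stk <- make_axis_movie(rep(list(12), 20))
  k <- build_kymograph(stk, cbind(x = c(1, 30), y = c(0, 0)))
  expect_equal(max_speed_from_kymograph(k), 0)
})

test_that("the steepest of several ridges wins", {
  xs <- lapply(0:49, function(k) c(4 + k * 0.1 * 3, 8 + k * 0.1 * 6))
  stk <- make_axis_movie(xs)
  k <- build_kymograph(stk, cbind(x = c(1, 30), y = c(0, 0)))
  v <- max_speed_from_kymograph(k)
  expect_lt(abs(v - 6) / 6, 0.1)
})

test_that("featureless kymographs give a missing max speed", {
  stk <- make_axis_movie(rep(list(numeric(0)), 10))
  k <- build_kymograph(stk, cbind(x = c(1, 30), y = c(0, 0)))
  expect_true(is.na(max_speed_from_kymograph(k)))
})

test_that("kymograph sampling never amplifies total intensity", {
  stk <- make_axis_movie(rep(list(c(5, 10)), 5))
  k <- build_kymograph(stk, cbind(x = c(1, 30), y = c(0, 0)))
  for (j in seq_len(ncol(k$values))) {
    expect_lte(sum(k$values[, j]), sum(stk[, , j]))
  }
})

test_that("movement classification follows the 15 um straight-run rule", {
  # 20 um constant-velocity excursion -> continuous
  xs <- lapply(0:49, function(k) 4 + k * 0.1 * 4)    # 20 um at 4 um/s
  k1 <- build_kymograph(make_axis_movie(xs),
                        cbind(x = c(1, 30), y = c(0, 0)))
  c1 <- classify_movement(k1, continuous_min_length = 15)
  expect_equal(c1$label, "continuous")
  expect_gte(c1$qualifying_run_length, 15)
  # stop-and-go with 8 um runs -> discontinuous by construction
  pos <- numeric(60); x <- 4; mode <- rep(c(TRUE, FALSE), each = 20)
  for (i in seq_len(60)) {
    if (mode[(i - 1) %% 40 + 1]) x <- x + 0.4
    pos[i] <- x
  }
  k2 <- build_kymograph(make_axis_movie(as.list(pos)),
                        cbind(x = c(1, 30), y = c(0, 0)))
  c2 <- classify_movement(k2, continuous_min_length = 15)
  expect_equal(c2$label, "discontinuous")
  # stationary -> discontinuous
  k3 <- build_kymograph(make_axis_movie(rep(list(10), 30)),
                        cbind(x = c(1, 30), y = c(0, 0)))
  expect_equal(classify_movement(k3)$label, "discontinuous")
})

test_that("track-level classification recovers the generator mixture", {
  geom <- root_hair_geometry("mature")
  axis <- geometry_axis(geom)
  tr <- simulate_population(geom, get_preset("FYVE"), 50, 20, seed = 41,
                            n_dancing_pairs = 0, n_fusion_pairs = 0)
  tk <- truth_to_tracks(tr, noise_sd = 0.03, seed = 42)
  labs <- vapply(split(tk, tk$track_id), function(d) {
    classify_track_movement(d, axis)$label
  }, character(1))
  f <- mean(labs == "continuous")
  expect_lt(abs(f - 0.4), 0.1)
})
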