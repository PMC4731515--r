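# DoG detection vs brute-force local maxima; watershed sizing; area
# fractions.

test_that("flat frames yield no detections", {
  m <- matrix(0, 64, 64)
  attr(m, "pixel_size") <- 0.26
  expect_equal(nrow(dog_detect(m, detection_params())), 0)
  m2 <- matrix(7, 64, 64)
  attr(m2, "pixel_size") <- 0.26
  expect_equal(nrow(dog_detect(m2, detection_params())), 0)
})

test_that("oversized dog_diameter is rejected", {
  m <- matrix(runif(64), 8, 8)
  expect_error(dog_detect(m, detection_params(dog_diameter = 20)),
               "larger than the image")
})

test_that("a single rendered spot is localized within 0.25 px", {
  m <- make_spot_frame(cbind(x = 10.30, y = 20.70))
  sp <- dog_detect(m, detection_params(use_median_filter = FALSE))
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x_um / 0.26 - 10.30), 0.25)
  expect_lt(abs(sp$y_um / 0.26 - 20.70), 0.25)
  # intensity-centroid oracle on the noise-free frame agrees
  cx <- sum(sweep(m, 2, seq_len(ncol(m)) - 0.5, "*")) / sum(m)
  cy <- sum(sweep(m, 1, seq_len(nrow(m)) - 0.5, "*")) / sum(m)
  expect_lt(abs(sp$x_um / 0.26 - cx), 0.25)
  expect_lt(abs(sp$y_um / 0.26 - cy), 0.25)
})

test_that("well-separated equal spots are all found, ordered by quality then scan order", {
  m <- make_spot_frame(cbind(x = c(20.5, 30.5), y = c(20.5, 20.5)))
  sp <- dog_detect(m, detection_params(use_median_filter = FALSE))
  expect_equal(nrow(sp), 2)
  expect_true(all(diff(sp$quality) <= 1e-9))
  # equal quality: row-major tie-break puts the left spot first
  expect_lt(sp$x_um[1], sp$x_um[2])
})

test_that("detection equals a brute-force maxima scan on multi-spot frames", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    pos <- cbind(x = runif(n, 8, 56), y = runif(n, 8, 56))
    # enforce >= 6 px separation
    keep <- rep(TRUE, n)
    for (i in seq_len(n)[-1]) {
      if (any(sqrt((pos[seq_len(i - 1), 1][keep[seq_len(i - 1)]] - pos[i, 1])^2 +
                   (pos[seq_len(i - 1), 2][keep[seq_len(i - 1)]] - pos[i, 2])^2) < 6)) {
        keep[i] <- FALSE
      }
    }
    pos <- pos[keep, , drop = FALSE]
    m <- make_spot_frame(pos)
    sp <- dog_detect(m, detection_params(use_median_filter = FALSE,
                                         subpixel = FALSE))
    expect_equal(nrow(sp), nrow(pos))
    for (i in seq_len(nrow(pos))) {
      d <- sqrt((sp$x_um / 0.26 - pos[i, 1])^2 + (sp$y_um / 0.26 - pos[i, 2])^2)
      expect_lt(min(d), 1)
    }
  }
})

test_that("sub-pixel refinement never moves a spot more than 0.5 px", {
  set.seed(12)
  pos <- cbind(x = runif(6, 8, 56), y = runif(6, 8, 56))
  m <- make_spot_frame(pos)
  a <- dog_detect(m, detection_params(use_median_filter = FALSE, subpixel = FALSE))
  b <- dog_detect(m, detection_params(use_median_filter = FALSE, subpixel = TRUE))
  expect_equal(nrow(a), nrow(b))
  a <- dplyr::arrange(a, .data$x_um, .data$y_um)
  b <- dplyr::arrange(b, .data$x_um, .data$y_um)
  expect_true(all(abs(a$x_um - b$x_um) / 0.26 <= 0.5 + 1e-9))
  expect_true(all(abs(a$y_um - b$y_um) / 0.26 <= 0.5 + 1e-9))
})

test_that("watershed sizing recovers a disk's equivalent diameter", {
  m <- matrix(0, 41, 41)
  for (r in 1:41) for (cc in 1:41) {
    if ((r - 20.5)^2 + (cc - 20.5)^2 <= 5^2) m[r, cc] <- 100
  }
  attr(m, "pixel_size") <- 0.26
  spots <- tibble::tibble(frame = 0L, t = 0, x_um = 20 * 0.26,
                          y_um = 20 * 0.26, intensity = 100, quality = 1)
  out <- measure_diameter_watershed(m, spots, threshold = 50)
  # rasterized disk of radius 5 px: diameter ~ 2 * 5 px * 0.26 = 2.6 um
  expect_lt(abs(out$diameter_um - 2.6), 0.26)
})

test_that("seeded watershed splits touching objects", {
  pos <- cbind(x = c(18, 24), y = c(20, 20))
  m <- make_spot_frame(pos, sigma_px = 2.5, nrow_px = 41, ncol_px = 41)
  spots <- tibble::tibble(frame = 0L, t = 0, x_um = pos[, 1] * 0.26,
                          y_um = pos[, 2] * 0.26, intensity = 1, quality = 1)
  out <- measure_diameter_watershed(m, spots)
  expect_true(all(!is.na(out$diameter_um)))
  # union area oracle: each split region is smaller than the union
  rng <- range(m)
  img <- (m - rng[1]) / (rng[2] - rng[1])
  mask_area <- sum(img > EBImage::otsu(img, range = c(0, 1)))
  d_union <- 2 * sqrt(mask_area / pi) * 0.26
  expect_true(all(out$diameter_um < d_union))
})

test_that("empty spot list passes through watershed unchanged", {
  m <- make_spot_frame(cbind(x = 20, y = 20))
  empty <- tibble::tibble(frame = integer(), t = numeric(), x_um = numeric(),
                          y_um = numeric(), intensity = numeric(),
                          quality = numeric())
  out <- measure_diameter_watershed(m, empty)
  expect_equal(nrow(out), 0)
})

test_that("area_fraction counts pixels exactly and is monotone in threshold", {
  img <- matrix(0, 10, 10)
  img[1:5, ] <- 10                      # exactly half above
  labels <- matrix("apical", 10, 10)
  af <- area_fraction(img, labels, threshold = 5)
  expect_equal(af$fraction, 0.5)
  expect_equal(area_fraction(matrix(0, 4, 4), matrix("apical", 4, 4),
                             threshold = 1)$fraction, 0)
  expect_equal(area_fraction(matrix(9, 4, 4), matrix("apical", 4, 4),
                             threshold = 5)$fraction, 1)
  # monotone non-increasing in threshold
  set.seed(3)
  img2 <- matrix(runif(100), 10, 10)
  fr <- vapply(c(0.2, 0.4, 0.6, 0.8),
               function(th) area_fraction(img2, labels, threshold = th)$fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("single-pixel zones are handled", {
  labels <- matrix("outside", 4, 4)
  labels[1, 1] <- "apical"
  af <- area_fraction(matrix(1, 4, 4), labels, threshold = 0.5)
  expect_equal(af$fraction[af$zone == "apical"], 1)
})
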