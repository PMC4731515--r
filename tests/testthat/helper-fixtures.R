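# Shared fixtures: small synthetic frames and brute-force oracles.

# Noise-free frame with Gaussian spots at sub-pixel positions (px units).
# positions: matrix/data.frame with columns x, y in PIXEL coordinates
# (pixel centre convention: centre of pixel (row, col) is (col - 0.5,
# row - 0.5) + origin/pixel_size ... here origin = c(0, 0), pixel_size
# in um/px so that x_um = x_px * pixel_size).
make_spot_frame <- function(positions, sigma_px = 0.85, amplitude = 100,
                            nrow_px = 64, ncol_px = 64, background = 0,
                            pixel_size = 0.26) {
  m <- matrix(background, nrow_px, ncol_px)
  for (i in seq_len(nrow(positions))) {
    cx <- positions[i, 1] + 0.5   # pixel-centre index coordinates
    cy <- positions[i, 2] + 0.5
    ix <- pmax(1, floor(cx - 5 * sigma_px)):pmin(ncol_px, ceiling(cx + 5 * sigma_px))
    iy <- pmax(1, floor(cy - 5 * sigma_px)):pmin(nrow_px, ceiling(cy + 5 * sigma_px))
    gx <- exp(-((ix - cx)^2) / (2 * sigma_px^2))
    gy <- exp(-((iy - cy)^2) / (2 * sigma_px^2))
    m[iy, ix] <- m[iy, ix] + amplitude * (gy %o% gx)
  }
  attr(m, "pixel_size") <- pixel_size
  attr(m, "origin") <- c(0, 0)
  m
}

# Brute-force 2D local maxima above a threshold: a pixel is a maximum if
# it is >= all pixels within Chebyshev radius h (scan in row-major order).
brute_local_maxima <- function(m, h = 1L, thresh = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- NULL
  for (r in (h + 1):(nr - h)) {
    for (cc in (h + 1):(nc - h)) {
      w <- m[(r - h):(r + h), (cc - h):(cc + h)]
      if (m[r, cc] >= thresh && m[r, cc] == max(w)) {
        out <- rbind(out, c(row = r, col = cc))
      }
    }
  }
  out
}

# Brute-force optimal gated matching cost: minimum over all feasible
# partial matchings of sum(cost of links) + gate_cost * (number of
# unmatched rows + columns). Enumeration, for tiny instances only.
brute_match_cost <- function(cost, gate_cost) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  best <- Inf
  recurse <- function(i, used_cols, acc) {
    if (acc >= best) return()
    if (i > n1) {
      total <- acc + gate_cost * (n2 - sum(used_cols))
      if (total < best) best <<- total
      return()
    }
    # row i unmatched
    recurse(i + 1, used_cols, acc + gate_cost)
    for (j in seq_len(n2)) {
      if (!used_cols[j] && cost[i, j] <= gate_cost) {
        used_cols[j] <- TRUE
        recurse(i + 1, used_cols, acc + cost[i, j])
        used_cols[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, n2), 0)
  best
}

# Cost of the matching produced by lap_match_gated under the same
# objective as brute_match_cost.
matching_cost <- function(cost, match, gate_cost) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  linked <- !is.na(match)
  sum(cost[cbind(which(linked), match[linked])]) +
    gate_cost * (sum(!linked) + (n2 - sum(linked)))
}

# Track tibble from explicit positions.
make_track <- function(id, x, y, t = seq_along(x) * 0.1 - 0.1,
                       intensity = 1) {
  tibble::tibble(track_id = id, frame = seq_along(x) - 1L, t = t,
                 x_um = x, y_um = y,
                 intensity = rep_len(intensity, length(x)),
                 inferred = FALSE)
}

# all permutations of 1..n (tiny n)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  unname(out)
}
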