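# FWHM-based size measurement on SIM-like frames.

#' FWHM of a normalized intensity profile across a particle
#'
#' Samples the image along a line through `center` (bilinear
#' interpolation at `pixel_size / 4` steps), subtracts the background
#' (median of the profile endpoints), min-max normalizes, and returns the
#' distance between the first and the last crossing of 0.5 — so a
#' two-peaked ring profile yields its outer extent. The number of peaks
#' (local maxima at height >= 0.5 with prominence >= 0.15) and, for
#' two-peaked profiles, the peak-to-peak distance are recorded.
#'
#' @param frame Numeric matrix with `pixel_size` (um/px) and `origin`
#'   attributes (e.g. from [render_sim_frame()]).
#' @param center Particle centre, um: `c(x, y)`.
#' @param direction Unit vector of the profile direction (default
#'   horizontal).
#' @param length_um Profile length, um (default 8x the PSF-scale width of
#'   the frame's features, 1.6 um).
#' @return A one-row tibble: fwhm_nm, n_peaks, peak_to_peak_nm, plus the
#'   sampled profile as attribute `profile` (tibble pos_nm, value).
#' @export
fwhm_profile <- function(frame, center, direction = c(1, 0),
                         length_um = 1.6) {
  px <- attr(frame, "pixel_size") %||% 1
  origin <- attr(frame, "origin") %||% c(0, 0)
  direction <- direction / sqrt(sum(direction^2))
  step <- px / 4
  s <- seq(-length_um / 2, length_um / 2, by = step)
  qx <- center[1] + s * direction[1]
  qy <- center[2] + s * direction[2]
  cxp <- (qx - origin[1]) / px + 0.5
  ryp <- (qy - origin[2]) / px + 0.5
  nr <- nrow(frame); nc <- ncol(frame)
  if (any(cxp < 1 | cxp > nc | ryp < 1 | ryp > nr)) {
    rlang::abort("profile segment leaves the frame")
  }
  prof <- bilinear_sample(unclass(frame), ryp, cxp)
  n <- length(prof)
  ends <- c(prof[1:3], prof[(n - 2):n])
  prof <- prof - stats::median(ends)
  mx <- max(prof)
  if (mx <= 0) rlang::abort("flat profile: no signal above background")
  prof <- prof / mx
  above <- which(prof >= 0.5)
  if (!length(above) || above[1] == 1 || above[length(above)] == n) {
    rlang::abort("profile has no clean half-maximum crossings (flat or saturated)")
  }
  cross <- function(i0, i1) {
    # linear interpolation of the 0.5 crossing between samples i0 < i1
    s[i0] + (0.5 - prof[i0]) / (prof[i1] - prof[i0]) * (s[i1] - s[i0])
  }
  first <- above[1]; last <- above[length(above)]
  x_left <- cross(first - 1L, first)
  x_right <- cross(last + 1L, last)
  fwhm_um <- x_right - x_left
  # peaks: local maxima >= 0.5 with prominence >= 0.15
  pk <- integer(0)
  for (i in 2:(n - 1)) {
    if (prof[i] >= 0.5 && prof[i] >= prof[i - 1] && prof[i] > prof[i + 1]) {
      pk <- c(pk, i)
    }
  }
  if (length(pk) > 1) {
    keep <- rep(TRUE, length(pk))
    for (j in seq_along(pk)[-1]) {
      valley <- min(prof[pk[j - 1]:pk[j]])
      if (min(prof[pk[j - 1]], prof[pk[j]]) - valley < 0.15) {
        drop_j <- if (prof[pk[j]] < prof[pk[j - 1]]) j else j - 1
        keep[drop_j] <- FALSE
      }
    }
    pk <- pk[keep]
  }
  n_peaks <- max(1L, length(pk))
  ptp <- if (length(pk) >= 2) (s[pk[length(pk)]] - s[pk[1]]) * 1000 else NA_real_
  out <- tibble::tibble(fwhm_nm = fwhm_um * 1000, n_peaks = n_peaks,
                        peak_to_peak_nm = ptp)
  attr(out, "profile") <- tibble::tibble(pos_nm = s * 1000, value = prof)
  out
}

#' Size distribution summary
#'
#' @param diameters Numeric vector of measured diameters (nm), or a
#'   tibble with an `fwhm_nm` column.
#' @param bin_width Histogram bin width, nm (default 20).
#' @return A `size_distribution` object: list with `histogram` (tibble:
#'   bin_mid, count) and `summary` (tibble: mean, sd, min, max, n);
#'   [generics::tidy()] returns the histogram, [generics::glance()] the
#'   summary.
#' @export
size_distribution <- function(diameters, bin_width = 20) {
  d <- if (is.data.frame(diameters)) diameters$fwhm_nm else diameters
  d <- d[!is.na(d)]
  if (!length(d)) rlang::abort("no size records")
  lo <- floor(min(d) / bin_width) * bin_width
  breaks <- seq(lo, max(d) + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(
    list(histogram = tibble::tibble(bin_mid = h$mids, count = h$counts),
         summary = tibble::tibble(mean = mean(d),
                                  sd = if (length(d) > 1) stats::sd(d) else NA_real_,
                                  min = min(d), max = max(d), n = length(d))),
    class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  s <- x$summary
  cat("<size_distribution> n =", s$n, " mean =", signif(s$mean, 4),
      "nm  sd =", signif(s$sd, 3), " range =", signif(s$min, 4), "-",
      signif(s$max, 4), "nm\n")
  invisible(x)
}
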