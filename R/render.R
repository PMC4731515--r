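# Optical forward model: particles -> photon-count images.

#' Optics configuration
#'
#' Acquisition parameters for the two supported modalities. Spinning-disc
#' defaults follow routine settings for EMCCD spinning-disc imaging of
#' root hairs (0.26 um/px, 0.1 s/frame, PSF FWHM 0.25 um ~ the
#' diffraction limit of the NA 1.2-1.57 objectives used for this kind of
#' imaging); SIM defaults emulate reconstructed super-resolution frames
#' (~100 nm lateral resolution, finely sampled at 25 nm/px).
#'
#' @param modality `"spinning_disc"` or `"sim"`.
#' @param pixel_size um/px.
#' @param frame_interval s/frame (ignored for single SIM frames).
#' @param psf_fwhm Point-spread-function FWHM, um.
#' @param background Background level, photons/px.
#' @param photon_scale Photons per unit ground-truth intensity.
#' @param read_noise_sigma Gaussian read noise RMS, photons.
#' @param seed Integer seed for the rendering noise.
#' @return An `optics_config` list.
#' @export
optics_config <- function(modality = c("spinning_disc", "sim"),
                          pixel_size = NULL, frame_interval = 0.1,
                          psf_fwhm = NULL, background = NULL,
                          photon_scale = NULL, read_noise_sigma = 2,
                          seed = 1) {
  modality <- match.arg(modality)
  pixel_size <- pixel_size %||% switch(modality, spinning_disc = 0.26, sim = 0.025)
  psf_fwhm <- psf_fwhm %||% switch(modality, spinning_disc = 0.25, sim = 0.1)
  background <- background %||% switch(modality, spinning_disc = 10, sim = 2)
  photon_scale <- photon_scale %||% switch(modality, spinning_disc = 100, sim = 200)
  if (pixel_size <= 0) rlang::abort("pixel_size must be positive")
  if (modality == "spinning_disc" && frame_interval <= 0) {
    rlang::abort("frame_interval must be positive")
  }
  if (psf_fwhm <= 0) rlang::abort("psf_fwhm must be positive")
  structure(list(modality = modality, pixel_size = pixel_size,
                 frame_interval = frame_interval, psf_fwhm = psf_fwhm,
                 background = background, photon_scale = photon_scale,
                 read_noise_sigma = read_noise_sigma, seed = seed),
            class = "optics_config")
}

# Add one Gaussian of total `photons` to `img`, integrating the profile
# over each pixel area (what a camera pixel does); photon count and
# centroid are conserved exactly up to the 5-sigma patch truncation.
add_gaussian <- function(img, cx, cy, sigma_px, photons) {
  nr <- nrow(img); nc <- ncol(img)
  R <- ceiling(5 * sigma_px) + 1L
  ix0 <- floor(cx) - R; ix1 <- ceiling(cx) + R
  iy0 <- floor(cy) - R; iy1 <- ceiling(cy) + R
  if (ix1 < 1 || iy1 < 1 || ix0 > nc || iy0 > nr) return(img)
  ix <- max(1L, ix0):min(nc, ix1)
  iy <- max(1L, iy0):min(nr, iy1)
  gx <- stats::pnorm((ix + 0.5 - cx) / sigma_px) -
    stats::pnorm((ix - 0.5 - cx) / sigma_px)
  gy <- stats::pnorm((iy + 0.5 - cy) / sigma_px) -
    stats::pnorm((iy - 0.5 - cy) / sigma_px)
  img[iy, ix] <- img[iy, ix] + photons * (gy %o% gx)
  img
}

#' Render a ground-truth population as a spinning-disc movie
#'
#' One frame per ground-truth time point. Each particle is a 2D Gaussian
#' whose FWHM is `max(psf_fwhm, apparent_diameter)` and whose integrated
#' signal is `intensity * photon_scale` photons (so fluorescence is
#' conserved on fusion). Photon shot noise is Poisson on background plus
#' signal; Gaussian read noise is added on top. Particles whose 3-sigma
#' footprint leaves the field of view are clipped silently and listed in
#' the render report (`attr(stack, "render_report")`).
#'
#' @param truth An `endosome_truth` from [simulate_population()].
#' @param optics An [optics_config()] with `modality = "spinning_disc"`.
#' @param noise Apply shot/read noise? (`FALSE` gives the noise-free
#'   expectation image.)
#' @return An `image_stack`: numeric array (rows x cols x frames) of
#'   photon counts with attributes `pixel_size` (um/px), `frame_interval`
#'   (s), `origin` (um coordinates of the image corner) and
#'   `render_report`.
#' @export
render_movie <- function(truth, optics = optics_config("spinning_disc"),
                         noise = TRUE) {
  if (optics$modality != "spinning_disc") {
    rlang::abort("render_movie requires spinning_disc optics")
  }
  geometry <- attr(truth, "geometry")
  dt <- attr(truth, "frame_interval") %||% optics$frame_interval
  duration <- attr(truth, "duration") %||%
    ((max(truth$particles$frame, 0) + 1) * dt)
  n_frames <- max(1L, round(duration / dt))
  px <- optics$pixel_size
  r <- geometry$radius
  t_last <- (n_frames - 1) * dt
  Lx <- tip_at(geometry, t_last) + 2      # 1 um margin past base and tip
  nx <- ceiling(Lx / px); ny <- ceiling(2 * (r + 1) / px)
  origin <- c(-1, -(r + 1))
  frames <- purrr::map(seq_len(n_frames), ~ matrix(0, ny, nx))
  clipped <- list()
  p <- truth$particles
  if (nrow(p)) {
    sig_um <- fwhm_to_sigma(pmax(optics$psf_fwhm, p$apparent_diameter / 1000))
    sig_px <- sig_um / px
    cx <- (p$x - origin[1]) / px + 0.5
    cy <- (p$y - origin[2]) / px + 0.5
    photons <- p$intensity * optics$photon_scale
    for (i in seq_len(nrow(p))) {
      k <- p$frame[i] + 1L
      ext <- 3 * sig_px[i]
      if (cx[i] - ext < 0.5 || cx[i] + ext > nx + 0.5 ||
          cy[i] - ext < 0.5 || cy[i] + ext > ny + 0.5) {
        clipped[[length(clipped) + 1L]] <-
          tibble::tibble(particle_id = p$particle_id[i], frame = p$frame[i])
      }
      frames[[k]] <- add_gaussian(frames[[k]], cx[i], cy[i], sig_px[i],
                                  photons[i])
    }
  }
  stack <- array(unlist(frames), dim = c(ny, nx, n_frames)) +
    optics$background
  if (noise) {
    stack <- with_seed(optics$seed, {
      shot <- array(stats::rpois(length(stack), lambda = stack), dim = dim(stack))
      shot + array(stats::rnorm(length(stack), 0, optics$read_noise_sigma),
                   dim = dim(stack))
    })
  }
  structure(stack, class = c("image_stack", "array"),
            pixel_size = px, frame_interval = dt, origin = origin,
            render_report = if (length(clipped)) purrr::list_rbind(clipped)
                            else tibble::tibble(particle_id = integer(),
                                                frame = integer()))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat("<image_stack>", d[1], "x", d[2], "px,", d[3], "frames,",
      attr(x, "pixel_size"), "um/px,", attr(x, "frame_interval"), "s/frame\n")
  invisible(x)
}

# Outer-extent FWHM of a thin ring of radius r0 convolved with a Gaussian
# PSF of sd `sigma` (all nm), from the analytic angular integral of the
# line profile through the centre.
ring_outer_fwhm <- function(r0, sigma) {
  xs <- seq(0, r0 + 5 * sigma, by = max(0.5, sigma / 20))
  th <- seq(0, pi, length.out = 61)
  ct <- r0 * cos(th); st2 <- (r0 * sin(th))^2
  prof <- vapply(xs, function(x) {
    mean(exp(-((x - ct)^2 + st2) / (2 * sigma^2)))
  }, numeric(1))
  pk <- max(prof)
  half <- pk / 2
  above <- which(prof >= half)
  i_last <- max(above)
  if (i_last == length(prof)) return(2 * xs[i_last])
  x0 <- xs[i_last]; x1 <- xs[i_last + 1]
  f0 <- prof[i_last]; f1 <- prof[i_last + 1]
  xh <- x0 + (half - f0) / (f1 - f0) * (x1 - x0)
  2 * xh
}

# Shell radius whose rendered outer-extent FWHM equals `target_nm`.
# The monotone r0 -> outer-FWHM curve is tabulated once per PSF width
# and inverted by interpolation.
.ring_cal_cache <- new.env(parent = emptyenv())

ring_radius_for_fwhm <- function(target_nm, psf_fwhm_nm) {
  key <- sprintf("psf%.3f", psf_fwhm_nm)
  cal <- .ring_cal_cache[[key]]
  if (is.null(cal) || max(cal$fwhm) < max(target_nm)) {
    sigma <- fwhm_to_sigma(psf_fwhm_nm)
    r0s <- seq(2, max(400, max(target_nm)), length.out = 120)
    fw <- vapply(r0s, ring_outer_fwhm, numeric(1), sigma = sigma)
    cal <- list(r0 = r0s, fwhm = fw)
    .ring_cal_cache[[key]] <- cal
  }
  stats::approx(cal$fwhm, cal$r0, xout = target_nm, rule = 2)$y
}

#' Render a single SIM-like frame
#'
#' Early-class particles are rendered as Gaussian spots whose profile
#' FWHM equals the requested apparent diameter by construction (the PSF
#' is folded into the apparent size). Late-class particles are rendered
#' as thin circular shells convolved with the SIM PSF; the shell radius
#' is calibrated numerically so that the outer-extent FWHM of a profile
#' through the centre equals the requested apparent diameter, and the
#' profile is two-peaked (ring-like). Late particles whose apparent
#' diameter is below the PSF FWHM cannot form a resolvable ring; they are
#' rendered as PSF-limited spots and flagged in `attr(frame, "flags")`.
#'
#' @param particles Tibble/data frame with columns `x`, `y` (um),
#'   `diameter_nm`, `class` ("early"/"late"); optional `intensity`
#'   (default 1).
#' @param optics An [optics_config()] with `modality = "sim"`.
#' @param width_um,height_um Field of view (default: particle extent plus
#'   a 1 um margin).
#' @param noise Apply shot/read noise (default `FALSE`: reconstructed SIM
#'   frames are treated as noise-averaged).
#' @return Numeric matrix of photon counts with attributes `pixel_size`,
#'   `origin` and `flags`.
#' @export
render_sim_frame <- function(particles, optics = optics_config("sim"),
                             width_um = NULL, height_um = NULL,
                             noise = FALSE) {
  if (optics$modality != "sim") rlang::abort("render_sim_frame requires sim optics")
  px <- optics$pixel_size
  p <- tibble::as_tibble(particles)
  if (nrow(p) && !"intensity" %in% names(p)) p$intensity <- 1
  if (nrow(p)) {
    x0 <- min(p$x) - 1; x1 <- max(p$x) + 1
    y0 <- min(p$y) - 1; y1 <- max(p$y) + 1
  } else {
    x0 <- 0; y0 <- 0; x1 <- width_um %||% 5; y1 <- height_um %||% 5
  }
  if (!is.null(width_um)) x1 <- x0 + width_um
  if (!is.null(height_um)) y1 <- y0 + height_um
  nx <- ceiling((x1 - x0) / px); ny <- ceiling((y1 - y0) / px)
  origin <- c(x0, y0)
  img <- matrix(0, ny, nx)
  flags <- list()
  psf_sigma_px <- fwhm_to_sigma(optics$psf_fwhm) / px
  for (i in seq_len(nrow(p))) {
    cx <- (p$x[i] - origin[1]) / px + 0.5
    cy <- (p$y[i] - origin[2]) / px + 0.5
    photons <- p$intensity[i] * optics$photon_scale
    d_nm <- p$diameter_nm[i]
    if (p$class[i] == "early") {
      img <- add_gaussian(img, cx, cy, fwhm_to_sigma(d_nm / 1000) / px, photons)
    } else if (d_nm < optics$psf_fwhm * 1000) {
      flags[[length(flags) + 1L]] <- tibble::tibble(
        index = i, reason = "ring below PSF resolution")
      img <- add_gaussian(img, cx, cy, psf_sigma_px, photons)
    } else {
      r0_px <- ring_radius_for_fwhm(d_nm, optics$psf_fwhm * 1000) / 1000 / px
      K <- max(36L, ceiling(2 * pi * r0_px / (0.4 * psf_sigma_px)))
      th <- (seq_len(K) - 1) * 2 * pi / K
      R <- ceiling(r0_px + 4 * psf_sigma_px) + 1L
      ix <- max(1L, floor(cx) - R):min(nx, ceiling(cx) + R)
      iy <- max(1L, floor(cy) - R):min(ny, ceiling(cy) + R)
      X <- matrix(ix, length(iy), length(ix), byrow = TRUE)
      Y <- matrix(iy, length(iy), length(ix))
      patch <- matrix(0, length(iy), length(ix))
      for (j in seq_len(K)) {
        xk <- cx + r0_px * cos(th[j]); yk <- cy + r0_px * sin(th[j])
        gxk <- stats::pnorm((ix + 0.5 - xk) / psf_sigma_px) -
          stats::pnorm((ix - 0.5 - xk) / psf_sigma_px)
        gyk <- stats::pnorm((iy + 0.5 - yk) / psf_sigma_px) -
          stats::pnorm((iy - 0.5 - yk) / psf_sigma_px)
        patch <- patch + (photons / K) * (gyk %o% gxk)
      }
      img[iy, ix] <- img[iy, ix] + patch
    }
  }
  img <- img + optics$background
  if (noise) {
    img <- with_seed(optics$seed, {
      matrix(stats::rpois(length(img), img), ny, nx) +
        matrix(stats::rnorm(length(img), 0, optics$read_noise_sigma), ny, nx)
    })
  }
  structure(img, pixel_size = px, origin = origin,
            flags = if (length(flags)) purrr::list_rbind(flags)
                    else tibble::tibble(index = integer(), reason = character()))
}
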