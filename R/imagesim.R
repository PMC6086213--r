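## synthetic two-photon-like rendering of axon segments and beads

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # sigma = FWHM * this

#' Imaging geometry, optics, and noise specification
#'
#' Defaults mirror a high-resolution in vivo two-photon setup: 0.1 um lateral
#' pixels, 1 um z-steps, a 0.4 um lateral / 2.0 um axial FWHM Gaussian
#' point-spread function, and motion amplitudes inside the quality gates used
#' for chronic imaging (slow drift < 5 px, fast jitter < 2 px).
#'
#' @param pixel_size lateral um/pixel
#' @param z_step axial step in um
#' @param psf_fwhm_lateral,psf_fwhm_axial Gaussian PSF FWHMs in um
#' @param axon_shaft_diameter shaft FWHM in um (Gaussian cross-section)
#' @param background_level additive background, counts
#' @param photon_scale shaft peak intensity in the noise-free image, counts
#' @param noise_model one of `"poisson"`, `"gaussian"`, `"poisson+gaussian"`,
#'   `"none"`
#' @param gaussian_sd read-noise SD in counts (gaussian models)
#' @param slow_drift_amplitude per-stack rigid drift bound, pixels
#' @param fast_jitter_amplitude per-frame jitter bound, pixels
#' @param fov nominal field of view in um (metadata; rendering crops to the
#'   traced axon plus a margin)
#' @return an object of class `imaging_spec`
#' @export
imaging_spec <- function(pixel_size = 0.1, z_step = 1.0,
                         psf_fwhm_lateral = 0.4, psf_fwhm_axial = 2.0,
                         axon_shaft_diameter = 0.6,
                         background_level = 10, photon_scale = 100,
                         noise_model = c("poisson", "gaussian",
                                         "poisson+gaussian", "none"),
                         gaussian_sd = 3,
                         slow_drift_amplitude = 2, fast_jitter_amplitude = 1,
                         fov = 360) {
  noise_model <- match.arg(noise_model)
  if (psf_fwhm_lateral < 2 * pixel_size)
    stop_named("psf_fwhm_lateral must be >= 2 pixels for renderability")
  if (slow_drift_amplitude >= 5 || fast_jitter_amplitude >= 2)
    stop_named("motion amplitudes outside imaging quality gates (<5 / <2 px)")
  structure(list(pixel_size = pixel_size, z_step = z_step,
                 psf_fwhm_lateral = psf_fwhm_lateral,
                 psf_fwhm_axial = psf_fwhm_axial,
                 axon_shaft_diameter = axon_shaft_diameter,
                 background_level = background_level,
                 photon_scale = photon_scale, noise_model = noise_model,
                 gaussian_sd = gaussian_sd,
                 slow_drift_amplitude = slow_drift_amplitude,
                 fast_jitter_amplitude = fast_jitter_amplitude, fov = fov),
            class = "imaging_spec")
}

gauss_kernel <- function(sigma_px) {
  if (sigma_px < 1e-6) return(1)
  r <- ceiling(4 * sigma_px)
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k / sum(k)
}

## separable convolution along rows (x), columns (y) and planes (z)
conv_x <- function(plane, k) {
  if (length(k) == 1) return(plane)
  r <- (length(k) - 1) / 2
  n <- ncol(plane)
  t(apply(plane, 1, function(row)
    stats::convolve(row, rev(k), type = "open")[(r + 1):(r + n)]))
}

conv_y_matrix <- function(ny, k) {
  if (length(k) == 1) return(diag(ny))
  r <- (length(k) - 1) / 2
  idx <- outer(seq_len(ny), seq_len(ny), "-") + r + 1
  K <- matrix(0, ny, ny)
  inb <- idx >= 1 & idx <= length(k)
  K[inb] <- k[idx[inb]]
  K
}

psf_convolve <- function(vox, spec) {
  dims <- dim(vox)
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  kl <- gauss_kernel(spec$psf_fwhm_lateral * FWHM_TO_SIGMA /
                       spec$pixel_size)
  kz <- gauss_kernel(spec$psf_fwhm_axial * FWHM_TO_SIGMA / spec$z_step)
  Ky <- conv_y_matrix(ny, kl)
  for (z in seq_len(nz))
    vox[, , z] <- Ky %*% conv_x(vox[, , z], kl)
  if (length(kz) > 1 && nz > 1) {
    Kz <- conv_y_matrix(nz, kz)
    m <- matrix(vox, ny * nx, nz)
    vox <- array(m %*% t(Kz), dims)
  }
  vox
}

apply_noise <- function(vox, spec) {
  n <- length(vox)
  if (spec$noise_model %in% c("poisson", "poisson+gaussian"))
    vox <- array(stats::rpois(n, pmax(vox, 0)), dim(vox))
  if (spec$noise_model %in% c("gaussian", "poisson+gaussian"))
    vox <- vox + array(stats::rnorm(n, 0, spec$gaussian_sd), dim(vox))
  vox
}

## analytic post-PSF peak of an infinite line source with Gaussian
## cross-section of SD sigma_s, unit density amplitude
line_peak_factor <- function(sigma_s, spec) {
  sl <- spec$psf_fwhm_lateral * FWHM_TO_SIGMA
  sa <- spec$psf_fwhm_axial * FWHM_TO_SIGMA
  (sigma_s / sqrt(sigma_s^2 + sl^2)) * (sigma_s / sqrt(sigma_s^2 + sa^2))
}

#' Render a synthetic two-photon image stack of one axonal segment
#'
#' Draws the axon as a tube with Gaussian cross-section along a smooth
#' low-tortuosity planar path, places every ground-truth bouton present on
#' `day` as a Gaussian blob of its true diameter (FWHM) with peak emission
#' 2.5x the shaft, convolves the volume with the anisotropic Gaussian PSF,
#' applies per-stack drift and per-frame jitter, scales so the shaft peaks
#' near `photon_scale` counts, adds background, and applies the noise model.
#' The rendered volume is a band around the traced axon (trace bounding box
#' plus `margin_um`), not the full nominal field of view.
#'
#' @param truth a `segment_truth` from [sample_segment()]
#' @param day imaging day (must be in the segment's schedule)
#' @param spec an [imaging_spec()]
#' @param seed integer seed (path wiggle, motion, noise)
#' @param margin_um empty margin around the traced axon, um
#' @return an object of class `rendered_stack`: `vox` (array y,x,z of counts),
#'   `spec`, `trace` (data frame `arc_um,x_um,y_um,z_um` in the volume frame),
#'   `segment_id`, `day`, `seed`
#' @export
render_segment <- function(truth, day, spec = imaging_spec(), seed,
                           margin_um = 5) {
  stopifnot(inherits(truth, "segment_truth"), inherits(spec, "imaging_spec"))
  if (!day %in% truth$schedule$imaging_days)
    stop_named("day %d not in the segment's imaging schedule", day)
  if (missing(seed)) stop_named("render_segment requires an explicit seed")
  px <- spec$pixel_size
  L <- truth$length_um

  with_seed(derive_seed(seed, 17L), {
    ## smooth planar path, parameterised by arc length
    a <- stats::runif(2, 0.3, 0.8)
    lam <- c(stats::runif(1, 60, 120), stats::runif(1, 35, 60))
    ph <- stats::runif(2, 0, 2 * pi)
    xf <- seq(0, L * 1.05, by = 0.05)
    yf <- a[1] * sin(2 * pi * xf / lam[1] + ph[1]) +
      a[2] * sin(2 * pi * xf / lam[2] + ph[2])
    arc <- c(0, cumsum(sqrt(diff(xf)^2 + diff(yf)^2)))
    x_of_arc <- stats::approxfun(arc, xf)
    y_of_arc <- stats::approxfun(arc, yf)

    ## volume geometry (um, volume frame; z = 0 at the axon plane)
    x0 <- margin_um
    xmax <- x_of_arc(L) + 2 * margin_um
    yr <- range(yf[arc <= L])
    y0 <- margin_um - yr[1] + 2      # path y -> volume y offset
    ymax <- diff(yr) + 2 * (margin_um + 2)
    nx <- ceiling(xmax / px); ny <- ceiling(ymax / px)
    z_vals <- seq(-4, 4, by = spec$z_step)
    nz <- length(z_vals)
    xc <- (seq_len(nx) - 0.5) * px
    yc <- (seq_len(ny) - 0.5) * px

    ## motion: one drift offset per stack, one jitter offset per frame
    drift <- stats::runif(2, -1, 1) * spec$slow_drift_amplitude * px
    jit <- matrix(stats::runif(2 * nz, -1, 1) *
                    spec$fast_jitter_amplitude * px, nz, 2)

    b <- truth$boutons[bouton_present(truth$boutons, day), , drop = FALSE]
    if (nrow(b) && any(b$arc_position_um < 0 | b$arc_position_um > L))
      stop_named("bouton %s lies outside the rendered volume",
                 b$bouton_id[which(b$arc_position_um < 0 |
                                     b$arc_position_um > L)[1]])
    bx <- x0 + x_of_arc(b$arc_position_um)
    by <- y0 + y_of_arc(b$arc_position_um)
    s_sh <- spec$axon_shaft_diameter * FWHM_TO_SIGMA

    vox <- array(0, c(ny, nx, nz))
    for (k in seq_len(nz)) {
      dxk <- drift[1] + jit[k, 1]
      dyk <- drift[2] + jit[k, 2]
      ## shifted shaft centreline y as a function of volume x
      ypk <- y0 + stats::approx(x0 + xf + dxk, yf + dyk, xout = xc,
                                rule = 2)$y
      on_axon <- xc >= x0 + dxk & xc <= x0 + x_of_arc(L) + dxk
      ## shaft: Gaussian in transverse (vertical) distance and in z
      zfac <- exp(-z_vals[k]^2 / (2 * s_sh^2))
      if (zfac > 1e-8) {
        dy2 <- (matrix(yc, ny, nx) -
                  matrix(ypk, ny, nx, byrow = TRUE))^2
        plane <- exp(-dy2 / (2 * s_sh^2)) * zfac
        plane[, !on_axon] <- 0
        vox[, , k] <- vox[, , k] + plane
      }
      ## boutons: spherical Gaussian blobs, peak emission 2.5x shaft.
      ## A varicosity is a local swelling of the neurite, so the blob
      ## replaces the shaft density where it dominates (pmax), keeping the
      ## transverse profile at the bouton a clean Gaussian of its diameter.
      if (nrow(b)) for (i in seq_len(nrow(b))) {
        s_b <- b$diameter_um[i] * FWHM_TO_SIGMA
        zf <- exp(-(z_vals[k])^2 / (2 * s_b^2))
        if (zf < 1e-8) next
        xi <- which(abs(xc - (bx[i] + dxk)) <= 4 * s_b)
        yi <- which(abs(yc - (by[i] + dyk)) <= 4 * s_b)
        if (!length(xi) || !length(yi)) next
        gx <- exp(-(xc[xi] - (bx[i] + dxk))^2 / (2 * s_b^2))
        gy <- exp(-(yc[yi] - (by[i] + dyk))^2 / (2 * s_b^2))
        vox[yi, xi, k] <- pmax(vox[yi, xi, k], 2.5 * zf * outer(gy, gx))
      }
    }

    vox <- psf_convolve(vox, spec)
    vox <- vox * (spec$photon_scale / line_peak_factor(s_sh, spec)) +
      spec$background_level
    vox <- apply_noise(vox, spec)

    arc_pts <- seq(0, L, by = 0.5)
    trace <- data.frame(arc_um = arc_pts,
                        x_um = x0 + x_of_arc(arc_pts),
                        y_um = y0 + y_of_arc(arc_pts),
                        z_um = 0)
    structure(list(vox = vox, spec = spec, trace = trace,
                   z_values_um = z_vals, segment_id = truth$segment_id,
                   day = day, seed = seed),
              class = "rendered_stack")
  })
}

#' @export
print.rendered_stack <- function(x, ...) {
  d <- dim(x$vox)
  cat(sprintf(
    "rendered_stack %s day %s: %d x %d px x %d planes (%.1f x %.1f um)\n",
    x$segment_id %||% "?", as.character(x$day %||% "?"), d[2], d[1], d[3],
    d[2] * x$spec$pixel_size, d[1] * x$spec$pixel_size))
  invisible(x)
}

#' Render a sub-resolution fluorescent bead
#'
#' A single bead (Gaussian emitter of FWHM equal to its diameter) at the
#' volume centre, convolved with the PSF and noised like any other stack:
#' the standard calibration image for measuring the effective resolution.
#' Measuring the rendered bead with [measure_fwhm()] should give
#' approximately the quadrature sum of bead diameter and lateral PSF FWHM.
#'
#' @param spec an [imaging_spec()]
#' @param bead_diameter bead diameter in um (> 0)
#' @param seed integer seed for the noise draw
#' @param fov_um lateral extent of the rendered crop, um
#' @return a `rendered_stack` (trace absent)
#' @export
render_bead <- function(spec = imaging_spec(), bead_diameter = 0.1,
                        seed = 1L, fov_um = 8) {
  stopifnot(bead_diameter > 0)
  px <- spec$pixel_size
  n <- ceiling(fov_um / px)
  cc <- (seq_len(n) - 0.5) * px
  ctr <- fov_um / 2
  z_vals <- seq(-4, 4, by = spec$z_step)
  s_b <- bead_diameter * FWHM_TO_SIGMA
  g <- exp(-(cc - ctr)^2 / (2 * s_b^2))
  vox <- array(0, c(n, n, length(z_vals)))
  for (k in seq_along(z_vals))
    vox[, , k] <- outer(g, g) * exp(-z_vals[k]^2 / (2 * s_b^2))
  vox <- psf_convolve(vox, spec)
  vox <- vox * (spec$photon_scale / max(vox)) + spec$background_level
  vox <- with_seed(derive_seed(seed, 23L), apply_noise(vox, spec))
  structure(list(vox = vox, spec = spec,
                 trace = NULL, z_values_um = z_vals,
                 segment_id = "bead", day = NA, seed = seed,
                 center_um = c(ctr, ctr, 0)),
            class = "rendered_stack")
}
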