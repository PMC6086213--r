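## bouton identification, measurement and classification on image stacks

## bilinear interpolation of a matrix at fractional (row, col) positions;
## zero outside the matrix
bilinear <- function(m, r, cc) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  val <- numeric(length(r))
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  get(r0, c0) * (1 - fr) * (1 - fc) + get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc + get(r0 + 1, c0 + 1) * fr * fc
}

## max-intensity projection over planes within dz_um of the trace plane
project_stack <- function(stack, z_center = 0, dz_um = 2) {
  keep <- which(abs(stack$z_values_um - z_center) <= dz_um + 1e-9)
  if (!length(keep)) keep <- seq_along(stack$z_values_um)
  apply(stack$vox[, , keep, drop = FALSE], c(1, 2), max)
}

## FWHM of a 1D profile by half-maximum crossing interpolation around the
## peak index; censored at the window edge when the profile never falls
## below half maximum
fwhm_crossings <- function(t, v, peak_idx, baseline) {
  half <- baseline + (v[peak_idx] - baseline) / 2
  left <- t[1]; right <- t[length(t)]
  i <- peak_idx
  while (i > 1 && v[i - 1] > half) i <- i - 1
  if (i > 1)
    left <- t[i - 1] + (t[i] - t[i - 1]) * (half - v[i - 1]) /
      (v[i] - v[i - 1])
  i <- peak_idx
  while (i < length(v) && v[i + 1] > half) i <- i + 1
  if (i < length(v))
    right <- t[i] + (t[i + 1] - t[i]) * (half - v[i + 1]) /
      (v[i] - v[i + 1])
  right - left
}

#' Width and intensity profile along a traced axon
#'
#' For every 0.1 um arc-length sample of the trace, extracts the intensity
#' profile perpendicular to the local trace direction from the maximum
#' projection (planes within +/-2 um of the trace plane), and measures the
#' transverse FWHM width and peak (background-subtracted) intensity. Local
#' shaft references are rolling lower quartiles over a +/-7.5 um window that
#' excludes the sample's own +/-1.5 um neighbourhood, so that neither the
#' varicosity itself nor a neighbouring bouton inflates its reference.
#'
#' @param stack a `rendered_stack`
#' @param trace backbone trace (`arc_um,x_um,y_um,z_um`); defaults to the
#'   stack's own trace
#' @param step arc sampling step, um
#' @param halfwidth transverse profile half-extent, um
#' @param ref_window,ref_exclude rolling-reference half-window and exclusion
#'   radius, um (lower-quartile reference over `+/-ref_window` excluding
#'   `+/-ref_exclude`)
#' @return an object of class `axon_profile`: data frame `arc_um`,
#'   `width_um`, `intensity`, `ref_width_um`, `ref_intensity`, with the
#'   background level and step as attributes
#' @export
extract_profile <- function(stack, trace = NULL, step = 0.1, halfwidth = 3,
                            ref_window = 7.5, ref_exclude = 1.5) {
  trace <- trace %||% stack$trace
  if (is.null(trace)) stop_named("no trace supplied and stack carries none")
  if (max(trace$arc_um) < 30)
    stop_named("trace must cover at least 30 um of arc length")
  px <- stack$spec$pixel_size
  proj <- project_stack(stack, z_center = stats::median(trace$z_um))
  bg <- stats::median(proj)

  ## resample the trace at the arc grid
  arc <- seq(0, max(trace$arc_um), by = step)
  x <- stats::approx(trace$arc_um, trace$x_um, arc)$y
  y <- stats::approx(trace$arc_um, trace$y_um, arc)$y
  if (any(x < 0 | y < 0 | x > ncol(proj) * px | y > nrow(proj) * px))
    stop_named("trace exits the imaged volume at arc %.1f um",
               arc[which(x < 0 | y < 0 | x > ncol(proj) * px |
                           y > nrow(proj) * px)[1]])
  n <- length(arc)
  tx <- c(x[2] - x[1], diff(x, lag = 2) / 2, x[n] - x[n - 1])
  ty <- c(y[2] - y[1], diff(y, lag = 2) / 2, y[n] - y[n - 1])
  nrm <- sqrt(tx^2 + ty^2)
  nxv <- -ty / nrm; nyv <- tx / nrm

  tt <- seq(-halfwidth, halfwidth, by = px)
  nt <- length(tt)
  ## all profile sample coordinates at once (n x nt)
  X <- outer(x, rep(1, nt)) + outer(nxv, tt)
  Y <- outer(y, rep(1, nt)) + outer(nyv, tt)
  P <- matrix(bilinear(proj, Y / px + 0.5, X / px + 0.5), n, nt)

  ## peak within +/-2 um of the trace, width from half-max crossings
  ctr <- which(abs(tt) <= 2)
  width <- numeric(n); intensity <- numeric(n)
  for (i in seq_len(n)) {
    p <- P[i, ]
    pk <- ctr[which.max(p[ctr])]
    intensity[i] <- p[pk] - bg
    width[i] <- fwhm_crossings(tt, p, pk, bg)
  }

  ## rolling local shaft references excluding the sample's own
  ## neighbourhood; the lower quartile (not the median) is used so that a
  ## neighbouring large bouton inside the window cannot masquerade as shaft
  iw <- round(ref_window / step); ie <- round(ref_exclude / step)
  ref_w <- numeric(n); ref_i <- numeric(n)
  for (i in seq_len(n)) {
    idx <- c(seq(max(1, i - iw), max(0, i - ie - 1)),
             seq(min(n + 1, i + ie + 1), min(n, i + iw)))
    idx <- idx[idx >= 1 & idx <= n & idx != i]
    if (!length(idx)) idx <- i
    ref_w[i] <- stats::quantile(width[idx], 0.25, names = FALSE)
    ref_i[i] <- stats::quantile(intensity[idx], 0.25, names = FALSE)
  }

  structure(data.frame(arc_um = arc, width_um = width,
                       intensity = intensity, ref_width_um = ref_w,
                       ref_intensity = ref_i),
            class = c("axon_profile", "data.frame"),
            background = bg, step = step)
}

#' Detection configuration
#'
#' @param width_excess_um minimum width above the local shaft width
#'   (default 0.3 um, i.e. 3 pixels at 0.1 um/px)
#' @param brightness_ratio minimum peak intensity over the local backbone
#'   intensity (default 2)
#' @param merge_radius_um candidate runs closer than this are merged into
#'   one call (default 1 um)
#' @param class_threshold_um alpha/beta diameter boundary (default 2 um,
#'   exclusive for alpha)
#' @return a named list
#' @export
detect_config <- function(width_excess_um = 0.3, brightness_ratio = 2,
                          merge_radius_um = 1, class_threshold_um = 2) {
  list(width_excess_um = width_excess_um,
       brightness_ratio = brightness_ratio,
       merge_radius_um = merge_radius_um,
       class_threshold_um = class_threshold_um)
}

## Split one candidate run into sub-runs, one per resolvable intensity
## peak: peaks must be separated by at least sep_pts samples and by an
## intensity valley dipping below valley_frac of the lower peak (otherwise
## they are the same varicosity). Returns a list of
## list(peak, lo, hi) index triples relative to the run.
split_run_peaks <- function(v, sep_pts, valley_frac = 0.75) {
  n <- length(v)
  v[!is.finite(v)] <- -Inf
  if (n <= 2) return(list(list(peak = which.max(v), lo = 1, hi = n)))
  is_pk <- which(v >= c(-Inf, v[-n]) & v >= c(v[-1], -Inf))
  if (!length(is_pk)) is_pk <- which.max(v)
  is_pk <- is_pk[order(v[is_pk], decreasing = TRUE)]
  acc <- integer()
  for (p in is_pk) {
    if (!length(acc)) { acc <- p; next }
    near <- acc[which.min(abs(acc - p))]
    if (abs(near - p) < sep_pts) next
    valley <- min(v[seq(min(p, near), max(p, near))])
    if (valley <= valley_frac * min(v[p], v[near])) acc <- c(acc, p)
  }
  acc <- sort(acc)
  if (length(acc) == 1) return(list(list(peak = acc, lo = 1, hi = n)))
  ## boundaries at the valley minima between accepted peaks
  cuts <- vapply(seq_len(length(acc) - 1), function(i) {
    seg <- acc[i]:acc[i + 1]
    seg[which.min(v[seg])]
  }, 0L)
  lo <- c(1L, cuts + 1L)
  hi <- c(cuts, n)
  lapply(seq_along(acc), function(i)
    list(peak = acc[i], lo = lo[i], hi = hi[i]))
}

#' Detect boutons on an axon profile
#'
#' A candidate is a contiguous arc run whose width exceeds the local shaft
#' width by more than `width_excess_um` *and* whose intensity exceeds
#' `brightness_ratio` times the local backbone intensity. Runs closer than
#' `merge_radius_um` are merged so one varicosity is never double-called;
#' conversely a run containing several resolvable intensity peaks
#' (separated by more than the merge radius and a clear intensity valley)
#' is split, one call per peak. Calls are positioned at the intensity peak
#' and the diameter is the widest transverse FWHM within 0.5 um of it.
#'
#' @param profile an `axon_profile` from [extract_profile()]
#' @param config a [detect_config()]
#' @return bouton-call data frame: `arc_position_um`, `diameter_um`
#'   (transverse FWHM at the peak), `brightness_ratio`, `width_excess_um`,
#'   `class`, `excluded_isolated` (all FALSE; see
#'   [apply_isolation_filter()]); zero rows when nothing qualifies
#' @export
detect_boutons <- function(profile, config = detect_config()) {
  mask <- profile$width_um > profile$ref_width_um + config$width_excess_um &
    profile$intensity > config$brightness_ratio * profile$ref_intensity
  mask[is.na(mask)] <- FALSE
  empty <- data.frame(arc_position_um = numeric(), diameter_um = numeric(),
                      brightness_ratio = numeric(),
                      width_excess_um = numeric(), class = character(),
                      excluded_isolated = logical())
  if (!any(mask)) return(empty)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  ## merge runs separated by less than the merge radius
  step <- attr(profile, "step") %||% 0.1
  gap_pts <- config$merge_radius_um / step
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs$start[i] - merged$end[nrow(merged)] < gap_pts)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    idx <- merged$start[i]:merged$end[i]
    peaks <- split_run_peaks(profile$intensity[idx],
                             sep_pts = ceiling(gap_pts),
                             valley_frac = 0.75)
    do.call(rbind, lapply(peaks, function(sub) {
      pk <- idx[sub$peak]
      ## diameter at the widest sample within 0.5 um of the bouton centre
      near <- idx[sub$lo:sub$hi]
      near <- near[abs(profile$arc_um[near] - profile$arc_um[pk]) <= 0.5]
      wk <- near[which.max(profile$width_um[near])]
      data.frame(arc_position_um = profile$arc_um[pk],
                 diameter_um = profile$width_um[wk],
                 brightness_ratio = profile$intensity[pk] /
                   profile$ref_intensity[pk],
                 width_excess_um = profile$width_um[wk] -
                   profile$ref_width_um[wk])
    }))
  }))
  calls$class <- classify_bouton(calls$diameter_um,
                                 config$class_threshold_um)
  calls$excluded_isolated <- FALSE
  calls
}

#' Classify a bouton diameter as alpha or beta
#'
#' Alpha boutons are strictly larger than the threshold (default 2 um, the
#' trough of the bimodal diameter distribution); everything else, including
#' exactly 2 um, is beta.
#'
#' @param diameter diameter(s) in um, positive
#' @param threshold_um class boundary
#' @return character vector, `"alpha"` or `"beta"`
#' @examples
#' classify_bouton(c(1.2, 2.0, 2.5))  # beta, beta, alpha
#' @export
classify_bouton <- function(diameter, threshold_um = 2) {
  if (any(is.na(diameter)) || any(diameter <= 0))
    stop_named("bouton diameters must be positive")
  ifelse(diameter > threshold_um, "alpha", "beta")
}

#' Flag isolated boutons (> 50 um from their nearest neighbour)
#'
#' Boutons whose nearest neighbouring call is more than `max_gap_um` away --
#' or which have no neighbour at all -- are flagged `excluded_isolated`, so
#' that long bouton-free stretches do not bias density estimates. Flagged
#' calls are retained in the output but should be dropped from density and
#' turnover computations. The filter is order-independent and idempotent.
#'
#' @param calls bouton-call data frame
#' @param max_gap_um isolation distance (default 50 um)
#' @return `calls` with `excluded_isolated` set
#' @examples
#' apply_isolation_filter(data.frame(arc_position_um = c(10, 40, 100)))
#' @export
apply_isolation_filter <- function(calls, max_gap_um = 50) {
  n <- nrow(calls)
  if (n == 0) return(calls)
  if (n == 1) { calls$excluded_isolated <- TRUE; return(calls) }
  a <- calls$arc_position_um
  nn <- vapply(seq_len(n), function(i) min(abs(a[-i] - a[i])), 0)
  calls$excluded_isolated <- nn > max_gap_um
  calls
}

#' Measure a lateral FWHM by Gaussian fit
#'
#' Fits `b + a * exp(-(t - m)^2 / (2 s^2))` to the lateral intensity
#' profiles through the brightest voxel near `center_um` (both lateral axes,
#' averaged) on the maximum projection, and returns `2 sqrt(2 log 2) s`.
#' Used for bead-based resolution calibration.
#'
#' @param stack a `rendered_stack`
#' @param center_um optional c(x, y) in um; defaults to the stack's stored
#'   bead centre or the global maximum
#' @param window_um half-extent of the fitted profile, um
#' @return FWHM in um
#' @export
measure_fwhm <- function(stack, center_um = NULL, window_um = 1.5) {
  px <- stack$spec$pixel_size
  proj <- project_stack(stack, z_center = 0, dz_um = 2)
  if (is.null(center_um)) {
    if (!is.null(stack$center_um)) center_um <- stack$center_um[1:2]
    else {
      w <- which(proj == max(proj), arr.ind = TRUE)[1, ]
      center_um <- c(w[2] - 0.5, w[1] - 0.5) * px
    }
  }
  ## brightest voxel within 1 um of the requested centre
  ci <- round(center_um / px + 0.5)
  rpix <- ceiling(1 / px)
  rows <- max(1, ci[2] - rpix):min(nrow(proj), ci[2] + rpix)
  cols <- max(1, ci[1] - rpix):min(ncol(proj), ci[1] + rpix)
  sub <- proj[rows, cols, drop = FALSE]
  if (diff(range(proj)) < 1e-9 * max(abs(proj)) ||
      max(sub) <= stats::median(proj) + 1e-9 * max(abs(proj)))
    stop_named("no local maximum within 1 um of the requested centre")
  w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  pr <- rows[w[1]]; pc <- cols[w[2]]

  fit_axis <- function(v, t) {
    b0 <- min(v); a0 <- max(v) - b0
    m0 <- t[which.max(v)]
    fit <- try(suppressWarnings(
      stats::nls(v ~ b + a * exp(-(t - m)^2 / (2 * s^2)),
                 start = list(b = b0, a = a0, m = m0, s = 0.2),
                 control = stats::nls.control(warnOnly = TRUE))),
      silent = TRUE)
    if (inherits(fit, "try-error"))
      return(fwhm_crossings(t, v, which.max(v), b0))
    abs(stats::coef(fit)[["s"]]) / FWHM_TO_SIGMA
  }
  wpix <- ceiling(window_um / px)
  cr <- max(1, pc - wpix):min(ncol(proj), pc + wpix)
  rr <- max(1, pr - wpix):min(nrow(proj), pr + wpix)
  fx <- fit_axis(proj[pr, cr], (cr - 0.5) * px)
  fy <- fit_axis(proj[rr, pc], (rr - 0.5) * px)
  mean(c(fx, fy))
}

#' Full detection pass on one rendered stack
#'
#' [extract_profile()], [detect_boutons()], [apply_isolation_filter()] in
#' sequence.
#'
#' @param stack a `rendered_stack` (with trace)
#' @param config a [detect_config()]
#' @return bouton-call data frame with `segment_id` and `day` prepended
#' @export
detect_segment <- function(stack, config = detect_config()) {
  prof <- extract_profile(stack)
  calls <- detect_boutons(prof, config)
  calls <- apply_isolation_filter(calls)
  if (nrow(calls))
    cbind(data.frame(segment_id = stack$segment_id, day = stack$day),
          calls)
  else
    cbind(data.frame(segment_id = character(), day = integer()), calls)
}
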