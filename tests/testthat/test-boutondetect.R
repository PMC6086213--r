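## synthetic axon_profile with a single rectangular varicosity bump,
## for exercising the detection criteria in isolation
bump_profile <- function(width_excess = 0.5, brightness = 3,
                         shaft_w = 0.72, shaft_i = 100,
                         center = 25, halfspan = 0.6, n_um = 50) {
  arc <- seq(0, n_um, by = 0.1)
  w <- rep(shaft_w, length(arc))
  i <- rep(shaft_i, length(arc))
  in_bump <- abs(arc - center) <= halfspan
  w[in_bump] <- shaft_w + width_excess
  i[in_bump] <- shaft_i * brightness
  structure(data.frame(arc_um = arc, width_um = w, intensity = i,
                       ref_width_um = rep(shaft_w, length(arc)),
                       ref_intensity = rep(shaft_i, length(arc))),
            class = c("axon_profile", "data.frame"), step = 0.1)
}

test_that("detection requires both the width and the brightness criterion", {
  expect_identical(nrow(detect_boutons(bump_profile(0.5, 3))), 1L)
  expect_identical(nrow(detect_boutons(bump_profile(0.2, 3))), 0L)
  expect_identical(nrow(detect_boutons(bump_profile(0.5, 1.5))), 0L)
  ## exact threshold values do not qualify (strict inequalities)
  expect_identical(nrow(detect_boutons(bump_profile(0.3, 3))), 0L)
  expect_identical(nrow(detect_boutons(bump_profile(0.5, 2))), 0L)
})

test_that("size classification is a strict step function at 2 um", {
  expect_identical(classify_bouton(1.2), "beta")
  expect_identical(classify_bouton(2.5), "alpha")
  expect_identical(classify_bouton(2.0), "beta")
  expect_identical(classify_bouton(c(1.99, 2.01)), c("beta", "alpha"))
  expect_error(classify_bouton(0), "positive")
  expect_error(classify_bouton(-1), "positive")
})

test_that("isolation filter flags boutons > 50 um from any neighbour", {
  calls <- data.frame(arc_position_um = c(10, 40, 100))
  out <- apply_isolation_filter(calls)
  expect_identical(out$excluded_isolated, c(FALSE, FALSE, TRUE))
  ## single call has no neighbour
  one <- apply_isolation_filter(data.frame(arc_position_um = 30))
  expect_true(one$excluded_isolated)
  ## exactly 49/50 um gaps are kept (exclusion is strictly > 50)
  edge <- apply_isolation_filter(data.frame(arc_position_um = c(10, 59,
                                                                108)))
  expect_false(any(edge$excluded_isolated))
  at50 <- apply_isolation_filter(data.frame(arc_position_um = c(0, 50)))
  expect_false(any(at50$excluded_isolated))
})

test_that("isolation filter is order-independent and idempotent", {
  set.seed(8)
  calls <- data.frame(arc_position_um = sort(runif(12, 0, 300)))
  out <- apply_isolation_filter(calls)
  perm <- sample(nrow(calls))
  out_perm <- apply_isolation_filter(calls[perm, , drop = FALSE])
  expect_identical(out$excluded_isolated[perm], out_perm$excluded_isolated)
  expect_identical(apply_isolation_filter(out)$excluded_isolated,
                   out$excluded_isolated)
})

test_that("a plain shaft yields a flat width profile at the quadrature width", {
  tr <- make_truth(50, numeric(), numeric())
  st <- render_segment(tr, 0, quiet_spec(), seed = 2)
  prof <- extract_profile(st)
  core <- prof[prof$arc_um > 3 & prof$arc_um < 47, ]
  expect_lt(stats::sd(core$width_um) / mean(core$width_um), 0.01)
  expect_lt(abs(mean(core$width_um) - sqrt(0.6^2 + 0.4^2)), 0.05)
  expect_identical(nrow(detect_boutons(prof)), 0L)
})

test_that("a single varicosity produces one width peak at its arc position", {
  tr <- make_truth(60, 30, 2.5)
  st <- render_segment(tr, 0, quiet_spec(), seed = 2)
  prof <- extract_profile(st)
  calls <- detect_boutons(prof)
  expect_identical(nrow(calls), 1L)
  expect_lt(abs(calls$arc_position_um - 30), 0.5)
  expect_gt(calls$brightness_ratio, 2)
  expect_identical(calls$class, "alpha")
})

test_that("measure_fwhm recovers an analytic Gaussian and rejects flat input", {
  px <- 0.1
  cc <- (seq_len(80) - 0.5) * px
  g <- outer(exp(-(cc - 4)^2 / (2 * 0.17^2)),
             exp(-(cc - 4)^2 / (2 * 0.17^2)))
  stack <- structure(list(vox = array(g, c(80, 80, 1)),
                          spec = imaging_spec(), z_values_um = 0,
                          center_um = c(4, 4, 0)),
                     class = "rendered_stack")
  expect_lt(abs(measure_fwhm(stack) - 2 * sqrt(2 * log(2)) * 0.17), 0.01)
  flat <- structure(list(vox = array(1, c(80, 80, 1)),
                         spec = imaging_spec(), z_values_um = 0,
                         center_um = c(4, 4, 0)),
                    class = "rendered_stack")
  expect_error(measure_fwhm(flat), "local maximum")
})

test_that("noise-free detection has perfect precision, recall and classes at >= 5 um spacing", {
  spec <- quiet_spec()
  total_truth <- 0; total_calls <- 0; total_matched <- 0
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:9, 1)
    pos <- 5 + cumsum(runif(n, 5, 12))
    L <- max(pos) + 5
    diam <- sample(c(1.0, 1.2, 1.5, 1.8, 2.3, 2.8), n, replace = TRUE)
    tr <- make_truth(max(L, 31), pos, diam)
    st <- render_segment(tr, 0, spec, seed = seed)
    calls <- detect_segment(st)
    truth <- truth_calls(tr, 0)
    lk <- match_days(calls, truth, tolerance = 1)
    expect_identical(nrow(calls), nrow(truth))
    expect_identical(nrow(lk), nrow(truth))
    expect_false(any(lk$class_change))
    total_truth <- total_truth + nrow(truth)
    total_calls <- total_calls + nrow(calls)
    total_matched <- total_matched + nrow(lk)
  }
  expect_identical(total_matched, total_truth)  # recall 1
  expect_identical(total_matched, total_calls)  # precision 1
})

test_that("motion within the quality gates degrades matched positions by < 0.5 um RMS", {
  rms <- function(jitter) {
    spec <- if (jitter) imaging_spec(noise_model = "none") else quiet_spec()
    errs <- c()
    for (seed in 1:4) {
      set.seed(100 + seed)
      pos <- 5 + cumsum(runif(5, 6, 12))
      tr <- make_truth(max(pos) + 5, pos, runif(5, 1.1, 1.8))
      st <- render_segment(tr, 0, spec, seed = seed)
      lk <- match_days(detect_segment(st), truth_calls(tr, 0),
                       tolerance = 1.5)
      errs <- c(errs, lk$displacement_um)
    }
    sqrt(mean(errs^2))
  }
  expect_lt(rms(TRUE) - rms(FALSE), 0.5)
})

test_that("close alpha pairs are split into separate calls by the intensity valley", {
  tr <- make_truth(60, c(25, 28), c(2.5, 2.6))
  st <- render_segment(tr, 0, quiet_spec(), seed = 9)
  calls <- detect_segment(st)
  expect_identical(nrow(calls), 2L)
  expect_identical(calls$class, c("alpha", "alpha"))
})
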