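test_that("cohort sampling is deterministic and partitions mice evenly", {
  c1 <- sample_cohort(preset_wt(), seed = 42)
  c2 <- sample_cohort(preset_wt(), seed = 42)
  expect_identical(lapply(c1$segments, `[[`, "boutons"),
                   lapply(c2$segments, `[[`, "boutons"))
  expect_length(c1$segments, 58)
  mice <- table(vapply(c1$segments, `[[`, "", "mouse_id"))
  expect_length(mice, 6)
  expect_setequal(as.integer(mice), c(10, 10, 10, 10, 9, 9))
  c3 <- sample_cohort(preset_wt(), seed = 43)
  expect_false(identical(c1$segments[[1]]$boutons,
                         c3$segments[[1]]$boutons))
})

test_that("identity dynamics: full survival and zero formation freeze the segment", {
  p <- cohort_preset(p_survive_training = 1, p_survive_rest_pre = 1,
                     p_stabilize_new = 1, formation_intensity_training = 0,
                     formation_intensity_rest = 0, alpha_p_survive_4d = 1)
  for (seed in 1:5) {
    seg <- sample_segment(p, seed = seed)
    b <- seg$boutons
    expect_true(all(b$birth_day == -1))
    expect_true(all(is.na(b$death_day)))
    for (d in c(0, 4, 8)) expect_true(all(bouton_present(b, d)))
  }
})

test_that("annihilation: zero training survival removes every baseline beta by day 4", {
  p <- cohort_preset(p_survive_training = 0)
  seg <- sample_segment(p, seed = 3)
  beta0 <- seg$boutons$class == "beta" & seg$boutons$birth_day == -1
  expect_gt(sum(beta0), 0)
  expect_false(any(bouton_present(seg$boutons, 4)[beta0]))
  expect_true(all(seg$boutons$death_day[beta0] == 4))
})

test_that("ground-truth invariants: positions, spacing, class-diameter consistency, death after birth", {
  coh <- sample_cohort(preset_mecp2dup(), seed = 9)
  for (seg in coh$segments) {
    b <- seg$boutons
    if (!nrow(b)) next
    expect_true(all(b$arc_position_um >= 0 &
                      b$arc_position_um <= seg$length_um))
    if (nrow(b) > 1)
      expect_gte(min(diff(sort(b$arc_position_um))), 0.5)
    expect_identical(b$class, ifelse(b$diameter_um > 2, "alpha", "beta"))
    has_death <- !is.na(b$death_day)
    expect_true(all(b$death_day[has_death] > b$birth_day[has_death]))
    expect_true(all(seg$length_um >= 30 & seg$length_um <= 360))
  }
})

test_that("baseline survival matches the latent probabilities in expectation", {
  p <- cohort_preset(n_segments = 1200L, n_mice = 6L)
  coh <- sample_cohort(p, seed = 101)
  b <- do.call(rbind, lapply(coh$segments, `[[`, "boutons"))
  base <- b[b$class == "beta" & b$birth_day == -1, ]
  n <- nrow(base)
  expect_gt(n, 5000)
  s4 <- mean(bouton_present(base, 4))
  s8 <- mean(bouton_present(base, 8))
  tol4 <- 3 * sqrt(p$p_survive_training * (1 - p$p_survive_training) / n)
  expect_lt(abs(s4 - p$p_survive_training), tol4)
  exp8 <- p$p_survive_training * p$p_survive_rest_pre
  expect_lt(abs(s8 - exp8), 3 * sqrt(exp8 * (1 - exp8) / n))
})

test_that("per-segment bookkeeping: baseline = eliminated-in-training + present-at-day-4, exactly", {
  coh <- sample_cohort(preset_wt(), seed = 77)
  for (seg in coh$segments) {
    b <- seg$boutons[seg$boutons$class == "beta" &
                       seg$boutons$birth_day == -1, ]
    expect_identical(nrow(b),
                     sum(!is.na(b$death_day) & b$death_day == 4) +
                       sum(bouton_present(b, 4)))
  }
})

test_that("with no mouse effect, per-mouse survival differs only by binomial noise", {
  p <- cohort_preset(n_segments = 240L, n_mice = 6L, mouse_effect_sd = 0)
  coh <- sample_cohort(p, seed = 55)
  b <- do.call(rbind, lapply(coh$segments, function(s)
    cbind(s$boutons, mouse = s$mouse_id)))
  base <- b[b$class == "beta" & b$birth_day == -1, ]
  for (m in unique(base$mouse)) {
    sub <- base[base$mouse == m, ]
    k <- sum(bouton_present(sub, 4)); n <- nrow(sub)
    ci <- stats::binom.test(k, n, p$p_survive_training)$conf.int
    ## exact 95% CI for the mouse's survival must cover the latent p
    expect_true(ci[1] <= p$p_survive_training &&
                  p$p_survive_training <= ci[2])
  }
})

test_that("presence table and ground-truth CSVs round-trip", {
  p <- cohort_preset(n_segments = 6L, n_mice = 2L)
  coh <- sample_cohort(p, seed = 2)
  pt <- presence_table(coh)
  expect_setequal(unique(pt$day), c(0, 4, 8))
  n_boutons <- sum(vapply(coh$segments, function(s) nrow(s$boutons), 0L))
  expect_identical(nrow(pt), n_boutons * 3L)
  dir <- withr::local_tempdir()
  paths <- write_ground_truth(coh, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["boutons"]])
  expect_equal(nrow(back), nrow(pt))
  p2 <- read_preset_yaml(paths[["preset"]])
  expect_equal(unclass(p2), unclass(coh$preset), tolerance = 1e-12)
})

test_that("calibration fixed point: zero-change targets return frozen dynamics", {
  tg <- list(elimination_training = 0, elimination_rest = 0,
             formation_training = 0, formation_rest = 0,
             survival_d4 = 1, survival_d8 = 1, stabilization = 0)
  p <- calibrate_preset(tg, preset_wt(), seed = 1, n_segments = 500)
  expect_equal(p$p_survive_training, 1)
  expect_equal(p$p_survive_rest_pre, 1)
  expect_equal(p$formation_intensity_training, 0)
  expect_equal(p$formation_intensity_rest, 0)
})

test_that("calibration round-trip: simulated cohort means hit the fitted targets within 0.01", {
  tg <- cohort_targets("WT")
  p <- calibrate_preset(tg, preset_wt(), seed = 19, n_segments = 1500)
  ach <- attr(p, "calibration")$achieved
  for (nm in c("formation_training", "formation_rest", "survival_d4",
               "survival_d8", "stabilization"))
    expect_lt(abs(ach[[nm]] - tg[[nm]]), 0.01)
  ## implied eliminations stay inside the published +/- 2 SEM bands
  expect_lt(abs(ach[["elimination_training"]] - 0.17), 0.06)
  expect_lt(abs(ach[["elimination_rest"]] - 0.06), 0.04)
})

test_that("infeasible calibration targets are rejected with the binding constraint", {
  tg <- cohort_targets("WT")
  tg$survival_d8 <- 0.9  # above survival_d4
  expect_error(calibrate_preset(tg, preset_wt(), seed = 1,
                                n_segments = 500), "survival_d8")
  tg <- cohort_targets("WT")
  tg$elimination_training <- 0.5  # exceeds 1 - survival_d4
  expect_error(calibrate_preset(tg, preset_wt(), seed = 1,
                                n_segments = 500), "elimination_training")
})
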