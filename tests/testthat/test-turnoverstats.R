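## small synthetic events table for arithmetic checks
events_fixture <- function() {
  ## 10 beta lineages: 8 baseline (2 die in training, 1 of the survivors
  ## dies in rest), 1 training-formed (stabilized), 1 rest-formed
  data.frame(
    lineage_id = sprintf("L%02d", 1:10),
    class = "beta",
    arc_position_um = seq(5, 95, by = 10),
    present_0 = c(rep(TRUE, 8), FALSE, FALSE),
    present_4 = c(rep(TRUE, 5), TRUE, FALSE, FALSE, TRUE, FALSE),
    present_8 = c(rep(TRUE, 5), FALSE, FALSE, FALSE, TRUE, TRUE),
    origin = c(rep("baseline", 8), "formed_training", "formed_rest"),
    eliminated_phase = c(rep(NA, 5), "rest", "training", "training",
                         NA, NA),
    stabilized = c(rep(NA, 8), TRUE, NA),
    reappeared = FALSE, class_change = FALSE)
}

test_that("densities are boutons per 100 um", {
  expect_equal(segment_density(data.frame(class = rep("beta", 8)), 200),
               4.0)
  expect_equal(segment_density(data.frame(class = character()), 150), 0)
  expect_error(segment_density(data.frame(class = "beta"), 0), "positive")
})

test_that("phase fractions use the total-observed denominator", {
  f <- phase_fractions(events_fixture())
  expect_identical(f$n_observed, 10L)
  expect_equal(f$formation_training, 0.1)
  expect_equal(f$elimination_training, 0.2)
  expect_equal(f$formation_rest, 0.1)
  expect_equal(f$elimination_rest, 0.1)      # pre-existing accounting
  expect_equal(f$elimination_rest_all, 0.1)  # the formed one stabilized
})

test_that("pooled published counts give the textbook fractions", {
  ## 314 baseline + 40 training-formed + 42 rest-formed observed lineages;
  ## 40/396 formed and 64/396 eliminated during training
  expect_equal(round(40 / 396, 3), 0.101)
  expect_equal(round(64 / 396, 3), 0.162)
  ## construct an events table with exactly those pooled counts and check
  ## phase_fractions returns the same ratios
  n <- 396
  origin <- c(rep("baseline", 314), rep("formed_training", 40),
              rep("formed_rest", 42))
  elim <- rep(NA_character_, n)
  elim[1:64] <- "training"            # 64 baseline lost in training
  elim[65:87] <- "rest"               # 23 more baseline lost in rest
  ev <- data.frame(
    lineage_id = sprintf("L%03d", 1:n), class = "beta",
    arc_position_um = seq_len(n),
    present_0 = origin == "baseline",
    present_4 = (origin == "baseline" & !(seq_len(n) <= 64)) |
      origin == "formed_training",
    present_8 = (origin == "baseline" & !(seq_len(n) <= 87)) |
      origin == "formed_rest",
    origin = origin, eliminated_phase = elim,
    stabilized = NA, reappeared = FALSE, class_change = FALSE)
  f <- phase_fractions(ev)
  expect_equal(f$formation_training, 40 / 396)
  expect_equal(f$elimination_training, 64 / 396)
  expect_equal(f$elimination_rest, 23 / 396)
})

test_that("turnover rate combines gain and loss against the interval-start pool", {
  ev <- events_fixture()
  tr <- turnover_rate(ev, length_um = 150, phase = "rest")
  ## present at day 4: 7 (6 baseline + 1 formed); lost in rest: 1; formed: 1
  expect_identical(tr$n_start, 7L)
  expect_identical(tr$n_formed, 1L)
  expect_identical(tr$n_lost, 1L)
  expect_equal(tr$tor_fraction, (1 / 7 + 1 / 7) / 2)
  expect_equal(tr$tor_per_100um, 100 * 2 / (2 * 150))
  ## formed 2, eliminated 1, length 150 -> 1 per 100 um
  expect_equal(100 * (2 + 1) / (2 * 150), 1.0)
})

test_that("survival and stabilization follow their founding populations", {
  sc <- survival_curve(events_fixture())
  expect_identical(sc$n_baseline, 8L)
  expect_equal(sc$survival_d4, 6 / 8)
  expect_equal(sc$survival_d8, 5 / 8)
  expect_equal(sc$maintenance_rest_preexisting, 5 / 6)
  st <- stabilization_rate(events_fixture())
  expect_equal(st$stabilization, 1)
  ## worked numbers: 10 baseline, 8 at day 4, 7 at day 8
  ev <- events_fixture()[1:8, ]
  expect_equal(survival_curve(ev)$survival_d4, 0.75)
  ## zero-change segment
  ev2 <- events_fixture()[1:5, ]
  expect_equal(survival_curve(ev2)$survival_d4, 1)
  expect_equal(phase_fractions(ev2)$elimination_training, 0)
})

test_that("cohort aggregation is the unweighted mean +/- SEM across segments", {
  x <- data.frame(genotype = "WT", f = c(0.1, 0.2, 0.3))
  agg <- aggregate_cohort(x, "f")
  expect_equal(agg$mean, 0.2)
  expect_equal(agg$sem, 0.0577, tolerance = 1e-3)
  expect_identical(agg$n, 3L)
  one <- aggregate_cohort(data.frame(genotype = "WT", f = 0.4), "f")
  expect_true(is.na(one$sem))
  expect_equal(one$mean, 0.4)
})

test_that("per-segment statistics equal an independent brute-force recount", {
  coh <- sample_cohort(cohort_preset(n_segments = 40L, n_mice = 4L),
                       seed = 13)
  ev <- track_cohort(coh)
  ps <- segment_statistics(ev, segment_table(coh))
  for (i in seq_along(coh$segments)) {
    seg <- coh$segments[[i]]
    rc <- recount_segment(seg)
    row <- ps[ps$segment_id == seg$segment_id, ]
    if (rc$n_observed == 0) next
    expect_equal(row$formation_training, rc$formation_training)
    expect_equal(row$formation_rest, rc$formation_rest)
    expect_equal(row$elimination_training, rc$elimination_training)
    expect_equal(row$elimination_rest, rc$elimination_rest)
    expect_equal(row$elimination_rest_all, rc$elimination_rest_all)
    if (is.finite(rc$survival_d4)) {
      expect_equal(row$survival_d4, rc$survival_d4)
      expect_equal(row$survival_d8, rc$survival_d8)
    }
    if (is.finite(rc$stabilization))
      expect_equal(row$stabilization, rc$stabilization)
    if (is.finite(rc$tor_beta_rest))
      expect_equal(row$tor_fraction_beta_rest, rc$tor_beta_rest)
    if (is.finite(rc$tor_alpha_rest))
      expect_equal(row$tor_fraction_alpha_rest, rc$tor_alpha_rest)
  }
})

test_that("per-segment bookkeeping: baseline survival + baseline-denominator elimination = 1", {
  coh <- sample_cohort(preset_wt(), seed = 21)
  ev <- track_cohort(coh)
  ps <- segment_statistics(ev, segment_table(coh))
  for (i in seq_len(nrow(ps))) {
    if (is.na(ps$survival_d4[i])) next
    elim_over_baseline <- ps$elimination_training[i] * ps$n_observed[i] /
      ps$n_baseline[i]
    expect_equal(ps$survival_d4[i] + elim_over_baseline, 1)
  }
})

test_that("the inclusive rest-elimination accounting is never below pre-existing-only", {
  coh <- sample_cohort(preset_wt(), seed = 29)
  ps <- segment_statistics(track_cohort(coh), segment_table(coh))
  ok <- !is.na(ps$elimination_rest)
  expect_true(all(ps$elimination_rest_all[ok] >= ps$elimination_rest[ok]))
})

test_that("statistics are invariant under segment relabelling and row order", {
  coh <- sample_cohort(cohort_preset(n_segments = 12L, n_mice = 3L),
                       seed = 3)
  ev <- track_cohort(coh)
  segs <- segment_table(coh)
  a <- aggregate_cohort(segment_statistics(ev, segs))
  perm_ev <- ev[sample(nrow(ev)), ]
  perm_segs <- segs[sample(nrow(segs)), ]
  b <- aggregate_cohort(segment_statistics(perm_ev, perm_segs))
  expect_equal(a[order(a$statistic), c("mean", "sem", "n")],
               b[order(b$statistic), c("mean", "sem", "n")],
               ignore_attr = TRUE)
})
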