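calls_at <- function(pos, class = NULL) {
  d <- data.frame(arc_position_um = pos)
  if (!is.null(class)) d$class <- class
  d
}

test_that("matching links nearest neighbours within tolerance", {
  lk <- match_days(calls_at(c(10.0, 50.0)), calls_at(c(10.4, 80.0)),
                   tolerance = 2)
  expect_identical(nrow(lk), 1L)
  expect_equal(lk$arc_i, 10.0)
  expect_equal(lk$arc_j, 10.4)
  ## 50.0 unlinked (eliminated side), 80.0 unlinked (formed side)
})

test_that("distance ties break toward the smaller arc position", {
  lk <- match_days(calls_at(10.0), calls_at(c(9.5, 10.5)))
  expect_identical(nrow(lk), 1L)
  expect_equal(lk$arc_j, 9.5)
})

test_that("identical call lists link completely with zero displacement", {
  x <- calls_at(c(5, 17, 33, 80))
  lk <- match_days(x, x)
  expect_identical(nrow(lk), 4L)
  expect_true(all(lk$displacement_um == 0))
})

test_that("duplicate arc positions within 0.01 um are rejected", {
  expect_error(match_days(calls_at(c(10, 10.005)), calls_at(20)),
               "duplicate")
})

test_that("matching is symmetric", {
  set.seed(5)
  for (rep in 1:20) {
    a <- sort(runif(sample(0:6, 1), 0, 60))
    b <- sort(runif(sample(0:6, 1), 0, 60))
    if (length(a) > 1 && any(diff(a) < 0.01)) next
    if (length(b) > 1 && any(diff(b) < 0.01)) next
    ab <- match_days(calls_at(a), calls_at(b))
    ba <- match_days(calls_at(b), calls_at(a))
    expect_identical(ab[order(ab$i), c("arc_i", "arc_j")],
                     setNames(ba[order(ba$j), c("arc_j", "arc_i")],
                              c("arc_i", "arc_j")),
                     ignore_attr = TRUE)
  }
})

test_that("greedy matching equals the optimal assignment on realistic small windows", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(1:6, 1)
    a <- 3 + cumsum(runif(n, 3, 10))      # >= 3 um spacing
    keep <- runif(n) > 0.2
    b <- (a + rnorm(n, 0, 0.3))[keep]     # realistic re-imaging scatter
    if (runif(1) > 0.5) b <- sort(c(b, runif(1, 0, max(a) + 5)))
    b <- sort(b)
    if (length(b) > 1 && any(diff(b) < 0.01)) next
    greedy <- match_days(calls_at(a), calls_at(b))
    opt <- match_optimal(a, b)
    n_opt <- if (is.null(opt)) 0L else nrow(opt)
    expect_identical(nrow(greedy), n_opt)
    if (n_opt) {
      gm <- as.matrix(greedy[order(greedy$i), c("i", "j")])
      om <- as.matrix(opt)
      storage.mode(gm) <- "double"; storage.mode(om) <- "double"
      expect_equal(unname(gm), unname(om))
    }
  }
})

test_that("event labelling covers the lineage taxonomy", {
  sched <- study_schedule()
  d0 <- calls_at(c(10, 20), class = c("beta", "beta"))
  d4 <- calls_at(c(10.1, 30), class = c("beta", "beta"))
  d8 <- calls_at(c(10.2, 30.1, 45), class = c("beta", "beta", "beta"))
  ev <- label_events(list(d0, d4, d8), sched)
  expect_identical(nrow(ev), 4L)
  b10 <- ev[abs(ev$arc_position_um - 10) < 1, ]
  expect_identical(b10$origin, "baseline")
  expect_true(is.na(b10$eliminated_phase))
  b20 <- ev[abs(ev$arc_position_um - 20) < 1, ]
  expect_identical(b20$origin, "baseline")
  expect_identical(b20$eliminated_phase, "training")
  b30 <- ev[abs(ev$arc_position_um - 30) < 1, ]
  expect_identical(b30$origin, "formed_training")
  expect_true(b30$stabilized)
  b45 <- ev[abs(ev$arc_position_um - 45) < 1, ]
  expect_identical(b45$origin, "formed_rest")
})

test_that("a reappearance is two flagged lineages, not one persistent bouton", {
  sched <- study_schedule()
  ev <- label_events(list(calls_at(15), calls_at(numeric()), calls_at(15.2)),
                     sched)
  expect_identical(nrow(ev), 2L)
  expect_true(all(ev$reappeared))
  expect_identical(sort(ev$origin), c("baseline", "formed_rest"))
  expect_identical(ev$eliminated_phase[ev$origin == "baseline"], "training")
})

test_that("unstabilized training-formed boutons are eliminated in rest", {
  ev <- label_events(list(calls_at(numeric()), calls_at(25),
                          calls_at(numeric())), study_schedule())
  expect_identical(ev$origin, "formed_training")
  expect_identical(ev$eliminated_phase, "rest")
  expect_false(ev$stabilized)
})

test_that("tracked ground-truth events reproduce the generator's birth/death records", {
  p <- cohort_preset(n_segments = 400L, n_mice = 8L)
  coh <- sample_cohort(p, seed = 33)
  ev <- track_cohort(coh)
  n_boutons <- sum(vapply(coh$segments, function(s) nrow(s$boutons), 0L))
  expect_gt(n_boutons, 3000)
  expect_identical(nrow(ev), n_boutons)
  for (seg in coh$segments[seq(1, 400, by = 7)]) {
    sub <- ev[ev$segment_id == seg$segment_id, ]
    b <- seg$boutons
    expect_identical(nrow(sub), nrow(b))
    for (d in coh$schedule$imaging_days) {
      truth_present <- sort(b$arc_position_um[bouton_present(b, d)])
      ev_present <- sort(sub$arc_position_um[sub[[paste0("present_", d)]]])
      expect_equal(ev_present, truth_present)
    }
    ## origins agree with birth days
    expect_identical(sum(sub$origin == "baseline"), sum(b$birth_day == -1))
    expect_identical(sum(sub$origin == "formed_training"),
                     sum(b$birth_day == 4))
    expect_identical(sum(sub$origin == "formed_rest"),
                     sum(b$birth_day == 8))
    ## eliminations agree with death days
    expect_identical(sum(!is.na(sub$eliminated_phase) &
                           sub$eliminated_phase == "training"),
                     sum(!is.na(b$death_day) & b$death_day == 4))
  }
})
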