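## per-segment turnover statistics and cohort aggregation
##
## Denominator conventions (documented in the methods vignette):
##  * formation/elimination *fractions*: distinct bouton lineages observed at
##    any imaging session of the schedule ("total observed" denominator);
##  * turnover *rates* (TOR): gain and loss counts relative to the boutons
##    present at the start of the interval, the convention of the chronic
##    bouton-imaging literature;
##  * survival/stabilization: fractions of the relevant founding population.

events_of_class <- function(events, class) {
  if (is.null(class)) events else events[events$class %in% class, ,
                                         drop = FALSE]
}

present_col <- function(events, day) events[[paste0("present_", day)]]

#' Bouton density of a segment
#'
#' @param calls bouton-call (or lineage) data frame with a `class` column;
#'   isolation-excluded calls should be removed beforehand
#' @param length_um segment length in micrometres (>= 0)
#' @param class size class to count (`"beta"`, `"alpha"`, or `NULL` for all)
#' @return boutons per 100 um
#' @examples
#' segment_density(data.frame(class = rep("beta", 8)), 200)  # 4 per 100 um
#' @export
segment_density <- function(calls, length_um, class = "beta") {
  if (length_um <= 0) stop_named("segment length must be positive")
  100 * nrow(events_of_class(calls, class)) / length_um
}

#' Formation and elimination fractions per phase
#'
#' Fractions of the total number of distinct bouton lineages observed across
#' all imaging sessions. Elimination is counted for baseline (pre-existing)
#' lineages by default; `elimination_<phase>_all` additionally counts losses
#' of lineages formed in earlier phases (always >= the pre-existing-only
#' figure).
#'
#' @param events lineage table from [label_events()] (one segment)
#' @param schedule the [study_schedule()] used for labelling
#' @param class size class analysed (default `"beta"`)
#' @return one-row data frame: `n_observed`, then `formation_<phase>`,
#'   `elimination_<phase>`, `elimination_<phase>_all` for each phase; all
#'   NA when no lineage of the class was observed
#' @export
phase_fractions <- function(events, schedule = study_schedule(),
                            class = "beta") {
  ev <- events_of_class(events, class)
  n <- nrow(ev)
  out <- data.frame(n_observed = n)
  for (ph in schedule$phase_labels) {
    f <- sum(ev$origin == paste0("formed_", ph))
    e_pre <- sum(ev$origin == "baseline" &
                   !is.na(ev$eliminated_phase) & ev$eliminated_phase == ph)
    e_all <- sum(!is.na(ev$eliminated_phase) & ev$eliminated_phase == ph)
    out[[paste0("formation_", ph)]] <- if (n) f / n else NA_real_
    out[[paste0("elimination_", ph)]] <- if (n) e_pre / n else NA_real_
    out[[paste0("elimination_", ph, "_all")]] <- if (n) e_all / n else
      NA_real_
  }
  out
}

#' Turnover rate over one schedule interval
#'
#' TOR = (gain rate + loss rate) / 2, with gain and loss counted against the
#' boutons present at the start of the interval; also returned per axon
#' length, (formed + eliminated) / (2 x length) x 100.
#'
#' @inheritParams phase_fractions
#' @param length_um segment length in micrometres
#' @param phase phase name of the interval (must be in the schedule)
#' @param class size class (`"beta"` or `"alpha"`)
#' @return one-row data frame: `n_start`, `n_formed`, `n_lost`,
#'   `tor_fraction`, `tor_per_100um`
#' @export
turnover_rate <- function(events, length_um, schedule = study_schedule(),
                          phase = "rest", class = "beta") {
  k <- phase_index(schedule, phase)
  d_start <- schedule$imaging_days[k]
  d_end <- schedule$imaging_days[k + 1]
  ev <- events_of_class(events, class)
  at_start <- present_col(ev, d_start)
  at_end <- present_col(ev, d_end)
  n_start <- sum(at_start)
  n_formed <- sum(!at_start & at_end & ev$origin == paste0("formed_", phase))
  n_lost <- sum(at_start & !at_end)
  data.frame(
    n_start = n_start, n_formed = n_formed, n_lost = n_lost,
    tor_fraction = if (n_start > 0)
      (n_formed / n_start + n_lost / n_start) / 2 else NA_real_,
    tor_per_100um = 100 * (n_formed + n_lost) / (2 * length_um))
}

#' Baseline-bouton survival fractions
#'
#' Fraction of the boutons present at the first imaging session that persist
#' at each later session, plus the rest-phase maintenance of pre-existing
#' boutons (present at the final session among those that had survived to the
#' middle session).
#'
#' @inheritParams phase_fractions
#' @return one-row data frame: `n_baseline`, `survival_d<day>` for each
#'   later imaging day, and (for three-session schedules)
#'   `maintenance_rest_preexisting`; NA when the segment has no baseline
#'   bouton of the class
#' @export
survival_curve <- function(events, schedule = study_schedule(),
                           class = "beta") {
  days <- schedule$imaging_days
  ev <- events_of_class(events, class)
  base <- ev[ev$origin == "baseline", , drop = FALSE]
  nb <- nrow(base)
  out <- data.frame(n_baseline = nb)
  for (d in days[-1])
    out[[paste0("survival_d", d)]] <- if (nb) sum(present_col(base, d)) / nb
      else NA_real_
  if (length(days) >= 3) {
    mid <- present_col(base, days[2])
    fin <- present_col(base, days[length(days)])
    out$maintenance_rest_preexisting <- if (nb && sum(mid) > 0)
      sum(mid & fin) / sum(mid) else NA_real_
  }
  out
}

#' Stabilization rate of training-formed boutons
#'
#' Fraction of boutons first seen at the second imaging session that are
#' still present at the third.
#'
#' @inheritParams phase_fractions
#' @return one-row data frame `n_formed_training`, `stabilization`
#'   (NA when no bouton formed during training)
#' @export
stabilization_rate <- function(events, schedule = study_schedule(),
                               class = "beta") {
  ev <- events_of_class(events, class)
  tf <- ev[ev$origin == paste0("formed_", schedule$phase_labels[1]), ,
           drop = FALSE]
  n <- nrow(tf)
  last_day <- schedule$imaging_days[length(schedule$imaging_days)]
  data.frame(n_formed_training = n,
             stabilization = if (n) sum(present_col(tf, last_day)) / n
               else NA_real_)
}

#' All per-segment turnover statistics for a cohort
#'
#' Computes, for every segment in a labelled-events table: alpha and beta
#' densities at baseline, formation/elimination fractions per phase (beta),
#' TOR per class over each interval, the survival curve, rest-phase
#' maintenance and stabilization (beta).
#'
#' @param events cohort events table ([track_cohort()] output, or anything
#'   with `segment_id` plus [label_events()] columns)
#' @param segments segment metadata table ([segment_table()])
#' @param schedule the [study_schedule()]
#' @return data frame, one row per segment (segments without any observed
#'   bouton yield NA statistics but keep their densities)
#' @export
segment_statistics <- function(events, segments,
                               schedule = study_schedule()) {
  d0 <- schedule$imaging_days[1]
  out <- lapply(seq_len(nrow(segments)), function(i) {
    sid <- segments$segment_id[i]
    L <- segments$length_um[i]
    ev <- events[events$segment_id == sid, , drop = FALSE]
    ev0 <- ev[present_col(ev, d0), , drop = FALSE]
    row <- data.frame(segment_id = sid, mouse_id = segments$mouse_id[i],
                      genotype = segments$genotype[i], length_um = L,
                      density_alpha = segment_density(ev0, L, "alpha"),
                      density_beta = segment_density(ev0, L, "beta"))
    row <- cbind(row, phase_fractions(ev, schedule, "beta"))
    for (cl in c("beta", "alpha")) for (ph in schedule$phase_labels) {
      tr <- turnover_rate(ev, L, schedule, ph, cl)
      row[[paste0("tor_fraction_", cl, "_", ph)]] <- tr$tor_fraction
      row[[paste0("tor_per_100um_", cl, "_", ph)]] <- tr$tor_per_100um
    }
    row <- cbind(row, survival_curve(ev, schedule, "beta"))
    row <- cbind(row, stabilization_rate(ev, schedule, "beta"))
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate per-segment statistics to cohort mean +/- SEM
#'
#' Unweighted mean and standard error across segments (segments are the
#' statistical unit; NA segment values, e.g. survival on segments without
#' baseline boutons, are excluded statistic-wise and the effective n
#' reported).
#'
#' @param per_segment output of [segment_statistics()]
#' @param stats character vector of statistic columns (default: every
#'   numeric column except lengths and counts)
#' @return data frame `genotype`, `statistic`, `mean`, `sem` (NA when a
#'   genotype contributes fewer than two segments), `n`
#' @examples
#' x <- data.frame(genotype = "WT", f = c(0.1, 0.2, 0.3))
#' aggregate_cohort(x, "f")  # mean 0.2, sem 0.0577
#' @export
aggregate_cohort <- function(per_segment, stats = NULL) {
  if (is.null(stats)) {
    num <- vapply(per_segment, is.numeric, TRUE)
    stats <- setdiff(names(per_segment)[num],
                     c("length_um", "n_observed", "n_baseline",
                       "n_formed_training"))
  }
  out <- list()
  for (g in unique(per_segment$genotype)) {
    sub <- per_segment[per_segment$genotype == g, , drop = FALSE]
    for (s in stats) {
      x <- sub[[s]]
      x <- x[!is.na(x)]
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, statistic = s,
        mean = if (length(x)) mean(x) else NA_real_,
        sem = sem(x), n = length(x))
    }
  }
  do.call(rbind, out)
}
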