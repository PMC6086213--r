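## synthetic cohorts of ground-truth bouton dynamics (tabular, no images)

#' Simulate ground-truth bouton dynamics for one axonal segment
#'
#' Draws a segment length, baseline alpha/beta boutons, and their
#' longitudinal birth/death dynamics under the preset's latent parameters
#' (see [cohort_preset()] for the model). Positions are uniform along the
#' segment with a minimum inter-bouton spacing of 0.5 um so that boutons stay
#' resolvable at the imaging point-spread function.
#'
#' @param preset a [cohort_preset()]
#' @param schedule a [study_schedule()]; the canonical 0/4/8
#'   training-then-rest design, or a two-day single-phase design (phase
#'   `"rest"` or `"training"`) for spontaneous-turnover experiments
#' @param seed integer seed; the draw is fully deterministic given it
#' @param segment_id,mouse_id identifiers stamped on the output
#' @param p_override optional named list overriding `p_survive_training` /
#'   `p_survive_rest_pre` (used by [sample_cohort()] for mouse-level random
#'   effects)
#' @return an object of class `segment_truth`: list with `segment_id`,
#'   `mouse_id`, `genotype`, `length_um`, `schedule` and a `boutons` data
#'   frame (`bouton_id`, `class`, `diameter_um`, `arc_position_um`,
#'   `birth_day` (-1 for baseline), `death_day` (NA if never eliminated))
#' @examples
#' seg <- sample_segment(preset_wt(), study_schedule(), seed = 1)
#' head(seg$boutons)
#' @export
sample_segment <- function(preset, schedule = study_schedule(), seed,
                           segment_id = "seg1", mouse_id = "m1",
                           p_override = NULL) {
  stopifnot(inherits(preset, "cohort_preset"),
            inherits(schedule, "study_schedule"))
  if (missing(seed)) stop_named("sample_segment requires an explicit seed")
  validate_preset(preset)
  p_st <- p_override$p_survive_training %||% preset$p_survive_training
  p_rp <- p_override$p_survive_rest_pre %||% preset$p_survive_rest_pre
  days <- schedule$imaging_days
  phases <- schedule$phase_labels

  with_seed(seed, {
    L <- rtruncnorm(1, preset$segment_length_mean, preset$segment_length_sd,
                    preset$segment_length_range[1],
                    preset$segment_length_range[2])
    if (L <= 0) stop_named("zero-length segment")

    draw_diam <- function(class, n) {
      d <- if (class == "alpha") preset$alpha_diameter_dist
           else preset$beta_diameter_dist
      rtruncnorm(n, d$mean, d$sd, d$lo, d$hi)
    }
    ## first imaging day absent, given survival probability per phase
    ## (phase index k covers days[k] -> days[k+1]); vectorised over boutons
    draw_death <- function(p_by_phase, from_phase) {
      m <- length(p_by_phase)
      death <- rep(NA_integer_, length(from_phase))
      alive <- rep(TRUE, length(from_phase))
      for (k in seq_len(m)) {
        at_risk <- alive & from_phase < k
        if (!any(at_risk)) next
        dies <- at_risk & stats::runif(length(alive)) > p_by_phase[k]
        death[dies & is.na(death)] <- days[k + 1]
        alive <- alive & !dies
      }
      death
    }

    ## baseline counts
    n_alpha <- stats::rpois(1, preset$alpha_density * L / 100)
    n_beta <- stats::rpois(1, preset$beta_density * L / 100)
    p_beta_phase <- ifelse(phases == "training", p_st, p_rp)
    p_alpha_phase <- rep(preset$alpha_p_survive_4d, length(phases))

    cls <- character(); diam <- numeric()
    birth <- integer(); death <- integer()
    emit <- function(class, n, birth_day, death_day) {
      cls <<- c(cls, rep(class, n))
      diam <<- c(diam, draw_diam(class, n))
      birth <<- c(birth, rep(as.integer(birth_day), n))
      death <<- c(death, as.integer(death_day))
    }

    ## baseline betas survive training with p_st, then rest with p_rp
    emit("beta", n_beta, -1L, draw_death(p_beta_phase, rep(0L, n_beta)))
    ## phase-formed betas: training-formed persist with the stabilization
    ## probability, later formations follow the pre-existing rest law
    for (k in seq_along(phases)) {
      lambda <- n_beta * (if (phases[k] == "training")
        preset$formation_intensity_training else
          preset$formation_intensity_rest)
      n_new <- stats::rpois(1, lambda)
      p_later <- if (phases[k] == "training")
        rep(preset$p_stabilize_new, length(phases)) else p_beta_phase
      emit("beta", n_new, days[k + 1],
           draw_death(p_later, rep(k, n_new)))
    }
    ## alphas: near-immortal with a stationary small formation term
    emit("alpha", n_alpha, -1L,
         draw_death(p_alpha_phase, rep(0L, n_alpha)))
    for (k in seq_along(phases)) {
      n_new <- stats::rpois(1, (1 - preset$alpha_p_survive_4d) * n_alpha)
      emit("alpha", n_new, days[k + 1],
           draw_death(p_alpha_phase, rep(k, n_new)))
    }

    n_tot <- length(cls)
    pos <- sample_positions(n_tot, L)
    o <- order(pos)
    boutons <- structure(
      list(bouton_id = sprintf("%s_b%03d", segment_id, seq_len(n_tot)),
           class = cls[o], diameter_um = diam[o], arc_position_um = pos[o],
           birth_day = birth[o], death_day = death[o]),
      class = "data.frame",
      row.names = if (n_tot) seq_len(n_tot) else integer())

    structure(list(segment_id = segment_id, mouse_id = mouse_id,
                   genotype = preset$genotype, length_um = L,
                   schedule = schedule, boutons = boutons, seed = seed),
              class = "segment_truth")
  })
}

## uniform positions on [0, L] with a minimum spacing, by iterative
## redraw of violators; gives up (keeping the best attempt) when the
## segment is too crowded to honour the spacing
sample_positions <- function(n, L, min_spacing = 0.5, max_rounds = 60L) {
  if (n == 0) return(numeric())
  x <- stats::runif(n, 0, L)
  for (r in seq_len(max_rounds)) {
    o <- order(x)
    bad <- o[which(diff(x[o]) < min_spacing) + 1L]
    if (!length(bad)) break
    x[bad] <- stats::runif(length(bad), 0, L)
  }
  x
}

#' Is a ground-truth bouton present on a given imaging day?
#'
#' @param boutons the `boutons` data frame of a `segment_truth`
#' @param day imaging day
#' @return logical vector
#' @export
bouton_present <- function(boutons, day) {
  born <- boutons$birth_day < 0 | boutons$birth_day <= day
  alive <- is.na(boutons$death_day) | boutons$death_day > day
  born & alive
}

#' Simulate a full cohort of segments with mouse assignments
#'
#' Partitions `preset$n_segments` segments as evenly as possible across
#' `preset$n_mice` mice and simulates each via [sample_segment()] with a
#' deterministic per-segment child seed. If `preset$mouse_effect_sd > 0`, a
#' logit-normal mouse-level random effect perturbs the two baseline survival
#' probabilities, giving the nested mixed model something to estimate.
#'
#' @inheritParams sample_segment
#' @return an object of class `cohort_truth`: list of `segment_truth` plus
#'   `preset`, `schedule`, `seed`
#' @examples
#' coh <- sample_cohort(preset_wt(), study_schedule(), seed = 1)
#' length(coh$segments)
#' @export
sample_cohort <- function(preset, schedule = study_schedule(), seed) {
  stopifnot(inherits(preset, "cohort_preset"))
  if (missing(seed)) stop_named("sample_cohort requires an explicit seed")
  n_seg <- preset$n_segments
  n_mice <- preset$n_mice
  per_mouse <- rep(n_seg %/% n_mice, n_mice) +
    c(rep(1L, n_seg %% n_mice), rep(0L, n_mice - n_seg %% n_mice))
  mouse_ids <- sprintf("%s_m%02d", tolower(preset$genotype), seq_len(n_mice))
  mouse_of_segment <- rep(mouse_ids, per_mouse)

  offsets <- rep(0, n_mice)
  if (preset$mouse_effect_sd > 0)
    offsets <- with_seed(derive_seed(seed, 0L),
                         stats::rnorm(n_mice, 0, preset$mouse_effect_sd))
  names(offsets) <- mouse_ids
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))

  segments <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    m <- mouse_of_segment[i]
    ov <- NULL
    if (offsets[m] != 0) {
      ov <- list(
        p_survive_training =
          inv_logit(logit(preset$p_survive_training) + offsets[m]),
        p_survive_rest_pre =
          inv_logit(logit(preset$p_survive_rest_pre) + offsets[m]))
    }
    segments[[i]] <- sample_segment(
      preset, schedule, seed = derive_seed(seed, i),
      segment_id = sprintf("%s_s%03d", tolower(preset$genotype), i),
      mouse_id = m, p_override = ov)
  }
  structure(list(segments = segments, preset = preset, schedule = schedule,
                 seed = seed),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("cohort_truth [%s]: %d segments, %d mice, seed %d\n",
              x$preset$genotype, length(x$segments), x$preset$n_mice,
              x$seed))
  invisible(x)
}

#' Long-format presence table for a cohort or segment
#'
#' One row per bouton per imaging day with a presence flag; this is the
#' ground-truth CSV format of the tabular pipeline.
#'
#' @param x a `cohort_truth` or `segment_truth`
#' @return data frame with columns `segment_id`, `mouse_id`, `genotype`,
#'   `day`, `bouton_id`, `arc_position_um`, `diameter_um`, `class`, `present`
#' @export
presence_table <- function(x) {
  segs <- if (inherits(x, "cohort_truth")) x$segments else list(x)
  out <- lapply(segs, function(s) {
    b <- s$boutons
    if (!nrow(b)) return(NULL)
    do.call(rbind, lapply(s$schedule$imaging_days, function(d) {
      data.frame(segment_id = s$segment_id, mouse_id = s$mouse_id,
                 genotype = s$genotype, day = d, bouton_id = b$bouton_id,
                 arc_position_um = b$arc_position_um,
                 diameter_um = b$diameter_um, class = b$class,
                 present = bouton_present(b, d))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Segment metadata table for a cohort
#'
#' @param cohort a `cohort_truth`
#' @return data frame `segment_id`, `mouse_id`, `genotype`, `length_um`
#' @export
segment_table <- function(cohort) {
  do.call(rbind, lapply(cohort$segments, function(s)
    data.frame(segment_id = s$segment_id, mouse_id = s$mouse_id,
               genotype = s$genotype, length_um = s$length_um)))
}

#' Ground-truth bouton calls for one segment on one day
#'
#' Presents the boutons present on `day` in the bouton-call format consumed
#' by the longitudinal tracker, so ground truth can flow through the same
#' tabular pipeline as image-derived detections.
#'
#' @param segment a `segment_truth`
#' @param day imaging day
#' @return data frame `arc_position_um`, `diameter_um`, `class`,
#'   `brightness_ratio` (NA for ground truth), `excluded_isolated`
#' @export
truth_calls <- function(segment, day) {
  b <- segment$boutons[bouton_present(segment$boutons, day), , drop = FALSE]
  n <- nrow(b)
  out <- data.frame(arc_position_um = b$arc_position_um,
                    diameter_um = b$diameter_um, class = b$class,
                    brightness_ratio = rep(NA_real_, n),
                    width_excess_um = rep(NA_real_, n),
                    excluded_isolated = rep(FALSE, n))
  out[order(out$arc_position_um), , drop = FALSE]
}

#' Write ground-truth CSVs (presence + segments) and run metadata
#'
#' @param cohort a `cohort_truth`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_ground_truth <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(boutons = file.path(dir, "ground_truth_boutons.csv"),
             segments = file.path(dir, "segments.csv"),
             preset = file.path(dir, "preset.yaml"),
             schedule = file.path(dir, "schedule.yaml"))
  utils::write.csv(presence_table(cohort), paths["boutons"],
                   row.names = FALSE)
  utils::write.csv(segment_table(cohort), paths["segments"],
                   row.names = FALSE)
  write_preset_yaml(cohort$preset, paths["preset"])
  yaml::write_yaml(c(unclass(cohort$schedule), list(seed = cohort$seed)),
                   paths["schedule"])
  invisible(paths)
}
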