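#' Generative parameters for one genotype cohort
#'
#' A `cohort_preset` bundles everything the synthetic-cohort generator needs
#' for one genotype: cohort size, the segment-length distribution, baseline
#' bouton densities, the alpha/beta diameter distributions, and the latent
#' birth/death parameters that drive longitudinal dynamics over a
#' training-then-rest schedule.
#'
#' Probabilistic model (per segment of length L, per class):
#' baseline counts are Poisson(density x L / 100); each baseline beta bouton
#' survives the training interval with `p_survive_training` and, if present at
#' day 4, survives the rest interval with `p_survive_rest_pre`. Boutons formed
#' during training number Poisson(`formation_intensity_training` x baseline
#' count) and persist to day 8 with `p_stabilize_new`; rest-formed boutons
#' number Poisson(`formation_intensity_rest` x baseline count). Alpha boutons
#' are near-immortal: they survive each 4-day interval with
#' `alpha_p_survive_4d` and are replenished by a matching small formation term
#' `(1 - alpha_p_survive_4d) x count` that keeps their density stationary.
#'
#' @param genotype `"WT"` or `"MECP2dup"`
#' @param n_mice number of mice in the cohort
#' @param n_segments total number of axonal segments across mice
#' @param segment_length_mean,segment_length_sd truncated-normal segment
#'   length parameters (micrometres); truncation bounds
#'   `segment_length_range`
#' @param segment_length_range length bounds in micrometres
#' @param alpha_density,beta_density baseline densities (boutons / 100 um)
#' @param alpha_diameter_dist,beta_diameter_dist lists
#'   `list(mean, sd, lo, hi)` of truncated-normal diameter parameters in
#'   micrometres; the two supports must not straddle the 2 um class boundary
#' @param p_survive_training probability a baseline beta bouton persists
#'   day 0 -> day 4
#' @param p_survive_rest_pre probability a day-4-surviving baseline bouton
#'   persists day 4 -> day 8
#' @param p_stabilize_new probability a training-formed bouton persists to
#'   day 8
#' @param formation_intensity_training,formation_intensity_rest expected new
#'   beta boutons per baseline bouton per phase
#' @param alpha_p_survive_4d alpha-bouton survival probability per 4-day
#'   interval
#' @param mouse_effect_sd logit-scale SD of a mouse-level random effect on
#'   the survival probabilities (default 0 = homogeneous mice; used only for
#'   mixed-model operating-characteristic experiments)
#' @return an object of class `cohort_preset`
#' @seealso [preset_wt()], [preset_mecp2dup()], [calibrate_preset()]
#' @export
cohort_preset <- function(genotype = c("WT", "MECP2dup"),
                          n_mice = 6L,
                          n_segments = 58L,
                          segment_length_mean = 138,
                          segment_length_sd = 73,
                          segment_length_range = c(30, 360),
                          alpha_density = 2.7,
                          beta_density = 4.0,
                          alpha_diameter_dist = list(mean = 2.6, sd = 0.35,
                                                     lo = 2.05, hi = 3.5),
                          beta_diameter_dist = list(mean = 1.4, sd = 0.25,
                                                    lo = 1.0, hi = 1.95),
                          p_survive_training = 0.77,
                          p_survive_rest_pre = 0.896,
                          p_stabilize_new = 0.32,
                          formation_intensity_training = 0.1506,
                          formation_intensity_rest = 0.1366,
                          alpha_p_survive_4d = 0.995,
                          mouse_effect_sd = 0) {
  genotype <- match.arg(genotype)
  p <- list(genotype = genotype,
            n_mice = as.integer(n_mice),
            n_segments = as.integer(n_segments),
            segment_length_mean = segment_length_mean,
            segment_length_sd = segment_length_sd,
            segment_length_range = segment_length_range,
            alpha_density = alpha_density,
            beta_density = beta_density,
            alpha_diameter_dist = alpha_diameter_dist,
            beta_diameter_dist = beta_diameter_dist,
            p_survive_training = p_survive_training,
            p_survive_rest_pre = p_survive_rest_pre,
            p_stabilize_new = p_stabilize_new,
            formation_intensity_training = formation_intensity_training,
            formation_intensity_rest = formation_intensity_rest,
            alpha_p_survive_4d = alpha_p_survive_4d,
            mouse_effect_sd = mouse_effect_sd)
  validate_preset(p)
  structure(p, class = "cohort_preset")
}

validate_preset <- function(p) {
  probs <- c(p$p_survive_training, p$p_survive_rest_pre, p$p_stabilize_new,
             p$alpha_p_survive_4d)
  if (any(probs < 0 | probs > 1))
    stop_named("all survival/stabilization probabilities must lie in [0, 1]")
  if (p$alpha_density <= 0 || p$beta_density <= 0)
    stop_named("bouton densities must be positive")
  if (p$formation_intensity_training < 0 || p$formation_intensity_rest < 0)
    stop_named("formation intensities must be nonnegative")
  if (p$segment_length_range[1] <= 0 ||
      diff(p$segment_length_range) <= 0)
    stop_named("invalid segment length range")
  if (p$beta_diameter_dist$hi >= 2 || p$alpha_diameter_dist$lo <= 2)
    stop_named(
      "diameter distributions must not overlap the 2 um class boundary")
  if (p$n_mice < 1) stop_named("n_mice must be >= 1")
  if (p$n_segments < 1) stop_named("n_segments must be >= 1")
  invisible(p)
}

#' @export
print.cohort_preset <- function(x, ...) {
  cat(sprintf("cohort_preset [%s]: %d segments / %d mice\n",
              x$genotype, x$n_segments, x$n_mice))
  cat(sprintf("  lengths ~ truncN(%.0f, %.0f) on [%g, %g] um\n",
              x$segment_length_mean, x$segment_length_sd,
              x$segment_length_range[1], x$segment_length_range[2]))
  cat(sprintf("  densities: alpha %.2f, beta %.2f /100 um\n",
              x$alpha_density, x$beta_density))
  cat(sprintf(
    "  beta dynamics: p_surv_train %.3f, p_surv_rest %.3f, p_stab %.3f\n",
    x$p_survive_training, x$p_survive_rest_pre, x$p_stabilize_new))
  cat(sprintf("  formation intensities: training %.3f, rest %.3f\n",
              x$formation_intensity_training, x$formation_intensity_rest))
  cat(sprintf("  alpha p_survive(4 d): %.3f\n", x$alpha_p_survive_4d))
  invisible(x)
}

#' Published cohort-level target statistics by genotype
#'
#' Per-segment cohort means (fractions, not percent) of the published
#' motor-cortex L5-to-L1 axonal bouton study that the synthetic generator is
#' calibrated against: beta-bouton formation and elimination fractions per
#' phase (total-observed denominator), baseline-bouton survival to day 4 and
#' day 8, and the stabilization rate of training-formed boutons.
#'
#' @param genotype `"WT"` or `"MECP2dup"`
#' @return named list of target fractions understood by [calibrate_preset()]
#' @export
cohort_targets <- function(genotype = c("WT", "MECP2dup")) {
  genotype <- match.arg(genotype)
  if (genotype == "WT") {
    list(elimination_training = 0.17, elimination_rest = 0.06,
         formation_training = 0.10, formation_rest = 0.09,
         survival_d4 = 0.77, survival_d8 = 0.69,
         stabilization = 0.32)
  } else {
    list(elimination_training = 0.05, elimination_rest = 0.04,
         formation_training = 0.10, formation_rest = 0.06,
         survival_d4 = 0.95, survival_d8 = 0.89,
         stabilization = 0.40)
  }
}

#' Wild-type cohort preset
#'
#' Cohort preset for the wild-type littermate condition: 58 segments from six
#' mice, alpha density 2.7 and beta density 4.0 boutons/100 um, segment
#' lengths 142 +/- 73 um truncated to [30, 360], and latent dynamics
#' pre-calibrated (via [calibrate_preset()]) to the published WT cohort
#' statistics in [cohort_targets()].
#'
#' @return a `cohort_preset`
#' @export
preset_wt <- function() {
  cohort_preset(genotype = "WT", n_mice = 6L, n_segments = 58L,
                segment_length_mean = 142, segment_length_sd = 73,
                alpha_density = 2.7, beta_density = 4.0,
                p_survive_training = 0.77,
                p_survive_rest_pre = 0.69 / 0.77,
                p_stabilize_new = 0.32,
                formation_intensity_training = 0.1506,
                formation_intensity_rest = 0.1366,
                alpha_p_survive_4d = 0.995)
}

#' MECP2-duplication cohort preset
#'
#' Cohort preset for the MECP2-duplication (Tg1) condition: 54 segments from
#' seven mice, alpha density 2.4 and beta density 5.8 boutons/100 um, segment
#' lengths 133 +/- 73 um, latent dynamics pre-calibrated to the published
#' mutant cohort statistics (high stability: 95% day-4 survival, 5% training
#' elimination).
#'
#' @return a `cohort_preset`
#' @export
preset_mecp2dup <- function() {
  cohort_preset(genotype = "MECP2dup", n_mice = 7L, n_segments = 54L,
                segment_length_mean = 133, segment_length_sd = 73,
                alpha_density = 2.4, beta_density = 5.8,
                p_survive_training = 0.95,
                p_survive_rest_pre = 0.89 / 0.95,
                p_stabilize_new = 0.40,
                formation_intensity_training = 0.1401,
                formation_intensity_rest = 0.0804,
                alpha_p_survive_4d = 0.995)
}

#' Serialize a preset (or schedule) to YAML
#'
#' @param x a `cohort_preset` or `study_schedule`
#' @param path file to write
#' @return `path`, invisibly
#' @export
write_preset_yaml <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' Read a preset from YAML
#'
#' @param path YAML file written by [write_preset_yaml()]
#' @return a `cohort_preset`
#' @export
read_preset_yaml <- function(path) {
  do.call(cohort_preset, yaml::read_yaml(path))
}
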