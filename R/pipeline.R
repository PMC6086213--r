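## end-to-end experiment orchestration

#' Configuration for an end-to-end run
#'
#' @param mode `"tabular"` (simulate -> track -> stats -> report) or
#'   `"imaging"` (simulate -> render -> detect -> track -> stats -> report)
#' @param presets list of [cohort_preset()] (one per genotype)
#' @param schedule a [study_schedule()]
#' @param imaging an [imaging_spec()] (imaging mode)
#' @param detection a [detect_config()]
#' @param seed master seed; every stage seed is derived from it
#' @param out_dir output directory
#' @param max_imaging_segments cap on rendered segments per genotype
#' @param tolerance_um longitudinal matching tolerance
#' @return an object of class `run_config`
#' @export
run_config <- function(mode = c("tabular", "imaging"),
                       presets = list(preset_wt(), preset_mecp2dup()),
                       schedule = study_schedule(),
                       imaging = imaging_spec(),
                       detection = detect_config(),
                       seed = 1L, out_dir = tempfile("boutonflux_run_"),
                       max_imaging_segments = 100L, tolerance_um = 2) {
  mode <- match.arg(mode)
  structure(list(mode = mode, presets = presets, schedule = schedule,
                 imaging = imaging, detection = detection,
                 seed = as.integer(seed), out_dir = out_dir,
                 max_imaging_segments = max_imaging_segments,
                 tolerance_um = tolerance_um),
            class = "run_config")
}

## events for one cohort through the imaging pipeline
image_mode_events <- function(cohort, config, warn) {
  sched <- cohort$schedule
  out <- list()
  for (s in cohort$segments) {
    calls <- lapply(sched$imaging_days, function(d) {
      st <- render_segment(s, d, config$imaging,
                           seed = derive_seed(cohort$seed,
                                              match(d, sched$imaging_days) *
                                                10000L + s$seed %% 10000L))
      cl <- detect_segment(st, config$detection)
      cl[!cl$excluded_isolated, , drop = FALSE]
    })
    ev <- label_events(calls, sched, config$tolerance_um)
    if (nrow(ev))
      out[[s$segment_id]] <- cbind(
        data.frame(segment_id = s$segment_id, mouse_id = s$mouse_id,
                   genotype = s$genotype), ev)
  }
  do.call(rbind, out)
}

#' Run a complete simulated experiment
#'
#' Simulates one cohort per preset, derives events (directly from ground
#' truth in tabular mode; through rendering and detection in imaging mode),
#' computes per-segment and cohort-level turnover statistics, runs the
#' inference battery, and writes every artefact plus a manifest into
#' `config$out_dir`. Reruns with the same config are reproducible.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with `per_segment`, `summary`, `contrasts`,
#'   `manifest`
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warns <- character()
  events_all <- list(); segs_all <- list()
  for (gi in seq_along(config$presets)) {
    preset <- config$presets[[gi]]
    message(sprintf("[boutonflux] simulating %s cohort (%d segments)",
                    preset$genotype, preset$n_segments))
    if (config$mode == "imaging" &&
        preset$n_segments > config$max_imaging_segments)
      stop_named("imaging mode limited to %d segments per genotype",
                 config$max_imaging_segments)
    cohort <- sample_cohort(preset, config$schedule,
                            seed = derive_seed(config$seed, gi))
    write_ground_truth(cohort,
                       file.path(config$out_dir,
                                 paste0("truth_", preset$genotype)))
    ev <- if (config$mode == "tabular")
      track_cohort(cohort, config$tolerance_um)
    else image_mode_events(cohort, config, warns)
    events_all[[gi]] <- ev
    segs_all[[gi]] <- segment_table(cohort)
  }
  events <- do.call(rbind, events_all)
  segments <- do.call(rbind, segs_all)
  per_segment <- segment_statistics(events, segments, config$schedule)
  n_na <- sum(is.na(per_segment$survival_d4))
  if (n_na) warns <- c(warns, sprintf(
    "%d segments without baseline beta boutons excluded from survival",
    n_na))
  summary_tab <- aggregate_cohort(per_segment)
  contrasts <- report_contrasts(per_segment)
  warns <- c(warns, contrasts$notes)

  paths <- c(events = file.path(config$out_dir, "events.csv"),
             per_segment = file.path(config$out_dir, "per_segment.csv"),
             summary = file.path(config$out_dir, "cohort_summary.json"),
             report = file.path(config$out_dir, "report.md"),
             config = file.path(config$out_dir, "config.yaml"),
             manifest = file.path(config$out_dir, "manifest.json"))
  utils::write.csv(events, paths["events"], row.names = FALSE)
  utils::write.csv(per_segment, paths["per_segment"], row.names = FALSE)
  jsonlite::write_json(summary_tab, paths["summary"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  write_report_md(summary_tab, contrasts, paths["report"])
  yaml::write_yaml(serialize_config(config), paths["config"])
  manifest <- list(
    mode = config$mode, seed = config$seed,
    config_md5 = unname(tools::md5sum(paths["config"])),
    genotypes = vapply(config$presets, `[[`, "", "genotype"),
    rows = list(events = nrow(events), per_segment = nrow(per_segment),
                summary = nrow(summary_tab)),
    files = basename(unname(paths)),
    warnings = warns)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  message(sprintf("[boutonflux] run complete: %s", config$out_dir))
  invisible(list(per_segment = per_segment, summary = summary_tab,
                 contrasts = contrasts, manifest = manifest))
}

serialize_config <- function(config) {
  list(mode = config$mode,
       presets = lapply(config$presets, unclass),
       schedule = unclass(config$schedule),
       imaging = unclass(config$imaging),
       detection = config$detection,
       seed = config$seed,
       tolerance_um = config$tolerance_um)
}

write_report_md <- function(summary_tab, contrasts, path) {
  lines <- c("# Bouton turnover report", "",
             "## Cohort means (per-segment mean +/- SEM)", "",
             "| genotype | statistic | mean | sem | n |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %.4g | %.3g | %d |",
                     summary_tab$genotype, summary_tab$statistic,
                     summary_tab$mean, summary_tab$sem, summary_tab$n),
             "", "## Mann-Whitney contrasts", "")
  if (!is.null(contrasts$mw))
    lines <- c(lines,
               "| response | contrast | group | U | n1 | n2 | p |",
               "|---|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %g | %d | %d | %.3g |",
                       contrasts$mw$response, contrasts$mw$contrast,
                       contrasts$mw$group, contrasts$mw$u, contrasts$mw$n1,
                       contrasts$mw$n2, contrasts$mw$p))
  for (nm in names(contrasts$lmm)) {
    r <- contrasts$lmm[[nm]]
    if (is.null(r)) next
    lines <- c(lines, "", sprintf("## Mixed model: %s", nm), "",
               "| term | estimate | se | t | p |", "|---|---|---|---|---|",
               sprintf("| %s | %.4g | %.3g | %.2f | %.3g |",
                       r$fixed_effects$term, r$fixed_effects$estimate,
                       r$fixed_effects$se, r$fixed_effects$t,
                       r$fixed_effects$p),
               sprintf("%s", if (r$boundary)
                 "(boundary fit: a variance component is zero)" else ""))
  }
  if (length(contrasts$notes))
    lines <- c(lines, "", "## Notes", "", paste("-", contrasts$notes))
  writeLines(lines, path)
  invisible(path)
}
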