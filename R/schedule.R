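#' Imaging schedule for a train-then-rest longitudinal experiment
#'
#' Describes the imaging days and the behavioural phase spanned by each
#' consecutive pair of days. The default is the three-time-point design used
#' throughout the package: baseline imaging at day 0, reimaging after 4 days
#' of rotarod training (phase `"training"`), and a final session after 4
#' further days of home-cage rest (phase `"rest"`).
#'
#' @param imaging_days strictly increasing integer vector of imaging days
#' @param phase_labels character vector naming the phase of each consecutive
#'   day interval; length must be `length(imaging_days) - 1`
#' @return an object of class `study_schedule` with elements `imaging_days`
#'   and `phase_labels`
#' @examples
#' study_schedule()
#' study_schedule(c(0, 4), "rest")  # a single spontaneous-turnover interval
#' @export
study_schedule <- function(imaging_days = c(0L, 4L, 8L),
                           phase_labels = if (length(imaging_days) == 3)
                             c("training", "rest") else NULL) {
  imaging_days <- as.integer(imaging_days)
  if (length(imaging_days) < 2 || any(diff(imaging_days) <= 0))
    stop_named("imaging_days must be strictly increasing, length >= 2")
  if (is.null(phase_labels) ||
      length(phase_labels) != length(imaging_days) - 1)
    stop_named("need exactly one phase label per consecutive day pair")
  structure(list(imaging_days = imaging_days,
                 phase_labels = as.character(phase_labels)),
            class = "study_schedule")
}

#' @export
print.study_schedule <- function(x, ...) {
  cat("study_schedule: days", paste(x$imaging_days, collapse = " -> "), "\n")
  iv <- paste0(utils::head(x$imaging_days, -1), "->",
               utils::tail(x$imaging_days, -1))
  cat("  phases:", paste(paste0(iv, " (", x$phase_labels, ")"),
                         collapse = ", "), "\n")
  invisible(x)
}

## interval index of a named phase
phase_index <- function(schedule, phase) {
  i <- match(phase, schedule$phase_labels)
  if (is.na(i)) stop_named("unknown phase '%s'", phase)
  i
}
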