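## two-group and mixed-model inference on per-segment statistics

#' Mann-Whitney U test (two-sided)
#'
#' U is computed with midrank tie handling. The p-value uses the exact
#' permutation distribution when the combined sample size is at most 20 and
#' there are no ties, and the normal approximation with tie and continuity
#' corrections otherwise. Two samples with all values identical are
#' degenerate: U = n1 n2 / 2, p = 1.
#'
#' @param a,b numeric samples (nonempty)
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   `NULL` (default) chooses by the rule above
#' @return an object of class `mw_result`: `u_statistic`, `n1`, `n2`,
#'   `p_two_sided`, `method` (`"exact"` or `"normal_approx"`),
#'   `degenerate`
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop_named("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (diff(range(c(a, b))) == 0) {
    res <- list(u_statistic = u, n1 = n1, n2 = n2, p_two_sided = 1,
                method = "degenerate", degenerate = TRUE)
    return(structure(res, class = "mw_result"))
  }
  use_exact <- exact %||% (n1 + n2 <= 20 && !ties)
  if (use_exact && ties)
    stop_named("exact Mann-Whitney p-values require untied data")
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, exact = use_exact, correct = TRUE, alternative = "two.sided"))
  structure(list(u_statistic = u, n1 = n1, n2 = n2,
                 p_two_sided = wt$p.value,
                 method = if (use_exact) "exact" else "normal_approx",
                 degenerate = FALSE),
            class = "mw_result")
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Nested linear mixed-effects model for genotype x phase designs
#'
#' Fits `response ~ genotype * phase + (1 | mouse) + (1 | mouse:axon)` by
#' REML (random intercepts for mouse and for axon nested in mouse), the
#' standard repeated-measures-style model for per-segment fractions measured
#' in two phases. Reference levels are the first genotype level (WT when
#' present) and phase `"rest"`, so the `phase` coefficient is the
#' training-minus-rest contrast. p-values use the normal reference for the
#' t statistics (documented choice; with dozens of segments the difference
#' from any df correction is negligible). Boundary (singular) fits are
#' flagged, never silent.
#'
#' @param data data frame in long format: one row per segment per phase
#' @param response name of the response column (a fraction)
#' @param genotype,phase,mouse,axon column names of the design factors
#' @return an object of class `lmm_result`: `fixed_effects` (data frame
#'   `term`, `estimate`, `se`, `t`, `p`), `variance_components` (mouse,
#'   axon, residual), `n_obs`, `n_mice`, `n_axons`, `converged`, `boundary`
#' @export
fit_lmm <- function(data, response, genotype = "genotype", phase = "phase",
                    mouse = "mouse_id", axon = "segment_id") {
  d <- data.frame(y = data[[response]],
                  genotype = factor(data[[genotype]]),
                  phase = factor(data[[phase]]),
                  mouse = factor(data[[mouse]]),
                  axon = factor(data[[axon]]))
  d <- d[!is.na(d$y), , drop = FALSE]
  if ("WT" %in% levels(d$genotype))
    d$genotype <- stats::relevel(d$genotype, "WT")
  if ("rest" %in% levels(d$phase))
    d$phase <- stats::relevel(d$phase, "rest")
  if (nlevels(d$genotype) >= 2) {
    per_geno <- tapply(d$mouse, d$genotype,
                       function(m) length(unique(m)))
    if (any(per_geno < 2))
      stop_named("need at least 2 mice per genotype for the mixed model")
  }
  if (stats::var(d$y) < 1e-24) {
    ## perfectly constant response: the mixed model is degenerate (zero
    ## residual variance breaks the REML machinery); report the exact
    ## boundary solution directly
    X <- stats::model.matrix(~ genotype * phase, d)
    fe <- data.frame(term = colnames(X),
                     estimate = c(d$y[1], rep(0, ncol(X) - 1)),
                     se = 0, t = NA_real_, p = NA_real_, row.names = NULL)
    return(structure(list(fixed_effects = fe,
                          variance_components = c(mouse = 0, axon = 0,
                                                  residual = 0),
                          n_obs = nrow(d), n_mice = nlevels(d$mouse),
                          n_axons = nlevels(droplevels(d$axon)),
                          converged = TRUE, boundary = TRUE, fit = NULL),
                     class = "lmm_result"))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ genotype * phase + (1 | mouse) + (1 | mouse:axon),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  co <- summary(fit)$coefficients
  fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                   se = co[, "Std. Error"], t = co[, "t value"],
                   row.names = NULL)
  fe$p <- 2 * stats::pnorm(-abs(fe$t))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- c(mouse = vc$vcov[vc$grp == "mouse"],
             axon = vc$vcov[vc$grp == "mouse:axon"],
             residual = vc$vcov[vc$grp == "Residual"])
  conv <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0
  structure(list(fixed_effects = fe, variance_components = vcomp,
                 n_obs = nrow(d), n_mice = nlevels(d$mouse),
                 n_axons = nlevels(droplevels(d$axon)),
                 converged = conv,
                 boundary = lme4::isSingular(fit, tol = 1e-6),
                 fit = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("linear mixed model: %d obs, %d mice, %d axons%s%s\n",
              x$n_obs, x$n_mice, x$n_axons,
              if (x$boundary) " [boundary fit]" else "",
              if (!x$converged) " [convergence warning]" else ""))
  print(transform(x$fixed_effects, estimate = signif(estimate, 4),
                  se = signif(se, 3), t = round(t, 2), p = signif(p, 3)),
        row.names = FALSE)
  cat("variance components:",
      paste(names(x$variance_components),
            signif(x$variance_components, 3), collapse = ", "), "\n")
  invisible(x)
}

## reshape a per-segment statistics table into the long per-segment-per-phase
## format the mixed model consumes
segment_phase_long <- function(per_segment, responses =
                                 c(elimination = "elimination",
                                   formation = "formation")) {
  phases <- unique(sub("^(formation|elimination)_", "",
                       grep("^formation_[a-z]+$", names(per_segment),
                            value = TRUE)))
  out <- list()
  for (ph in phases) {
    row <- data.frame(segment_id = per_segment$segment_id,
                      mouse_id = per_segment$mouse_id,
                      genotype = per_segment$genotype, phase = ph)
    for (nm in names(responses)) {
      col <- paste0(responses[[nm]], "_", ph)
      row[[nm]] <- if (col %in% names(per_segment)) per_segment[[col]]
        else NA_real_
    }
    ## survival over the interval ending each phase
    surv_col <- c(training = "survival_d4",
                  rest = "maintenance_rest_preexisting")[ph]
    row$survival <- if (!is.na(surv_col) && surv_col %in%
                          names(per_segment)) per_segment[[surv_col]]
      else NA_real_
    out[[ph]] <- row
  }
  do.call(rbind, out)
}

#' Full two-group comparison battery
#'
#' Emits, for elimination, formation and survival: the training-vs-rest
#' Mann-Whitney comparison within each genotype, the between-genotype
#' Mann-Whitney comparison within each phase, and (when both genotypes are
#' present) the genotype x phase linear mixed model. With a single genotype
#' the genotype contrasts are skipped with an explicit notice.
#'
#' @param per_segment per-segment statistics from [segment_statistics()]
#' @return an object of class `contrast_report`: `mw` (data frame of all
#'   Mann-Whitney contrasts), `lmm` (named list of `lmm_result`), `notes`
#' @export
report_contrasts <- function(per_segment) {
  long <- segment_phase_long(per_segment)
  genos <- unique(as.character(per_segment$genotype))
  phases <- unique(long$phase)
  responses <- c("elimination", "formation", "survival")
  notes <- character()
  mw <- list()
  add_mw <- function(resp, contrast, group, a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) return()
    r <- mann_whitney(a, b)
    mw[[length(mw) + 1L]] <<- data.frame(
      response = resp, contrast = contrast, group = group,
      u = r$u_statistic, n1 = r$n1, n2 = r$n2, p = r$p_two_sided,
      method = r$method)
  }
  for (resp in responses) {
    for (g in genos) {
      sub <- long[long$genotype == g, ]
      if (all(c("training", "rest") %in% phases))
        add_mw(resp, "training_vs_rest", g,
               sub[[resp]][sub$phase == "training"],
               sub[[resp]][sub$phase == "rest"])
    }
    if (length(genos) >= 2) {
      for (ph in phases) {
        sub <- long[long$phase == ph, ]
        add_mw(resp, "genotype", ph,
               sub[[resp]][sub$genotype == genos[1]],
               sub[[resp]][sub$genotype == genos[2]])
      }
    }
  }
  if (length(genos) < 2)
    notes <- c(notes, paste("single genotype supplied: genotype contrasts",
                            "and mixed models skipped"))
  lmm <- list()
  if (length(genos) >= 2) {
    for (resp in responses) {
      lmm[[resp]] <- tryCatch(fit_lmm(long, resp),
                              error = function(e) {
                                notes <<- c(notes, sprintf(
                                  "lmm for %s failed: %s", resp,
                                  conditionMessage(e)))
                                NULL
                              })
    }
  }
  ## stabilization: one value per segment, Mann-Whitney across genotypes
  if (length(genos) >= 2 && "stabilization" %in% names(per_segment))
    add_mw("stabilization", "genotype", "rest",
           per_segment$stabilization[per_segment$genotype == genos[1]],
           per_segment$stabilization[per_segment$genotype == genos[2]])
  structure(list(mw = do.call(rbind, mw), lmm = lmm, notes = notes),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("Mann-Whitney contrasts:\n")
  if (!is.null(x$mw))
    print(transform(x$mw, p = signif(p, 3)), row.names = FALSE)
  for (nm in names(x$lmm)) {
    cat("\nmixed model --", nm, "\n")
    print(x$lmm[[nm]])
  }
  if (length(x$notes)) cat("\nnotes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
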