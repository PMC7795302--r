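## The user-facing model: hb_fit() runs all three stages on a cohort of
## sessions and returns a fitted classifier with the usual S3 methods.

#' Pipeline configuration
#'
#' All tunable settings of the three-stage pipeline in one validated object.
#' A fully-defaulted configuration is valid.
#'
#' @param grid_n Points of the common \[0, 1\] registration grid.
#' @param smooth_window Odd moving-average window for alignment curves.
#' @param threshold Landmark activation threshold (fraction of range).
#' @param n_points Reference-template length for DTW detection.
#' @param rest_frac Rest fraction of the reference template.
#' @param repetition Repetition selected for analysis (2 = second).
#' @param basis_dim B-spline dimension of the health-score models.
#' @param penalty Ridge penalty of the health-score models.
#' @param baseline `"rest_window"` or `"first_sample"` intensity baseline.
#' @param n_rest Rest-window length (samples) for the baseline.
#' @param speed_transform `"residual"` or `"none"` for speed curves.
#' @param olr_tol,olr_max_iter Ordinal-fit convergence control.
#' @param stepwise Use stepwise AIC selection (otherwise all labels enter).
#' @param outlier_z Robust z threshold of the intensity-outlier warning.
#' @param seed Seed for any randomized steps (simulation only).
#' @return List of class `hb_config`.
#' @export
hb_config <- function(grid_n = 100L, smooth_window = 5L, threshold = 0.15,
                      n_points = 100L, rest_frac = 0.2, repetition = 2L,
                      basis_dim = 8L, penalty = 1e-3,
                      baseline = c("rest_window", "first_sample"), n_rest = 5L,
                      speed_transform = c("residual", "none"),
                      olr_tol = 1e-8, olr_max_iter = 500L, stepwise = TRUE,
                      outlier_z = 5, seed = 1L) {
  cfg <- list(grid_n = as.integer(grid_n),
              smooth_window = as.integer(smooth_window),
              threshold = threshold, n_points = as.integer(n_points),
              rest_frac = rest_frac, repetition = as.integer(repetition),
              basis_dim = as.integer(basis_dim), penalty = penalty,
              baseline = match.arg(baseline), n_rest = as.integer(n_rest),
              speed_transform = match.arg(speed_transform),
              olr_tol = olr_tol, olr_max_iter = as.integer(olr_max_iter),
              stepwise = isTRUE(stepwise), outlier_z = outlier_z,
              seed = as.integer(seed))
  if (cfg$grid_n < 10) hb_stop("bad_config", "grid_n must be >= 10")
  if (cfg$smooth_window < 1 || cfg$smooth_window %% 2 == 0)
    hb_stop("bad_config", "smooth_window must be a positive odd integer")
  if (cfg$threshold <= 0 || cfg$threshold >= 0.5)
    hb_stop("bad_config", "threshold must be in (0, 0.5)")
  if (cfg$rest_frac <= 0 || cfg$rest_frac >= 1)
    hb_stop("bad_config", "rest_frac must be in (0, 1)")
  if (cfg$basis_dim < 1) hb_stop("bad_config", "basis_dim must be >= 1")
  if (cfg$penalty < 0) hb_stop("bad_config", "penalty must be >= 0")
  class(cfg) <- "hb_config"
  cfg
}

## registration + indicators for a list of sessions; failures are collected,
## not fatal for the cohort
cohort_indicators <- function(sessions, config, warn_outliers = TRUE) {
  inds <- list(); failures <- list()
  for (s in sessions) {
    res <- tryCatch({
      rs <- register_session(s, grid_n = config$grid_n,
                             smooth_window = config$smooth_window,
                             threshold = config$threshold,
                             n_points = config$n_points,
                             rest_frac = config$rest_frac,
                             repetition = config$repetition)
      compute_indicators(rs, grid_n = config$grid_n,
                         baseline = config$baseline, n_rest = config$n_rest)
    }, hbgrade_error = function(e) e)
    if (inherits(res, "error")) failures[[s$session_id]] <- conditionMessage(res)
    else inds[[s$session_id]] <- res
  }
  if (length(failures))
    warning(sprintf("registration failed for %d session(s): %s",
                    length(failures),
                    paste(names(failures), collapse = ", ")), call. = FALSE)
  if (warn_outliers && length(inds) >= 3)
    check_intensity_outliers(inds, config$outlier_z)
  list(indicators = inds, failures = failures)
}

#' Fit the full House-Brackmann grading model
#'
#' Runs the complete three-stage procedure on a cohort: registers every
#' session and computes its indicator curves; fits one scalar-on-function
#' logistic health-score model per indicator on the Healthy (adjusted HB1)
#' versus Sick (adjusted HB6) extreme groups; scores all sessions; and fits
#' the inverse-frequency-weighted proportional-odds classifier on the scores
#' (with stepwise AIC selection by default). Sessions flagged `excluded` are
#' dropped; per-session registration failures are reported and skipped.
#'
#' @param sessions List of [session()] objects.
#' @param grades Raw clinician grades (1-6), one per session; defaults to
#'   each session's stored `hb_clinician`. Adjusted internally (4 to 3,
#'   5 to 6).
#' @param config An [hb_config()].
#' @return Object of class `hb_model` with components `flr_models`, `olr`,
#'   `scores` (long `hb_scores`), `grades` (adjusted, named by session),
#'   `confusion`, `accuracy`, `spearman`, `config`, `failures`.
#' @seealso [predict.hb_model()], [summary.hb_model()]
#' @export
hb_fit <- function(sessions, grades = NULL, config = hb_config()) {
  stopifnot(inherits(config, "hb_config"))
  if (is.null(grades))
    grades <- vapply(sessions, function(s) {
      if (is.null(s$hb_clinician))
        hb_stop("bad_grade",
                sprintf("session %s has no clinician grade", s$session_id))
      s$hb_clinician
    }, numeric(1))
  if (length(grades) != length(sessions))
    hb_stop("bad_input", "one grade per session required")
  keep <- !vapply(sessions, function(s) isTRUE(s$excluded), logical(1))
  if (!all(keep))
    message(sprintf("dropping %d excluded session(s)", sum(!keep)))
  sessions <- sessions[keep]; grades <- grades[keep]
  adj <- adjust_grade(grades)
  ci <- cohort_indicators(sessions, config)
  inds <- ci$indicators
  ids <- vapply(inds, function(i) i$session_id, character(1))
  adj <- stats::setNames(adj, vapply(sessions, function(s) s$session_id,
                                     character(1)))[ids]
  flr_models <- fit_flr_models(inds, adj, basis_dim = config$basis_dim,
                               penalty = config$penalty,
                               speed_transform = config$speed_transform)
  scores <- score_dataset(flr_models, inds)
  weights <- inverse_frequency_weights(adj)
  olr <- if (config$stepwise) stepwise_select(scores, adj, weights)
  else fit_olr(scores, adj, weights)
  sm <- score_matrix(scores)
  pred <- predict(olr, sm)
  cm <- confusion_matrix(adj, pred)
  structure(list(flr_models = flr_models, olr = olr, scores = scores,
                 grades = adj, fitted_grades = stats::setNames(pred, ids),
                 confusion = cm, accuracy = accuracy_report(cm),
                 spearman = spearman_vs_grade(scores, adj),
                 config = config, failures = ci$failures),
            class = "hb_model")
}

#' @export
print.hb_model <- function(x, ...) {
  cat(sprintf("<hb_model> fitted on %d sessions (grades %s)\n",
              length(x$grades),
              paste(sprintf("HB%d:%d", hb_levels(),
                            tabulate(match(x$grades, hb_levels()), 4)),
                    collapse = " ")))
  cat(sprintf("  health-score models: %d; selected for classification: %s\n",
              length(x$flr_models),
              if (length(x$olr$selected_labels))
                paste(x$olr$selected_labels, collapse = ", ")
              else "(none)"))
  cat(sprintf("  in-sample correct %d%%, approximate %d%%\n",
              x$accuracy$overall_correct_pct, x$accuracy$overall_approximate_pct))
  invisible(x)
}

#' Summaries of a fitted grading model
#'
#' @param object An `hb_model`.
#' @param ... Unused.
#' @return `summary()`: list of class `summary.hb_model` with the
#'   score-grade Spearman table, the selected labels with coefficients, the
#'   confusion matrix and the accuracy report.
#' @export
summary.hb_model <- function(object, ...) {
  structure(list(n = length(object$grades),
                 spearman = object$spearman,
                 selected = object$olr$selected_labels,
                 coefficients = coef(object$olr),
                 confusion = object$confusion,
                 accuracy = object$accuracy),
            class = "summary.hb_model")
}

#' @export
print.summary.hb_model <- function(x, ...) {
  cat("House-Brackmann grading model —", x$n, "sessions\n\n")
  cat("Spearman correlation of health scores with clinician grades:\n")
  print(transform(x$spearman, rho = round(rho, 2), p_value = round(p_value, 3)),
        row.names = FALSE)
  cat("\nSelected scores and proportional-odds coefficients:\n")
  print(round(x$coefficients, 3))
  cat("\nConfusion matrix (rows = clinician):\n")
  print(unclass(x$confusion))
  cat("\n")
  print(x$accuracy)
  invisible(x)
}

#' @export
coef.hb_model <- function(object, ...) coef(object$olr)

#' @export
fitted.hb_model <- function(object, ...) object$fitted_grades

#' @export
residuals.hb_model <- function(object, ...) {
  object$fitted_grades - object$grades
}

#' Predict grades for new sessions
#'
#' Registers and scores new sessions with the fitted health-score models,
#' then applies the proportional-odds classifier.
#'
#' @param object An `hb_model`.
#' @param newdata List of [session()] objects, a single `hb_session`, or a
#'   precomputed score matrix (sessions x labels).
#' @param type `"class"` (argmax grade, ties toward the lower grade),
#'   `"prob"` (probability matrix over grades), or `"scores"` (the health
#'   scores).
#' @param ... Unused.
#' @return Per `type`: integer grades, a probability matrix, or a score
#'   matrix, with session ids as names/rownames.
#' @export
predict.hb_model <- function(object, newdata,
                             type = c("class", "prob", "scores"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "hb_session")) newdata <- list(newdata)
  if (is.list(newdata) && all(vapply(newdata, inherits, logical(1), "hb_session"))) {
    ci <- cohort_indicators(newdata, object$config, warn_outliers = FALSE)
    if (length(ci$failures))
      hb_stop("registration_failed",
              sprintf("registration failed for: %s",
                      paste(names(ci$failures), collapse = ", ")))
    sm <- score_matrix(score_dataset(object$flr_models, ci$indicators))
  } else sm <- as.matrix(newdata)
  if (type == "scores") return(sm)
  predict(object$olr, sm, type = type)
}

#' @export
#' @rdname summary.hb_model
#' @param x An `hb_model`.
#' @param which `"correlogram"` (Pearson correlations between health scores)
#'   or `"beta"` (the functional coefficients of the health-score models).
plot.hb_model <- function(x, which = c("correlogram", "beta"), ...) {
  which <- match.arg(which)
  if (which == "correlogram") {
    cm <- score_correlogram(x$scores)
    p <- ncol(cm)
    graphics::image(seq_len(p), seq_len(p), t(cm[p:1, , drop = FALSE]),
                    zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(41, "Blue-Red 3", rev = TRUE),
                    main = "Health-score correlogram")
    graphics::axis(1, seq_len(p), colnames(cm), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(p), rev(rownames(cm)), las = 2, cex.axis = 0.7)
  } else {
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(x$flr_models)),
                         mar = c(3, 3, 2, 1))
    on.exit(graphics::par(old))
    for (m in x$flr_models) plot(m)
  }
  invisible(x)
}
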