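## Stage-1 output: the 14 indicator curves.
##
## Symmetry compares homologous left/right distances (min/max ratio, 1 =
## perfect symmetry). Intensity measures range of motion relative to the
## resting baseline (signed: 0 at rest, farther from zero = larger motion).
## Speed is the warping function itself, rescaled to the unit square (steep
## early = fast onset). All curves live on a common normalized [0,1] grid so
## they are comparable across sessions.

## Table of indicator definitions: measured POI pairs per exercise
symmetry_pairs <- function(exercise) {
  switch(exercise,
         Raising  = ,
         Frowning = list(left = c(4L, 2L), right = c(10L, 8L)),
         Smiling  = ,
         Baring   = list(left = c(14L, 3L), right = c(15L, 9L)),
         hb_stop("not_indicator_exercise",
                 sprintf("no symmetry pairs for '%s'", exercise)))
}

#' Symmetry indicator curve
#'
#' Pointwise ratio of the smaller to the larger of two homologous left/right
#' distances: `SI(t) = min(vL(t), vR(t)) / max(vL(t), vR(t))`, always in
#' (0, 1\], equal to 1 iff both halves move identically. For Raising/Frowning
#' the distances run from the inner eyebrows (POI 4, 10) to the inner eye
#' corners (POI 2, 8); for Smiling/Baring from the mouth corners (POI 14, 15)
#' to the outer eye corners (POI 3, 9) — eye corners being the most stable
#' reference points.
#'
#' @param rec A registered [exercise_recording()].
#' @param left_pair,right_pair Integer POI index pairs `(P1, P2)`.
#' @return An `hb_curve`.
#' @export
symmetry_curve <- function(rec, left_pair, right_pair) {
  vl <- distance_curve(rec, left_pair[1], left_pair[2])$values
  vr <- distance_curve(rec, right_pair[1], right_pair[2])$values
  if (any(vl <= 0) || any(vr <= 0))
    hb_stop("degenerate_geometry", "zero left/right distance at some sample")
  hb_curve(rec$times, pmin(vl, vr) / pmax(vl, vr))
}

## baseline distance v(.)(0): mean over the first `n_rest` samples (damping
## sensor noise) or literally the first sample
baseline_value <- function(values, baseline = c("rest_window", "first_sample"),
                           n_rest = 5L) {
  baseline <- match.arg(baseline)
  if (baseline == "first_sample") values[1]
  else mean(values[seq_len(min(n_rest, length(values)))])
}

#' Intensity indicator curves
#'
#' Signed range-of-motion indicators, all exactly 0 at the baseline:
#' * `intensity_ratio_curve()` (Raising, Frowning, Smiling):
#'   `I(t) = 1 - 1 / max(vL(t)/vL(0), vR(t)/vR(0))`, using the same POI pairs
#'   as the symmetry indicator;
#' * `intensity_baring_curve()`: change of the area of the mouth ellipse
#'   spanned by POI 13-16, `I(t) = 1 - (v(14,15)(0) v(13,16)(0)) /
#'   (v(14,15)(t) v(13,16)(t))` (the ellipse constant pi/4 cancels);
#' * `intensity_pursing_curve()`: change of the mouth-corner distance,
#'   `I(t) = 1 - v(14,15)(0) / v(14,15)(t)`.
#'
#' Motions that shrink the measured distance give negative values; the
#' magnitude, not the sign, reflects the range of motion.
#'
#' @inheritParams symmetry_curve
#' @param baseline `"rest_window"` (mean of the first `n_rest` samples,
#'   default) or `"first_sample"` (the literal formula).
#' @param n_rest Rest-window length in samples.
#' @return An `hb_curve`.
#' @export
intensity_ratio_curve <- function(rec, left_pair, right_pair,
                                  baseline = "rest_window", n_rest = 5L) {
  vl <- distance_curve(rec, left_pair[1], left_pair[2])$values
  vr <- distance_curve(rec, right_pair[1], right_pair[2])$values
  vl0 <- baseline_value(vl, baseline, n_rest)
  vr0 <- baseline_value(vr, baseline, n_rest)
  if (vl0 <= 0 || vr0 <= 0)
    hb_stop("degenerate_geometry", "zero baseline distance")
  hb_curve(rec$times, 1 - 1 / pmax(vl / vl0, vr / vr0))
}

#' @rdname intensity_ratio_curve
#' @export
intensity_baring_curve <- function(rec, baseline = "rest_window", n_rest = 5L) {
  va <- distance_curve(rec, 14L, 15L)$values
  vb <- distance_curve(rec, 13L, 16L)$values
  if (any(va <= 0) || any(vb <= 0))
    hb_stop("degenerate_geometry", "zero mouth extent at some sample")
  a0 <- baseline_value(va, baseline, n_rest)
  b0 <- baseline_value(vb, baseline, n_rest)
  hb_curve(rec$times, 1 - (a0 * b0) / (va * vb))
}

#' @rdname intensity_ratio_curve
#' @export
intensity_pursing_curve <- function(rec, baseline = "rest_window", n_rest = 5L) {
  v <- distance_curve(rec, 14L, 15L)$values
  if (any(v <= 0))
    hb_stop("degenerate_geometry", "zero mouth-corner distance at some sample")
  v0 <- baseline_value(v, baseline, n_rest)
  hb_curve(rec$times, 1 - v0 / v)
}

#' Speed indicator curve
#'
#' The exercise's warping function, taken in the sample-to-reference
#' direction and affinely rescaled so that both domain and range are
#' \[0, 1\]. A session that runs ahead of the reference (fast onset, typical
#' of healthy performance) gives a curve above the diagonal early on;
#' strictly increasing by construction.
#'
#' @param w An `hb_warping` (see [fit_warping()]).
#' @param grid Output grid on \[0, 1\] (also used, densified, to invert the
#'   warp numerically).
#' @return An `hb_curve` on the unit square.
#' @export
speed_curve <- function(w, grid = seq(0, 1, length.out = 100L)) {
  g <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  fine <- seq(grid[1], grid[length(grid)], length.out = 4L * length(grid))
  v <- warp_eval(w, fine)
  u <- (fine - fine[1]) / (fine[length(fine)] - fine[1])
  vr <- (v - v[1]) / (v[length(v)] - v[1])
  hb_curve(g, stats::approx(vr, u, xout = g, rule = 2)$y)
}

## resample a curve onto `n` points of its own normalized time span
resample_unit <- function(curve, n = 100L) {
  tt <- curve$times
  u <- (tt - tt[1]) / (tt[length(tt)] - tt[1])
  g <- seq(0, 1, length.out = n)
  hb_curve(g, stats::approx(u, curve$values, xout = g, rule = 2)$y)
}

#' Compute all indicator curves of a session
#'
#' Computes the 14 indicator curves (symmetry, intensity, speed per
#' indicator-bearing exercise; Pursing has no symmetry) from a registered
#' session. Symmetry and intensity are evaluated on the selected repetition
#' and resampled onto a common normalized \[0, 1\] grid; speed is the
#' exercise's full warping function. Missing exercises yield flagged absent
#' labels, never an error.
#'
#' @param rs An `hb_registered_session` (see [register_session()]).
#' @param grid_n Output grid length.
#' @param baseline,n_rest Baseline anchoring (see [intensity_ratio_curve()]).
#' @return List of class `hb_indicators`: `session_id`, `hb_clinician`,
#'   `curves` (named list of `hb_curve` on the common grid) and `absent`
#'   (character vector of unavailable labels).
#' @export
compute_indicators <- function(rs, grid_n = 100L, baseline = "rest_window",
                               n_rest = 5L) {
  stopifnot(inherits(rs, "hb_registered_session"))
  curves <- list()
  grid <- seq(0, 1, length.out = grid_n)
  for (ex in intersect(indicator_exercises(), names(rs$registrations))) {
    reg <- rs$registrations[[ex]]
    rec <- reg$recording
    pre <- exercise_prefix(ex)
    if (ex %in% c("Raising", "Frowning", "Smiling", "Baring")) {
      pr <- symmetry_pairs(ex)
      curves[[paste0(pre, ".symmetry")]] <-
        resample_unit(symmetry_curve(rec, pr$left, pr$right), grid_n)
    }
    curves[[paste0(pre, ".intensity")]] <- resample_unit(switch(ex,
      Baring  = intensity_baring_curve(rec, baseline, n_rest),
      Pursing = intensity_pursing_curve(rec, baseline, n_rest),
      intensity_ratio_curve(rec, symmetry_pairs(ex)$left,
                            symmetry_pairs(ex)$right, baseline, n_rest)),
      grid_n)
    curves[[paste0(pre, ".speed")]] <- speed_curve(reg$warping, grid)
  }
  structure(list(session_id = rs$session_id, hb_clinician = rs$hb_clinician,
                 curves = curves,
                 absent = setdiff(indicator_labels(), names(curves))),
            class = "hb_indicators")
}

#' @export
print.hb_indicators <- function(x, ...) {
  cat(sprintf("<hb_indicators> %s: %d of 14 indicator curves\n",
              x$session_id, length(x$curves)))
  if (length(x$absent))
    cat("  absent:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' Indicator curves as a long table
#'
#' Long-format export of indicator curves: one row per session, label and
#' grid point.
#'
#' @param x An `hb_indicators` or a list of them.
#' @return A data.frame with columns `session_id`, `label`, `t`, `value`.
#' @export
indicator_table <- function(x) {
  if (inherits(x, "hb_indicators")) x <- list(x)
  do.call(rbind, lapply(x, function(ind) {
    do.call(rbind, lapply(names(ind$curves), function(lab) {
      cur <- ind$curves[[lab]]
      data.frame(session_id = ind$session_id, label = lab,
                 t = cur$times, value = cur$values)
    }))
  }))
}

#' Warn about extreme intensity outliers
#'
#' Outlier exclusion remains a human decision; this helper only warns when a
#' session's peak absolute intensity lies beyond a robust z-score threshold
#' of the cohort (median/MAD), mirroring the visual-inspection step of the
#' clinical workflow.
#'
#' @param inds List of `hb_indicators`.
#' @param z_threshold Robust z-score threshold.
#' @return Invisibly, a data.frame of flagged (session_id, label, z) rows.
#' @export
check_intensity_outliers <- function(inds, z_threshold = 5) {
  labs <- grep("\\.intensity$", indicator_labels(), value = TRUE)
  flagged <- list()
  for (lab in labs) {
    ids <- vapply(inds, function(i) i$session_id, character(1))
    peak <- vapply(inds, function(i) {
      if (is.null(i$curves[[lab]])) NA_real_ else max(abs(i$curves[[lab]]$values))
    }, numeric(1))
    ok <- !is.na(peak)
    if (sum(ok) < 3) next
    med <- stats::median(peak[ok]); s <- stats::mad(peak[ok])
    if (s <= 0) next
    z <- (peak - med) / s
    hit <- which(ok & abs(z) > z_threshold)
    if (length(hit))
      flagged[[lab]] <- data.frame(session_id = ids[hit], label = lab,
                                   z = z[hit])
  }
  out <- if (length(flagged)) do.call(rbind, flagged)
  else data.frame(session_id = character(), label = character(), z = numeric())
  if (nrow(out))
    warning(sprintf("possible intensity outliers (robust |z| > %g): %s",
                    z_threshold,
                    paste(unique(out$session_id), collapse = ", ")),
            call. = FALSE)
  invisible(out)
}
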