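## Stage 1: landmark-based curve registration.
##
## For each indicator-bearing exercise, a scalar alignment curve (the
## distance that changes most during the exercise) is smoothed and min-max
## normalized; the number of repetitions (2-4) is identified by dynamic time
## warping against raised-cosine reference templates; repetition begin/end
## landmarks are located at a threshold crossing of the normalized curve;
## a monotone piecewise-cubic warping function maps the reference timeline
## to the session's; all 63 coordinate curves of the exercise are then
## evaluated on a common reference grid and the second repetition selected.

#' Moving-average smoothing
#'
#' Centered moving average with window truncation at the endpoints
#' (default), or Savitzky-Golay smoothing via the `signal` package.
#'
#' @param values Numeric vector.
#' @param window Odd positive integer window length; 1 = no smoothing.
#' @param method `"ma"` (moving average) or `"sg"` (Savitzky-Golay,
#'   polynomial order 3, needs the `signal` package).
#' @return Numeric vector, same length.
#' @export
smooth_curve <- function(values, window = 5L, method = c("ma", "sg")) {
  method <- match.arg(method)
  if (window < 1 || window %% 2 == 0)
    hb_stop("bad_window", "smoothing window must be a positive odd integer")
  if (window == 1) return(values)
  n <- length(values)
  if (method == "sg") {
    if (!requireNamespace("signal", quietly = TRUE))
      hb_stop("missing_package", "Savitzky-Golay smoothing needs the 'signal' package")
    return(as.numeric(signal::sgolayfilt(values, p = min(3, window - 1), n = window)))
  }
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Alignment curve of an exercise
#'
#' The per-exercise scalar summary used for registration: for Raising and
#' Frowning the sum of the left (POI 4-2) and right (POI 10-8)
#' eyebrow-to-inner-eye-corner distances; for Smiling, Baring and Pursing
#' the mouth-corner distance (POI 14-15). It deliberately includes both
#' facial halves, since some patients move only one side.
#'
#' @param rec An [exercise_recording()] of an indicator-bearing exercise.
#' @return An `hb_curve` with attribute `exercise`.
#' @export
alignment_curve <- function(rec) {
  stopifnot(inherits(rec, "hb_recording"))
  if (!(rec$exercise %in% indicator_exercises()))
    hb_stop("not_indicator_exercise",
            sprintf("'%s' has no alignment curve", rec$exercise))
  cur <- if (rec$exercise %in% c("Raising", "Frowning")) {
    l <- distance_curve(rec, 4L, 2L)
    r <- distance_curve(rec, 10L, 8L)
    hb_curve(l$times, l$values + r$values)
  } else {
    distance_curve(rec, 14L, 15L)
  }
  attr(cur, "exercise") <- rec$exercise
  cur
}

## min-max normalize to [0,1]; flip polarity if the curve starts (at rest)
## in the upper half of its range, so activity always shows as bumps
normalize_curve <- function(values) {
  rng <- range(values)
  if (diff(rng) <= max(1e-12, 1e-9 * max(abs(rng))))
    hb_stop("flat_signal", "alignment curve is (numerically) constant")
  v <- (values - rng[1]) / diff(rng)
  flipped <- mean(v[seq_len(min(3L, length(v)))]) > 0.5
  if (flipped) v <- 1 - v
  list(values = v, flipped = flipped)
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with symmetric steps (diagonal,
#' horizontal, vertical) and squared-difference local cost. Returns the total
#' distance, one optimal warping path, and the path-length-normalized
#' ("average") distance used for template comparison. The distance is 0 iff
#' an exact monotone alignment exists.
#'
#' @param a,b Numeric sequences of length >= 2 (callers normalize to
#'   \[0, 1\] beforehand for scale-free matching).
#' @return List with `distance`, `path` (L x 2 index matrix) and
#'   `normalized` (= distance / L).
#' @export
dtw_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n < 2 || m < 2) hb_stop("empty_input", "DTW needs sequences of length >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    hb_stop("empty_input", "DTW inputs must be finite")
  D <- matrix(Inf, n, m)
  step <- matrix(0L, n, m)      # 1 = diag, 2 = up (i-1), 3 = left (j-1)
  cost1 <- (a[1] - b)^2
  D[1, ] <- cumsum(cost1)
  step[1, ] <- 3L
  colcost <- (a - b[1])^2
  D[, 1] <- cumsum(colcost)
  step[, 1] <- 2L
  step[1, 1] <- 0L
  for (i in 2:n) {
    ai <- a[i]
    Dim1 <- D[i - 1, ]
    Di <- D[i, ]
    si <- step[i, ]
    for (j in 2:m) {
      cands <- c(Dim1[j - 1], Dim1[j], Di[j - 1])
      w <- which.min(cands)
      Di[j] <- (ai - b[j])^2 + cands[w]
      si[j] <- w
    }
    D[i, ] <- Di
    step[i, ] <- si
  }
  ## backtrack one optimal path
  path <- matrix(NA_integer_, n + m, 2)
  i <- n; j <- m; L <- 0L
  repeat {
    L <- L + 1L
    path[L, ] <- c(i, j)
    if (i == 1 && j == 1) break
    s <- step[i, j]
    if (s == 1L) { i <- i - 1L; j <- j - 1L }
    else if (s == 2L) i <- i - 1L
    else j <- j - 1L
  }
  path <- path[L:1, , drop = FALSE]
  list(distance = D[n, m], path = path, normalized = D[n, m] / L)
}

#' Reference repetition templates
#'
#' Unit-amplitude rest-bump reference curve with `k` raised-cosine bumps of
#' equal width; rests (20% of the span by default) separate the bumps and pad
#' both ends. Used for DTW-based repetition-count detection.
#'
#' @param k Number of repetitions, 2-4.
#' @param n_points Template length.
#' @param rest_frac Fraction of the span spent at rest.
#' @return Numeric vector in \[0, 1\] of length `n_points`.
#' @export
reference_template <- function(k, n_points = 100L, rest_frac = 0.2) {
  if (!(length(k) == 1 && k %in% 2:4))
    hb_stop("bad_k", "repetition count k must be 2, 3 or 4")
  activation_pattern(seq(0, 1, length.out = n_points), k, rest_frac)
}

#' Reference landmark times
#'
#' Begin/end reference instants t0 of each of the `k` repetitions on the
#' normalized \[0, 1\] timeline: the times where the reference template's
#' bumps cross `threshold` of their unit amplitude — the same rule the
#' landmark extractor applies to a session's curve, so that a session
#' performing exactly the template maps onto itself.
#'
#' @inheritParams reference_template
#' @param threshold Activation threshold in (0, 0.5).
#' @return Strictly increasing numeric vector of length `2k`.
#' @export
reference_landmarks <- function(k, threshold = 0.15, rest_frac = 0.2) {
  if (!(length(k) == 1 && k %in% 2:4))
    hb_stop("bad_k", "repetition count k must be 2, 3 or 4")
  unlist(lapply(seq_len(k), bump_threshold_times, k = k,
                threshold = threshold, rest_frac = rest_frac))
}

#' Detect the number of exercise repetitions
#'
#' Min-max normalizes the alignment curve (flipping polarity if the resting
#' level sits high), computes the path-length-normalized DTW distance to the
#' reference templates for 2, 3 and 4 repetitions, and returns the count with
#' the minimal average distance; ties break toward 3, the instructed count.
#'
#' @param curve An `hb_curve` (see [alignment_curve()]), typically smoothed.
#' @param n_points Template length.
#' @param rest_frac Template rest fraction.
#' @return Integer in {2, 3, 4}.
#' @export
detect_repetitions <- function(curve, n_points = 100L, rest_frac = 0.2) {
  stopifnot(inherits(curve, "hb_curve"))
  v <- normalize_curve(curve$values)$values
  ks <- 2:4
  d <- vapply(ks, function(k)
    dtw_distance(v, reference_template(k, n_points, rest_frac))$normalized,
    numeric(1))
  best <- d <= min(d) + 1e-12
  if (best[2]) 3L else ks[which(best)[1]]
}

#' Extract repetition landmarks
#'
#' Locates the begin/end time of each of the `k` repetitions: the DTW path to
#' the `k`-bump reference template delimits each bump's stretch of the
#' signal, and within each stretch the first and last crossing of
#' `threshold` (of the normalized range) is refined by linear interpolation.
#'
#' @param curve An `hb_curve`, typically smoothed.
#' @param k Repetition count from [detect_repetitions()].
#' @param threshold Activation threshold in (0, 0.5), fraction of range.
#' @param n_points,rest_frac Template settings (match detection).
#' @return List of class `hb_landmarks` with `times` (strictly increasing,
#'   length `2k`) and `k`.
#' @export
extract_landmarks <- function(curve, k, threshold = 0.15, n_points = 100L,
                              rest_frac = 0.2) {
  stopifnot(inherits(curve, "hb_curve"))
  if (!(k %in% 2:4)) hb_stop("bad_k", "k must be 2, 3 or 4")
  v <- normalize_curve(curve$values)$values
  tt <- curve$times
  tmpl <- reference_template(k, n_points, rest_frac)
  path <- dtw_distance(v, tmpl)$path
  s_tmpl <- seq(0, 1, length.out = n_points)
  ## resting floor: the min-max normalization bottoms out at the deepest noise
  ## dip, so on low-amplitude curves the rest level sits well above 0; the
  ## activation threshold is referenced to the median of the samples the DTW
  ## path maps onto the template's rest regions
  rest_idx <- path[tmpl[path[, 2]] < 1e-9, 1]
  floor_lvl <- if (length(rest_idx) >= 3) stats::median(v[rest_idx]) else 0
  floor_lvl <- min(max(floor_lvl, 0), 0.6)
  thr <- floor_lvl + threshold * (1 - floor_lvl)
  out <- numeric(0)
  for (j in seq_len(k)) {
    sup <- bump_support(j, k, rest_frac)
    tin <- which(s_tmpl >= sup[1] & s_tmpl <= sup[2])
    sig <- path[path[, 2] %in% tin, 1]
    lo <- min(sig); hi <- max(sig)
    if (max(v[lo:hi]) < thr)
      hb_stop("landmarks",
              sprintf("no activation above threshold in repetition %d", j))
    ## grow the above-threshold run outward from the window's peak: robust to
    ## spurious noise crossings elsewhere in the window
    peak <- which.max(v[lo:hi]) + lo - 1L
    beg <- peak; while (beg > 1L && v[beg - 1L] >= thr) beg <- beg - 1L
    end <- peak; while (end < length(v) && v[end + 1L] >= thr) end <- end + 1L
    out <- c(out, cross_time(tt, v, beg, thr, rising = TRUE),
             cross_time(tt, v, end, thr, rising = FALSE))
  }
  ## adjacent runs may touch on noisy low-amplitude curves: clip at midpoints
  for (i in seq_len(k - 1)) {
    if (out[2 * i] >= out[2 * i + 1]) {
      mid <- (out[2 * i] + out[2 * i + 1]) / 2
      out[2 * i] <- mid - 1e-9
      out[2 * i + 1] <- mid + 1e-9
    }
  }
  if (any(diff(out) <= 0))
    hb_stop("landmarks", "extracted landmark times are not strictly increasing")
  structure(list(times = out, k = as.integer(k)), class = "hb_landmarks")
}

## linear-interpolated time at which v crosses `thr` adjacent to sample idx
cross_time <- function(tt, v, idx, thr, rising) {
  nb <- if (rising) idx - 1L else idx + 1L
  if (nb < 1 || nb > length(v) || v[nb] >= thr) return(tt[idx])
  f <- (thr - v[nb]) / (v[idx] - v[nb])
  tt[nb] + f * (tt[idx] - tt[nb])
}

#' Fit a monotone warping function
#'
#' Monotone piecewise-cubic interpolant w with w(t0_j) = t_ij, mapping the
#' reference timeline to the session's, extended linearly (with the boundary
#' slope) outside the knot range. A Hyman-filtered cubic spline is used:
#' its slopes come from a C2 spline fit (markedly more accurate between
#' sparse landmark knots than local-secant Hermite slopes) while the Hyman
#' filter guarantees the monotonicity — hence invertibility — that a time
#' warp must have.
#'
#' @param landmarks An `hb_landmarks` (session landmark times t_ij) or a
#'   strictly increasing numeric vector.
#' @param reference Strictly increasing reference landmark times t0_j (see
#'   [reference_landmarks()]), same length.
#' @return An object of class `hb_warping`: `reference_knots`,
#'   `sample_knots`, and the interpolant usable via [warp_eval()].
#' @export
fit_warping <- function(landmarks, reference) {
  ti <- if (inherits(landmarks, "hb_landmarks")) landmarks$times else as.numeric(landmarks)
  t0 <- as.numeric(reference)
  if (length(ti) != length(t0) || length(t0) < 2)
    hb_stop("bad_landmarks", "landmark and reference sets must have equal length >= 2")
  if (any(diff(ti) <= 0) || any(diff(t0) <= 0))
    hb_stop("bad_landmarks", "landmark times must be strictly increasing")
  f <- stats::splinefun(t0, ti, method = "hyman")
  slope_lo <- f(t0[1], deriv = 1)
  slope_hi <- f(t0[length(t0)], deriv = 1)
  if (!is.finite(slope_lo) || slope_lo <= 0)
    slope_lo <- (ti[2] - ti[1]) / (t0[2] - t0[1])
  m <- length(t0)
  if (!is.finite(slope_hi) || slope_hi <= 0)
    slope_hi <- (ti[m] - ti[m - 1]) / (t0[m] - t0[m - 1])
  structure(list(reference_knots = t0, sample_knots = ti, spline = f,
                 slope_lo = slope_lo, slope_hi = slope_hi),
            class = "hb_warping")
}

#' @rdname fit_warping
#' @param w An `hb_warping`.
#' @param t Times on the reference timeline.
#' @return `warp_eval()`: w(t), the corresponding session times.
#' @export
warp_eval <- function(w, t) {
  stopifnot(inherits(w, "hb_warping"))
  t0 <- w$reference_knots; ti <- w$sample_knots
  m <- length(t0)
  out <- w$spline(t)
  lo <- t < t0[1]; hi <- t > t0[m]
  out[lo] <- ti[1] + (t[lo] - t0[1]) * w$slope_lo
  out[hi] <- ti[m] + (t[hi] - t0[m]) * w$slope_hi
  out
}

#' @export
print.hb_warping <- function(x, ...) {
  cat(sprintf("<hb_warping> %d knots mapping [%.3f, %.3f] -> [%.3f, %.3f] s\n",
              length(x$reference_knots), min(x$reference_knots),
              max(x$reference_knots), min(x$sample_knots), max(x$sample_knots)))
  invisible(x)
}

#' Apply a warping function to a recording
#'
#' Evaluates every one of the 63 coordinate curves of a recording at the
#' warped times w(t) for each reference grid point t (linear interpolation
#' between samples, clamped at the recording's ends), yielding a recording on
#' the common reference grid. All coordinate curves of one exercise share the
#' same w, derived from its alignment curve.
#'
#' @param rec An [exercise_recording()].
#' @param w An `hb_warping` (see [fit_warping()]).
#' @param grid Strictly increasing reference time grid.
#' @return An `hb_recording` with `times = grid` and the warping stored in
#'   attribute `"warping"`.
#' @export
apply_warping <- function(rec, w, grid) {
  stopifnot(inherits(rec, "hb_recording"))
  if (length(grid) < 2) hb_stop("empty_grid", "reference grid must have >= 2 points")
  wt <- warp_eval(w, grid)
  wt <- pmin(pmax(wt, rec$times[1]), rec$times[length(rec$times)])
  n <- length(grid)
  pos <- array(NA_real_, dim = c(n, 21, 3))
  for (p in 1:21) for (ax in 1:3)
    pos[, p, ax] <- stats::approx(rec$times, rec$positions[, p, ax], xout = wt,
                                  rule = 2)$y
  out <- exercise_recording(rec$exercise, grid, pos)
  attr(out, "warping") <- list(reference_knots = w$reference_knots,
                               sample_knots = w$sample_knots)
  out
}

#' Select one repetition of a registered recording
#'
#' Cuts the sub-recording of the chosen repetition (the second by default:
#' first and last repetitions are more often corrupted by noise at the start
#' or end of an exercise), with a rest margin extending to the midpoint
#' toward the neighbouring repetitions (or to the domain ends). With only 2
#' repetitions, index 2 is the last one.
#'
#' @param registered An `hb_recording` on the reference grid (see
#'   [apply_warping()]).
#' @param landmarks Reference-timeline landmark times (numeric `2k`, or an
#'   `hb_landmarks`).
#' @param index Repetition to keep (1-based).
#' @return An `hb_recording` spanning the selected repetition; attribute
#'   `"repetition_span"` holds the begin/end landmark times.
#' @export
select_repetition <- function(registered, landmarks, index = 2L) {
  stopifnot(inherits(registered, "hb_recording"))
  lt <- if (inherits(landmarks, "hb_landmarks")) landmarks$times else as.numeric(landmarks)
  k <- length(lt) %/% 2L
  if (index < 1 || index > k)
    hb_stop("bad_repetition_index",
            sprintf("repetition index %d exceeds the %d detected repetitions", index, k))
  beg <- lt[2 * index - 1]; end <- lt[2 * index]
  tt <- registered$times
  lo <- if (index == 1) tt[1] else (lt[2 * index - 2] + beg) / 2
  hi <- if (index == k) tt[length(tt)] else (end + lt[2 * index + 1]) / 2
  keep <- which(tt >= lo - 1e-12 & tt <= hi + 1e-12)
  if (length(keep) < 2)
    hb_stop("bad_repetition_index", "selected repetition spans fewer than 2 grid points")
  out <- exercise_recording(registered$exercise, tt[keep],
                            registered$positions[keep, , , drop = FALSE])
  attr(out, "warping") <- attr(registered, "warping")
  attr(out, "repetition_span") <- c(begin = beg, end = end)
  out
}

#' Register one exercise recording
#'
#' Full stage-1 treatment of a single indicator-bearing recording: smooth the
#' alignment curve, detect the repetition count, extract landmarks, fit the
#' warping function, align all 63 coordinate curves on the reference grid,
#' and select the second repetition.
#'
#' @param rec An [exercise_recording()] of an indicator-bearing exercise.
#' @param grid_n Number of points of the common \[0, 1\] reference grid.
#' @param smooth_window Moving-average window for the alignment curve.
#' @param threshold Landmark activation threshold (fraction of range).
#' @param n_points,rest_frac Reference-template settings.
#' @param repetition Repetition index to select.
#' @return List of class `hb_registration`: `recording` (the selected
#'   repetition on the reference grid), `registered` (the full aligned
#'   recording), `warping`, `k`, `landmarks` (session times), `reference`
#'   (reference landmark times) and `flipped` (alignment-curve polarity).
#' @export
register_recording <- function(rec, grid_n = 100L, smooth_window = 5L,
                               threshold = 0.15, n_points = 100L,
                               rest_frac = 0.2, repetition = 2L) {
  ac <- alignment_curve(rec)
  sm <- hb_curve(ac$times, smooth_curve(ac$values, smooth_window))
  flipped <- normalize_curve(sm$values)$flipped
  k <- detect_repetitions(sm, n_points, rest_frac)
  lm <- extract_landmarks(sm, k, threshold, n_points, rest_frac)
  t0 <- reference_landmarks(k, threshold, rest_frac)
  w <- fit_warping(lm, t0)
  grid <- seq(0, 1, length.out = grid_n)
  reg <- apply_warping(rec, w, grid)
  sel <- select_repetition(reg, t0, index = min(repetition, k))
  structure(list(recording = sel, registered = reg, warping = w, k = k,
                 landmarks = lm, reference = t0, flipped = flipped),
            class = "hb_registration")
}

#' Register a whole session
#'
#' Applies [register_recording()] to every indicator-bearing exercise present
#' in the session. Exercises that are absent are skipped; a registration
#' failure for one exercise aborts the session (callers looping over cohorts
#' should catch and report).
#'
#' @param x An [session()].
#' @param ... Settings passed to [register_recording()].
#' @return List of class `hb_registered_session`: session metadata plus one
#'   `hb_registration` per available indicator exercise.
#' @export
register_session <- function(x, ...) {
  stopifnot(inherits(x, "hb_session"))
  present <- intersect(indicator_exercises(), names(x$recordings))
  regs <- lapply(x$recordings[present], register_recording, ...)
  structure(list(session_id = x$session_id, patient_id = x$patient_id,
                 hb_clinician = x$hb_clinician, excluded = x$excluded,
                 registrations = regs),
            class = "hb_registered_session")
}

#' @export
print.hb_registered_session <- function(x, ...) {
  cat(sprintf("<hb_registered_session> %s: %d registered exercises (%s)\n",
              x$session_id, length(x$registrations),
              paste(names(x$registrations), collapse = ", ")))
  invisible(x)
}
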