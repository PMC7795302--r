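## Synthetic session generator.
##
## Emulates the statistical structure the pipeline assumes: per exercise a
## rest - n_repetitions raised-cosine activation bumps - rest trajectory of
## the 21 POI, with grade-dependent left/right asymmetry (attenuation of the
## affected side), range of motion, and execution speed (a monotone power
## distortion of normalized time), variable per-session sampling rate, and
## additive Gaussian sensor noise. The displacement of each measured POI pair
## runs along the pair's separation vector, so the alignment distances are
## linear in the activation and repetition boundaries are well defined.

#' Neutral face template
#'
#' A bilaterally symmetric 21 x 3 coordinate template (meters; x across the
#' face with the left side positive, y up, z toward the sensor; nose tip near
#' the origin). Left/right homologue POI pairs mirror each other about the
#' midsagittal plane x = 0.
#'
#' @return Numeric matrix `21 x 3` with rows in POI index order 0-20.
#' @export
neutral_face <- function() {
  left <- rbind(
    c(0.032,  0.024, 0.000),   # 0 left eye, bottom
    c(0.032,  0.036, 0.000),   # 1 left eye, top
    c(0.016,  0.030, 0.000),   # 2 left eye, inner corner
    c(0.048,  0.030, 0.004),   # 3 left eye, outer corner
    c(0.018,  0.052, 0.002),   # 4 left eyebrow, inner
    c(0.036,  0.056, 0.002))   # 5 left eyebrow, centre
  right <- left
  right[, 1] <- -right[, 1]
  out <- rbind(
    left, right,
    c(0.000,  0.000, 0.020),   # 12 nose tip
    c(0.000, -0.046, 0.010),   # 13 lower lip, centre-bottom
    c(0.026, -0.038, 0.006),   # 14 mouth, left corner
    c(-0.026, -0.038, 0.006),  # 15 mouth, right corner
    c(0.000, -0.030, 0.012),   # 16 upper lip, centre-top
    c(0.000, -0.066, 0.008),   # 17 chin, centre
    c(0.000,  0.078, 0.004),   # 18 forehead, centre
    c(0.046, -0.010, 0.006),   # 19 left cheek, centre
    c(-0.046, -0.010, 0.006))  # 20 right cheek, centre
  dimnames(out) <- list(0:20, c("x", "y", "z"))
  out
}

## grade -> default severity parameters: attenuation of the affected side,
## global range-of-motion multiplier, and the speed-profile exponent
## (gamma < 1 = fast onset, typical of healthy performance)
grade_param_map <- function(grade) {
  i <- match(grade, c(1L, 2L, 3L, 6L))
  if (is.na(i)) hb_stop("bad_grade", "grade must be an adjusted grade in {1,2,3,6}")
  list(asymmetry_attenuation = c(1.0, 0.8, 0.5, 0.05)[i],
       intensity_scale       = c(1.0, 0.9, 0.7, 0.4)[i],
       speed_gamma           = c(0.75, 0.90, 1.05, 1.25)[i])
}

#' Simulation parameters
#'
#' Parameter set for [simulate_session()]. All defaults not supplied are
#' derived from `grade` (worse grades move less, less symmetrically and with
#' slower onset).
#'
#' @param grade Adjusted House-Brackmann grade in {1, 2, 3, 6}.
#' @param affected_side `"left"` or `"right"`.
#' @param asymmetry_attenuation Motion multiplier on the affected side, in
#'   \[0, 1\]; 1 = perfectly symmetric.
#' @param intensity_scale Global range-of-motion multiplier (> 0).
#' @param speed_gamma Exponent of the monotone power distortion of normalized
#'   time (`< 1`: fast onset; `> 1`: slow onset).
#' @param n_repetitions Number of exercise repetitions, 2-4.
#' @param sampling_hz_range Sampling-rate interval (Hz) the per-session rate
#'   is drawn from (the sensor's rate is variable).
#' @param noise_sd Additive Gaussian sensor noise per coordinate, meters.
#' @param time_jitter Timestamp jitter as a fraction of the sampling interval
#'   (in \[0, 0.4\]); emulates irregular sampling.
#' @param seed Integer RNG seed; identical parameter sets give bit-identical
#'   sessions.
#' @return A list of class `hb_sim_params`.
#' @export
sim_params <- function(grade = 1L, affected_side = "left",
                       asymmetry_attenuation = NULL, intensity_scale = NULL,
                       speed_gamma = NULL, n_repetitions = 3L,
                       sampling_hz_range = c(12, 30), noise_sd = 5e-4,
                       time_jitter = 0.1, seed = 1L) {
  defaults <- grade_param_map(grade)
  p <- list(grade = as.integer(grade),
            affected_side = match.arg(affected_side, c("left", "right")),
            asymmetry_attenuation = asymmetry_attenuation %||% defaults$asymmetry_attenuation,
            intensity_scale = intensity_scale %||% defaults$intensity_scale,
            speed_gamma = speed_gamma %||% defaults$speed_gamma,
            n_repetitions = as.integer(n_repetitions),
            sampling_hz_range = as.numeric(sampling_hz_range),
            noise_sd = as.numeric(noise_sd),
            time_jitter = as.numeric(time_jitter),
            seed = as.integer(seed))
  if (p$asymmetry_attenuation < 0 || p$asymmetry_attenuation > 1)
    hb_stop("bad_params", "asymmetry_attenuation must be in [0, 1]")
  if (p$intensity_scale <= 0) hb_stop("bad_params", "intensity_scale must be > 0")
  if (p$speed_gamma <= 0) hb_stop("bad_params", "speed_gamma must be > 0")
  if (!(p$n_repetitions %in% 2:4))
    hb_stop("bad_params", "n_repetitions must be 2, 3 or 4")
  if (length(p$sampling_hz_range) != 2 || any(p$sampling_hz_range <= 0) ||
      diff(p$sampling_hz_range) < 0)
    hb_stop("bad_params", "sampling_hz_range must be an increasing positive pair")
  if (p$noise_sd < 0) hb_stop("bad_params", "noise_sd must be >= 0")
  if (p$time_jitter < 0 || p$time_jitter > 0.4)
    hb_stop("bad_params", "time_jitter must be in [0, 0.4]")
  class(p) <- "hb_sim_params"
  p
}

## activation pattern on normalized time [0,1]: k raised-cosine bumps of
## equal width separated by equal rests; rests take `rest_frac` of the total
activation_pattern <- function(s, k, rest_frac = 0.2) {
  r <- rest_frac / (k + 1)
  b <- (1 - rest_frac) / k
  out <- numeric(length(s))
  for (j in seq_len(k)) {
    start <- j * r + (j - 1) * b
    inb <- s >= start & s <= start + b
    out[inb] <- 0.5 * (1 - cos(2 * pi * (s[inb] - start) / b))
  }
  out
}

## normalized-time support edges [start, end] of bump j of k
bump_support <- function(j, k, rest_frac = 0.2) {
  r <- rest_frac / (k + 1)
  b <- (1 - rest_frac) / k
  c(j * r + (j - 1) * b, j * r + j * b)
}

## normalized times where bump j crosses `threshold` of its unit amplitude
bump_threshold_times <- function(j, k, threshold = 0.15, rest_frac = 0.2) {
  sup <- bump_support(j, k, rest_frac)
  b <- diff(sup)
  delta <- b * acos(1 - 2 * threshold) / (2 * pi)
  c(sup[1] + delta, sup[2] - delta)
}

## per-exercise displacement field at unit activation: 21 x 3 matrix.
## Measured POI pairs are displaced along their separation vectors so that
## the measured distances respond linearly to the activation.
unit_dir <- function(face, from, to) {
  d <- face[to + 1L, ] - face[from + 1L, ]
  d / sqrt(sum(d^2))
}

motion_field <- function(exercise, face, scale) {
  D <- matrix(0, 21, 3)
  amp <- function(a) a * scale
  if (exercise == "Raising") {
    D[5, ]  <- amp(0.012) * unit_dir(face, 2L, 4L)    # left inner brow away from inner eye
    D[11, ] <- amp(0.012) * unit_dir(face, 8L, 10L)
    D[6, ]  <- amp(0.012) * c(0, 1, 0)                # brow centres, cosmetic
    D[12, ] <- amp(0.012) * c(0, 1, 0)
    D[19, ] <- amp(0.005) * c(0, 1, 0)                # forehead
  } else if (exercise == "Frowning") {
    D[5, ]  <- -amp(0.008) * unit_dir(face, 2L, 4L)   # brows pulled down toward the eyes
    D[11, ] <- -amp(0.008) * unit_dir(face, 8L, 10L)
    D[6, ]  <- -amp(0.006) * c(0, 1, 0)
    D[12, ] <- -amp(0.006) * c(0, 1, 0)
  } else if (exercise == "Smiling") {
    D[15, ] <- amp(0.010) * unit_dir(face, 14L, 3L)   # mouth corners toward outer eye corners
    D[16, ] <- amp(0.010) * unit_dir(face, 15L, 9L)
    D[20, ] <- amp(0.004) * c(0, 1, 0)                # cheeks rise
    D[21, ] <- amp(0.004) * c(0, 1, 0)
  } else if (exercise == "Baring") {
    ## corners widen and retract toward the outer eye corners (sharing the
    ## smiling activation pattern, as patients barely distinguish the two),
    ## while the lips part vertically
    dl <- 0.7 * unit_dir(face, 15L, 14L) + 0.3 * unit_dir(face, 14L, 3L)
    dr <- 0.7 * unit_dir(face, 14L, 15L) + 0.3 * unit_dir(face, 15L, 9L)
    D[15, ] <- amp(0.007) * dl / sqrt(sum(dl^2))
    D[16, ] <- amp(0.007) * dr / sqrt(sum(dr^2))
    D[14, ] <- amp(0.006) * unit_dir(face, 16L, 13L)
    D[17, ] <- amp(0.003) * unit_dir(face, 13L, 16L)
  } else if (exercise == "Pursing") {
    D[15, ] <- amp(0.008) * unit_dir(face, 14L, 15L)  # mouth corners inward
    D[16, ] <- amp(0.008) * unit_dir(face, 15L, 14L)
  }
  D
}

## attenuation factor per POI: affected side scaled, midline points averaged
side_factors <- function(face, affected_side, attenuation) {
  x <- face[, 1]
  f <- rep(1, 21)
  onside <- if (affected_side == "left") x > 1e-9 else x < -1e-9
  midline <- abs(x) <= 1e-9
  f[onside] <- attenuation
  f[midline] <- (1 + attenuation) / 2
  f
}

## run `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate one measurement session
#'
#' Generates a complete 9-exercise session plus the ground truth needed to
#' validate registration: for each indicator-bearing exercise a
#' rest-bumps-rest trajectory with the affected side attenuated, the time
#' axis distorted by the speed profile, sampled at a per-session rate drawn
#' from `sampling_hz_range`, with i.i.d. Gaussian noise on every coordinate.
#' Non-indicator exercises are rest plus noise. Ground-truth repetition
#' boundaries are defined as the times where the activation crosses 15% of
#' its peak (the registration default threshold).
#'
#' @param params An [sim_params()] object.
#' @param session_id,patient_id Identifiers stored in the session.
#' @return List with elements `session` (an [session()]) and `truth`
#'   (class `hb_ground_truth`: the parameters, the sampling rate, and per
#'   indicator exercise the true landmark times and duration).
#' @export
simulate_session <- function(params, session_id = "sim", patient_id = session_id) {
  stopifnot(inherits(params, "hb_sim_params"))
  with_seed(params$seed, simulate_session_impl(params, session_id, patient_id))
}

simulate_session_impl <- function(params, session_id, patient_id) {
  face <- neutral_face()
  k <- params$n_repetitions
  hz <- stats::runif(1, params$sampling_hz_range[1], params$sampling_hz_range[2])
  sides <- side_factors(face, params$affected_side, params$asymmetry_attenuation)
  recordings <- list()
  landmarks <- list()
  durations <- list()
  for (ex in exercise_names()) {
    bearing <- ex %in% indicator_exercises()
    T_ex <- if (bearing) 2.0 + 3.0 * k else 5.0
    n <- max(2L, floor(T_ex * hz) + 1L)
    times <- seq(0, by = 1 / hz, length.out = n)
    if (params$time_jitter > 0 && n > 2) {
      jit <- stats::runif(n - 2, -params$time_jitter, params$time_jitter) / hz
      times[2:(n - 1)] <- times[2:(n - 1)] + jit
    }
    pos <- array(rep(face, each = n), dim = c(n, 21, 3))
    if (bearing) {
      u <- times / T_ex
      act <- activation_pattern(u^params$speed_gamma, k)
      D <- motion_field(ex, face, params$intensity_scale) * sides
      for (ax in 1:3)
        pos[, , ax] <- pos[, , ax] + outer(act, D[, ax])
      lm_s <- unlist(lapply(seq_len(k), bump_threshold_times, k = k))
      landmarks[[ex]] <- T_ex * lm_s^(1 / params$speed_gamma)
      durations[[ex]] <- T_ex
    }
    if (params$noise_sd > 0)
      pos <- pos + stats::rnorm(length(pos), sd = params$noise_sd)
    recordings[[ex]] <- exercise_recording(ex, times, pos)
  }
  sess <- session(session_id, patient_id, recordings,
                  hb_clinician = params$grade)
  truth <- structure(list(params = params, sampling_hz = hz,
                          landmarks = landmarks, durations = durations),
                     class = "hb_ground_truth")
  list(session = sess, truth = truth)
}

#' Simulate a cohort of sessions
#'
#' Draws `n` sessions with adjusted grades from `class_mix` and
#' grade-conditional parameter draws (mild within-grade variation around the
#' defaults of the grade-severity map), reproducibly under `seed`.
#'
#' @param n Number of sessions.
#' @param class_mix Probability vector over adjusted grades (1, 2, 3, 6); the
#'   default mirrors the clinical cohort proportions 58/21/23/20 of 122.
#' @param seed Integer master seed.
#' @param ... Overrides passed to every session's [sim_params()] (e.g.
#'   `noise_sd = 0`).
#' @return List with `sessions` (list of `hb_session`), `truths` (list of
#'   `hb_ground_truth`) and `grades` (integer vector of adjusted grades).
#' @export
simulate_cohort <- function(n, class_mix = c(58, 21, 23, 20) / 122, seed = 1L, ...) {
  if (n < 1) hb_stop("bad_params", "n must be >= 1")
  class_mix <- as.numeric(class_mix)
  if (length(class_mix) != 4 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8)
    hb_stop("bad_mix", "class_mix must be 4 nonnegative probabilities summing to 1")
  with_seed(seed, simulate_cohort_impl(n, class_mix, ...))
}

simulate_cohort_impl <- function(n, class_mix, ...) {
  grades <- sample(hb_levels(), n, replace = TRUE, prob = class_mix)
  sides <- sample(c("left", "right"), n, replace = TRUE)
  reps <- sample(2:4, n, replace = TRUE)
  seeds <- sample.int(.Machine$integer.max, n)
  jit_att <- stats::rnorm(n, 0, 0.04)
  jit_int <- exp(stats::rnorm(n, 0, 0.08))
  jit_gam <- exp(stats::rnorm(n, 0, 0.08))
  overrides <- list(...)
  sessions <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    base <- grade_param_map(grades[i])
    args <- list(grade = grades[i], affected_side = sides[i],
                 asymmetry_attenuation =
                   min(1, max(0, base$asymmetry_attenuation + jit_att[i])),
                 intensity_scale = base$intensity_scale * jit_int[i],
                 speed_gamma = base$speed_gamma * jit_gam[i],
                 n_repetitions = reps[i], seed = seeds[i])
    args[names(overrides)] <- overrides
    p <- do.call(sim_params, args)
    id <- sprintf("S%03d", i)
    out <- simulate_session(p, session_id = id, patient_id = id)
    sessions[[i]] <- out$session
    truths[[i]] <- out$truth
  }
  list(sessions = sessions, truths = truths, grades = as.integer(grades))
}
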