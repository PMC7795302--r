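test_that("moving-average smoothing has its closed-form behavior", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(smooth_curve(x, 1), x)                    # window 1 = identity
  expect_equal(smooth_curve(rep(3, 10), 7), rep(3, 10))  # constants unchanged
  imp <- c(0, 0, 6, 0, 0)
  expect_equal(smooth_curve(imp, 3), c(0, 2, 2, 2, 0))   # h/3 plateau
  expect_hb_error(smooth_curve(x, 4), "bad_window")
  expect_hb_error(smooth_curve(x, -1), "bad_window")
})

test_that("alignment curves use the prescribed distances", {
  p <- sim_params(grade = 1, asymmetry_attenuation = 1, noise_sd = 0,
                  time_jitter = 0, seed = 8)
  s <- simulate_session(p)$session
  # symmetric raising: the two-sided curve equals twice one side
  ra <- s$recordings$Raising
  expect_equal(alignment_curve(ra)$values,
               2 * distance_curve(ra, 4, 2)$values, tolerance = 1e-12)
  # smiling: the mouth-corner distance by definition
  sm <- s$recordings$Smiling
  expect_equal(alignment_curve(sm)$values, distance_curve(sm, 14, 15)$values)
  expect_hb_error(alignment_curve(s$recordings$Closing),
                  "not_indicator_exercise")
})

test_that("a noiseless 3-repetition alignment curve has exactly 3 maxima", {
  p <- sim_params(n_repetitions = 3, noise_sd = 0, time_jitter = 0, seed = 9)
  s <- simulate_session(p)$session
  v <- alignment_curve(s$recordings$Raising)$values
  v <- (v - min(v)) / diff(range(v))
  peaks <- sum(diff(sign(diff(v))) == -2 & v[2:(length(v) - 1)] > 0.5)
  expect_equal(peaks, 3)
})

test_that("dtw_distance is a true DTW: zero on identical, symmetric, optimal", {
  a <- c(0, 0.5, 1, 0.5, 0)
  r <- dtw_distance(a, a)
  expect_equal(r$distance, 0)
  expect_equal(r$path, cbind(1:5, 1:5), ignore_attr = TRUE)
  b <- c(0, 1, 1, 0)
  expect_equal(dtw_distance(c(0, 1, 0), b)$distance,
               brute_dtw(c(0, 1, 0), b))
  expect_equal(dtw_distance(a, b)$distance, dtw_distance(b, a)$distance)
  expect_hb_error(dtw_distance(numeric(0), a), "empty_input")
})

test_that("dtw_distance equals brute-force enumeration on short sequences", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    a <- round(runif(n), 3); b <- round(runif(m), 3)
    expect_equal(dtw_distance(a, b)$distance, brute_dtw(a, b),
                 tolerance = 1e-12)
  }
})

test_that("reference templates are unit-amplitude k-bump patterns", {
  for (k in 2:4) {
    tp <- reference_template(k, 200)
    expect_equal(min(tp), 0)
    expect_equal(max(tp), 1, tolerance = 1e-3)
    # k distinct bumps: k upward crossings of half amplitude
    rises <- sum(tp[-1] >= 0.5 & tp[-length(tp)] < 0.5)
    expect_equal(rises, k)
  }
  expect_gt(dtw_distance(reference_template(2), reference_template(4))$distance, 0)
  expect_hb_error(reference_template(5), "bad_k")
})

test_that("repetition-count detection recovers the true count, flags flat curves", {
  for (k in 2:4) {
    p <- sim_params(n_repetitions = k, noise_sd = 0, time_jitter = 0,
                    seed = 20 + k)
    s <- simulate_session(p)$session
    ac <- alignment_curve(s$recordings$Raising)
    expect_equal(detect_repetitions(ac), k)
  }
  flat <- hb_curve(seq(0, 5, 0.1), rep(2, 51))
  expect_hb_error(detect_repetitions(flat), "flat_signal")
})

test_that("landmark extraction recovers ground truth within half a sample", {
  for (k in 2:4) {
    p <- sim_params(n_repetitions = k, noise_sd = 0, time_jitter = 0,
                    seed = 30 + k)
    out <- simulate_session(p)
    ac <- alignment_curve(out$session$recordings$Smiling)
    lm <- extract_landmarks(ac, k)
    expect_length(lm$times, 2 * k)
    expect_true(all(diff(lm$times) > 0))
    dt <- 1 / out$truth$sampling_hz
    expect_lt(max(abs(lm$times - out$truth$landmarks$Smiling)), dt / 2)
  }
})

test_that("warping functions interpolate exactly and stay strictly monotone", {
  t0 <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  # identity map
  w <- fit_warping(t0, t0)
  probe <- seq(0, 1, length.out = 100)
  expect_equal(warp_eval(w, probe), probe, tolerance = 1e-9)
  # linear stretch reproduced everywhere on the knot range
  w2 <- fit_warping(2 * t0, t0)
  inside <- seq(0.1, 0.9, length.out = 50)
  expect_equal(warp_eval(w2, inside), 2 * inside, tolerance = 1e-9)
  # interpolation conditions hold exactly at the knots
  set.seed(6)
  for (i in 1:10) {
    ti <- cumsum(runif(6, 0.2, 1))
    wi <- fit_warping(ti, sort(runif(6)))
    expect_equal(warp_eval(wi, wi$reference_knots), ti, tolerance = 1e-12)
    dense <- seq(-0.2, 1.2, length.out = 300)
    expect_true(all(diff(warp_eval(wi, dense)) > 0))
  }
  expect_hb_error(fit_warping(c(1, 1, 2), c(0, 0.5, 1)), "bad_landmarks")
  expect_hb_error(fit_warping(c(1, 2), c(0, 0.5, 1)), "bad_landmarks")
})

test_that("apply_warping evaluates all 63 curves on the reference grid", {
  rec <- random_recording(n = 30, seed = 5)
  span <- range(rec$times)
  knots <- seq(span[1], span[2], length.out = 4)
  w <- fit_warping(knots, seq(0, 1, length.out = 4))
  grid <- seq(0, 1, length.out = 40)
  reg <- apply_warping(rec, w, grid)
  expect_equal(reg$times, grid)
  # identity warp on the recording's own grid leaves it unchanged
  wid <- fit_warping(span, span)
  reg2 <- apply_warping(rec, wid, rec$times)
  expect_equal(reg2$positions, rec$positions, tolerance = 1e-9)
  expect_hb_error(apply_warping(rec, w, numeric(0)), "empty_grid")
})

test_that("sessions with different speed profiles align after warping", {
  mk <- function(g, seed)
    simulate_session(sim_params(grade = 1, speed_gamma = g, n_repetitions = 3,
                                noise_sd = 0, time_jitter = 0, seed = seed))
  a <- register_recording(mk(0.8, 1)$session$recordings$Smiling)
  b <- register_recording(mk(1.2, 2)$session$recordings$Smiling)
  na <- alignment_curve(a$registered)$values
  nb <- alignment_curve(b$registered)$values
  na <- (na - min(na)) / diff(range(na))
  nb <- (nb - min(nb)) / diff(range(nb))
  expect_lt(sqrt(mean((na - nb)^2)), 0.02)   # 2% RMS of range
})

test_that("the second repetition is selected with its rest margin", {
  p <- sim_params(n_repetitions = 3, noise_sd = 0, time_jitter = 0, seed = 55)
  out <- simulate_session(p)
  reg <- register_recording(out$session$recordings$Raising)
  expect_equal(reg$k, 3L)
  sel <- reg$recording
  # span strictly inside the middle third of the reference timeline
  span <- attr(sel, "repetition_span")
  expect_gt(span["begin"], 1 / 3)
  expect_lt(span["end"], 2 / 3)
  # exactly one activation bump inside the selected stretch
  v <- alignment_curve(sel)$values
  v <- (v - min(v)) / diff(range(v))
  peaks <- sum(diff(sign(diff(v))) == -2 & v[2:(length(v) - 1)] > 0.5)
  expect_equal(peaks, 1)
  # requesting a repetition beyond the detected count errors
  expect_hb_error(select_repetition(reg$registered, reg$reference, index = 5),
                  "bad_repetition_index")
  # with 2 repetitions, index 2 is the last one
  p2 <- sim_params(n_repetitions = 2, noise_sd = 0, time_jitter = 0, seed = 56)
  reg2 <- register_recording(simulate_session(p2)$session$recordings$Raising)
  expect_equal(reg2$k, 2L)
  expect_gt(attr(reg2$recording, "repetition_span")["begin"], 0.4)
})

test_that("registered sessions serialize with their warping knots", {
  p <- sim_params(n_repetitions = 2, noise_sd = 0, time_jitter = 0, seed = 60)
  s <- simulate_session(p)$session
  rs <- register_session(s)
  recs <- lapply(rs$registrations, function(r) r$recording)
  out <- session(s$session_id, s$patient_id, unname(recs))
  attr(out, "registered") <- TRUE
  d <- withr::local_tempdir()
  write_session(out, d)
  expect_true(any(grepl("^registered=true", readLines(file.path(d, "manifest.txt")))))
  back <- read_session(d)
  w <- attr(back$recordings$Raising, "warping")
  expect_equal(w$sample_knots, rs$registrations$Raising$warping$sample_knots,
               tolerance = 1e-9)
})
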