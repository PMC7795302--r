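# Fixtures are generated in code; the shared cohort/model is cached so the
# expensive end-to-end fit runs once per test session.

.fixture_cache <- new.env(parent = emptyenv())

# 30-session default-noise cohort with its fitted model
shared_cohort_model <- function() {
  if (is.null(.fixture_cache$model)) {
    coh <- simulate_cohort(30, seed = 2024)
    m <- suppressWarnings(suppressMessages(hb_fit(coh$sessions)))
    .fixture_cache$cohort <- coh
    .fixture_cache$model <- m
  }
  list(cohort = .fixture_cache$cohort, model = .fixture_cache$model)
}

# a static recording: constant positions over `n` samples
static_recording <- function(exercise, pos, n = 6, dt = 0.1) {
  arr <- array(rep(pos, each = n), dim = c(n, 21, 3))
  exercise_recording(exercise, seq(0, by = dt, length.out = n), arr)
}

# a recording whose positions jump from pos0 (first `n0` samples) to pos1
two_phase_recording <- function(exercise, pos0, pos1, n0 = 1, n1 = 1, dt = 0.1) {
  arr <- array(NA_real_, dim = c(n0 + n1, 21, 3))
  for (i in seq_len(n0)) arr[i, , ] <- pos0
  for (i in seq_len(n1)) arr[n0 + i, , ] <- pos1
  exercise_recording(exercise, seq(0, by = dt, length.out = n0 + n1), arr)
}

# random finite recording for oracle comparisons
random_recording <- function(exercise = "Smiling", n = 20, seed = 1) {
  set.seed(seed)
  arr <- array(stats::rnorm(n * 21 * 3, sd = 0.05), dim = c(n, 21, 3))
  arr <- arr + array(rep(neutral_face(), each = n), dim = c(n, 21, 3))
  exercise_recording(exercise, sort(stats::runif(n, 0, 5)), arr)
}

# exhaustive DTW: minimum squared-difference cost over all monotone paths
brute_dtw <- function(a, b) {
  rec <- function(i, j) {
    cost <- (a[i] - b[j])^2
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    cost + best
  }
  rec(length(a), length(b))
}

expect_hb_error <- function(expr, what) {
  expect_error(expr, class = paste0("hbgrade_", what))
}
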