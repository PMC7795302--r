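# Stage-3 weighted cumulative-logit classifier.

# draw grades from a proportional-odds model P(<=j) = plogis(a_j + z beta)
draw_po <- function(Z, beta, ths = c(-1, 0.5, 2)) {
  eta <- drop(Z %*% beta)
  cum <- vapply(ths, function(a) plogis(a + eta), numeric(length(eta)))
  hb_levels()[1 + rowSums(runif(length(eta)) > cum)]
}

test_that("inverse-frequency weights balance the classes", {
  grades <- rep(hb_levels(), times = c(58, 21, 23, 20))
  w <- inverse_frequency_weights(grades)
  expect_equal(unique(w[grades == 1]), 1 / 58)
  expect_equal(unique(w[grades == 2]), 1 / 21)
  expect_equal(unique(w[grades == 3]), 1 / 23)
  expect_equal(unique(w[grades == 6]), 1 / 20)
  expect_equal(sum(w), 4)                        # one unit per class
  balanced <- rep(hb_levels(), each = 10)
  expect_equal(length(unique(inverse_frequency_weights(balanced))), 1)
  expect_hb_error(inverse_frequency_weights(integer(0)), "empty_input")
})

test_that("intercept-only fit on balanced data reproduces empirical frequencies", {
  grades <- rep(hb_levels(), times = c(10, 20, 30, 40))
  f <- fit_olr(matrix(numeric(0), 100, 0), grades, weights = rep(1, 100),
               tol = 1e-12)
  p <- class_probabilities(f, matrix(numeric(0), 1, 0))
  expect_equal(drop(p), c(`1` = 0.1, `2` = 0.2, `3` = 0.3, `6` = 0.4),
               tolerance = 1e-6)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(201)
  n <- 60
  Z <- matrix(rnorm(n * 3), n, 3)
  yidx <- sample(1:4, n, replace = TRUE)
  w <- runif(n, 0.5, 2)
  for (rep in 1:20) {
    th <- rnorm(6, sd = 0.8)
    g <- hbgrade:::olr_grad(th, Z, yidx, w)
    fd <- vapply(seq_along(th), function(i) {
      h <- 1e-6
      tp <- th; tm <- th
      tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      (hbgrade:::olr_nll(tp, Z, yidx, w) -
         hbgrade:::olr_nll(tm, Z, yidx, w)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1)), 1e-6)
  }
})

test_that("the fit agrees with an independent proportional-odds implementation", {
  skip_if_not_installed("MASS")
  set.seed(202)
  Z <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  y <- draw_po(Z, c(1.5, -0.8))
  f <- fit_olr(Z, y, weights = rep(1, 300))
  pol <- MASS::polr(factor(y, levels = hb_levels()) ~ Z, method = "logistic")
  # same model, opposite slope convention
  expect_equal(unname(f$thresholds), unname(pol$zeta), tolerance = 1e-4)
  expect_equal(unname(f$coefficients), unname(-coef(pol)), tolerance = 1e-4)
  expect_true(all(diff(f$thresholds) > 0))
})

test_that("coefficients are recovered within 2 SE across replicates", {
  set.seed(203)
  hits <- replicate(20, {
    Z <- matrix(rnorm(500), 500, 1, dimnames = list(NULL, "s"))
    beta <- 1.2
    y <- draw_po(Z, beta)
    f <- fit_olr(Z, y, weights = rep(1, 500))
    # observed-information SE via finite differences of the analytic gradient
    th <- c(f$thresholds[1], log(diff(f$thresholds)), f$coefficients)
    yidx <- match(y, hb_levels())
    H <- vapply(seq_along(th), function(i) {
      h <- 1e-5
      tp <- th; tm <- th; tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      (hbgrade:::olr_grad(tp, Z, yidx, rep(1, 500)) -
         hbgrade:::olr_grad(tm, Z, yidx, rep(1, 500))) / (2 * h)
    }, numeric(length(th)))
    se <- sqrt(diag(solve((H + t(H)) / 2)))[length(th)]
    abs(f$coefficients - beta) <= 2 * se
  })
  expect_gte(sum(hits), 19)
})

test_that("class probabilities telescope from the cumulative logits", {
  f <- fit_olr(matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b"))),
               rep(hb_levels(), 10), weights = rep(1, 40))
  # beta = 0, thresholds (0, 1, 2): closed form
  f0 <- f
  f0$coefficients[] <- 0
  f0$thresholds <- c(0, 1, 2)
  p <- drop(class_probabilities(f0, c(a = 0.3, b = -1)))
  expect_equal(unname(p),
               c(plogis(0), plogis(1) - plogis(0), plogis(2) - plogis(1),
                 1 - plogis(2)), tolerance = 1e-12)
  # probabilities sum to one and reproduce the cumulative form
  set.seed(204)
  Z <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  P <- class_probabilities(f, Z)
  expect_equal(unname(rowSums(P)), rep(1, 10), tolerance = 1e-9)
  expect_true(all(P >= 0))
  cum <- t(apply(P, 1, cumsum))[, 1:3]
  eta <- drop(Z %*% f$coefficients)
  expect_equal(unname(cum),
               unname(vapply(f$thresholds, function(a) plogis(a + eta),
                             numeric(10))), tolerance = 1e-9)
  # raising every score (positive coefficients) shifts mass to lower grades
  fpos <- f; fpos$coefficients[] <- c(2, 1)
  p_lo <- class_probabilities(fpos, c(a = 0.2, b = 0.2))
  p_hi <- class_probabilities(fpos, c(a = 0.8, b = 0.8))
  expect_gt(cumsum(drop(p_hi))[1], cumsum(drop(p_lo))[1])
  expect_hb_error(class_probabilities(f, c(a = 1)), "missing_scores")
})

test_that("prediction takes the most probable grade, ties to the lower grade", {
  expect_equal(grade_from_probabilities(c(0, 0, 0.05, 0.95)), 6L)
  expect_equal(grade_from_probabilities(c(0.06, 0.25, 0.58, 0.11)), 3L)
  expect_equal(grade_from_probabilities(c(0.4, 0.4, 0.1, 0.1)), 1L)
  expect_equal(grade_from_probabilities(rbind(c(1, 0, 0, 0), c(0, 0, 0.2, 0.8))),
               c(1L, 6L))
})

test_that("weighted log-likelihood and predictions are scale invariant", {
  set.seed(205)
  Z <- matrix(rnorm(240), 120, 2, dimnames = list(NULL, c("a", "b")))
  y <- draw_po(Z, c(1, -0.5))
  w <- inverse_frequency_weights(y)
  f1 <- fit_olr(Z, y, weights = w)
  f2 <- fit_olr(Z, y, weights = 10 * w)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_identical(predict(f1, Z), predict(f2, Z))
})

test_that("stepwise AIC keeps the informative score and rejects noise", {
  # the per-draw noise admission of AIC stepwise is stochastic (each noise
  # column clears the AIC bar with chi-square tail probability ~0.16), so the
  # selection property is checked over replicated draws under one fixed seed
  set.seed(206)
  n <- 200
  res <- replicate(5, {
    informative <- rnorm(n)
    y <- draw_po(matrix(informative), 2)
    Z <- cbind(informative, matrix(rnorm(n * 9), n, 9))
    colnames(Z) <- c("signal", paste0("noise", 1:9))
    f <- stepwise_select(Z, y, weights = rep(1, n))
    f0 <- stepwise_select(Z[, -1], y, weights = rep(1, n))
    empty <- fit_olr(Z[, 0, drop = FALSE], y, weights = rep(1, n))
    c(signal = "signal" %in% f$selected_labels,
      noise = sum(grepl("noise", f$selected_labels)),
      nullsel = length(f0$selected_labels),
      aic_ok = f$aic <= empty$aic && f0$aic <= empty$aic)
  })
  expect_true(all(res["signal", ] == 1))          # the signal always enters
  expect_gte(sum(res["noise", ] <= 2), 3)         # >= 7/9 noise rejected, typically
  expect_gte(sum(res["nullsel", ] <= 1), 2)       # all-noise: near-empty models
  expect_lte(mean(res["nullsel", ]), 3)
  expect_true(all(res["aic_ok", ] == 1))          # never worse than the empty model
})

test_that("confusion matrix counts match a manual tally", {
  true <- c(1, 1, 2, 3, 6, 6)
  pred <- c(1, 2, 2, 6, 6, 3)
  cm <- confusion_matrix(true, pred)
  expect_equal(sum(cm), 6)
  expect_equal(cm["1", "1"], 1)
  expect_equal(cm["1", "2"], 1)
  expect_equal(cm["3", "6"], 1)
  expect_equal(cm["6", "3"], 1)
  expect_equal(cm["6", "6"], 1)
  # perfect prediction gives a diagonal matrix
  cmp <- confusion_matrix(true, true)
  expect_equal(sum(cmp) - sum(diag(cmp)), 0)
  expect_hb_error(confusion_matrix(1:3, 1:4), "length_mismatch")
})

test_that("accuracy report: approximate >= correct, perfect matrix is 100%", {
  id <- diag(c(5L, 5L, 5L, 5L))
  dimnames(id) <- list(c(1, 2, 3, 6), c(1, 2, 3, 6))
  acc <- accuracy_report(id)
  expect_equal(acc$per_class$correct_pct, rep(100L, 4))
  expect_equal(acc$per_class$approximate_pct, rep(100L, 4))
  expect_equal(acc$overall_correct_pct, 100L)
  set.seed(207)
  for (i in 1:5) {
    cm <- matrix(rpois(16, 4), 4, 4)
    acc <- accuracy_report(cm)
    expect_true(all(acc$per_class$approximate >= acc$per_class$correct,
                    na.rm = TRUE))
    expect_gte(acc$overall_approximate, acc$overall_correct)
  }
  # an empty row is flagged undefined, not an error
  cm0 <- diag(c(2L, 0L, 1L, 1L))
  acc0 <- accuracy_report(cm0)
  expect_true(is.na(acc0$per_class$correct[2]))
})
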