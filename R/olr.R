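## Stage 3: weighted cumulative-logit (proportional-odds) classification.
##
## P(HB <= j) = plogis(alpha_j + sum_i beta_i p_i), with class-independent
## coefficients beta_i on the health scores and strictly increasing
## thresholds alpha_j enforced by a log-gap parametrization. Fitting
## maximizes the weighted log-likelihood by BFGS with the analytic gradient;
## inverse-class-frequency weights compensate the dominance of HB1. Stepwise
## bidirectional AIC selection starts from the empty model.

#' Inverse class-frequency weights
#'
#' One weight per session: the reciprocal of its class's frequency in the
#' cohort, so every class carries the same total weight (the sum equals the
#' number of classes present).
#'
#' @param grades Adjusted grades (values in {1, 2, 3, 6}).
#' @return Numeric weight vector, same length.
#' @export
inverse_frequency_weights <- function(grades) {
  if (length(grades) == 0) hb_stop("empty_input", "no grades supplied")
  if (!all(grades %in% hb_levels()))
    hb_stop("bad_grade", "grades must be adjusted grades in {1,2,3,6}")
  counts <- table(factor(grades, levels = hb_levels()))
  1 / as.numeric(counts[as.character(grades)])
}

## negative weighted log-likelihood and analytic gradient.
## theta = (a1, g2, g3, beta...); alpha = a1 + cumsum(c(0, exp(g)))
olr_nll <- function(theta, Z, yidx, w) {
  p <- ncol(Z)
  g <- theta[2:3]
  alphas <- theta[1] + c(0, cumsum(exp(g)))
  eta <- if (p) drop(Z %*% theta[-(1:3)]) else numeric(length(yidx))
  Fm  <- ifelse(yidx <= 3, stats::plogis(alphas[pmin(yidx, 3)] + eta), 1)
  Fm1 <- ifelse(yidx >= 2, stats::plogis(alphas[pmax(yidx - 1, 1)] + eta), 0)
  P <- pmax(Fm - Fm1, 1e-300)
  -sum(w * log(P))
}

olr_grad <- function(theta, Z, yidx, w) {
  p <- ncol(Z)
  g <- theta[2:3]
  eg <- exp(g)
  alphas <- theta[1] + c(0, cumsum(eg))
  eta <- if (p) drop(Z %*% theta[-(1:3)]) else numeric(length(yidx))
  top <- yidx == 4
  bot <- yidx == 1
  Fm  <- ifelse(top, 1, stats::plogis(alphas[pmin(yidx, 3)] + eta))
  Fm1 <- ifelse(bot, 0, stats::plogis(alphas[pmax(yidx - 1, 1)] + eta))
  P <- pmax(Fm - Fm1, 1e-300)
  fm  <- ifelse(top, 0, Fm * (1 - Fm))     # logistic density at upper bound
  fm1 <- ifelse(bot, 0, Fm1 * (1 - Fm1))   # ... and at lower bound
  cw <- w / P
  ## d/d a1: every finite threshold shifts together
  d_a1 <- sum(cw * (fm - fm1))
  ## d/d g_l: threshold alpha_j moves by exp(g_l) iff j >= l (l = 2, 3)
  up_j <- pmin(yidx, 3); lo_j <- yidx - 1
  d_g <- vapply(2:3, function(l) {
    eg[l - 1] * sum(cw * (fm * (!top & up_j >= l) - fm1 * (!bot & lo_j >= l)))
  }, numeric(1))
  d_beta <- if (p) drop(crossprod(Z, cw * (fm - fm1))) else numeric(0)
  -c(d_a1, d_g, d_beta)
}

#' Fit a weighted proportional-odds model on health scores
#'
#' Weighted maximum-likelihood fit of the cumulative-logit model over the
#' ordered adjusted grades (1, 2, 3, 6). Thresholds are kept strictly
#' increasing by parametrizing the gaps on the log scale; the optimizer is
#' BFGS on the negative weighted log-likelihood with its analytic gradient.
#' Weights are rescaled to mean 1, which leaves the fit and the predictions
#' unchanged but keeps the AIC on the usual per-observation scale.
#'
#' @param scores Numeric matrix (sessions x indicator labels) of health
#'   scores, or an `hb_scores` long table.
#' @param grades Adjusted grades, one per row.
#' @param weights Observation weights; defaults to
#'   [inverse_frequency_weights()].
#' @param tol Relative convergence tolerance.
#' @param max_iter Maximum BFGS iterations.
#' @return Object of class `hb_olr`: `thresholds` (alpha_j, strictly
#'   increasing), `coefficients` (named beta_i), `selected_labels`,
#'   `weights_used`, `loglik`, `aic`, `converged`, `n`.
#' @export
fit_olr <- function(scores, grades, weights = NULL, tol = 1e-8,
                    max_iter = 500L) {
  if (inherits(scores, "hb_scores")) scores <- score_matrix(scores)
  Z <- as.matrix(scores)
  if (is.null(colnames(Z)) && ncol(Z))
    colnames(Z) <- paste0("score", seq_len(ncol(Z)))
  if (length(grades) != nrow(Z))
    hb_stop("bad_input", "one grade per score row required")
  if (anyNA(Z))
    hb_stop("missing_scores", "missing scores among the model's columns")
  yidx <- match(grades, hb_levels())
  if (anyNA(yidx)) hb_stop("bad_grade", "grades must be in {1,2,3,6}")
  if (length(unique(yidx)) < 2)
    hb_stop("one_class", "need at least 2 distinct classes")
  if (is.null(weights)) weights <- inverse_frequency_weights(grades)
  if (length(weights) != nrow(Z) || any(weights <= 0))
    hb_stop("bad_input", "weights must be positive, one per session")
  w <- weights / mean(weights)
  ## initialize thresholds at the weighted empirical cumulative logits
  cumw <- cumsum(vapply(1:3, function(j) sum(w[yidx == j]), numeric(1))) / sum(w)
  cumw <- pmin(pmax(cumw, 1e-3), 1 - 1e-3)
  cumw <- cummax(cumw + (1:3) * 1e-6)
  al0 <- stats::qlogis(cumw)
  theta0 <- c(al0[1], log(pmax(diff(al0), 1e-3)), rep(0, ncol(Z)))
  opt <- stats::optim(theta0, olr_nll, olr_grad, Z = Z, yidx = yidx, w = w,
                      method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  theta <- opt$par
  alphas <- theta[1] + c(0, cumsum(exp(theta[2:3])))
  beta <- stats::setNames(theta[-(1:3)], colnames(Z))
  ll <- -opt$value
  npar <- 3L + ncol(Z)
  structure(list(levels = hb_levels(), thresholds = alphas,
                 coefficients = beta, selected_labels = colnames(Z),
                 weights_used = w, loglik = ll, aic = 2 * npar - 2 * ll,
                 converged = opt$convergence == 0, n = nrow(Z),
                 inclusion_order = colnames(Z)),
            class = "hb_olr")
}

#' @export
print.hb_olr <- function(x, ...) {
  cat(sprintf("<hb_olr> proportional-odds model on %d sessions, %d scores\n",
              x$n, length(x$coefficients)))
  cat("  thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = " < "), "\n")
  if (length(x$coefficients)) {
    cat("  coefficients:\n")
    print(round(x$coefficients, 3))
  }
  cat(sprintf("  logLik %.3f, AIC %.2f, converged: %s\n",
              x$loglik, x$aic, x$converged))
  invisible(x)
}

#' @export
coef.hb_olr <- function(object, ...) {
  c(stats::setNames(object$thresholds, paste0("alpha_", 1:3)),
    object$coefficients)
}

#' @export
logLik.hb_olr <- function(object, ...) {
  structure(object$loglik, df = 3L + length(object$coefficients),
            class = "logLik")
}

#' Class probabilities under a fitted proportional-odds model
#'
#' Differences of the cumulative probabilities: `P(HB = j) = P(HB <= j) -
#' P(HB <= j-1)`, with `P(HB <= 6) = 1`. Rows are nonnegative and sum to 1.
#'
#' @param model An `hb_olr`.
#' @param scores Named numeric vector (one session) or matrix with the
#'   model's selected labels as columns.
#' @return Matrix of probabilities, sessions x grades (columns "1","2","3","6").
#' @export
class_probabilities <- function(model, scores) {
  stopifnot(inherits(model, "hb_olr"))
  Z <- if (is.null(dim(scores))) matrix(scores, nrow = 1,
                                        dimnames = list(NULL, names(scores)))
  else as.matrix(scores)
  sel <- model$selected_labels
  if (length(sel)) {
    if (!all(sel %in% colnames(Z)))
      hb_stop("missing_scores",
              sprintf("missing selected scores: %s",
                      paste(setdiff(sel, colnames(Z)), collapse = ", ")))
    Z <- Z[, sel, drop = FALSE]
    if (anyNA(Z)) hb_stop("missing_scores", "NA among selected scores")
    eta <- drop(Z %*% model$coefficients)
  } else eta <- numeric(nrow(Z))
  Fj <- vapply(model$thresholds, function(a) stats::plogis(a + eta),
               numeric(length(eta)))
  Fj <- matrix(Fj, nrow = length(eta))
  out <- cbind(Fj, 1) - cbind(0, Fj)
  dimnames(out) <- list(rownames(Z), as.character(model$levels))
  out
}

#' Grade with the highest probability
#'
#' @param prob Probability matrix/vector over the grades (1, 2, 3, 6); ties
#'   break toward the lower (healthier) grade.
#' @return Integer vector of predicted adjusted grades.
#' @export
grade_from_probabilities <- function(prob) {
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1)
  hb_levels()[apply(prob, 1, which.max)]
}

#' @export
#' @rdname class_probabilities
#' @param object An `hb_olr`.
#' @param newdata Score matrix (or named vector) to predict for.
#' @param type `"class"` for the argmax grade, `"prob"` for the full
#'   probability matrix.
#' @param ... Unused.
predict.hb_olr <- function(object, newdata,
                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- class_probabilities(object, newdata)
  if (type == "prob") p else grade_from_probabilities(p)
}

#' Stepwise AIC selection of health scores
#'
#' Greedy bidirectional search starting from the intercept-only model:
#' repeatedly applies the single add-or-drop move that most reduces
#' `AIC = 2 (#parameters) - 2 (weighted log-likelihood)`, stopping when no
#' move reduces it. Candidate fits that fail are skipped with a warning.
#'
#' @param scores Score matrix (sessions x labels) or `hb_scores` table;
#'   columns with missing values are dropped from the candidate set.
#' @param grades Adjusted grades.
#' @param weights See [fit_olr()].
#' @param trace Print each accepted move.
#' @return The final refitted `hb_olr`, with `inclusion_order` recording the
#'   order labels entered the model.
#' @export
stepwise_select <- function(scores, grades, weights = NULL, trace = FALSE) {
  if (inherits(scores, "hb_scores")) scores <- score_matrix(scores)
  Z <- as.matrix(scores)
  complete <- colSums(is.na(Z)) == 0
  if (!all(complete)) {
    warning(sprintf("dropping candidates with missing scores: %s",
                    paste(colnames(Z)[!complete], collapse = ", ")), call. = FALSE)
    Z <- Z[, complete, drop = FALSE]
  }
  if (ncol(Z) == 0) hb_stop("bad_input", "no candidate score columns")
  if (is.null(weights)) weights <- inverse_frequency_weights(grades)
  fit_subset <- function(labels) {
    tryCatch(fit_olr(Z[, labels, drop = FALSE], grades, weights),
             error = function(e) {
               warning(sprintf("candidate fit {%s} failed: %s",
                               paste(labels, collapse = ","),
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  }
  current <- character(0)
  best <- fit_subset(current)
  if (is.null(best)) hb_stop("fit_failed", "the empty model failed to fit")
  order_in <- character(0)
  repeat {
    moves <- c(lapply(setdiff(colnames(Z), current),
                      function(l) list(action = "add", label = l)),
               lapply(current, function(l) list(action = "drop", label = l)))
    best_move <- NULL; best_fit <- NULL; best_aic <- best$aic
    for (mv in moves) {
      labels <- if (mv$action == "add") c(current, mv$label)
      else setdiff(current, mv$label)
      fit <- fit_subset(labels)
      if (!is.null(fit) && fit$aic < best_aic - 1e-8) {
        best_aic <- fit$aic; best_move <- mv; best_fit <- fit
      }
    }
    if (is.null(best_move)) break
    if (trace)
      cat(sprintf("%s %s: AIC %.3f -> %.3f\n", best_move$action,
                  best_move$label, best$aic, best_aic))
    current <- if (best_move$action == "add") c(current, best_move$label)
    else setdiff(current, best_move$label)
    if (best_move$action == "add") order_in <- c(order_in, best_move$label)
    else order_in <- setdiff(order_in, best_move$label)
    best <- best_fit
  }
  best$inclusion_order <- order_in
  best
}

#' Confusion matrix over adjusted grades
#'
#' @param true,predicted Equal-length vectors of adjusted grades; rows of the
#'   result are the clinician (true) grades, columns the model's.
#' @return 4 x 4 integer matrix of class `hb_confusion`.
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) != length(predicted))
    hb_stop("length_mismatch", "true and predicted grades differ in length")
  lv <- as.character(hb_levels())
  m <- table(factor(true, levels = lv), factor(predicted, levels = lv))
  m <- unclass(matrix(as.integer(m), 4, 4, dimnames = list(
    `HB by clinician` = lv, `HB by model` = lv)))
  structure(m, class = c("hb_confusion", class(m)))
}

#' Classification accuracy report
#'
#' Per-class and overall rates of correct classification (diagonal over the
#' row total) and approximate classification: the predicted grade differs
#' from the clinician's by at most 1 on the numeric grade values, so a
#' prediction of 6 for a true 3 (distance 3) is not approximate. Exact
#' fractions are retained; percentages are rounded to integers for display.
#'
#' @param cm An `hb_confusion` (or any 4x4 count matrix over grades
#'   1, 2, 3, 6 with true grades in rows).
#' @return List of class `hb_accuracy`: `per_class` data.frame (`class`, `n`,
#'   `correct`, `approximate`, exact fractions plus `*_pct` integers),
#'   `overall_correct`, `overall_approximate` (fractions),
#'   `overall_correct_pct`, `overall_approximate_pct`,
#'   `misclassified_pct` (100 minus the approximate percentage).
#' @export
accuracy_report <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (!all(dim(cm) == c(4, 4))) hb_stop("bad_input", "expected a 4x4 count matrix")
  lv <- hb_levels()
  approx_mask <- abs(outer(lv, lv, "-")) <= 1
  row_n <- rowSums(cm)
  if (sum(row_n) == 0) hb_stop("empty_input", "empty confusion matrix")
  correct <- diag(cm) / row_n
  approx <- rowSums(cm * approx_mask) / row_n
  correct[row_n == 0] <- NA
  approx[row_n == 0] <- NA
  per_class <- data.frame(
    class = lv, n = as.integer(row_n),
    correct = correct, approximate = approx,
    correct_pct = as.integer(round(100 * correct)),
    approximate_pct = as.integer(round(100 * approx)),
    row.names = NULL)
  oc <- sum(diag(cm)) / sum(cm)
  oa <- sum(cm * approx_mask) / sum(cm)
  structure(list(per_class = per_class,
                 overall_correct = oc, overall_approximate = oa,
                 overall_correct_pct = as.integer(round(100 * oc)),
                 overall_approximate_pct = as.integer(round(100 * oa)),
                 misclassified_pct = 100L - as.integer(round(100 * oa)),
                 n = sum(cm)),
            class = "hb_accuracy")
}

#' @export
print.hb_accuracy <- function(x, ...) {
  cat("Accuracy of classification (", x$n, " sessions)\n", sep = "")
  tab <- x$per_class
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  HB%-2d correct %3s%%  approximate %3s%%  (n = %d)\n",
                tab$class[i], tab$correct_pct[i], tab$approximate_pct[i],
                tab$n[i]))
  cat(sprintf("  Altogether correct %d%%, approximate %d%% (%d%% misclassified)\n",
              x$overall_correct_pct, x$overall_approximate_pct,
              x$misclassified_pct))
  invisible(x)
}
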