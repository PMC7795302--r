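## Stage 2: scalar-on-function logistic regression (health scores).
##
## Each indicator curve X(t) enters a logistic model
##   p = 1 / (1 + exp(-alpha - integral X(t) beta(t) dt))
## with beta(t) expanded in a B-spline basis; the integral is evaluated by
## trapezoid quadrature on the common grid, which reduces the fit to a
## penalized (ridge) logistic regression on the quadrature-weighted basis
## scores. The model is trained on the extreme groups only (Healthy = HB1 vs
## Sick = HB6 adjusted) and then scores every session: the health score is
## the fitted probability of belonging to the Healthy group.

## B-spline basis for beta(t); dimension 1 degenerates to the constant basis
## (the model then reduces to scalar logistic regression on the curve integral)
flr_basis <- function(grid, dim, boundary = range(grid)) {
  if (dim == 1) return(matrix(1, length(grid), 1))
  splines::bs(grid, df = dim, degree = min(3L, dim - 1L), intercept = TRUE,
              Boundary.knots = boundary)
}

trapezoid_weights <- function(grid) {
  G <- length(grid)
  d <- diff(grid)
  c(d[1] / 2, (d[-(G - 1)] + d[-1]) / 2, d[G - 1] / 2)
}

## speed indicator curves enter as warping-minus-identity residuals by
## default, removing the deterministic diagonal trend
apply_transform <- function(values, times, transform) {
  if (identical(transform, "residual")) values - times else values
}

#' Fit a functional logistic regression (health-score model)
#'
#' Maximum penalized-likelihood fit of the scalar-on-function logistic model
#' for one indicator label, trained on Healthy vs Sick group labels. A small
#' ridge penalty on the basis coefficients (not the intercept) keeps the fit
#' finite under complete separation, which is the norm for well-separated
#' extreme groups and rich functional covariates.
#'
#' @param X Numeric matrix of curves, one row per session, columns on `grid`;
#'   or a list of `hb_curve` on a common grid.
#' @param healthy Logical vector (TRUE = Healthy group), one per row.
#' @param grid Common time grid (taken from the curves when `X` is a list).
#' @param label Indicator label carried in the model.
#' @param basis_dim B-spline basis dimension for beta(t).
#' @param penalty Ridge penalty on the basis coefficients.
#' @param transform `"none"` or `"residual"` (subtract the identity from the
#'   curve values before fitting; used for speed indicators).
#' @param max_iter,tol IRLS iteration control.
#' @return Object of class `hb_flr` with elements `alpha`, `coefficients`
#'   (basis coefficients of beta), `basis` (type/dimension/domain), `penalty`,
#'   `group_sizes`, `converged`, `separation` (logical diagnostic).
#' @export
fit_flr <- function(X, healthy, grid = NULL, label = "indicator",
                    basis_dim = 8L, penalty = 1e-3, transform = "none",
                    max_iter = 100L, tol = 1e-10) {
  if (is.list(X) && !is.data.frame(X)) {
    grid <- X[[1]]$times
    X <- do.call(rbind, lapply(X, function(c) c$values))
  }
  X <- as.matrix(X)
  if (is.null(grid)) hb_stop("bad_input", "grid required with a matrix input")
  healthy <- as.logical(healthy)
  if (length(healthy) != nrow(X))
    hb_stop("bad_input", "one group label per curve required")
  n1 <- sum(healthy); n0 <- sum(!healthy)
  if (n1 == 0 || n0 == 0)
    hb_stop("one_class", "both Healthy and Sick groups must be present")
  if (n1 < 3 || n0 < 3)
    hb_stop("too_few_curves", "need at least 3 curves per group")
  X <- t(apply(X, 1, apply_transform, times = grid, transform = transform))
  q <- trapezoid_weights(grid)
  B <- flr_basis(grid, basis_dim)
  M <- q * B                                   # G x dim quadrature-weighted basis
  Z <- X %*% M                                 # n x dim design
  y <- as.numeric(healthy)
  p_dim <- ncol(Z) + 1L
  theta <- numeric(p_dim)
  pen <- c(0, rep(penalty, ncol(Z)))           # no penalty on the intercept
  W <- cbind(1, Z)
  obj_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(W %*% theta)
    p <- stats::plogis(eta)
    obj <- -sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300))) +
      0.5 * sum(pen * theta^2)
    g <- -drop(crossprod(W, y - p)) + pen * theta
    v <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(W, W * v) + diag(pen, p_dim)
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) break
    ## halve the step until the objective does not increase
    stp <- 1
    repeat {
      theta_new <- theta - stp * delta
      eta_new <- drop(W %*% theta_new)
      p_new <- stats::plogis(eta_new)
      obj_new <- -sum(y * log(pmax(p_new, 1e-300)) +
                      (1 - y) * log(pmax(1 - p_new, 1e-300))) +
        0.5 * sum(pen * theta_new^2)
      if (obj_new <= obj + 1e-12 || stp < 1e-8) break
      stp <- stp / 2
    }
    theta <- theta_new
    if (abs(obj_old - obj_new) < tol * (abs(obj_new) + 1)) { converged <- TRUE; break }
    obj_old <- obj_new
  }
  eta <- drop(W %*% theta)
  separation <- max(abs(eta)) > 25
  if (separation && penalty == 0)
    warning(sprintf("flr[%s]: complete separation; unpenalized estimates diverge",
                    label), call. = FALSE)
  structure(list(label = label, alpha = unname(theta[1]),
                 coefficients = unname(theta[-1]),
                 basis = list(type = "bs", dimension = as.integer(basis_dim),
                              domain = range(grid), grid = grid),
                 quadrature = M, penalty = penalty, transform = transform,
                 group_sizes = c(healthy = n1, sick = n0),
                 converged = converged, separation = separation),
            class = "hb_flr")
}

#' @export
print.hb_flr <- function(x, ...) {
  cat(sprintf("<hb_flr> %s: alpha = %.3f, %d basis coefficients (penalty %g)\n",
              x$label, x$alpha, length(x$coefficients), x$penalty))
  cat(sprintf("  trained on %d Healthy vs %d Sick curves; converged: %s\n",
              x$group_sizes[1], x$group_sizes[2], x$converged))
  invisible(x)
}

#' @export
coef.hb_flr <- function(object, ...) {
  c(alpha = object$alpha,
    stats::setNames(object$coefficients,
                    paste0("beta", seq_along(object$coefficients))))
}

#' Evaluate the functional coefficient beta(t)
#'
#' @param model An `hb_flr`.
#' @param t Evaluation times within the model domain.
#' @return Numeric vector beta(t).
#' @export
flr_beta <- function(model, t = model$basis$grid) {
  B <- flr_basis(t, model$basis$dimension, model$basis$domain)
  drop(B %*% model$coefficients)
}

#' @export
plot.hb_flr <- function(x, ...) {
  t <- x$basis$grid
  graphics::plot(t, flr_beta(x, t), type = "l", xlab = "t (registered)",
                 ylab = expression(beta(t)),
                 main = sprintf("FLR coefficient curve: %s", x$label), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Health score of one curve
#'
#' Evaluates the fitted scalar-on-function logistic model: the probability of
#' the curve's belonging to the Healthy group.
#'
#' @param model An `hb_flr`.
#' @param curve An `hb_curve` on the model's grid, or a numeric matrix of
#'   curve rows.
#' @return Numeric score(s) in \[0, 1\].
#' @export
flr_score <- function(model, curve) {
  X <- if (inherits(curve, "hb_curve")) {
    if (length(curve$times) != length(model$basis$grid) ||
        max(abs(curve$times - model$basis$grid)) > 1e-8)
      hb_stop("grid_mismatch", "curve grid differs from the model's grid")
    matrix(curve$values, nrow = 1)
  } else as.matrix(curve)
  if (ncol(X) != length(model$basis$grid))
    hb_stop("grid_mismatch", "curve grid differs from the model's grid")
  X <- t(apply(X, 1, apply_transform, times = model$basis$grid,
               transform = model$transform))
  drop(stats::plogis(model$alpha + X %*% model$quadrature %*% model$coefficients))
}

#' @export
predict.hb_flr <- function(object, newdata, ...) flr_score(object, newdata)

#' Fit all per-indicator health-score models
#'
#' Fits one independent [fit_flr()] per available indicator label on the
#' extreme groups: Healthy = adjusted grade 1, Sick = adjusted grade 6.
#'
#' @param inds List of `hb_indicators` (see [compute_indicators()]).
#' @param grades Adjusted grades, one per session.
#' @param basis_dim,penalty See [fit_flr()].
#' @param speed_transform `"residual"` (default) or `"none"` for the speed
#'   indicator curves.
#' @return Named list of `hb_flr` models (one per label with enough data).
#' @export
fit_flr_models <- function(inds, grades, basis_dim = 8L, penalty = 1e-3,
                           speed_transform = "residual") {
  stopifnot(length(inds) == length(grades))
  models <- list()
  for (lab in indicator_labels()) {
    have <- which(vapply(inds, function(i) !is.null(i$curves[[lab]]), logical(1)))
    extreme <- have[grades[have] %in% c(1L, 6L)]
    if (length(extreme) == 0) next
    healthy <- grades[extreme] == 1L
    if (sum(healthy) < 3 || sum(!healthy) < 3) next
    curves <- lapply(inds[extreme], function(i) i$curves[[lab]])
    transform <- if (grepl("\\.speed$", lab)) speed_transform else "none"
    models[[lab]] <- fit_flr(curves, healthy, label = lab,
                             basis_dim = basis_dim, penalty = penalty,
                             transform = transform)
  }
  models
}

#' Score a dataset of sessions
#'
#' Applies the per-label health-score models to every session's indicator
#' curves (all sessions, not only the extreme training groups). Absent
#' indicators yield `NA` scores, flagged rather than fatal.
#'
#' @param models Named list of `hb_flr` (see [fit_flr_models()]).
#' @param inds List of `hb_indicators`.
#' @return Long-format data.frame (`session_id`, `label`, `score`) of class
#'   `hb_scores`.
#' @export
score_dataset <- function(models, inds) {
  rows <- lapply(inds, function(ind) {
    labs <- names(models)
    score <- vapply(labs, function(lab) {
      cur <- ind$curves[[lab]]
      if (is.null(cur)) NA_real_ else flr_score(models[[lab]], cur)
    }, numeric(1))
    data.frame(session_id = ind$session_id, label = labs, score = score,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hb_scores", "data.frame")
  out
}

#' Wide score matrix
#'
#' @param scores An `hb_scores` long table.
#' @return Numeric matrix, sessions x indicator labels.
#' @export
score_matrix <- function(scores) {
  ids <- unique(scores$session_id)
  labs <- unique(scores$label)
  m <- matrix(NA_real_, length(ids), length(labs),
              dimnames = list(ids, labs))
  m[cbind(match(scores$session_id, ids), match(scores$label, labs))] <- scores$score
  m
}

#' Spearman correlation of health scores with clinician grades
#'
#' Per-label Spearman rank correlation (mid-rank ties) between health scores
#' and adjusted clinician grades, with two-sided p-values from the
#' t-approximation; sorted by correlation coefficient. Recovered function is
#' negative correlations: higher scores (healthier) at lower grades.
#'
#' @param scores An `hb_scores` long table.
#' @param grades Named numeric vector of adjusted grades (names =
#'   session ids), or unnamed in the order of `unique(scores$session_id)`.
#' @return data.frame (`label`, `rho`, `p_value`, `n`), `NA` rho for
#'   degenerate (constant) inputs.
#' @export
spearman_vs_grade <- function(scores, grades) {
  m <- score_matrix(scores)
  g <- if (!is.null(names(grades))) grades[rownames(m)] else grades
  if (length(g) != nrow(m))
    hb_stop("bad_input", "one grade per session required")
  res <- lapply(colnames(m), function(lab) {
    ok <- !is.na(m[, lab]) & !is.na(g)
    n <- sum(ok)
    if (n < 3) return(data.frame(label = lab, rho = NA, p_value = NA, n = n))
    x <- m[ok, lab]; y <- g[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("spearman[%s]: constant input, rho undefined", lab),
              call. = FALSE)
      return(data.frame(label = lab, rho = NA, p_value = NA, n = n))
    }
    rho <- stats::cor(x, y, method = "spearman")
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    data.frame(label = lab, rho = rho,
               p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
  })
  out <- do.call(rbind, res)
  out[order(out$rho), , drop = FALSE]
}

#' Pearson correlogram of health scores
#'
#' Symmetric matrix of pairwise Pearson correlations between the per-label
#' health scores over sessions (pairwise-complete observations, unit
#' diagonal). Degenerate (constant) columns give `NA` with a warning.
#'
#' @param scores An `hb_scores` long table.
#' @return Symmetric correlation matrix, labels x labels.
#' @export
score_correlogram <- function(scores) {
  m <- score_matrix(scores)
  if (nrow(m) < 3) hb_stop("too_few_curves", "need at least 3 sessions")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning(sprintf("degenerate (constant) score columns: %s",
                    paste(colnames(m)[!is.na(sds) & sds == 0], collapse = ", ")),
            call. = FALSE)
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}
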