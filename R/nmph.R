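#' Theory-constrained cubic fit of representational change
#'
#' Fits a least-squares cubic to change-by-similarity data with the leading
#' coefficient constrained to be positive (`a >= a_min`), the functional
#' form of the nonmonotonic plasticity hypothesis: a dip (differentiation)
#' at moderate similarity followed by a positive inflection (integration)
#' at high similarity. Levels are centred and scaled to unit SD before
#' fitting; coefficients are reported on both scales. When the
#' unconstrained solution already satisfies the constraint the two
#' solutions coincide; otherwise the leading coefficient is pinned at
#' `a_min` and the remaining coefficients re-estimated by least squares
#' (the active-set solution of this single-constraint problem).
#'
#' @param x similarity levels (>= 4 distinct values); default 1:8.
#' @param y change values: a vector of `length(x)`, or a matrix of stacked
#'   participant curves (participants in rows) fitted as pooled points.
#' @param a_min lower bound on the leading coefficient (default 1e-6).
#' @return object of class `nmph_cubic` with components `coefficients`
#'   (standardized scale, named a, b, c, d), `coefficients_raw`,
#'   `fitted.values`, `residuals`, `sse`, `sse_unconstrained`,
#'   `constraint_active`, `x`, `y`, `x_center`, `x_scale`, `a_min`.
#' @seealso [loo_cv()], [dip_contrasts()]
#' @examples
#' curve <- planted_cubic(1:8, a = 0.05, c = -0.08)
#' fit <- fit_constrained_cubic(1:8, curve)
#' coef(fit)
#' predict(fit, newdata = 1:8)
#' @export
fit_constrained_cubic <- function(x = 1:8, y, a_min = 1e-6) {
  if (is.matrix(y)) {
    ylong <- as.vector(t(y))
    xlong <- rep(x, nrow(y))
  } else {
    ylong <- as.numeric(y)
    xlong <- x
  }
  if (length(unique(x)) < 4L)
    stopf("underdetermined: need >= 4 distinct x values for a cubic")
  stopifnot(length(ylong) == length(xlong))
  ctr <- mean(x); scl <- sd(x)
  xs <- (xlong - ctr) / scl
  X <- cbind(xs^3, xs^2, xs, 1)
  fit_u <- lm.fit(X, ylong)
  beta_u <- fit_u$coefficients
  sse_u <- sum(fit_u$residuals^2)
  if (beta_u[1] >= a_min) {
    beta <- beta_u
    active <- FALSE
  } else {
    fit_c <- lm.fit(X[, 2:4, drop = FALSE], ylong - a_min * xs^3)
    beta <- c(a_min, fit_c$coefficients)
    active <- TRUE
  }
  names(beta) <- c("a", "b", "c", "d")
  fitted <- as.vector(X %*% beta)
  # raw-scale coefficients via a 4-point Vandermonde solve on the fitted
  # polynomial
  xr <- c(0, 1, 2, 3)
  yr <- beta[1] * ((xr - ctr) / scl)^3 + beta[2] * ((xr - ctr) / scl)^2 +
    beta[3] * ((xr - ctr) / scl) + beta[4]
  raw <- solve(cbind(xr^3, xr^2, xr, 1), yr)
  names(raw) <- c("a", "b", "c", "d")
  structure(list(coefficients = beta, coefficients_raw = raw,
                 fitted.values = fitted, residuals = ylong - fitted,
                 sse = sum((ylong - fitted)^2), sse_unconstrained = sse_u,
                 constraint_active = active, x = xlong, y = ylong,
                 x_center = ctr, x_scale = scl, a_min = a_min),
            class = "nmph_cubic")
}

#' @export
print.nmph_cubic <- function(x, digits = 4, ...) {
  cat("Theory-constrained cubic (leading coefficient >= ",
      format(x$a_min), ")\n", sep = "")
  cat("Coefficients (standardized levels):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("SSE %.5g (unconstrained %.5g)%s\n", x$sse,
              x$sse_unconstrained,
              if (x$constraint_active) "; constraint active" else ""))
  invisible(x)
}

#' @export
coef.nmph_cubic <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  if (scale == "raw") object$coefficients_raw else object$coefficients
}

#' @export
predict.nmph_cubic <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  xs <- (x - object$x_center) / object$x_scale
  b <- object$coefficients
  as.vector(b[1] * xs^3 + b[2] * xs^2 + b[3] * xs + b[4])
}

#' @export
residuals.nmph_cubic <- function(object, ...) object$residuals

#' @export
fitted.nmph_cubic <- function(object, ...) object$fitted.values

#' @export
summary.nmph_cubic <- function(object, ...) {
  xs <- sort(unique(object$x))
  out <- list(coefficients = object$coefficients,
              coefficients_raw = object$coefficients_raw,
              sse = object$sse,
              constraint_active = object$constraint_active,
              n_points = length(object$y),
              curve = data.frame(level = xs,
                                 predicted = predict(object, xs)))
  class(out) <- "summary.nmph_cubic"
  out
}

#' @export
print.summary.nmph_cubic <- function(x, ...) {
  cat(sprintf("Constrained cubic over %d points%s\n", x$n_points,
              if (x$constraint_active) " (leading coefficient at bound)" else ""))
  print(round(x$coefficients, 4))
  cat("Predicted change by level:\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.nmph_cubic <- function(x, ...) {
  xs <- sort(unique(x$x))
  grid <- seq(min(xs), max(xs), length.out = 100)
  graphics::plot(x$x, x$y, xlab = "model similarity level",
                 ylab = expression(Delta * r), ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Leave-one-participant-out cross-validation of the constrained cubic
#'
#' For each fold, fits the constrained cubic to the level-wise mean of the
#' remaining participants' change curves, predicts the held-out
#' participant's curve, and Pearson-correlates prediction with observation;
#' the per-fold correlations are averaged raw.
#'
#' @param curves participants x levels matrix of change curves.
#' @param x similarity levels (default `1:ncol(curves)`).
#' @param a_min leading-coefficient bound.
#' @return list of class `nmph_cv`: `mean_r`, `per_fold_r` (NA for skipped
#'   zero-variance folds), `n_folds`.
#' @export
loo_cv <- function(curves, x = seq_len(ncol(curves)), a_min = 1e-6) {
  n <- nrow(curves)
  if (n < 3L) stopf("need >= 3 participants for cross-validation")
  per_fold <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    held <- curves[i, ]
    if (sd(held) == 0) {
      message(sprintf("fold %d skipped: zero-variance held-out curve", i))
      next
    }
    train <- colMeans(curves[-i, , drop = FALSE])
    fit <- fit_constrained_cubic(x, train, a_min)
    pred <- predict(fit, x)
    per_fold[i] <- if (sd(pred) == 0) 0 else cor(pred, held)
  }
  structure(list(mean_r = mean(per_fold, na.rm = TRUE),
                 per_fold_r = per_fold, n_folds = n),
            class = "nmph_cv")
}

#' @export
print.nmph_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out CV over %d participants: mean r = %.4f\n",
              x$n_folds, x$mean_r))
  invisible(x)
}

#' Dip contrasts of a group change curve
#'
#' Signed contrasts characterizing the U-shape: the change at levels 5 and
#' 6 (the trough region, tested against zero) and the flanking peaks at
#' levels 4 and 8 relative to the trough (mean of levels 5 and 6).
#'
#' @param curve length-8 group-mean change curve.
#' @return named numeric vector: `level5`, `level6`, `level4_minus_trough`,
#'   `level8_minus_trough`.
#' @export
dip_contrasts <- function(curve) {
  stopifnot(length(curve) == 8L)
  trough <- mean(curve[5:6])
  c(level5 = curve[5], level6 = curve[6],
    level4_minus_trough = curve[4] - trough,
    level8_minus_trough = curve[8] - trough)
}

#' Cross-validated NMPH statistic for resampling
#'
#' Convenience statistic functions plugging the cubic cross-validation into
#' [bootstrap_ci()] and [shuffle_null()]: given a list of per-participant
#' pattern sets (elements of a `pattern_set`), recompute the change curves
#' (optionally under a re-pairing permutation) and return the LOO-CV mean
#' correlation.
#'
#' @param participants list of per-participant elements of a `pattern_set`.
#' @param perm optional permutation of pair indices re-assigning B images.
#' @param a_min leading-coefficient bound.
#' @return scalar mean cross-validated correlation.
#' @export
nmph_cv_stat <- function(participants, perm = NULL, a_min = 1e-6) {
  curves <- change_curves(structure(participants, class = "pattern_set"),
                          perm = perm)
  loo_cv(curves, a_min = a_min)$mean_r
}
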