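test_that("an exactly-cubic curve with positive leading coefficient is recovered", {
  y <- planted_cubic(1:8, a = 0.02, b = -0.01, c = 0.05, d = 0.003)
  fit <- fit_constrained_cubic(1:8, y)
  expect_equal(unname(coef(fit)), c(0.02, -0.01, 0.05, 0.003),
               tolerance = 1e-6)
  expect_false(fit$constraint_active)
  expect_lt(fit$sse, 1e-12)
  # raw-scale coefficients predict identically
  raw <- coef(fit, "raw")
  xs <- 1:8
  expect_equal(raw[1] * xs^3 + raw[2] * xs^2 + raw[3] * xs + raw[4],
               predict(fit, xs), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a negative-leading-coefficient curve activates the constraint", {
  y <- planted_cubic(1:8, a = -0.02, c = 0.05)
  fit <- fit_constrained_cubic(1:8, y, a_min = 1e-6)
  expect_equal(unname(coef(fit)[1]), 1e-6)
  expect_true(fit$constraint_active)
  expect_gte(fit$sse, fit$sse_unconstrained - 1e-9)
  expect_gt(fit$sse, fit$sse_unconstrained)
})

test_that("the constrained solution matches an independent box-constrained solver", {
  set.seed(4)
  for (rep in 1:6) {
    x <- 1:5
    y <- rnorm(5, sd = 0.3) - 0.05 * ((x - 3) / sd(x))^3
    fit <- fit_constrained_cubic(x, y, a_min = 1e-6)
    xs <- (x - mean(x)) / sd(x)
    sse_fn <- function(b) sum((y - (b[1] * xs^3 + b[2] * xs^2 +
                                      b[3] * xs + b[4]))^2)
    oracle <- optim(c(1, 0, 0, 0), sse_fn, method = "L-BFGS-B",
                    lower = c(1e-6, -Inf, -Inf, -Inf),
                    control = list(factr = 1e3, maxit = 500))
    expect_equal(fit$sse, oracle$value, tolerance = 1e-5)
    expect_equal(unname(coef(fit)), oracle$par, tolerance = 1e-3)
  }
})

test_that("constrained SSE never beats the unconstrained fit", {
  set.seed(9)
  for (rep in 1:50) {
    y <- rnorm(8, sd = 0.1)
    fit <- fit_constrained_cubic(1:8, y)
    expect_gte(fit$sse + 1e-12, fit$sse_unconstrained)
  }
})

test_that("the fit is invariant to affine relabelling of the levels", {
  y <- c(0.02, 0, -0.03, -0.07, -0.1, -0.08, -0.01, 0.08)
  f1 <- fit_constrained_cubic(1:8, y)
  f2 <- fit_constrained_cubic(2 * (1:8) + 3, y)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-9)
})

test_that("stacked curves and underdetermined input are handled", {
  curves <- rbind(planted_cubic(1:8, 0.03, 0, -0.05, 0),
                  planted_cubic(1:8, 0.03, 0, -0.05, 0))
  fit <- fit_constrained_cubic(1:8, curves)
  expect_equal(unname(coef(fit)), c(0.03, 0, -0.05, 0), tolerance = 1e-6)
  expect_error(fit_constrained_cubic(c(1, 1, 2, 3), 1:4), "underdetermined")
})

test_that("model methods behave like a classed fit object", {
  y <- planted_cubic(1:8, 0.04, 0.01, -0.06, -0.02) + rnorm(8, sd = 0.005)
  fit <- fit_constrained_cubic(1:8, y)
  expect_s3_class(fit, "nmph_cubic")
  expect_equal(fitted(fit) + residuals(fit), y, ignore_attr = TRUE)
  expect_output(print(fit), "constrained cubic")
  expect_output(print(summary(fit)), "Predicted change")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("leave-one-out CV is exact on consensus data and null on noise", {
  curve <- planted_cubic(1:8, 0.05, 0, -0.08, 0)
  curves <- matrix(rep(curve, 10), 10, 8, byrow = TRUE)
  cv <- loo_cv(curves)
  expect_equal(cv$mean_r, 1, tolerance = 1e-9)
  expect_equal(cv$n_folds, 10L)
  set.seed(3)
  noise <- matrix(rnorm(30 * 8, sd = 0.1), 30, 8)
  cv0 <- loo_cv(noise)
  expect_lt(abs(cv0$mean_r), 2 / sqrt(8 * 30) * 3)
  expect_error(loo_cv(noise[1:2, ]), "3 participants")
})

test_that("three hand-worked folds reproduce loo_cv", {
  curves <- rbind(c(0.02, 0, -0.02, -0.06, -0.09, -0.07, 0, 0.06),
                  c(0.01, 0.01, -0.04, -0.05, -0.11, -0.06, 0.01, 0.05),
                  c(0.03, -0.01, -0.01, -0.07, -0.08, -0.09, -0.01, 0.07))
  cv <- loo_cv(curves)
  per_fold <- vapply(1:3, function(i) {
    train <- colMeans(curves[-i, , drop = FALSE])
    fit <- fit_constrained_cubic(1:8, train)
    cor(predict(fit, 1:8), curves[i, ])
  }, numeric(1))
  expect_equal(cv$per_fold_r, per_fold, tolerance = 1e-12)
  expect_equal(cv$mean_r, mean(per_fold), tolerance = 1e-12)
})

test_that("dip contrasts isolate the trough and its flanks", {
  expect_equal(unname(dip_contrasts(rep(0, 8))), rep(0, 4))
  u <- c(0.02, 0.01, -0.02, 0.13, -0.09, -0.09, 0.0, 0.15)
  dc <- dip_contrasts(u)
  expect_lt(dc[["level5"]], 0)
  expect_lt(dc[["level6"]], 0)
  expect_gt(dc[["level4_minus_trough"]], 0)
  expect_gt(dc[["level8_minus_trough"]], 0)
  # arithmetic oracle
  expect_equal(dc[["level4_minus_trough"]], u[4] - mean(u[5:6]))
  expect_equal(dc[["level8_minus_trough"]], u[8] - mean(u[5:6]))
})

test_that("the resampling statistic agrees with direct curve computation", {
  spec <- sim_spec(n_participants = 5, n_voxels = 80, seed = 12)
  ps <- synthetic_patterns(spec)
  direct <- loo_cv(nmphtools:::change_curves(ps))$mean_r
  expect_equal(nmph_cv_stat(unclass(ps)), direct, tolerance = 1e-12)
  # under a permutation, equals the lookup-table recomputation
  perm <- c(3, 1, 2, 5, 4, 7, 8, 6)
  tabs <- lapply(ps, cross_cor_tables)
  curves_lu <- t(vapply(tabs, function(tb)
    tb$post[cbind(1:8, perm)] - tb$pre[cbind(1:8, perm)], numeric(8)))
  expect_equal(nmph_cv_stat(unclass(ps), perm), loo_cv(curves_lu)$mean_r,
               tolerance = 1e-12)
})
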