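test_that("the GLM solves a tiny problem identically to hand-written normal equations", {
  run <- manual_run(onsets = c(0, 3), tr = 1, n_volumes = 3)
  X <- cbind(design_matrix(run, 1), 1)
  y <- c(0.2, 1.1, 0.4)
  beta_hand <- solve(t(X) %*% X, t(X) %*% y)
  est <- fit_glm(matrix(y, 1, 3), run, n_images = 1)
  expect_equal(est[1, 1], beta_hand[1], tolerance = 1e-10)
  # all-zero series -> all-zero betas
  run2 <- generate_run("templating", seed = 1)
  z <- fit_glm(matrix(0, 3, 203), run2)
  expect_true(all(z == 0))
  # an image that never occurs gives an all-zero regressor -> singular
  bad <- manual_run(onsets = c(6, 10), n_volumes = 30, image_ids = 1L)
  expect_error(fit_glm(matrix(rnorm(30), 1, 30), bad, n_images = 16),
               "singular")
})

test_that("pairmate similarity matches the Pearson formula and flags degenerate input", {
  V <- 400
  set.seed(1)
  pat <- matrix(rnorm(16 * V), 16, V)
  pat[2, ] <- pat[1, ]  # pair 1: identical
  prof <- pairmate_similarity(pat)
  expect_equal(prof[1], 1)
  expect_true(all(abs(prof[-1]) < 2 / sqrt(V) * 2))
  # covariance / (sd * sd) oracle on pair 3
  a <- pat[5, ]; b <- pat[6, ]
  r_hand <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(prof[3], r_hand, tolerance = 1e-12)
  pat[4, ] <- 0
  expect_error(pairmate_similarity(pat), "image 4")
})

test_that("correspondence is the Fisher-transformed second-order correlation", {
  prof <- seq(0.1, 0.8, length.out = 8)
  expect_warning(z <- correspondence(prof), "clamped")
  expect_equal(z, atanh(1 - 1e-7))  # clamped rather than infinite
  expect_message(z0 <- correspondence(rep(0.3, 8)), "zero-variance")
  expect_true(is.na(z0))
  prof2 <- c(0.1, 0.5, 0.2, 0.6, 0.3, 0.4, 0.7, 0.65)
  expect_equal(correspondence(prof2), atanh(cor(1:8, prof2)))
})

test_that("representational change subtracts pre from post with the stated sign convention", {
  pre <- structure(rep(0.4, 8), class = "similarity_profile")
  post <- structure(rep(0.4, 8), class = "similarity_profile")
  expect_equal(representational_change(pre, post), rep(0, 8))
  post2 <- structure(rep(0.5, 8), class = "similarity_profile")
  expect_equal(representational_change(pre, post2), rep(0.1, 8))
  # differentiation (pairmates grow apart) is negative
  post3 <- structure(rep(0.1, 8), class = "similarity_profile")
  expect_true(all(representational_change(pre, post3) < 0))
  expect_error(representational_change(pre[1:4], post), "consistency")
})

test_that("arrangement analysis computes hand-checkable geometry", {
  # one participant, one trial, two pairs placed by hand
  pl <- data.frame(participant = 1, trial = 1, image_id = c(1, 2, 3, 4),
                   x = c(0, 3, 0, 5), y = c(0, 4, 1, 13))
  res <- arrangement_analysis(pl, pairing = default_pairing(2), levels = 1:2)
  expect_equal(res$distances[1, ], c(5, 13))  # 3-4-5 and 5-12-13 triangles
  # distances exactly 9 - level give a perfect negative correlation
  pl2 <- do.call(rbind, lapply(1:8, function(p)
    data.frame(participant = 1, trial = 1, image_id = c(2 * p - 1, 2 * p),
               x = c(0, 9 - p), y = 0)))
  res2 <- arrangement_analysis(pl2)
  expect_equal(res2$participant_r[1], -1)
  # all images at one point: degenerate, reported as NA
  pl3 <- data.frame(participant = 1, trial = 1, image_id = 1:16, x = 0, y = 0)
  res3 <- arrangement_analysis(pl3)
  expect_true(is.na(res3$group_r))
  # a pair never co-presented errors out
  expect_error(arrangement_analysis(pl3[-2, ]), "missing-pair")
})

test_that("bootstrap CIs degenerate correctly and match exhaustive enumeration", {
  same <- rep(list(3.5), 6)
  res <- bootstrap_ci(function(x) mean(unlist(x)), same, n_boot = 200, seed = 1)
  expect_equal(res$ci_low, 3.5)
  expect_equal(res$ci_high, 3.5)
  # n = 3: enumerate all 27 equally likely ordered resamples exactly; the
  # inverse-ECDF quantiles of that atom distribution are the exact bounds
  vals <- list(0, 1, 5)
  enum <- apply(expand.grid(1:3, 1:3, 1:3), 1, function(idx)
    mean(unlist(vals[idx])))
  exact <- quantile(enum, c(0.025, 0.975), names = FALSE, type = 1)
  res3 <- bootstrap_ci(function(x) mean(unlist(x)), vals, n_boot = 20000,
                       seed = 2)
  expect_equal(res3$ci_low, exact[1], tolerance = 1e-9)
  expect_equal(res3$ci_high, exact[2], tolerance = 1e-9)
  expect_error(bootstrap_ci(mean, list(1), n_boot = 10), "2 participants")
})

test_that("failed bootstrap resamples are excluded and counted", {
  inputs <- list(1, 2, 3, 4, 6)  # full-sample sum 16: observed stat succeeds
  flaky <- function(x) {
    if (sum(unlist(x)) %% 5 == 0) stop("bad resample")
    mean(unlist(x))
  }
  res <- suppressWarnings(bootstrap_ci(flaky, inputs, n_boot = 300, seed = 3))
  expect_gt(res$n_failed, 0)
  expect_false(is.na(res$ci_low))
})

test_that("the re-pairing null includes the identity pairing at the expected rate", {
  draws <- nmphtools:::with_seed(11, replicate(40000, sample.int(5)))
  n_id <- sum(colSums(draws == 1:5) == 5)
  p_id <- 1 / factorial(5)  # 1/120
  expect_lt(abs(n_id / 40000 - p_id),
            4 * sqrt(p_id * (1 - p_id) / 40000))
  # add-one p-value rule
  obs_stat <- function(inputs, perm) if (is.null(perm)) 10 else 0
  res <- shuffle_null(obs_stat, list(1, 2), n_pairs = 8, n_perm = 99, seed = 1)
  expect_equal(res$p, 1 / 100)
})

test_that("searchlights match brute-force neighbourhood enumeration", {
  d <- c(6, 6, 6)
  set.seed(2)
  vol <- array(rnorm(prod(d) * 16), c(d, 16))
  mask <- array(TRUE, d)
  mask[1, , ] <- FALSE
  stat_n <- function(pat) ncol(pat)  # statistic = neighbourhood size
  map <- searchlight_map(vol, mask, stat_n, radius = 2, fisher = FALSE)
  # corner voxel (2,1,1): brute-force cube [1..4]x[1..3]x[1..3] minus the
  # masked x = 1 plane -> 3*3*3 = 27 voxels
  expect_equal(map[2, 1, 1], 27)
  # interior voxel (4,4,4): cube spans x 2:6, clear of the masked plane
  expect_equal(map[4, 4, 4], 125)
  # radius 0 equals the direct per-voxel statistic
  stat_m <- function(pat) mean(pat)
  map0 <- searchlight_map(vol, mask, stat_m, radius = 0, fisher = FALSE)
  expect_equal(map0[3, 3, 3], mean(vol[3, 3, 3, ]))
  # homogeneous volume: constant map away from edges
  vol1 <- array(rep(rnorm(16), each = prod(d)), c(d, 16))
  mapc <- searchlight_map(vol1, array(TRUE, d), stat_m, radius = 1,
                          fisher = FALSE)
  inner <- mapc[2:5, 2:5, 2:5]
  expect_lt(diff(range(inner)), 1e-12)
  expect_error(searchlight_map(vol, array(FALSE, d), stat_m), "empty")
})
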