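test_that("intended schedule is linear from 0 to 1", {
  s <- intended_schedule(8)
  expect_equal(s[1], 0)
  expect_equal(s[8], 1)
  expect_equal(round(s[2], 2), 0.14)  # 1/7
  expect_true(all(diff(s) > 0))
  expect_equal(intended_schedule(2), c(0, 1))
  expect_error(intended_schedule(1), "config error")
})

test_that("laplacian pyramid reconstructs exactly and damps high frequencies", {
  x <- array(rnorm(24 * 24 * 3), c(24, 24, 3))
  bands <- nmphtools:::laplacian_pyramid(x, 3)
  expect_equal(nmphtools:::pyramid_reconstruct(bands), x, tolerance = 1e-6)
  # single band: output proportional to input
  y1 <- laplacian_regularize(x, 1)
  expect_equal(cor(as.vector(y1), as.vector(x)), 1, tolerance = 1e-12)
  # white noise: high-frequency band energy fraction must drop
  frac_hf <- function(z) {
    b <- nmphtools:::laplacian_pyramid(z, 3)
    sum(b[[1]]^2) / sum(vapply(b, function(v) sum(v^2), numeric(1)))
  }
  y <- laplacian_regularize(x, 3)
  expect_lt(frac_hf(y), frac_hf(x))
  expect_warning(laplacian_regularize(array(rnorm(12), c(2, 2, 3)), 5),
                 "pyramid levels")
})

test_that("channel optimization ascends; zero iterations is the identity", {
  ext <- tiny_extractor(1)
  spec <- tiny_spec()
  act0 <- mean(array(extract_features(ext, noise_image(16, 16, spec$seed),
                                      "conv2", center = FALSE)$conv2,
                     c(8, 8, 5))[, , 2])
  img <- channel_image(ext, "conv2", 2, iters = 30, spec)
  act1 <- mean(array(extract_features(ext, img, "conv2",
                                      center = FALSE)$conv2, c(8, 8, 5))[, , 2])
  expect_gt(act1, act0)
  img0 <- channel_image(ext, "conv2", 2, iters = 0, spec)
  expect_identical(img0$pixels, noise_image(16, 16, spec$seed)$pixels)
  expect_error(channel_image(ext, "conv2", 99, 5, spec), "invalid")
})

test_that("a monotone objective with an averaging kernel drives pixels to the box maximum", {
  # with an all-positive averaging kernel and a monotone nonlinearity the
  # constrained maximizer of the channel mean is the all-ones image
  ext <- tiny_extractor(5, channels = c(1, 1))
  ext$weights[[1]][] <- 1 / 9
  ext$biases[[1]] <- 0
  spec <- tiny_spec(image_size = 8, step_size = 0.2, pyramid_levels = 1)
  img <- channel_image(ext, "conv1", 1, iters = 200, spec, seed = 2)
  expect_gt(mean(img$pixels), 0.95)
})

test_that("endpoint selection matches exhaustive search and avoids duplicates", {
  ext <- tiny_extractor(3)
  spec <- tiny_spec()
  imgs <- lapply(1:4, function(i) noise_image(16, 16, i))
  sel <- select_endpoints(imgs, ext, k = 2)
  expect_equal(nrow(sel), 1L)
  # oracle: all 6 pairs, minimal |r|
  feats <- sapply(imgs, function(im)
    unlist(extract_features(ext, im, target_taps(ext)), use.names = FALSE))
  rm_ <- abs(cor(feats))
  combos <- combn(4, 2)
  best <- combos[, which.min(rm_[t(combos)])]
  expect_setequal(c(sel$channel_a, sel$channel_b), best)
  # a duplicated image is never paired with itself
  imgs2 <- c(imgs[1:3], imgs[1])
  sel2 <- select_endpoints(imgs2, ext, k = 2)
  expect_false(setequal(c(sel2$channel_a, sel2$channel_b), c(1, 4)))
  expect_error(select_endpoints(imgs, ext, k = 8), "config error")
  expect_error(select_endpoints(imgs, ext, k = 3), "even")
  # full-scale bookkeeping: k = 16 yields 8 pairs
  expect_equal(16L %/% 2L, 8L)
})

test_that("pair initialization respects weights and symmetry", {
  ext <- tiny_extractor(1)
  spec <- tiny_spec(init_iters = 8)
  ep <- data.frame(layer_id = "conv2", channel_a = 1, channel_b = 3)
  expect_error(initialize_pair(ext, ep, 2, "A", spec), "weight")
  # weight 1: A and B objectives coincide, so same seed gives same image
  a <- initialize_pair(ext, ep, 1, "A", spec, seed = 9)
  b <- initialize_pair(ext, ep, 1, "B", spec, seed = 9)
  expect_identical(a$pixels, b$pixels)
  # first trace entry equals an independent recomputation of the objective
  w <- 0.4
  a2 <- initialize_pair(ext, ep, w, "A", spec, seed = 9)
  tr <- attr(a2, "trace")
  f0 <- array(extract_features(ext, noise_image(16, 16, 9), "conv2",
                               center = FALSE)$conv2, c(8, 8, 5))
  expect_equal(tr[1], mean(f0[, , 1]) + w * mean(f0[, , 3]), tolerance = 1e-12)
})

test_that("correlation tuning reaches targets and honours its invariants", {
  ext <- tiny_extractor(1)
  spec <- tiny_spec()
  a <- noise_image(16, 16, 1)
  b <- noise_image(16, 16, 2)
  # already-converged: targets equal to current achieved -> no movement
  cur <- nmphtools:::pair_correlations(ext, a, b, c("conv1", "conv2"))
  p0 <- tune_pair(ext, a, b, cur, tune_iters = 5, spec)
  expect_equal(p0$cost_trace[1], 0, tolerance = 1e-12)
  expect_identical(p0$image_a$pixels, a$pixels)
  # identical images with all-1 targets: zero cost at every layer
  p1 <- tune_pair(ext, a, a, c(conv1 = 1, conv2 = 1), tune_iters = 2, spec)
  expect_equal(p1$cost_trace[1], 0, tolerance = 1e-12)
  # achieved values equal an independent from-scratch recomputation
  p2 <- tune_pair(ext, a, b, c(conv1 = 0.25, conv2 = 0.5),
                  tune_iters = 60, spec)
  fa <- extract_features(ext, p2$image_a)
  fb <- extract_features(ext, p2$image_b)
  expect_equal(p2$achieved[["conv1"]], cor(fa$conv1, fb$conv1),
               tolerance = 1e-6)
  expect_equal(p2$achieved[["conv2"]], cor(fa$conv2, fb$conv2),
               tolerance = 1e-6)
  # best-so-far cost trace is non-increasing and ends at or below the start
  expect_true(all(diff(p2$cost_trace) <= 0))
  expect_lte(tail(p2$cost_trace, 1), p2$cost_trace[1])
  # a dead tap (all-zero weights) has constant activations -> named error
  ext0 <- tiny_extractor(1)
  ext0$weights[[2]][] <- 0
  ext0$biases[[2]][] <- 0
  expect_error(tune_pair(ext0, a, b, c(conv2 = 0.5), 2, spec), "conv2")
})

test_that("multi-scale synthesis collapses to init + tune with a degenerate schedule", {
  ext <- tiny_extractor(1)
  spec <- tiny_spec(init_iters = 6, tune_iters = 6)
  ep <- data.frame(layer_id = "conv2", channel_a = 1, channel_b = 3)
  pair <- multiscale_synthesize(ext, ep, level = 2,
                                spec = synthesis_spec(
                                  n_levels = 2, image_size = 16,
                                  init_iters = 6, tune_iters = 6,
                                  volleys = 1, window_fraction = 1,
                                  crop_quantile = 0, pyramid_levels = 2,
                                  seed = 7))
  seed <- nmphtools:::derive_seed(7, 2)
  t_level <- 1
  a <- initialize_pair(ext, ep, t_level, "A", spec,
                       seed = nmphtools:::derive_seed(seed, 1))
  b <- initialize_pair(ext, ep, t_level, "B", spec,
                       seed = nmphtools:::derive_seed(seed, 2))
  ref <- tune_pair(ext, a, b,
                   c(conv1 = 0.25, conv2 = t_level), 6, spec)
  expect_identical(pair$image_a$pixels, ref$image_a$pixels)
  expect_identical(pair$image_b$pixels, ref$image_b$pixels)
})

test_that("volleys magnify by 40% with half-up rounding", {
  ext <- tiny_extractor(1)
  spec <- synthesis_spec(n_levels = 2, image_size = 32, init_iters = 2,
                         tune_iters = 2, volleys = 3, magnification = 1.4,
                         window_fraction = 0.9, crop_quantile = 0,
                         pyramid_levels = 2, seed = 3)
  pair <- multiscale_synthesize(ext, data.frame(layer_id = "conv2",
                                                channel_a = 1, channel_b = 2),
                                level = 1, spec)
  # 32 -> 45 -> 63 under round-half-up
  expect_equal(dim(pair$image_a$pixels)[1:2], c(63, 63))
  expect_equal(nmphtools:::round_half_up(32 * 1.4), 45)
  expect_equal(nmphtools:::round_half_up(44.8 * 1.4), 63)
})

test_that("moving window updates central pixels at least as often as corners", {
  ext <- tiny_extractor(1)
  spec <- synthesis_spec(n_levels = 2, image_size = 16, init_iters = 10,
                         tune_iters = 10, volleys = 1, window_fraction = 0.6,
                         crop_quantile = 0, pyramid_levels = 2, seed = 5)
  pair <- multiscale_synthesize(ext, data.frame(layer_id = "conv2",
                                                channel_a = 1, channel_b = 2),
                                level = 1, spec)
  counts <- pair$image_a$iter_count + pair$image_b$iter_count
  centre <- counts[8, 8]
  corners <- c(counts[1, 1], counts[1, 16], counts[16, 1], counts[16, 16])
  expect_true(all(centre >= corners))
  # brute-force coverage bound: a window of side ceil(0.6*16)=10 always
  # contains the centre, so the centre count equals the total update count
  expect_equal(centre, max(counts))
})

test_that("cropping peels low-count borders and rejects over-cropping", {
  counts <- matrix(10, 20, 20)
  counts[1:3, ] <- 0
  counts[, 19:20] <- 0
  cr <- nmphtools:::crop_by_counts(counts, 0.2)
  expect_equal(cr$rows, 4:20)
  expect_equal(cr$cols, 1:18)
  spiky <- outer(dnorm(1:20, 10.5, 2), dnorm(1:20, 10.5, 2))
  expect_error(nmphtools:::crop_by_counts(spiky, 0.9), "over-crop")
})

test_that("a full grid yields the expected image count and is reproducible", {
  ext <- tiny_extractor(2, channels = c(3, 16))
  spec <- synthesis_spec(n_levels = 8, image_size = 16, init_iters = 1,
                         tune_iters = 1, volleys = 1, window_fraction = 1,
                         crop_quantile = 0, pyramid_levels = 2, seed = 11)
  eps <- data.frame(layer_id = "conv2",
                    channel_a = c(1, 3, 5, 7, 9, 11, 13, 15),
                    channel_b = c(2, 4, 6, 8, 10, 12, 14, 16))
  set1 <- synthesize_set(ext, eps, spec)
  expect_equal(n_images(set1), 128L)
  set2 <- synthesize_set(ext, eps, spec)
  expect_identical(set1$pairs[[3, 5]]$image_a$pixels,
                   set2$pairs[[3, 5]]$image_a$pixels)
  rep <- validate_set(set1, ext)
  expect_equal(nrow(rep$achieved), 64L)
  # second-order statistic equals a by-hand Pearson on the report columns
  expect_equal(rep$second_order[["conv2"]],
               cor(rep$achieved$intended, rep$achieved$conv2))
  # constant achieved values at a tap are reported as NA
  degen <- set1
  for (e in 1:8) for (l in 1:8) {
    degen$pairs[[e, l]]$image_a <- set1$pairs[[1, 1]]$image_a
    degen$pairs[[e, l]]$image_b <- set1$pairs[[1, 1]]$image_b
  }
  rep2 <- validate_set(degen, ext)
  expect_true(is.na(rep2$second_order[["conv2"]]))
})
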