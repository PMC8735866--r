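#' Linearly spaced intended-correlation schedule
#'
#' Similarity levels 1..n map to intended target-layer feature correlations
#' spaced evenly from 0 (unrelated) to 1 (almost identical).
#'
#' @param n_levels number of similarity levels (>= 2); default 8.
#' @return numeric vector of length `n_levels`, strictly increasing, first 0,
#'   last 1.
#' @export
intended_schedule <- function(n_levels = 8L) {
  if (n_levels < 2L) stopf("config error: n_levels must be >= 2")
  seq(0, 1, length.out = n_levels)
}

#' Synthesis configuration
#'
#' Collects every tunable of the image-pair synthesis loop: the similarity
#' schedule, the fixed inter-image correlation target for constrained
#' (lower/middle) layers, per-phase iteration counts, the multi-scale volley
#' schedule, the moving-window fraction, the final iteration-count crop, and
#' the optimizer step.
#'
#' @param n_levels number of similarity levels.
#' @param schedule intended target-layer correlation per level; default
#'   linear 0..1.
#' @param constrained_target fixed correlation target for constrained taps.
#' @param init_iters,tune_iters iterations of the weighted-channel
#'   initialization and correlation-tuning phases (per volley).
#' @param volleys number of multi-scale volleys (image magnified between).
#' @param magnification scale factor applied between volleys (> 1).
#' @param window_fraction side of the moving gradient window relative to the
#'   image side, in (0, 1].
#' @param crop_quantile quantile of per-row/column update counts below which
#'   boundary rows/columns are cropped after synthesis; 0 disables cropping.
#' @param step_size gradient step (applied after normalizing the regularized
#'   gradient to unit mean absolute value).
#' @param pyramid_levels Laplacian-pyramid bands for gradient regularization.
#' @param image_size starting image side in pixels.
#' @param seed master seed; all per-pair seeds derive from it.
#' @return object of class `synthesis_spec`.
#' @export
synthesis_spec <- function(n_levels = 8L, schedule = intended_schedule(n_levels),
                           constrained_target = 0.25,
                           init_iters = 200L, tune_iters = 200L,
                           volleys = 3L, magnification = 1.4,
                           window_fraction = 0.9, crop_quantile = 0.1,
                           step_size = 0.05, pyramid_levels = 3L,
                           image_size = 64L, seed = 1L) {
  if (length(schedule) != n_levels || any(diff(schedule) <= 0) ||
      abs(schedule[1]) > 1e-12 || abs(schedule[n_levels] - 1) > 1e-12)
    stopf("schedule must increase strictly from 0 to 1 over n_levels")
  if (volleys < 1L) stopf("volleys must be >= 1")
  if (magnification <= 1) stopf("magnification must be > 1")
  if (window_fraction <= 0 || window_fraction > 1)
    stopf("window_fraction must be in (0, 1]")
  if (crop_quantile < 0 || crop_quantile >= 1)
    stopf("crop_quantile must be in [0, 1)")
  if (step_size <= 0) stopf("step_size must be positive")
  structure(list(n_levels = as.integer(n_levels), schedule = schedule,
                 constrained_target = constrained_target,
                 init_iters = as.integer(init_iters),
                 tune_iters = as.integer(tune_iters),
                 volleys = as.integer(volleys), magnification = magnification,
                 window_fraction = window_fraction,
                 crop_quantile = crop_quantile, step_size = step_size,
                 pyramid_levels = as.integer(pyramid_levels),
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "synthesis_spec")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Draw a square moving window (side = ceil(fraction * min side)) uniformly
# inside the image; NULL when the window covers the whole image.
draw_window <- function(height, width, fraction) {
  side_h <- ceiling(fraction * height)
  side_w <- ceiling(fraction * width)
  if (side_h >= height && side_w >= width) return(NULL)
  top <- sample.int(height - side_h + 1L, 1L)
  left <- sample.int(width - side_w + 1L, 1L)
  list(rows = top:(top + side_h - 1L), cols = left:(left + side_w - 1L))
}

# One regularized, normalized, windowed gradient step on a synth_image.
# direction +1 ascends, -1 descends; step_scale shrinks the step (used by
# correlation tuning, where the step is proportional to the remaining
# error). Updates iter_count inside the window.
gradient_step <- function(image, grad, spec, direction, window = NULL,
                          step_scale = 1) {
  g <- suppressWarnings(laplacian_regularize(grad, spec$pyramid_levels))
  scale <- mean(abs(g))
  if (scale > 0) g <- g / scale
  g <- g * step_scale
  if (!is.null(window)) {
    mask <- array(0, dim(g))
    mask[window$rows, window$cols, ] <- 1
    g <- g * mask
    image$iter_count[window$rows, window$cols] <-
      image$iter_count[window$rows, window$cols] + 1L
  } else {
    image$iter_count <- image$iter_count + 1L
  }
  image$pixels <- clip01(image$pixels + direction * spec$step_size * g)
  image
}

# Upstream tap gradient selecting the mean activation of one or more
# channels of a layer, each with its own weight.
channel_mean_grad <- function(dims, weights_by_channel) {
  g <- array(0, dims)
  hw <- dims[1] * dims[2]
  for (ch in names(weights_by_channel))
    g[, , as.integer(ch)] <- weights_by_channel[[ch]] / hw
  as.vector(g)
}

channel_mean_value <- function(act_array, weights_by_channel) {
  v <- 0
  for (ch in names(weights_by_channel))
    v <- v + weights_by_channel[[ch]] * mean(act_array[, , as.integer(ch)])
  v
}

# Core weighted-channel ascent shared by channel_image and initialize_pair.
ascend_channels <- function(extractor, layer_id, weights_by_channel, iters,
                            spec, image, window_fn = NULL) {
  k <- match(layer_id, extractor$taps$layer_id)
  if (is.na(k)) stopf("tap not found: %s", layer_id)
  best <- image
  best_val <- -Inf
  flat_run <- 0L
  trace <- numeric(0)
  for (it in seq_len(iters)) {
    fw <- extractor_forward(extractor, image)
    dims <- dim(fw$a[[k]])
    val <- channel_mean_value(fw$a[[k]], weights_by_channel)
    trace <- c(trace, val)
    if (val > best_val) { best_val <- val; best <- image }
    tg <- list()
    tg[[layer_id]] <- channel_mean_grad(dims, weights_by_channel)
    grad <- extractor_gradient(extractor, image, tg, forward = fw)
    if (mean(abs(grad)) < 1e-12) {
      flat_run <- flat_run + 1L
      if (flat_run >= 10L) {
        warning("flat objective for 10 consecutive iterations; returning best-so-far")
        return(structure(best, trace = trace))
      }
    } else flat_run <- 0L
    window <- if (is.null(window_fn)) NULL else window_fn(it)
    image <- gradient_step(image, grad, spec, direction = +1, window = window)
  }
  # keep the final image (counts reflect every iteration) unless ascent
  # stalled; the post-step image is what downstream phases consume
  structure(image, trace = trace)
}

#' Maximize a single feature channel
#'
#' Gradient-ascends a seeded noise image (or a supplied starting image) so
#' that the mean activation of one channel of one layer is maximized, with
#' Laplacian-pyramid gradient regularization. This is the classic
#' activation-maximization step used to visualize what a channel encodes;
#' here it produces the candidate endpoint images.
#'
#' @param extractor a `feature_extractor`.
#' @param layer_id tap to optimize.
#' @param channel channel index within the tap.
#' @param iters iterations; 0 returns the starting image unchanged.
#' @param spec a `synthesis_spec`.
#' @param start optional starting `synth_image`; default seeded noise.
#' @param seed seed for the starting noise.
#' @return optimized `synth_image`.
#' @export
channel_image <- function(extractor, layer_id, channel, iters, spec,
                          start = NULL, seed = spec$seed) {
  k <- match(layer_id, extractor$taps$layer_id)
  if (is.na(k)) stopf("tap not found: %s", layer_id)
  if (channel < 1L || channel > extractor$taps$n_channels[k])
    stopf("channel %d invalid for %s", channel, layer_id)
  if (is.null(start))
    start <- noise_image(spec$image_size, spec$image_size, seed)
  if (iters < 1L) return(start)
  w <- list(); w[[as.character(channel)]] <- 1
  ascend_channels(extractor, layer_id, w, iters, spec, start)
}

#' Select maximally decorrelated endpoint channel pairs
#'
#' Feeds the optimized channel images back through the extractor, correlates
#' their activation patterns at the target taps, keeps the `k` images whose
#' patterns are least inter-correlated, and pairs the survivors into k/2
#' endpoint pairs (most-decorrelated disjoint pairs first). Subset selection
#' is exhaustive whenever the number of candidate subsets is small enough to
#' enumerate, and greedy backward elimination (repeatedly dropping the image
#' with the largest mean absolute correlation to the rest) otherwise.
#'
#' @param channel_images list of `synth_image`s, one per candidate channel.
#' @param extractor a `feature_extractor`.
#' @param taps taps over which patterns are correlated; default target taps.
#' @param k number of survivors (even); default 16.
#' @param channels channel index of each candidate; default 1..n.
#' @param layer_id layer the channels belong to; default deepest target tap.
#' @return data frame with columns `layer_id`, `channel_a`, `channel_b`, one
#'   row per endpoint pair, plus attribute `selected` (surviving channels).
#' @export
select_endpoints <- function(channel_images, extractor,
                             taps = target_taps(extractor), k = 16L,
                             channels = seq_along(channel_images),
                             layer_id = tail(target_taps(extractor), 1L)) {
  n <- length(channel_images)
  if (k > n) stopf("config error: k = %d exceeds %d candidate images", k, n)
  if (k %% 2L != 0L) stopf("config error: k must be even")
  feats <- vapply(channel_images, function(im)
    unlist(extract_features(extractor, im, taps), use.names = FALSE),
    numeric(length(unlist(extract_features(extractor, channel_images[[1]], taps)))))
  rmat <- abs(cor(feats))
  diag(rmat) <- 0
  n_subsets <- choose(n, k)
  if (is.finite(n_subsets) && n_subsets <= 10000) {
    combos <- utils::combn(n, k)
    totals <- apply(combos, 2, function(idx) sum(rmat[idx, idx]) / 2)
    keep <- combos[, which.min(totals)]
  } else {
    keep <- seq_len(n)
    while (length(keep) > k) {
      sub <- rmat[keep, keep, drop = FALSE]
      worst <- which.max(rowMeans(sub))
      keep <- keep[-worst]
    }
  }
  # pair survivors: sweep all within-survivor pairs by |r| ascending,
  # greedily taking disjoint ones
  pairs_idx <- utils::combn(keep, 2)
  ord <- order(rmat[t(pairs_idx)])
  used <- integer(0)
  out <- list()
  for (p in ord) {
    a <- pairs_idx[1, p]; b <- pairs_idx[2, p]
    if (a %in% used || b %in% used) next
    out[[length(out) + 1L]] <- c(a, b)
    used <- c(used, a, b)
    if (length(out) == k %/% 2L) break
  }
  res <- data.frame(
    layer_id = layer_id,
    channel_a = channels[vapply(out, `[`, integer(1), 1L)],
    channel_b = channels[vapply(out, `[`, integer(1), 2L)]
  )
  attr(res, "selected") <- channels[keep]
  res
}

#' Weighted-channel pair initialization
#'
#' Optimizes one image of a pair toward its own endpoint channel at full
#' weight plus the pairmate's endpoint channel at weight `weight` (the
#' intended correlation), the summed objective driving gradient ascent.
#'
#' @param extractor a `feature_extractor`.
#' @param endpoint one row of the `select_endpoints` result (or a list with
#'   `layer_id`, `channel_a`, `channel_b`).
#' @param weight pairmate-channel weight in \[0, 1\].
#' @param which `"A"` (own channel = `channel_a`) or `"B"`.
#' @param spec a `synthesis_spec`.
#' @param seed seed for the starting noise.
#' @param start optional starting image; default seeded noise.
#' @param iters iteration count; default `spec$init_iters`.
#' @param window_fn optional function(iteration) returning a moving window.
#' @return optimized `synth_image`.
#' @export
initialize_pair <- function(extractor, endpoint, weight, which = c("A", "B"),
                            spec, seed = spec$seed, start = NULL,
                            iters = spec$init_iters, window_fn = NULL) {
  which <- match.arg(which)
  if (weight < 0 || weight > 1) stopf("weight must lie in [0, 1]")
  own <- if (which == "A") endpoint$channel_a else endpoint$channel_b
  other <- if (which == "A") endpoint$channel_b else endpoint$channel_a
  w <- list()
  w[[as.character(own)]] <- 1
  if (weight > 0 && other != own)
    w[[as.character(other)]] <- weight
  if (is.null(start))
    start <- noise_image(spec$image_size, spec$image_size, seed)
  if (iters < 1L) return(start)
  ascend_channels(extractor, endpoint$layer_id, w, iters, spec, start,
                  window_fn = window_fn)
}

# d Pearson r(a, b) / d a, holding b fixed
cor_grad <- function(a, b) {
  ac <- a - mean(a); bc <- b - mean(b)
  na <- sqrt(sum(ac^2)); nb <- sqrt(sum(bc^2))
  r <- sum(ac * bc) / (na * nb)
  g <- bc / (na * nb) - r * ac / na^2
  # account for the centring of a: d mean / d a_i terms cancel because both
  # bc and ac are zero-mean, so g is already the full gradient
  list(r = r, grad = g)
}

pair_correlations <- function(extractor, image_a, image_b, taps) {
  fa <- extract_features(extractor, image_a, taps)
  fb <- extract_features(extractor, image_b, taps)
  vapply(taps, function(l) safe_cor(fa[[l]], fb[[l]], what = l), numeric(1))
}

#' Correlation tuning of an image pair
#'
#' Alternately updates images A and B by gradient descent on the summed
#' squared deviation of the pair's per-layer feature correlations from their
#' targets: constrained taps are driven to the fixed constrained target and
#' target taps to the level's scheduled value. Best-so-far images are
#' tracked, so the returned pair's total cost never exceeds the initial one.
#'
#' @param extractor a `feature_extractor`.
#' @param image_a,image_b `synth_image`s from the initialization phase.
#' @param targets named numeric vector or list, layer_id -> intended r; must
#'   cover every constrained and target tap being tuned.
#' @param tune_iters iterations; default `spec$tune_iters`.
#' @param spec a `synthesis_spec`.
#' @param window_fn optional function(iteration) returning a moving window.
#' @return list of class `synthesized_pair`: `image_a`, `image_b`,
#'   `intended`, `achieved` (named per-layer r of the returned images),
#'   `cost_trace`.
#' @export
tune_pair <- function(extractor, image_a, image_b, targets,
                      tune_iters = spec$tune_iters, spec, window_fn = NULL) {
  taps <- names(targets)
  unknown <- setdiff(taps, extractor$taps$layer_id)
  if (length(unknown)) stopf("tap not found: %s", paste(unknown, collapse = ", "))
  targets <- unlist(targets)[taps]
  best_cost <- Inf
  best <- list(a = image_a, b = image_b)
  trace <- numeric(0)
  d_ab <- dim(as_pixels(image_a))
  base <- extractor_baseline(extractor, d_ab[1], d_ab[2])
  for (it in seq_len(tune_iters + 1L)) {
    fwa <- extractor_forward(extractor, image_a)
    fwb <- extractor_forward(extractor, image_b)
    ks <- match(taps, extractor$taps$layer_id)
    cg <- vector("list", length(taps)); names(cg) <- taps
    cost <- 0
    for (i in seq_along(taps)) {
      a <- as.vector(fwa$a[[ks[i]]] - base[[ks[i]]])
      b <- as.vector(fwb$a[[ks[i]]] - base[[ks[i]]])
      if (sd(a) == 0 || sd(b) == 0)
        stopf("undefined correlation: zero-variance activation vector (%s)", taps[i])
      update_a <- it %% 2L == 1L
      cg[[i]] <- if (update_a) cor_grad(a, b) else cor_grad(b, a)
      cost <- cost + (cg[[i]]$r - targets[[i]])^2
    }
    trace <- c(trace, unname(cost))
    if (cost < best_cost) {
      best_cost <- cost
      best <- list(a = image_a, b = image_b)
    }
    if (it > tune_iters) break
    update_a <- it %% 2L == 1L
    tg <- list()
    for (i in seq_along(taps)) {
      dims <- dim(if (update_a) fwa$a[[ks[i]]] else fwb$a[[ks[i]]])
      tg[[taps[i]]] <- 2 * (cg[[i]]$r - targets[i]) * cg[[i]]$grad
    }
    window <- if (is.null(window_fn)) NULL else window_fn(it)
    err_scale <- min(1, sum(abs(vapply(seq_along(taps), function(i)
      cg[[i]]$r - targets[i], numeric(1)))))
    if (update_a) {
      grad <- extractor_gradient(extractor, image_a, tg, forward = fwa)
      image_a <- gradient_step(image_a, grad, spec, direction = -1,
                               window = window, step_scale = err_scale)
    } else {
      grad <- extractor_gradient(extractor, image_b, tg, forward = fwb)
      image_b <- gradient_step(image_b, grad, spec, direction = -1,
                               window = window, step_scale = err_scale)
    }
  }
  achieved <- pair_correlations(extractor, best$a, best$b, taps)
  # cost_trace tracks the best-so-far objective (non-increasing by
  # construction); the raw per-iteration costs ride along as an attribute
  structure(list(image_a = best$a, image_b = best$b,
                 intended = targets, achieved = achieved,
                 cost_trace = structure(cummin(trace), raw = trace)),
            class = "synthesized_pair")
}

#' @export
print.synthesized_pair <- function(x, ...) {
  cat("<synthesized_pair>\n")
  if (!is.null(x$level)) cat(sprintf("  level: %d\n", x$level))
  cat("  achieved r:\n")
  for (l in names(x$achieved))
    cat(sprintf("    %s: %.3f (intended %.3f)\n", l, x$achieved[[l]],
                x$intended[[l]]))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

# Peel boundary rows/columns whose mean update count falls below the given
# quantile of the per-row / per-column count distribution.
crop_by_counts <- function(counts, crop_quantile) {
  if (crop_quantile <= 0) return(list(rows = seq_len(nrow(counts)),
                                      cols = seq_len(ncol(counts))))
  rm_ <- rowMeans(counts); cm <- colMeans(counts)
  rthr <- quantile(rm_, crop_quantile); cthr <- quantile(cm, crop_quantile)
  rows <- seq_along(rm_); cols <- seq_along(cm)
  while (length(rows) > 1 && rm_[rows[1]] < rthr) rows <- rows[-1]
  while (length(rows) > 1 && rm_[rows[length(rows)]] < rthr)
    rows <- rows[-length(rows)]
  while (length(cols) > 1 && cm[cols[1]] < cthr) cols <- cols[-1]
  while (length(cols) > 1 && cm[cols[length(cols)]] < cthr)
    cols <- cols[-length(cols)]
  if (length(rows) * length(cols) < 0.5 * length(rm_) * length(cm))
    stopf("over-crop: crop would remove > 50%% of pixels (kept %d x %d of %d x %d)",
          length(rows), length(cols), length(rm_), length(cm))
  list(rows = rows, cols = cols)
}

crop_image <- function(image, rows, cols) {
  synth_image(image$pixels[rows, cols, , drop = FALSE],
              image$iter_count[rows, cols, drop = FALSE])
}

resize_image <- function(image, height, width) {
  px <- clip01(cpp_resize_bilinear(image$pixels, height, width))
  ic <- cpp_resize_bilinear(array(image$iter_count,
                                  c(dim(image$iter_count), 1L)),
                            height, width)[, , 1]
  synth_image(px, round(ic))
}

#' Multi-scale synthesis of one image pair
#'
#' Runs the full three-phase loop for one endpoint pair at one similarity
#' level: per volley, weighted-channel initialization then correlation
#' tuning; between volleys the image is magnified; gradients are applied
#' through a moving window slightly smaller than the image so peripheral
#' pixels are updated less often; finally, boundary rows/columns with low
#' update counts are cropped and the achieved correlations are measured on
#' the cropped images. Both images share each iteration's window position so
#' the final crop (derived from the pooled update counts) is identical for
#' the pairmates.
#'
#' @param extractor a `feature_extractor`.
#' @param endpoint one endpoint pair (row of `select_endpoints` output).
#' @param level similarity level in 1..`spec$n_levels`.
#' @param spec a `synthesis_spec`.
#' @param seed per-pair seed; default derived from `spec$seed` and `level`.
#' @return `synthesized_pair` with `level`, `endpoint`, cropped images,
#'   `intended`, `achieved` and `cost_trace` fields.
#' @export
multiscale_synthesize <- function(extractor, endpoint, level, spec,
                                  seed = derive_seed(spec$seed, level)) {
  t_level <- spec$schedule[level]
  taps <- extractor$taps$layer_id
  targets <- stats::setNames(
    ifelse(extractor$taps$role == "target", t_level, spec$constrained_target),
    taps)
  seed_a <- derive_seed(seed, 1L); seed_b <- derive_seed(seed, 2L)
  image_a <- noise_image(spec$image_size, spec$image_size, seed_a)
  image_b <- noise_image(spec$image_size, spec$image_size, seed_b)
  trace <- numeric(0)
  with_seed(derive_seed(seed, 3L), {
    for (v in seq_len(spec$volleys)) {
      if (v > 1L) {
        d <- dim(image_a$pixels)
        nh <- as.integer(round_half_up(d[1] * spec$magnification))
        nw <- as.integer(round_half_up(d[2] * spec$magnification))
        image_a <- resize_image(image_a, nh, nw)
        image_b <- resize_image(image_b, nh, nw)
      }
      d <- dim(image_a$pixels)
      wfn <- function(it) draw_window(d[1], d[2], spec$window_fraction)
      # shared window per iteration: draw once, serve both images
      make_shared <- function() {
        cache <- new.env(parent = emptyenv())
        function(it) {
          key <- as.character(it)
          if (is.null(cache[[key]])) cache[[key]] <- list(draw_window(
            d[1], d[2], spec$window_fraction))
          cache[[key]][[1]]
        }
      }
      win_init <- make_shared()
      image_a <- initialize_pair(extractor, endpoint, t_level, "A", spec,
                                 start = image_a, window_fn = win_init)
      image_b <- initialize_pair(extractor, endpoint, t_level, "B", spec,
                                 start = image_b, window_fn = win_init)
      win_tune <- make_shared()
      pair <- tune_pair(extractor, image_a, image_b, targets,
                        tune_iters = spec$tune_iters, spec,
                        window_fn = win_tune)
      image_a <- pair$image_a; image_b <- pair$image_b
      trace <- c(trace, pair$cost_trace)
    }
  })
  counts <- image_a$iter_count + image_b$iter_count
  cr <- crop_by_counts(counts, spec$crop_quantile)
  image_a <- crop_image(image_a, cr$rows, cr$cols)
  image_b <- crop_image(image_b, cr$rows, cr$cols)
  achieved <- pair_correlations(extractor, image_a, image_b, taps)
  structure(list(image_a = image_a, image_b = image_b, level = level,
                 endpoint = endpoint, intended = targets, achieved = achieved,
                 cost_trace = trace),
            class = "synthesized_pair")
}

#' Synthesize a full endpoint-by-level stimulus grid
#'
#' @param extractor a `feature_extractor`.
#' @param endpoints endpoint pairs (`select_endpoints` output).
#' @param spec a `synthesis_spec`.
#' @param progress print one line per pair.
#' @return object of class `stimulus_set`: list with `pairs` (list indexed
#'   `[endpoint][level]`), `endpoints`, `spec`.
#' @export
synthesize_set <- function(extractor, endpoints, spec, progress = FALSE) {
  n_e <- nrow(endpoints)
  pairs <- vector("list", n_e * spec$n_levels)
  dim(pairs) <- c(n_e, spec$n_levels)
  for (e in seq_len(n_e)) {
    for (l in seq_len(spec$n_levels)) {
      seed <- derive_seed(spec$seed, e * 1000L + l)
      pairs[[e, l]] <- multiscale_synthesize(extractor, endpoints[e, ], l,
                                             spec, seed = seed)
      if (progress)
        message(sprintf("endpoint %d level %d: target-layer r = %.3f", e, l,
                        tail(pairs[[e, l]]$achieved, 1)))
    }
  }
  structure(list(pairs = pairs, endpoints = endpoints, spec = spec),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  d <- dim(x$pairs)
  cat(sprintf("<stimulus_set: %d endpoints x %d levels = %d images>\n",
              d[1], d[2], 2 * d[1] * d[2]))
  invisible(x)
}

#' Number of images in a stimulus set
#' @param set a `stimulus_set`.
#' @export
n_images <- function(set) 2L * prod(dim(set$pairs))

#' Validate a synthesized stimulus set
#'
#' Feeds every final image pair back through the extractor, records the
#' achieved inter-image correlation per tap, and summarizes fidelity: per
#' target tap, the second-order Pearson correlation across pairs between
#' intended and achieved values; per constrained tap, the mean and SD of the
#' achieved values (intended to be uniform).
#'
#' @param set a `stimulus_set`.
#' @param extractor the extractor used for synthesis.
#' @return list with `achieved` (data frame: endpoint, level, intended, one
#'   column per tap), `second_order` (per target tap; NA when achieved
#'   values have zero variance), `constrained` (mean/SD per constrained tap).
#' @export
validate_set <- function(set, extractor) {
  d <- dim(set$pairs)
  if (any(vapply(set$pairs, is.null, logical(1))))
    stopf("incomplete stimulus set: missing pairs in the grid")
  taps <- extractor$taps$layer_id
  rows <- list()
  for (e in seq_len(d[1])) for (l in seq_len(d[2])) {
    p <- set$pairs[[e, l]]
    ach <- pair_correlations(extractor, p$image_a, p$image_b, taps)
    rows[[length(rows) + 1L]] <- c(endpoint = e, level = l,
                                   intended = set$spec$schedule[l], ach)
  }
  achieved <- as.data.frame(do.call(rbind, rows))
  tt <- target_taps(extractor); ct <- constrained_taps(extractor)
  second_order <- vapply(tt, function(l) {
    if (sd(achieved[[l]]) == 0) return(NA_real_)
    cor(achieved$intended, achieved[[l]])
  }, numeric(1))
  constrained <- data.frame(
    tap = ct,
    mean = vapply(ct, function(l) mean(achieved[[l]]), numeric(1)),
    sd = vapply(ct, function(l) sd(achieved[[l]]), numeric(1))
  )
  list(achieved = achieved, second_order = second_order,
       constrained = constrained)
}
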