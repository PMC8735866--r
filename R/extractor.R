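#' Images for synthesis
#'
#' A `synth_image` bundles an H x W x 3 pixel array with values in \[0, 1\]
#' and a per-pixel update count (`iter_count`) recording how many
#' optimization iterations touched each pixel. The count drives the final
#' crop of the multi-scale synthesis loop.
#'
#' @param pixels numeric array, height x width x 3, values in \[0, 1\].
#' @param iter_count integer matrix height x width; defaults to zeros.
#' @return an object of class `synth_image`.
#' @export
synth_image <- function(pixels, iter_count = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stopf("pixels must be H x W x 3")
  if (!all(is.finite(pixels))) stopf("invalid input: non-finite pixel values")
  if (any(pixels < 0 | pixels > 1)) stopf("pixel values must lie in [0, 1]")
  if (is.null(iter_count)) iter_count <- matrix(0L, d[1], d[2])
  stopifnot(all(dim(iter_count) == d[1:2]), all(iter_count >= 0))
  structure(list(pixels = pixels, iter_count = iter_count),
            class = "synth_image")
}

#' @export
print.synth_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<synth_image %d x %d, mean iter_count %.1f>\n",
              d[1], d[2], mean(x$iter_count)))
  invisible(x)
}

#' Seeded uniform-noise starting image
#'
#' @param height,width image size in pixels.
#' @param seed integer seed.
#' @return a `synth_image` of uniform noise in \[0, 1\].
#' @export
noise_image <- function(height, width, seed) {
  px <- with_seed(seed, array(runif(height * width * 3), c(height, width, 3)))
  synth_image(px)
}

#' Write / read an image as 8-bit RGB PNG
#'
#' Values are scaled by 255 and rounded on write.
#'
#' @param image a `synth_image`.
#' @param path file path.
#' @export
write_image_png <- function(image, path) {
  px <- aperm(image$pixels, c(1, 2, 3))
  png::writePNG(px, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  synth_image(px[, , 1:3, drop = FALSE])
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
softplus_grad <- function(z) stats::plogis(z)

#' Deterministic toy convolutional feature extractor
#'
#' Builds a small stack of fixed random-weight 3x3 convolutions with a
#' softplus nonlinearity and 2x average pooling between layers. Every layer
#' is tapped; shallow taps are marked `constrained` and the deepest
#' `n_target` taps are marked `target`, mirroring the split between
#' lower/middle layers (whose inter-image correlations are held fixed during
#' synthesis) and higher layers (whose correlations are driven along the
#' similarity schedule). The extractor is fully deterministic given `seed`
#' and satisfies the forward and gradient contracts used by the synthesis
#' engine, so the whole algorithm is testable without pretrained weights.
#'
#' @param seed integer seed for the random weights.
#' @param n_layers number of convolutional layers (>= 2).
#' @param channels integer vector of output channels per layer (recycled).
#' @param n_target how many of the deepest taps are `target` layers.
#' @return an object of class `feature_extractor` with elements `weights`,
#'   `biases`, `taps` (data frame: layer_id, role, depth_rank, n_channels).
#' @export
make_toy_extractor <- function(seed, n_layers = 4L,
                               channels = rep(6L, n_layers),
                               n_target = max(1L, n_layers %/% 3L)) {
  if (n_layers < 2L)
    stopf("config error: need n_layers >= 2 (distinct constrained and target layers)")
  channels <- rep_len(as.integer(channels), n_layers)
  if (any(channels < 1L)) stopf("config error: channels must be positive")
  if (n_target >= n_layers) stopf("config error: n_target must leave a constrained layer")
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  with_seed(seed, {
    cin <- 3L
    for (k in seq_len(n_layers)) {
      cout <- channels[k]
      weights[[k]] <- array(rnorm(9 * cin * cout, sd = 1 / sqrt(9 * cin)),
                            c(3, 3, cin, cout))
      biases[[k]] <- rnorm(cout, sd = 0.1)
      cin <- cout
    }
  })
  taps <- data.frame(
    layer_id = paste0("conv", seq_len(n_layers)),
    role = c(rep("constrained", n_layers - n_target), rep("target", n_target)),
    depth_rank = seq_len(n_layers),
    n_channels = channels,
    stringsAsFactors = FALSE
  )
  structure(list(weights = weights, biases = biases, taps = taps,
                 n_layers = n_layers, channels = channels, seed = seed,
                 cache = new.env(parent = emptyenv())),
            class = "feature_extractor")
}

# Per-unit baseline: the extractor's response to a uniform mid-gray image
# of the given size. Activation patterns are reported relative to this
# baseline, so inter-image correlations reflect input-driven structure
# rather than the fixed activation profile a random-weight network imposes
# on every image. Cached per image size.
extractor_baseline <- function(extractor, height, width) {
  key <- paste0(height, "x", width)
  if (is.null(extractor$cache[[key]])) {
    gray <- array(0.5, c(height, width, 3))
    extractor$cache[[key]] <- extractor_forward(extractor, gray)$a
  }
  extractor$cache[[key]]
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor: %d conv layers (%s), taps %s>\n",
              x$n_layers, paste(x$channels, collapse = "-"),
              paste(x$taps$layer_id, x$taps$role, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Tap ids by role
#'
#' @param extractor a `feature_extractor`.
#' @return character vector of layer ids whose inter-image correlation is
#'   driven along the similarity schedule (`target_taps`) or held at the
#'   fixed constrained value (`constrained_taps`).
#' @export
target_taps <- function(extractor) {
  extractor$taps$layer_id[extractor$taps$role == "target"]
}

#' @rdname target_taps
#' @export
constrained_taps <- function(extractor) {
  extractor$taps$layer_id[extractor$taps$role == "constrained"]
}

as_pixels <- function(image) {
  if (inherits(image, "synth_image")) image$pixels else image
}

# Full forward pass, caching pre-activations (z) and activations (a) per
# layer so the backward pass can reuse them. Input is centred at 0.5.
extractor_forward <- function(extractor, image) {
  x <- as_pixels(image)
  if (!all(is.finite(x))) stopf("invalid input: non-finite pixel values")
  cur <- x - 0.5
  z <- vector("list", extractor$n_layers)
  a <- vector("list", extractor$n_layers)
  for (k in seq_len(extractor$n_layers)) {
    z[[k]] <- cpp_conv2d_fwd(cur, extractor$weights[[k]], extractor$biases[[k]])
    a[[k]] <- softplus(z[[k]])
    dim(a[[k]]) <- dim(z[[k]])
    if (k < extractor$n_layers) {
      d <- dim(a[[k]])
      if (d[1] < 2L || d[2] < 2L)
        stopf("image too small for %d layers (feature map %dx%d before pooling)",
              extractor$n_layers, d[1], d[2])
      cur <- cpp_avgpool2_fwd(a[[k]])
    }
  }
  list(z = z, a = a)
}

#' Extract per-layer activation vectors
#'
#' Runs the extractor forward and returns, for each requested tap, the
#' flattened (channel-major) activation vector. The forward pass is
#' deterministic: the same image always yields bit-identical activations.
#' By default each unit's response to a uniform mid-gray image is
#' subtracted, so that pattern correlations between images measure
#' input-driven structure rather than the fixed activation profile a
#' random-weight network imposes on every input.
#'
#' @param extractor a `feature_extractor`.
#' @param image a `synth_image` or H x W x 3 pixel array.
#' @param taps character vector of layer ids; defaults to all taps.
#' @param center subtract the per-unit mid-gray baseline (default TRUE).
#' @return named list of numeric vectors, one per tap.
#' @export
extract_features <- function(extractor, image, taps = extractor$taps$layer_id,
                             center = TRUE) {
  unknown <- setdiff(taps, extractor$taps$layer_id)
  if (length(unknown))
    stopf("tap not found: %s", paste(unknown, collapse = ", "))
  fw <- extractor_forward(extractor, image)
  px <- as_pixels(image)
  base <- if (center) extractor_baseline(extractor, dim(px)[1], dim(px)[2])
  idx <- match(taps, extractor$taps$layer_id)
  out <- lapply(idx, function(k) {
    v <- fw$a[[k]]
    if (center) v <- v - base[[k]]
    as.vector(v)
  })
  names(out) <- taps
  out
}

# Backprop a set of per-tap upstream gradient vectors (d objective / d
# activation, flattened in the same order extract_features uses) down to a
# pixel-shaped gradient array.
extractor_gradient <- function(extractor, image, tap_grads, forward = NULL) {
  if (is.null(forward)) forward <- extractor_forward(extractor, image)
  nl <- extractor$n_layers
  g_pool <- NULL  # gradient flowing into the pooled output of layer k
  for (k in rev(seq_len(nl))) {
    d <- dim(forward$a[[k]])
    g_a <- array(0, d)
    lid <- extractor$taps$layer_id[k]
    if (!is.null(tap_grads[[lid]])) {
      tg <- tap_grads[[lid]]
      stopifnot(length(tg) == prod(d))
      g_a <- g_a + array(tg, d)
    }
    if (!is.null(g_pool)) g_a <- g_a + cpp_avgpool2_bwd(g_pool, d[1], d[2])
    g_z <- g_a * softplus_grad(forward$z[[k]])
    dim(g_z) <- d
    g_pool <- cpp_conv2d_bwd(g_z, extractor$weights[[k]])
  }
  g_pool  # H x W x 3 gradient w.r.t. (centred) pixels == w.r.t. pixels
}

# Central finite-difference pixel gradient of a scalar objective of the
# tapped activations; the independent oracle for extractor_gradient.
numeric_gradient <- function(extractor, pixels, objective, eps = 1e-5) {
  g <- array(0, dim(pixels))
  for (i in seq_along(pixels)) {
    p1 <- pixels; p1[i] <- p1[i] + eps
    p2 <- pixels; p2[i] <- p2[i] - eps
    g[i] <- (objective(extractor_forward(extractor, p1)) -
             objective(extractor_forward(extractor, p2))) / (2 * eps)
  }
  g
}
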