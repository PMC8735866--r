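# Laplacian pyramid decomposition of an H x W x C array. Level k holds the
# band g_k - upsample(g_{k+1}); the last level is the low-pass residual, so
# summing all levels (after upsampling each to full size) is an exact
# reconstruction.
laplacian_pyramid <- function(x, levels) {
  stopifnot(levels >= 1)
  d <- dim(x)
  bands <- vector("list", levels)
  g <- x
  for (k in seq_len(levels)) {
    dg <- dim(g)
    if (k == levels || dg[1] < 4L || dg[2] < 4L) {
      bands[[k]] <- g
      bands <- bands[seq_len(k)]
      break
    }
    g_next <- cpp_avgpool2_fwd(g)
    up <- cpp_resize_bilinear(g_next, dg[1], dg[2])
    bands[[k]] <- g - up
    g <- g_next
  }
  bands
}

# Invert the decomposition: upsample the running residual to each band's
# native size and add, from the coarsest band back to the finest.
pyramid_reconstruct <- function(bands) {
  out <- bands[[length(bands)]]
  for (k in rev(seq_len(length(bands) - 1L))) {
    d <- dim(bands[[k]])
    out <- bands[[k]] + cpp_resize_bilinear(out, d[1], d[2])
  }
  out
}

#' Laplacian-pyramid gradient regularization
#'
#' Decomposes a pixel gradient into frequency bands and rescales each band
#' to unit root-mean-square energy before recombining. This suppresses the
#' dominance of high-frequency components in activation-maximization
#' gradients, letting low-frequency structure and colour develop.
#'
#' @param gradient numeric array H x W x C.
#' @param pyramid_levels number of pyramid bands (>= 1); reduced with a
#'   warning if the image is too small.
#' @return regularized gradient, same shape as the input.
#' @export
laplacian_regularize <- function(gradient, pyramid_levels = 3L) {
  if (pyramid_levels < 1) stopf("pyramid_levels must be >= 1")
  d <- dim(gradient)
  max_levels <- max(1L, floor(log2(min(d[1], d[2]))) - 1L)
  if (pyramid_levels > max_levels) {
    warning(sprintf("image %dx%d supports only %d pyramid levels (%d requested)",
                    d[1], d[2], max_levels, pyramid_levels))
    pyramid_levels <- max_levels
  }
  bands <- laplacian_pyramid(gradient, pyramid_levels)
  eps <- 1e-12
  out <- array(0, d)
  for (k in seq_along(bands)) {
    b <- bands[[k]]
    b <- b / (sqrt(mean(b^2)) + eps)
    db <- dim(b)
    if (db[1] != d[1] || db[2] != d[2]) b <- cpp_resize_bilinear(b, d[1], d[2])
    out <- out + b
  }
  out
}
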