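# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept tiny so oracles (finite differences, exhaustive search,
# brute-force convolution) stay cheap.

tiny_extractor <- function(seed = 1, channels = c(4, 5)) {
  make_toy_extractor(seed, n_layers = 2L, channels = channels)
}

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_size = 16L, pyramid_levels = 2L, seed = 7L,
                   init_iters = 10L, tune_iters = 20L, volleys = 1L,
                   window_fraction = 1, crop_quantile = 0)
  do.call(synthesis_spec, utils::modifyList(defaults, args))
}

# brute-force 3x3 same-padding cross-correlation, index by index
brute_conv3 <- function(x, w, bias) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(w)[4]
  out <- array(0, c(H, W, Cout))
  for (o in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- bias[o]
    for (ci in seq_len(Cin)) for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, ci] * w[di + 2, dj + 2, ci, o]
    }
    out[i, j, o] <- acc
  }
  out
}

# minimal hand-built run design for GLM tests
manual_run <- function(onsets, tr = 1.5, n_volumes = 20L, image_ids = 1L) {
  events <- data.frame(onset = onsets, duration = 1,
                       image_id = rep_len(image_ids, length(onsets)),
                       pair_id = rep_len((image_ids + 1L) %/% 2L, length(onsets)),
                       position = "A", catch = FALSE)
  structure(list(kind = "templating", events = events, tr = tr,
                 n_volumes = n_volumes, lead_in = min(onsets),
                 isi_menu = c("1" = 0.4, "3" = 0.4, "5" = 0.2)),
            class = "run_design")
}

# per-participant 8x8 pre/post pairmate cross-correlation tables; makes
# permutation statistics cheap lookups in calibration tests
cross_cor_tables <- function(participant) {
  idx_a <- 2 * (1:8) - 1
  idx_b <- 2 * (1:8)
  list(pre = cor(t(participant$pre[idx_a, ]), t(participant$pre[idx_b, ])),
       post = cor(t(participant$post[idx_a, ]), t(participant$post[idx_b, ])))
}
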