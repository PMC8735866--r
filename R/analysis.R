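#' Estimate per-image activity patterns by ordinary least squares
#'
#' Fits, voxelwise, a GLM with one double-gamma-convolved regressor per
#' image plus an intercept, returning the image-by-voxel matrix of
#' parameter estimates.
#'
#' @param bold V x n_volumes matrix (voxels by volumes).
#' @param run the `run_design` that generated the series.
#' @param hrf HRF function of time.
#' @param n_images number of image regressors (default 16).
#' @return `n_images` x V pattern matrix.
#' @export
fit_glm <- function(bold, run, hrf = hrf_double_gamma, n_images = 16L) {
  if (ncol(bold) != run$n_volumes)
    stopf("series length %d does not match %d volumes", ncol(bold), run$n_volumes)
  X <- cbind(design_matrix(run, n_images, hrf), 1)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stopf("singular design: rank %d < %d columns (condition number %.3g)",
          qx$rank, ncol(X), kappa(X))
  beta <- qr.coef(qx, t(bold))
  beta[seq_len(n_images), , drop = FALSE]
}

default_pairing <- function(n_pairs = 8L)
  data.frame(pair = seq_len(n_pairs), a_row = 2L * seq_len(n_pairs) - 1L,
             b_row = 2L * seq_len(n_pairs))

#' Pairmate pattern similarity profile
#'
#' Pearson-correlates the two pattern vectors of each pairmate pair,
#' returning one similarity value per pair, ordered by similarity level.
#'
#' @param patterns 16 x V pattern matrix (rows ordered by image id).
#' @param pairing data frame with columns `pair`, `a_row`, `b_row`; default
#'   pairs rows (1,2), (3,4), ...
#' @param run_label `"pre"` or `"post"`, recorded as an attribute.
#' @return numeric vector of 8 correlations (class `similarity_profile`).
#' @export
pairmate_similarity <- function(patterns, pairing = default_pairing(),
                                run_label = "pre") {
  r <- vapply(seq_len(nrow(pairing)), function(i) {
    a <- patterns[pairing$a_row[i], ]
    b <- patterns[pairing$b_row[i], ]
    if (sd(a) == 0) stopf("undefined correlation: zero-variance pattern (image %d)",
                          pairing$a_row[i])
    if (sd(b) == 0) stopf("undefined correlation: zero-variance pattern (image %d)",
                          pairing$b_row[i])
    cor(a, b)
  }, numeric(1))
  structure(r, run_label = run_label, class = "similarity_profile")
}

#' Model-brain correspondence
#'
#' Fisher-transformed second-order Pearson correlation between similarity
#' level and the pairmate similarity profile: does similarity built into
#' the stimuli reappear in the measured patterns?
#'
#' @param profile a `similarity_profile` (or plain numeric vector).
#' @param levels similarity levels (default `1:length(profile)`).
#' @return Fisher z value; `NA` (with a message) if the profile has zero
#'   variance.
#' @export
correspondence <- function(profile, levels = seq_along(profile)) {
  if (length(profile) < 3L) stopf("need at least 3 levels")
  if (sd(profile) == 0 || sd(levels) == 0) {
    message("correspondence undefined: zero-variance profile")
    return(NA_real_)
  }
  fisher_z(cor(levels, as.numeric(profile)))
}

#' Representational change (post minus pre)
#'
#' Positive values signify integration (pairmates became more similar),
#' negative values differentiation.
#'
#' @param pre,post `similarity_profile`s from the pre- and post-learning
#'   templating runs, with matching pairings.
#' @return numeric change curve, one delta per level.
#' @export
representational_change <- function(pre, post) {
  if (length(pre) != length(post))
    stopf("consistency error: profiles have different pairings")
  as.numeric(post) - as.numeric(pre)
}

# per-participant change curves (participants x levels matrix), optionally
# under a re-pairing permutation of the B images
change_curves <- function(pattern_set, perm = NULL) {
  pairing <- default_pairing()
  if (!is.null(perm)) pairing$b_row <- 2L * perm
  t(vapply(pattern_set, function(s) {
    representational_change(
      pairmate_similarity(s$pre, pairing, "pre"),
      pairmate_similarity(s$post, pairing, "post"))
  }, numeric(8)))
}

#' Behavioral arrangement analysis
#'
#' Computes pairmate Euclidean distances per trial from final placement
#' coordinates, averages them within participant, and correlates distance
#' with similarity level per participant and on the participant-averaged
#' distances.
#'
#' @param placements data frame with columns participant, trial, image_id,
#'   x, y.
#' @param pairing pairing data frame (see [pairmate_similarity()]); `a_row`
#'   and `b_row` here index image ids.
#' @param levels similarity level per pair (default the pair index).
#' @return list with `distances` (participants x pairs matrix of
#'   trial-averaged distances), `participant_r`, `group_r` (both `NA` when
#'   distances are degenerate).
#' @export
arrangement_analysis <- function(placements, pairing = default_pairing(),
                                 levels = pairing$pair) {
  participants <- sort(unique(placements$participant))
  n_pairs <- nrow(pairing)
  dist_mat <- matrix(NA_real_, length(participants), n_pairs)
  for (si in seq_along(participants)) {
    sub <- placements[placements$participant == participants[si], ]
    for (pi in seq_len(n_pairs)) {
      ds <- c()
      for (tr in unique(sub$trial)) {
        st <- sub[sub$trial == tr, ]
        a <- st[st$image_id == pairing$a_row[pi], c("x", "y")]
        b <- st[st$image_id == pairing$b_row[pi], c("x", "y")]
        if (nrow(a) == 1 && nrow(b) == 1)
          ds <- c(ds, sqrt(sum((as.numeric(a) - as.numeric(b))^2)))
      }
      if (!length(ds))
        stopf("missing-pair error: pair %d never co-presented for participant %s",
              pi, participants[si])
      dist_mat[si, pi] <- mean(ds)
    }
  }
  safe_r <- function(d) if (sd(d) == 0) NA_real_ else cor(levels, d)
  participant_r <- apply(dist_mat, 1, safe_r)
  group_r <- safe_r(colMeans(dist_mat))
  list(distances = dist_mat, participant_r = participant_r, group_r = group_r)
}

stat_result <- function(estimate, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, n_boot = 0L, n_perm = 0L,
                        n_failed = 0L, null_values = NULL) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 p = p, n_boot = n_boot, n_perm = n_perm,
                 n_failed = n_failed, null_values = null_values),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("estimate = %.4f", x$estimate))
  if (!is.na(x$ci_low))
    cat(sprintf(", 95%% CI [%.4f, %.4f] (%d bootstraps)",
                x$ci_low, x$ci_high, x$n_boot))
  if (!is.na(x$p)) cat(sprintf(", p = %.4g (%d permutations)", x$p, x$n_perm))
  cat("\n")
  if (x$n_failed > 0) cat(sprintf("  (%d resamples failed and were excluded)\n",
                                  x$n_failed))
  invisible(x)
}

#' Participant bootstrap confidence interval
#'
#' Percentile 95% CI of a statistic over with-replacement resamples of
#' participants.
#'
#' @param stat_fn function taking a list of per-participant inputs and
#'   returning a scalar.
#' @param inputs list with one element per participant.
#' @param n_boot number of resamples (default 50000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return a `stat_result` with `estimate` (full-sample statistic) and CI;
#'   failed resamples are excluded and counted.
#' @export
bootstrap_ci <- function(stat_fn, inputs, n_boot = 50000L, seed = 1L,
                         conf = 0.95) {
  n <- length(inputs)
  if (n < 2L) stopf("need at least 2 participants")
  obs <- stat_fn(inputs)
  vals <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(stat_fn(inputs[idx]), error = function(e) NA_real_)
  }, numeric(1)))
  failed <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  alpha <- (1 - conf) / 2
  ci <- quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  stat_result(obs, ci[1], ci[2], n_boot = n_boot, n_failed = failed)
}

#' Pairmate re-shuffling permutation null
#'
#' Re-pairs the A and B images uniformly at random `n_perm` times (the true
#' pairing is NOT excluded, a conservative choice) and recomputes the
#' statistic under each re-pairing; the one-tailed p-value uses the add-one
#' rule, p = (#\{null >= observed\} + 1) / (n_perm + 1).
#'
#' @param stat_fn function `(inputs, perm)` where `perm` is a permutation of
#'   the pair indices assigning B images to A images; called with
#'   `perm = NULL` for the observed statistic.
#' @param inputs list of per-participant inputs.
#' @param n_pairs number of pairs being re-paired (default 8).
#' @param n_perm number of permutations (default 50000).
#' @param seed integer seed.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return a `stat_result` with `estimate`, `p` and the null values.
#' @export
shuffle_null <- function(stat_fn, inputs, n_pairs = 8L, n_perm = 50000L,
                         seed = 1L, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  obs <- stat_fn(inputs, NULL)
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stat_fn(inputs, sample.int(n_pairs))
  }, numeric(1)))
  k <- if (alternative == "greater") sum(null_values >= obs)
       else sum(null_values <= obs)
  stat_result(obs, p = (k + 1) / (n_perm + 1), n_perm = n_perm,
              null_values = null_values)
}

#' Cube searchlight map
#'
#' Applies a pattern statistic to every (2 * radius + 1)^3 cube neighborhood
#' (intersected with the mask) centred on each in-mask voxel, returning a
#' Fisher-transformed statistic volume.
#'
#' @param volume 4-D array, x by y by z by images.
#' @param mask logical 3-D array.
#' @param stat_fn function of an images x voxels pattern matrix returning a
#'   scalar (typically a correlation).
#' @param radius neighborhood radius in voxels (default 2, 125-voxel cube);
#'   0 gives per-voxel statistics.
#' @param fisher apply the Fisher transform to the map (default TRUE).
#' @return 3-D array of statistics (`NA` outside the mask and at skipped
#'   centres), with attribute `n_skipped`.
#' @export
searchlight_map <- function(volume, mask, stat_fn, radius = 2L,
                            fisher = TRUE) {
  d <- dim(volume)
  stopifnot(length(d) == 4L, all(dim(mask) == d[1:3]))
  if (!any(mask)) stopf("mask is empty")
  out <- array(NA_real_, d[1:3])
  skipped <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    cx <- idx[v, 1]; cy <- idx[v, 2]; cz <- idx[v, 3]
    xs <- max(1, cx - radius):min(d[1], cx + radius)
    ys <- max(1, cy - radius):min(d[2], cy + radius)
    zs <- max(1, cz - radius):min(d[3], cz + radius)
    nb <- mask[xs, ys, zs, drop = FALSE]
    n_vox <- sum(nb)
    if (n_vox < 2L && radius > 0L) { skipped <- skipped + 1L; next }
    block <- volume[xs, ys, zs, , drop = FALSE]
    flat <- array(block, c(length(xs) * length(ys) * length(zs), d[4]))
    pat <- t(flat[as.vector(nb), , drop = FALSE])
    val <- stat_fn(pat)
    out[cx, cy, cz] <- if (fisher) fisher_z(val) else val
  }
  attr(out, "n_skipped") <- skipped
  out
}
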