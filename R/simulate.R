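#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking about 5 s
#' after the event and an undershoot peaking about 15 s later, scaled down
#' by `ratio`.
#'
#' @param t time in seconds (vector).
#' @param peak_shape,under_shape,rate gamma parameters of the peak and
#'   undershoot lobes.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return HRF values at `t` (zero for negative `t`).
#' @export
hrf_double_gamma <- function(t, peak_shape = 6, under_shape = 16, rate = 1,
                             ratio = 6) {
  ifelse(t < 0, 0,
         dgamma(t, shape = peak_shape, rate = rate) -
           dgamma(t, shape = under_shape, rate = rate) / ratio)
}

#' @rdname hrf_double_gamma
#' @details `hrf_peak_latency()` returns the analytic mode of the positive
#'   lobe, `(peak_shape - 1) / rate` seconds.
#' @export
hrf_peak_latency <- function(peak_shape = 6, rate = 1) (peak_shape - 1) / rate

#' Build the GLM design matrix for a run
#'
#' One regressor per unique image: a delta function at each of the image's
#' onsets, convolved with the double-gamma HRF and sampled at the TR grid.
#'
#' @param run a `run_design`.
#' @param n_images number of image regressors (default 16).
#' @param hrf function of time giving the HRF (default
#'   [hrf_double_gamma()]).
#' @return matrix `n_volumes` x `n_images`.
#' @export
design_matrix <- function(run, n_images = 16L, hrf = hrf_double_gamma) {
  times <- (seq_len(run$n_volumes) - 1) * run$tr
  X <- matrix(0, run$n_volumes, n_images)
  for (img in seq_len(n_images)) {
    onsets <- run$events$onset[run$events$image_id == img]
    for (o in onsets) X[, img] <- X[, img] + hrf(times - o)
  }
  X
}

#' Simulation configuration with planted ground truth
#'
#' Defines the synthetic study: per-level baseline pairmate correlations
#' before learning, a planted pre-to-post change curve, measurement noise,
#' and the behavioral arrangement model (pairmate distance linear in
#' similarity level). The default planted curve mirrors the qualitative
#' U-shape of nonmonotonic plasticity at desk-scale magnitude: no change at
#' low similarity, differentiation at moderate similarity, integration at
#' the top of the scale.
#'
#' @param n_participants number of simulated participants.
#' @param n_voxels voxels per pattern.
#' @param baseline_pairmate_r length-8 pre-learning pairmate correlations.
#' @param planted_curve length-8 planted change (post minus pre) per level.
#' @param pattern_noise_sd per-run measurement noise SD on unit-variance
#'   voxel patterns.
#' @param bold_noise_sd Gaussian noise SD for simulated BOLD series.
#' @param arrangement_intercept,arrangement_slope mean pairmate distance (in
#'   arena pixels) = intercept + slope * level.
#' @param arrangement_participant_sd,arrangement_trial_sd distance noise SDs.
#' @param arena_radius behavioral arena radius in pixels.
#' @param seed master seed.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_participants = 36L, n_voxels = 2000L,
                     baseline_pairmate_r = seq(0, 0.3, length.out = 8),
                     planted_curve = c(0, 0.01, 0, -0.03, -0.09, -0.09,
                                       -0.01, 0.06),
                     pattern_noise_sd = 0.5, bold_noise_sd = 1,
                     arrangement_intercept = 360, arrangement_slope = -40,
                     arrangement_participant_sd = 15,
                     arrangement_trial_sd = 25, arena_radius = 350,
                     seed = 1L) {
  stopifnot(length(baseline_pairmate_r) == 8L, length(planted_curve) == 8L,
            all(abs(planted_curve) <= 2))
  if (any(abs(baseline_pairmate_r) >= 1) ||
      any(abs(baseline_pairmate_r + planted_curve) >= 1))
    stopf("range error: baseline and baseline + planted change must lie in (-1, 1)")
  structure(list(n_participants = as.integer(n_participants),
                 n_voxels = as.integer(n_voxels),
                 baseline_pairmate_r = baseline_pairmate_r,
                 planted_curve = planted_curve,
                 pattern_noise_sd = pattern_noise_sd,
                 bold_noise_sd = bold_noise_sd,
                 arrangement_intercept = arrangement_intercept,
                 arrangement_slope = arrangement_slope,
                 arrangement_participant_sd = arrangement_participant_sd,
                 arrangement_trial_sd = arrangement_trial_sd,
                 arena_radius = arena_radius, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Evaluate a cubic change curve over similarity levels
#'
#' Levels are standardized (zero mean, unit SD) before the polynomial is
#' evaluated, matching the parameterization used by the constrained cubic
#' fit. A positive leading coefficient produces the U-shape (dip followed by
#' a positive inflection) that nonmonotonic plasticity predicts.
#'
#' @param levels similarity levels (default 1:8).
#' @param a,b,c,d cubic coefficients on the standardized scale.
#' @return numeric change curve, one delta per level.
#' @export
planted_cubic <- function(levels = 1:8, a = 0, b = 0, c = 0, d = 0) {
  x <- (levels - mean(levels)) / sd(levels)
  a * x^3 + b * x^2 + c * x + d
}

# alpha-mixing coefficient delivering a measured pairmate correlation of r
# once independent per-run measurement noise of sd sigma is added to
# unit-variance signal patterns: cor = alpha / (1 + sigma^2).
alpha_for_r <- function(r, noise_sd) {
  alpha <- r * (1 + noise_sd^2)
  if (any(abs(alpha) >= 1))
    stopf("range error: target correlation %.3f infeasible at noise sd %.2f",
          r[which.max(abs(alpha))], noise_sd)
  alpha
}

#' Simulate pre/post voxel patterns with planted pairmate correlations
#'
#' For each participant and pair (one pair per similarity level), the B
#' pattern is an alpha-mixture of the A pattern and independent noise, with
#' alpha chosen so the measured pairmate correlation (after per-run
#' measurement noise) equals `baseline_pairmate_r[level]` pre-learning and
#' `baseline + planted_curve[level]` post-learning. The A pattern and B's
#' independent component are shared across runs (a stable item code);
#' measurement noise is drawn independently per run.
#'
#' @param spec a `sim_spec`.
#' @return list of class `pattern_set`: one element per participant, each
#'   with `pre` and `post` 16 x V matrices (rows ordered by image id; A of
#'   pair p in row 2p-1, B in row 2p) and `participant`.
#' @export
synthetic_patterns <- function(spec) {
  V <- spec$n_voxels
  sigma <- spec$pattern_noise_sd
  a_pre <- alpha_for_r(spec$baseline_pairmate_r, sigma)
  a_post <- alpha_for_r(spec$baseline_pairmate_r + spec$planted_curve, sigma)
  out <- with_seed(spec$seed, lapply(seq_len(spec$n_participants), function(s) {
    pre <- matrix(NA_real_, 16, V)
    post <- matrix(NA_real_, 16, V)
    for (p in 1:8) {
      base_a <- rnorm(V)
      base_eps <- rnorm(V)
      b_pre <- a_pre[p] * base_a + sqrt(1 - a_pre[p]^2) * base_eps
      b_post <- a_post[p] * base_a + sqrt(1 - a_post[p]^2) * base_eps
      pre[2 * p - 1, ] <- base_a + rnorm(V, sd = sigma)
      pre[2 * p, ] <- b_pre + rnorm(V, sd = sigma)
      post[2 * p - 1, ] <- base_a + rnorm(V, sd = sigma)
      post[2 * p, ] <- b_post + rnorm(V, sd = sigma)
    }
    list(pre = pre, post = post, participant = s)
  }))
  structure(out, class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set: %d participants, %d voxels>\n", length(x),
              ncol(x[[1]]$pre)))
  invisible(x)
}

#' Simulate a BOLD time series from patterns and a run design
#'
#' Forward model matching the GLM: the design matrix (onset deltas
#' convolved with the double-gamma HRF, sampled at the TR) times the
#' image-by-voxel pattern matrix, plus i.i.d. Gaussian noise.
#'
#' @param run a `run_design`.
#' @param patterns 16 x V pattern matrix.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @param hrf HRF function of time.
#' @return V x n_volumes matrix (voxels by volumes).
#' @export
synthetic_bold <- function(run, patterns, noise_sd = 1, seed = 1L,
                           hrf = hrf_double_gamma) {
  if (nrow(patterns) != 16L)
    stopf("consistency error: patterns must have 16 rows (one per image)")
  if (!all(run$events$image_id %in% 1:16))
    stopf("consistency error: run events reference images outside 1..16")
  X <- design_matrix(run, 16L, hrf)
  Y <- X %*% patterns
  noise <- with_seed(seed,
                     matrix(rnorm(length(Y), sd = noise_sd), nrow(Y), ncol(Y)))
  t(Y + noise)
}

#' Simulate behavioral arrangement placements
#'
#' Each trial places all 16 images in a circular arena. Pairmate distances
#' are drawn with mean `intercept + slope * level` plus participant- and
#' trial-level Gaussian noise (floored at 1 px), then realized as
#' coordinates: the pair's midpoint is placed uniformly in the inner arena
#' and the two images sit at half the distance on either side along a
#' random orientation.
#'
#' @param spec a `sim_spec`.
#' @param n_trials_per_participant trials per participant (>= 1).
#' @return data frame with columns participant, trial, image_id, x, y.
#' @export
synthetic_arrangements <- function(spec, n_trials_per_participant = 10L) {
  with_seed(derive_seed(spec$seed, 77L), {
    rows <- vector("list", spec$n_participants * n_trials_per_participant)
    i <- 0L
    for (s in seq_len(spec$n_participants)) {
      p_eff <- rnorm(1, sd = spec$arrangement_participant_sd)
      for (tr in seq_len(n_trials_per_participant)) {
        xy <- matrix(NA_real_, 16, 2)
        for (p in 1:8) {
          d <- max(1, spec$arrangement_intercept + spec$arrangement_slope * p +
                     p_eff + rnorm(1, sd = spec$arrangement_trial_sd))
          repeat {
            ang <- runif(1, 0, 2 * pi)
            mid_r <- spec$arena_radius * sqrt(runif(1)) * 0.5
            mid_a <- runif(1, 0, 2 * pi)
            mid <- mid_r * c(cos(mid_a), sin(mid_a))
            off <- (d / 2) * c(cos(ang), sin(ang))
            if (sqrt(sum((mid + off)^2)) <= spec$arena_radius &&
                sqrt(sum((mid - off)^2)) <= spec$arena_radius) break
          }
          xy[2 * p - 1, ] <- mid + off
          xy[2 * p, ] <- mid - off
        }
        i <- i + 1L
        rows[[i]] <- data.frame(participant = s, trial = tr, image_id = 1:16,
                                x = xy[, 1], y = xy[, 2])
      }
    }
    do.call(rbind, rows)
  })
}
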