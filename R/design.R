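#' Templating-run image order
#'
#' Concatenates `reps` random permutations of the image set, resampling each
#' block until no image repeats immediately — including across block
#' boundaries — so every image's evoked response can be measured in
#' isolation.
#'
#' @param n_images number of unique images (default 16).
#' @param reps presentations per image (default 5, giving 80 trials).
#' @param seed integer seed.
#' @return integer vector of image ids, length `n_images * reps`.
#' @export
templating_sequence <- function(n_images = 16L, reps = 5L, seed = 1L) {
  stopifnot(n_images >= 3L, reps >= 1L)
  with_seed(seed, {
    out <- integer(0)
    for (b in seq_len(reps)) {
      repeat {
        block <- sample.int(n_images)
        ok <- all(diff(block) != 0L) &&
          (length(out) == 0L || block[1] != out[length(out)])
        if (ok) break
      }
      out <- c(out, block)
    }
    out
  })
}

#' Statistical-learning-run image order
#'
#' Pairs are always presented intact, A immediately followed by B. Each
#' block is a random permutation of the pairs, with no pair repeated
#' back-to-back across block boundaries; images A and B of pair `p` carry
#' ids `2p - 1` and `2p`.
#'
#' @param n_pairs number of AB pairs (default 8).
#' @param blocks permutation blocks (default 5, giving 80 trials).
#' @param seed integer seed.
#' @return integer vector of image ids, length `n_pairs * 2 * blocks`.
#' @export
learning_sequence <- function(n_pairs = 8L, blocks = 5L, seed = 1L) {
  stopifnot(n_pairs >= 2L, blocks >= 1L)
  with_seed(seed, {
    pair_order <- integer(0)
    for (b in seq_len(blocks)) {
      repeat {
        block <- sample.int(n_pairs)
        ok <- length(pair_order) == 0L || block[1] != pair_order[length(pair_order)]
        if (ok) break
      }
      pair_order <- c(pair_order, block)
    }
    as.integer(rbind(2L * pair_order - 1L, 2L * pair_order))
  })
}

#' Run timing parameters
#'
#' @param tr repetition time in seconds (default 1.5).
#' @param n_volumes functional volumes per run (default 203).
#' @param lead_in seconds before the first onset (default 6).
#' @param duration image duration in seconds (default 1).
#' @param isi_menu named probabilities over the ISI menu, names are seconds
#'   (default 1 s / 3 s / 5 s at 40:40:20).
#' @return list of run parameters.
#' @export
run_params <- function(tr = 1.5, n_volumes = 203L, lead_in = 6,
                       duration = 1,
                       isi_menu = c("1" = 0.4, "3" = 0.4, "5" = 0.2)) {
  stopifnot(abs(sum(isi_menu) - 1) < 1e-9)
  list(tr = tr, n_volumes = n_volumes, lead_in = lead_in,
       duration = duration, isi_menu = isi_menu)
}

# Exact largest-remainder allocation of n items over the menu probabilities.
largest_remainder <- function(n, probs) {
  raw <- n * probs
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  as.integer(counts)
}

#' Assign onset timing to an image order
#'
#' Onsets accumulate lead-in + duration + ISI, with the inter-stimulus
#' intervals allocated exactly at the menu's ratio (largest-remainder
#' counts, then shuffled), guaranteeing the run fits the fixed scan length.
#'
#' @param order integer image ids in presentation order.
#' @param params a `run_params()` list.
#' @param seed integer seed for the ISI shuffle.
#' @param kind `"templating"` or `"learning"` (recorded on the design).
#' @return object of class `run_design`: data frame `events` (onset,
#'   duration, image_id, pair_id, position, catch) plus timing parameters.
#' @export
assign_timing <- function(order, params = run_params(), seed = 1L,
                          kind = c("templating", "learning")) {
  kind <- match.arg(kind)
  stopifnot(length(order) >= 1L)
  n_isi <- length(order) - 1L
  menu <- as.numeric(names(params$isi_menu))
  counts <- largest_remainder(n_isi, params$isi_menu)
  isis <- with_seed(seed, sample(rep(menu, counts)))
  onsets <- params$lead_in +
    c(0, cumsum(params$duration + isis))
  total <- params$tr * params$n_volumes
  last_offset <- onsets[length(onsets)] + params$duration
  if (last_offset > total)
    stopf("infeasible design: %d trials need %.1f s but the run holds %.1f s",
          length(order), last_offset, total)
  events <- data.frame(
    onset = onsets,
    duration = params$duration,
    image_id = as.integer(order),
    pair_id = as.integer((order + 1L) %/% 2L),
    position = ifelse(order %% 2L == 1L, "A", "B"),
    catch = FALSE
  )
  structure(list(kind = kind, events = events, tr = params$tr,
                 n_volumes = params$n_volumes, lead_in = params$lead_in,
                 isi_menu = params$isi_menu),
            class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat(sprintf("<run_design %s: %d trials, %d catch, %.1f s in %d x %.2g s volumes>\n",
              x$kind, nrow(x$events), sum(x$events$catch),
              max(x$events$onset) + x$events$duration[1],
              x$n_volumes, x$tr))
  invisible(x)
}

#' Flag catch trials
#'
#' Marks exactly `round(fraction * n_trials)` events (uniformly at random,
#' without replacement) as catch trials carrying the grey-patch detection
#' cover task.
#'
#' @param run a `run_design`.
#' @param fraction catch fraction in \[0, 1); default 0.10.
#' @param seed integer seed.
#' @return the `run_design` with its `catch` column set.
#' @export
assign_catch <- function(run, fraction = 0.10, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- nrow(run$events)
  k <- round(fraction * n)
  run$events$catch <- FALSE
  if (k > 0) {
    idx <- with_seed(seed, sample.int(n, k))
    run$events$catch[idx] <- TRUE
  }
  run
}

#' Generate a complete run design
#'
#' Convenience wrapper: sequence, timing, catch trials.
#'
#' @param kind `"templating"` or `"learning"`.
#' @param seed integer seed.
#' @param params a `run_params()` list.
#' @param n_images,reps templating-sequence parameters.
#' @param n_pairs,blocks learning-sequence parameters.
#' @param catch_fraction catch-trial fraction.
#' @return a `run_design`.
#' @export
generate_run <- function(kind = c("templating", "learning"), seed = 1L,
                         params = run_params(), n_images = 16L, reps = 5L,
                         n_pairs = 8L, blocks = 5L, catch_fraction = 0.10) {
  kind <- match.arg(kind)
  order <- if (kind == "templating")
    templating_sequence(n_images, reps, seed = derive_seed(seed, 1L))
  else
    learning_sequence(n_pairs, blocks, seed = derive_seed(seed, 1L))
  run <- assign_timing(order, params, seed = derive_seed(seed, 2L), kind = kind)
  assign_catch(run, catch_fraction, seed = derive_seed(seed, 3L))
}

#' Write / read a run design as a BIDS-style events TSV
#'
#' Columns: onset, duration, trial_type (image id), pair_id, position,
#' catch. The pair round-trips losslessly.
#'
#' @param run a `run_design`.
#' @param path file path for the TSV.
#' @export
write_events <- function(run, path) {
  ev <- run$events
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$image_id, pair_id = ev$pair_id,
                    position = ev$position, catch = as.integer(ev$catch))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  apply_fmt <- function(row) paste(
    format(row$onset, digits = 12), format(row$duration, digits = 12),
    row$trial_type, row$pair_id, row$position, row$catch, sep = "\t")
  for (i in seq_len(nrow(out))) writeLines(apply_fmt(out[i, ]), con)
  invisible(path)
}

#' @rdname write_events
#' @param kind,params metadata to attach to the reconstructed design.
#' @export
read_events <- function(path, kind = "templating", params = run_params()) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (any(diff(tab$onset) <= 0)) stopf("parse error: onsets not increasing")
  events <- data.frame(onset = tab$onset, duration = tab$duration,
                       image_id = as.integer(tab$trial_type),
                       pair_id = as.integer(tab$pair_id),
                       position = tab$position,
                       catch = as.logical(tab$catch))
  structure(list(kind = kind, events = events, tr = params$tr,
                 n_volumes = params$n_volumes, lead_in = params$lead_in,
                 isi_menu = params$isi_menu),
            class = "run_design")
}
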