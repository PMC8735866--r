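#' Precise CSV round-tripping
#'
#' Writes numeric columns with 12 significant digits; `read_table_file`
#' dispatches on extension (.csv, .tsv, .json, .yaml/.yml).
#'
#' @param table data frame.
#' @param path destination path.
#' @export
write_table_file <- function(table, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    out <- table
    for (j in seq_along(out))
      if (is.numeric(out[[j]])) out[[j]] <- format(out[[j]], digits = 12,
                                                   trim = TRUE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "tsv") {
    utils::write.table(table, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(table, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(table, path)
  } else stopf("unsupported table format: .%s", ext)
  invisible(path)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  res <- tryCatch(switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stopf("unsupported table format: .%s", ext)),
    error = function(e) stopf("parse error in %s: %s", path, conditionMessage(e)))
  res
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_table_file(config)
  if (!is.list(config)) stopf("config error: config must be a list or file path")
  config
}

validate_config <- function(config, required) {
  missing <- setdiff(required, names(config))
  if (length(missing))
    stopf("config error: missing field(s): %s", paste(missing, collapse = ", "))
  config
}

resample_defaults <- function(profile = "test") {
  switch(profile,
         test = list(n_boot = 2000L, n_perm = 2000L),
         paper = list(n_boot = 50000L, n_perm = 50000L),
         stopf("config error: unknown profile '%s'", profile))
}

write_manifest <- function(dir, config, files) {
  paths <- file.path(dir, files)
  manifest <- list(
    command = config$command,
    master_seed = config$master_seed,
    package = as.character(utils::packageVersion("nmphtools")),
    outputs = data.frame(file = files,
                         md5 = unname(tools::md5sum(paths)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  c(files, "manifest.json")
}

#' Execute a configured pipeline command
#'
#' Dispatches on `config$command` (`design`, `simulate`, `analyze`,
#' `nmphfit`, `synthesize`, `validate`, or `pipeline` for
#' simulate-analyze-nmphfit chained), writing outputs plus a
#' `manifest.json` of md5 checksums into `config$output_dir`. Identical
#' configs produce identical outputs.
#'
#' @param config list (or YAML/JSON path) with at least `command`,
#'   `master_seed`, `output_dir`, plus command-specific blocks; an optional
#'   `profile` (`"test"` or `"paper"`) sets bootstrap/permutation counts
#'   (2,000 vs 50,000).
#' @return invisibly, the vector of files written.
#' @export
run_config <- function(config) {
  config <- read_config(config)
  validate_config(config, c("command", "master_seed", "output_dir"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(config$command,
    design = cmd_design(config),
    simulate = cmd_simulate(config),
    analyze = cmd_analyze(config),
    nmphfit = cmd_nmphfit(config),
    synthesize = cmd_synthesize(config),
    validate = cmd_validate(config),
    pipeline = {
      f1 <- cmd_simulate(config)
      config$input_dir <- config$output_dir
      f2 <- cmd_analyze(config)
      f3 <- cmd_nmphfit(config)
      unique(c(f1, f2, f3))
    },
    stopf("config error: unknown command '%s'", config$command))
  files <- write_manifest(config$output_dir, config, files)
  invisible(files)
}

cmd_design <- function(config) {
  seed <- config$master_seed
  n_learning <- config$n_learning_runs %||% 6L
  runs <- c(list(list(kind = "templating", name = "templating_pre")),
            lapply(seq_len(n_learning), function(i)
              list(kind = "learning", name = sprintf("learning_run%d", i))),
            list(list(kind = "templating", name = "templating_post")))
  files <- character(0)
  for (i in seq_along(runs)) {
    run <- generate_run(runs[[i]]$kind, seed = derive_seed(seed, i))
    f <- paste0(runs[[i]]$name, "_events.tsv")
    write_events(run, file.path(config$output_dir, f))
    files <- c(files, f)
  }
  files
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_sim_spec <- function(config) {
  s <- config$sim %||% list()
  do.call(sim_spec, c(s[intersect(names(s), names(formals(sim_spec)))],
                      list(seed = config$master_seed)))
}

cmd_simulate <- function(config) {
  spec <- config_sim_spec(config)
  patterns <- synthetic_patterns(spec)
  files <- character(0)
  for (s in seq_along(patterns)) {
    for (run in c("pre", "post")) {
      f <- sprintf("sub-%02d_%s_patterns.csv", s, run)
      write_table_file(as.data.frame(patterns[[s]][[run]]),
                       file.path(config$output_dir, f))
      files <- c(files, f)
    }
  }
  arr <- synthetic_arrangements(spec, config$n_trials %||% 10L)
  write_table_file(arr, file.path(config$output_dir, "arrangements.csv"))
  c(files, "arrangements.csv")
}

read_pattern_dir <- function(dir) {
  pre_files <- sort(list.files(dir, pattern = "_pre_patterns\\.csv$"))
  if (!length(pre_files)) stopf("no pattern files found in %s", dir)
  structure(lapply(seq_along(pre_files), function(s) {
    list(pre = as.matrix(read_table_file(file.path(dir, pre_files[s]))),
         post = as.matrix(read_table_file(
           file.path(dir, sub("_pre_", "_post_", pre_files[s])))),
         participant = s)
  }), class = "pattern_set")
}

cmd_analyze <- function(config) {
  validate_config(config, "input_dir")
  patterns <- read_pattern_dir(config$input_dir)
  sims <- do.call(rbind, lapply(patterns, function(s) {
    rbind(data.frame(participant = s$participant, run = "pre", level = 1:8,
                     r = as.numeric(pairmate_similarity(s$pre))),
          data.frame(participant = s$participant, run = "post", level = 1:8,
                     r = as.numeric(pairmate_similarity(s$post))))
  }))
  curves <- change_curves(patterns)
  changes <- data.frame(participant = seq_len(nrow(curves)), curves)
  names(changes)[-1] <- paste0("level", 1:8)
  z <- vapply(patterns, function(s)
    correspondence(pairmate_similarity(s$pre)), numeric(1))
  rd <- resample_defaults(config$profile %||% "test")
  boot <- bootstrap_ci(function(inp) mean(vapply(inp, function(s)
    correspondence(pairmate_similarity(s$pre)), numeric(1))),
    patterns, n_boot = rd$n_boot, seed = derive_seed(config$master_seed, 11L))
  corr <- data.frame(participant = c(seq_along(z), NA),
                     fisher_z = c(z, boot$estimate),
                     ci_low = c(rep(NA, length(z)), boot$ci_low),
                     ci_high = c(rep(NA, length(z)), boot$ci_high))
  write_table_file(sims, file.path(config$output_dir, "similarity_by_level.csv"))
  write_table_file(changes, file.path(config$output_dir, "change_by_level.csv"))
  write_table_file(corr, file.path(config$output_dir, "correspondence.csv"))
  c("similarity_by_level.csv", "change_by_level.csv", "correspondence.csv")
}

cmd_nmphfit <- function(config) {
  changes_path <- config$changes %||%
    file.path(config$input_dir %||% config$output_dir, "change_by_level.csv")
  changes <- read_table_file(changes_path)
  curves <- as.matrix(changes[, paste0("level", 1:8)])
  fit <- fit_constrained_cubic(1:8, colMeans(curves))
  cv <- loo_cv(curves)
  rd <- resample_defaults(config$profile %||% "test")
  curve_list <- lapply(seq_len(nrow(curves)), function(i) curves[i, ])
  boot <- bootstrap_ci(function(inp)
    loo_cv(do.call(rbind, inp))$mean_r, curve_list,
    n_boot = rd$n_boot, seed = derive_seed(config$master_seed, 21L))
  out <- data.frame(
    a = coef(fit)[1], b = coef(fit)[2], c = coef(fit)[3], d = coef(fit)[4],
    a_raw = coef(fit, "raw")[1], b_raw = coef(fit, "raw")[2],
    c_raw = coef(fit, "raw")[3], d_raw = coef(fit, "raw")[4],
    cv_mean_r = cv$mean_r, cv_ci_low = boot$ci_low, cv_ci_high = boot$ci_high)
  write_table_file(out, file.path(config$output_dir, "nmph_fit.csv"))
  "nmph_fit.csv"
}

config_extractor <- function(config) {
  e <- config$extractor %||% list()
  make_toy_extractor(seed = e$seed %||% config$master_seed,
                     n_layers = e$n_layers %||% 4L,
                     channels = unlist(e$channels %||% c(6L, 6L, 6L, 24L)))
}

config_synthesis_spec <- function(config) {
  s <- config$synthesis %||% list()
  do.call(synthesis_spec,
          c(s[intersect(names(s), names(formals(synthesis_spec)))],
            list(seed = config$master_seed)))
}

cmd_synthesize <- function(config) {
  extractor <- config_extractor(config)
  spec <- config_synthesis_spec(config)
  n_candidates <- config$n_candidates %||%
    tail(extractor$channels, 1L)
  lid <- tail(target_taps(extractor), 1L)
  channel_imgs <- lapply(seq_len(n_candidates), function(ch)
    channel_image(extractor, lid, ch, iters = config$channel_iters %||% 50L,
                  spec, seed = derive_seed(spec$seed, 500L + ch)))
  endpoints <- select_endpoints(channel_imgs, extractor,
                                k = config$k_endpoints %||% 16L)
  set <- synthesize_set(extractor, endpoints, spec)
  files <- character(0)
  manifest_rows <- list()
  for (e in seq_len(nrow(endpoints))) for (l in seq_len(spec$n_levels)) {
    p <- set$pairs[[e, l]]
    for (im in c("A", "B")) {
      f <- sprintf("set%d_level%d_%s.png", e, l, im)
      write_image_png(if (im == "A") p$image_a else p$image_b,
                      file.path(config$output_dir, f))
      files <- c(files, f)
    }
    manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
      set = e, level = l, channel_a = endpoints$channel_a[e],
      channel_b = endpoints$channel_b[e],
      intended = spec$schedule[l],
      t(p$achieved))
  }
  write_table_file(do.call(rbind, manifest_rows),
                   file.path(config$output_dir, "manifest.csv"))
  rep <- validate_set(set, extractor)
  write_table_file(rep$achieved, file.path(config$output_dir, "validation.csv"))
  c(files, "manifest.csv", "validation.csv")
}

cmd_validate <- function(config) {
  validate_config(config, "input_dir")
  extractor <- config_extractor(config)
  man <- read_table_file(file.path(config$input_dir, "manifest.csv"))
  taps <- extractor$taps$layer_id
  rows <- lapply(seq_len(nrow(man)), function(i) {
    a <- read_image_png(file.path(config$input_dir,
                                  sprintf("set%d_level%d_A.png", man$set[i], man$level[i])))
    b <- read_image_png(file.path(config$input_dir,
                                  sprintf("set%d_level%d_B.png", man$set[i], man$level[i])))
    c(set = man$set[i], level = man$level[i], intended = man$intended[i],
      pair_correlations(extractor, a, b, taps))
  })
  write_table_file(as.data.frame(do.call(rbind, rows)),
                   file.path(config$output_dir, "validation.csv"))
  "validation.csv"
}
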