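#' Pipeline run configuration
#'
#' Settings for a full decoding run: labeling strategy, chromophore, IMF
#' index, SAX geometry, window shifting, k-NN search, channel-combination
#' search, and repetition. The study grid restricts `n_segments` to
#' \{100, 650, 1300\}, `alphabet_size` to 5..8, `imf_index` to 1..5 and
#' `max_combo_size` to 4; pass `allow_extended = TRUE` to leave the grid.
#'
#' @param strategy labeling strategy, 1, 2 or 3
#' @param chromophore which chromophore the trial set carries
#' @param imf_index which intrinsic mode function feeds SAX
#' @param n_segments SAX word length
#' @param alphabet_size SAX alphabet size
#' @param shift_mode `"augment"` or `"concat"` (triple window shifting)
#' @param shift_stride window offset in symbols; `NULL` = `floor(len/10)`
#' @param k_range candidate k values for the k-NN search
#' @param max_combo_size largest channel-combination size
#' @param channels channel indices to decompose and search; `NULL` = all
#' @param features `NULL` to run sequential forward selection, or a preset
#'   character vector such as `c("skewness", "kurtosis", "std")`
#' @param select how the reported combination is chosen: `"cv"` (highest
#'   training cross-validation accuracy; leakage-free default) or
#'   `"test_max"` (highest test accuracy, the optimistic protocol used for
#'   best-run-style reporting)
#' @param n_runs number of repeated runs (re-randomized splits)
#' @param target_len standardized length; `NULL` = set-wide maximum
#' @param train_frac training fraction
#' @param epsilon0,n_realizations,max_imfs ICEEMDAN parameters
#' @param seed master seed
#' @param allow_extended allow values outside the study grid
#' @return list of class `run_config`
#' @export
run_config <- function(strategy = 3L, chromophore = "DeoxyHb",
                       imf_index = 3L, n_segments = 1300L,
                       alphabet_size = 8L,
                       shift_mode = c("augment", "concat"),
                       shift_stride = NULL, k_range = 1:25,
                       max_combo_size = 4L, channels = NULL,
                       features = NULL, select = c("cv", "test_max"),
                       n_runs = 5L, target_len = NULL, train_frac = 0.7,
                       epsilon0 = 0.2, n_realizations = 100L, max_imfs = 8L,
                       seed = 1L, allow_extended = FALSE) {
  shift_mode <- match.arg(shift_mode)
  select <- match.arg(select)
  stopifnot(strategy %in% 1:3)
  if (!allow_extended) {
    if (!n_segments %in% c(100L, 650L, 1300L))
      stop("n_segments must be one of 100, 650, 1300 (or allow_extended)")
    if (!alphabet_size %in% 5:8)
      stop("alphabet_size must be in 5..8 (or allow_extended)")
    if (!imf_index %in% 1:5)
      stop("imf_index must be in 1..5 (or allow_extended)")
    if (max_combo_size > 4L)
      stop("max_combo_size must be <= 4 (or allow_extended)")
  }
  if (!is.null(features))
    stopifnot(all(features %in% FEATURE_MENU))
  structure(as.list(environment()), class = "run_config")
}

#' Decompose trials and build per-channel symbol instances
#'
#' The preprocessing and feature-extraction front end shared by all runs:
#' label, standardize length, ICEEMDAN per (trial, channel) with a
#' counter-derived noise seed, select the configured IMF, symbolize with
#' SAX, apply triple window shifting, and compute the five statistical
#' features per instance and channel.
#'
#' @param ts a [nirs_trial_set()]
#' @param cfg a [run_config()]
#' @return list: `labeled` (trial-level labels), `instances` (data frame
#'   `trial_id`, `label`, `window`), `channel_features` (per searched
#'   channel, instances x 5 features), `channels`
#' @export
pipeline_features <- function(ts, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  labeled <- label_trials(ts, cfg$strategy)
  keep <- nirs_trial_set(ts$trials[labeled$trial_id], ts$channel_names)
  target_len <- cfg$target_len
  if (is.null(target_len))  # SAX needs at least n_segments samples
    target_len <- max(cfg$n_segments,
                      vapply(keep$trials, function(t) ncol(t$data), 0L))
  std <- standardize_set(keep, target_len)
  channels <- if (is.null(cfg$channels)) seq_along(ts$channel_names) else
    as.integer(cfg$channels)
  icfg_base <- iceemdan_config(epsilon0 = cfg$epsilon0,
                               n_realizations = cfg$n_realizations,
                               max_imfs = cfg$max_imfs)
  scfg <- sax_config(cfg$n_segments, cfg$alphabet_size)
  n_win <- if (cfg$shift_mode == "augment") 3L else 1L
  ids <- labeled$trial_id
  feats <- lapply(channels, function(ch)
    matrix(NA_real_, length(ids) * n_win, length(FEATURE_MENU),
           dimnames = list(NULL, FEATURE_MENU)))
  names(feats) <- as.character(channels)
  for (i in seq_along(ids)) {
    trial <- std$trials[[ids[i]]]
    for (ci in seq_along(channels)) {
      ch <- channels[ci]
      icfg <- icfg_base
      icfg$seed <- derive_seed(cfg$seed, ids[i], ch)
      dec <- iceemdan(trial$data[ch, ], icfg)
      sym <- symbolize(select_imf(dec, cfg$imf_index), scfg)
      wins <- triple_window_shift(sym, mode = cfg$shift_mode,
                                  stride = cfg$shift_stride)
      for (w in seq_len(n_win))
        feats[[ci]][(i - 1L) * n_win + w, ] <- stat_features(wins[[w]])
    }
  }
  instances <- data.frame(
    trial_id = rep(ids, each = n_win),
    label = rep(labeled$label, each = n_win),
    window = rep(seq_len(n_win), length(ids)),
    stringsAsFactors = FALSE)
  list(labeled = labeled, instances = instances,
       channel_features = feats, channels = channels)
}

# one randomized run on prepared features: split, SFS, combo search, report
run_once <- function(prep, cfg, run_seed) {
  split <- make_split(prep$labeled, run_seed, cfg$train_frac)
  tr <- prep$instances$trial_id %in% split$train_ids
  if (is.null(cfg$features)) {
    x_all <- do.call(cbind, prep$channel_features)
    fold_tr <- trial_folds(prep$instances$trial_id[tr],
                           prep$instances$label[tr], 5L,
                           derive_seed(run_seed, "sfs"))
    menu <- sfs_select(x_all[tr, , drop = FALSE], prep$instances$label[tr],
                       feature_names = colnames(x_all),
                       evaluator = function(xs, ys)
                         unname(knn_cv_accs(xs, ys, ks = 5L, fold = fold_tr)))
  } else menu <- cfg$features
  ch_feats <- lapply(prep$channel_features,
                     function(m) m[, menu, drop = FALSE])
  combos <- enumerate_channel_combos(length(prep$channels),
                                     min(cfg$max_combo_size, length(prep$channels)))
  binary <- nlevels(droplevels(as.factor(prep$instances$label))) == 2L
  positive <- if (binary) "understood" else NULL
  results <- combo_search(ch_feats, prep$instances, split, combos = combos,
                          k_range = cfg$k_range, positive = positive,
                          seed = run_seed)
  best_i <- if (cfg$select == "test_max") 1L else
    order(-results$cv_accuracy, results$combo, method = "radix")[1]
  best <- results[best_i, , drop = FALSE]
  # map searched-channel indices back to real channel ids
  best$channels <- paste(prep$channels[as.integer(
    strsplit(best$combo, "+", fixed = TRUE)[[1]])], collapse = "+")
  report <- NULL
  if (binary) {
    pred <- attr(results, "predictions")[[best$combo]]
    report <- eval_report(pred$truth, pred$label, pred$score,
                          positive = positive)
  }
  list(split = split, features_used = menu, results = results,
       best = best, report = report, seed = run_seed)
}

#' Run the full decoding pipeline
#'
#' Executes the complete protocol on a trial set: label, standardize,
#' decompose, symbolize, extract features (with sequential forward
#' selection on each run's training split unless a preset menu is given),
#' then `n_runs` repeated stratified splits, each with a k-NN
#' channel-combination search and evaluation. The summary aggregates each
#' run's reported test accuracy (mean, min, max, SDV).
#'
#' @param ts a [nirs_trial_set()]
#' @param cfg a [run_config()]
#' @return object of class `nirsax_result`: `runs` (per-run outputs),
#'   `summary` (one-row data frame), `config`
#' @export
run_pipeline <- function(ts, cfg = run_config()) {
  prep <- pipeline_features(ts, cfg)
  runs <- lapply(seq_len(cfg$n_runs), function(r)
    run_once(prep, cfg, derive_seed(cfg$seed, "run", r)))
  cas <- vapply(runs, function(r) r$best$test_ca, 0)
  summary <- data.frame(
    strategy = cfg$strategy, chromophore = cfg$chromophore,
    imf_index = cfg$imf_index, n_segments = cfg$n_segments,
    alphabet_size = cfg$alphabet_size, n_runs = cfg$n_runs,
    mean_ca = mean(cas), min_ca = min(cas), max_ca = max(cas),
    sdv = if (length(cas) > 1) sd(cas) else 0)
  structure(list(runs = runs, summary = summary, config = cfg,
                 labeled = prep$labeled),
            class = "nirsax_result")
}

#' @export
print.nirsax_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<nirsax_result> strategy %d, %s IMF%d, %d segments, %d symbols\n",
    s$strategy, s$chromophore, s$imf_index, s$n_segments, s$alphabet_size))
  cat(sprintf("  %d run(s): mean CA %.2f%% (min %.2f, max %.2f, SDV %.2f)\n",
              s$n_runs, 100 * s$mean_ca, 100 * s$min_ca, 100 * s$max_ca,
              100 * s$sdv))
  invisible(x)
}

config_hash <- function(cfg) {
  # leading letter keeps the hash categorical through CSV round trips
  sprintf("h%08x", derive_seed(0L, paste(deparse(cfg[order(names(cfg))]),
                                         collapse = " ")))
}

read_config_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$k_range) && length(cfg$k_range) == 2L)
    cfg$k_range <- cfg$k_range[1]:cfg$k_range[2]
  cfg
}

#' Generate a synthetic trial set from a config file
#'
#' Config keys mirror [synth_config()] arguments, plus `out_dir` for the
#' on-disk trial-set location.
#'
#' @param config path to a YAML config, or an equivalent named list
#' @return the output directory, invisibly
#' @export
cmd_generate <- function(config) {
  cfg <- if (is.character(config)) read_config_file(config) else config
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config field 'out_dir' is required")
  cfg$out_dir <- NULL
  args <- cfg[intersect(names(cfg), names(formals(synth_config)))]
  unknown <- setdiff(names(cfg), names(formals(synth_config)))
  if (length(unknown))
    stop("unknown generator config field(s): ", paste(unknown, collapse = ", "))
  ts <- synth_generate(do.call(synth_config, args))
  write_trials(ts, out_dir)
  writeLines(yaml::as.yaml(c(args, list(config_hash = config_hash(args)))),
             file.path(out_dir, "generator_config.yaml"))
  message("wrote ", length(ts), " trials to ", out_dir)
  invisible(out_dir)
}

#' Run the pipeline from a config file
#'
#' Config keys mirror [run_config()] arguments, plus `trials_dir` (input
#' trial set) and `out_dir` (results location). Writes per-run combination
#' tables, a summary CSV, the best run's evaluation report as JSON, and a
#' log of per-stage trial counts.
#'
#' @param config path to a YAML config, or an equivalent named list
#' @return the [run_pipeline()] result, invisibly
#' @export
cmd_run <- function(config) {
  cfg <- if (is.character(config)) read_config_file(config) else config
  trials_dir <- cfg$trials_dir
  out_dir <- cfg$out_dir
  if (is.null(trials_dir) || is.null(out_dir))
    stop("config fields 'trials_dir' and 'out_dir' are required")
  cfg$trials_dir <- NULL
  cfg$out_dir <- NULL
  unknown <- setdiff(names(cfg), names(formals(run_config)))
  if (length(unknown))
    stop("unknown run config field(s): ", paste(unknown, collapse = ", "))
  rcfg <- do.call(run_config, cfg)
  ts <- read_trials(trials_dir)
  res <- run_pipeline(ts, rcfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  log <- c(sprintf("config_hash: %s", hash),
           sprintf("seed: %d", rcfg$seed),
           sprintf("trials loaded: %d", length(ts)),
           sprintf("trials labeled (strategy %d): %d",
                   rcfg$strategy, nrow(res$labeled)),
           sprintf("trials excluded: %d",
                   nrow(attr(res$labeled, "exclusions"))))
  for (r in seq_along(res$runs)) {
    run <- res$runs[[r]]
    tab <- run$results
    tab$seed <- run$seed
    tab$config_hash <- hash
    write.csv(tab, file.path(out_dir, sprintf("run%d_results.csv", r)),
              row.names = FALSE)
    log <- c(log, sprintf(
      "run %d: seed %d, features [%s], best combo %s (k=%d) test CA %.4f",
      r, run$seed, paste(run$features_used, collapse = ","),
      run$best$channels, run$best$k, run$best$test_ca))
    if (!is.null(run$report))
      write_eval_report(run$report,
                        file.path(out_dir, sprintf("run%d_report.json", r)))
  }
  summary <- res$summary
  summary$config_hash <- hash
  summary$seed <- rcfg$seed
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  write_exclusions(res$labeled, file.path(out_dir, "exclusions.csv"))
  writeLines(log, file.path(out_dir, "run.log"))
  message(paste(log, collapse = "\n"))
  invisible(res)
}

#' Aggregate results directories into summary tables
#'
#' Collects `run*_results.csv` files written by [cmd_run()], groups them
#' by config hash, and recomputes the per-config mean/min/max of each
#' run's best test accuracy.
#'
#' @param results_dir directory containing [cmd_run()] outputs
#' @return data frame, one row per (config hash, run) plus `"mean"` rows
#' @export
cmd_report <- function(results_dir) {
  files <- list.files(results_dir, "^run[0-9]+_results\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no run results under ", results_dir)
  rows <- do.call(rbind, lapply(files, function(f) {
    tab <- read.csv(f, stringsAsFactors = FALSE)
    data.frame(file = basename(f),
               config_hash = as.character(tab$config_hash[1]),
               seed = tab$seed[1], best_combo = tab$combo[1],
               best_ca = max(tab$test_ca), stringsAsFactors = FALSE)
  }))
  out <- list()
  for (h in unique(rows$config_hash)) {
    grp <- rows[rows$config_hash == h, , drop = FALSE]
    out[[h]] <- rbind(grp, data.frame(
      file = "mean", config_hash = h, seed = NA,
      best_combo = "", best_ca = mean(grp$best_ca),
      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
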