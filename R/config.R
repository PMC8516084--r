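# Config-driven experiment runner backing the command-line interface.
#
# One YAML file describes an experiment end to end: where the data come from
# (a file or a bundled synthetic generator), the preprocessing recipe,
# the group sizes (or a search grid), the base classifier, the evaluation
# protocol and the seed. Reports are written together with a manifest that
# snapshots the config and input checksums, so a run can be audited and
# reproduced; reruns of the same manifest are byte-identical.

#' Load an experiment configuration
#'
#' @param path path to a YAML experiment config.
#' @return The config as a named list, with the config path and checksum
#'   attached.
#' @export
lbm_load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (field in c("dataset", "protocol", "seed"))
    if (is.null(cfg[[field]]))
      stop("config field missing: '", field, "'", call. = FALSE)
  if (!cfg$protocol %in% c("loo", "train_test"))
    stop("config field 'protocol' must be 'loo' or 'train_test'",
         call. = FALSE)
  cfg$.path <- normalizePath(path)
  cfg$.md5 <- unname(tools::md5sum(path))
  cfg
}

config_dataset <- function(cfg) {
  d <- cfg$dataset
  checks <- character()
  if (!is.null(d$synthetic)) {
    gen <- switch(d$synthetic,
                  hill_valley = gen_hill_valley,
                  drift_table = gen_drift_table,
                  imbalanced_clouds = gen_imbalanced_clouds,
                  stop("unknown synthetic generator: '", d$synthetic, "'",
                       call. = FALSE))
    args <- if (is.null(d$args)) list() else d$args
    if (is.null(args$seed)) args$seed <- cfg$seed
    ds <- do.call(gen, args)
  } else if (!is.null(d$path)) {
    path <- d$path
    if (!file.exists(path) && !is.null(cfg$.path))
      path <- file.path(dirname(cfg$.path), d$path)
    if (grepl("\\.arff$", path, ignore.case = TRUE)) {
      ds <- read_arff(path,
                      label_attribute = d$label_column %||% "class",
                      mapping = unlist(d$mapping))
    } else {
      ds <- read_delimited(path,
                           label_column = d$label_column %||% "class",
                           delimiter = d$delimiter %||% ",",
                           id_column = d$id_column,
                           mapping = unlist(d$mapping),
                           transpose = isTRUE(d$transpose))
    }
    checks <- stats::setNames(unname(tools::md5sum(path)), path)
  } else stop("config dataset needs 'synthetic' or 'path'", call. = FALSE)
  if (!is.null(d$binarize_target))
    ds <- binarize_by_target(ds, d$binarize_target)
  attr(ds, "checksums") <- checks
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_base <- function(cfg) {
  b <- cfg$base
  if (is.null(b) || identical(b$name %||% "svm", "svm")) {
    svm_base(cost = b$cost %||% 1, gamma = b$gamma,
             score = b$score %||% "probability")
  } else if (identical(b$name, "centroid")) {
    centroid_base()
  } else stop("unknown base classifier: '", b$name, "'", call. = FALSE)
}

config_preprocess <- function(cfg, ds) {
  p <- cfg$preprocess
  ds <- preprocess(ds,
                   normalize = p$normalize %||% "none",
                   scale = isTRUE(p$scale),
                   drop_zero = isTRUE(p$drop_zero))
  if (isTRUE(cfg$ratios)) ds <- build_ratio_features(ds)
  ds
}

config_split <- function(cfg, ds) {
  s <- cfg$split
  if (is.null(s)) stop("protocol 'train_test' requires a 'split'", call. = FALSE)
  n <- nrow(ds$x)
  if (!is.null(s$test_last)) {
    k <- as.integer(s$test_last)
    if (k < 1 || k >= n) stop("split test_last out of range", call. = FALSE)
    list(train = seq_len(n - k), test = seq(n - k + 1, n))
  } else if (!is.null(s$train_ids) && !is.null(s$test_ids)) {
    if (length(intersect(s$train_ids, s$test_ids)))
      stop("train and test splits overlap", call. = FALSE)
    list(train = s$train_ids, test = s$test_ids)
  } else stop("split needs 'test_last' or 'train_ids'+'test_ids'",
              call. = FALSE)
}

run_protocol <- function(cfg, ds, sizes, base) {
  if (cfg$protocol == "loo") {
    run_loo(ds, sizes, base, seed = cfg$seed, warn_clamp = FALSE)
  } else {
    sp <- config_split(cfg, ds)
    run_train_test(subset_samples(ds, sp$train), subset_samples(ds, sp$test),
                   sizes, base, seed = cfg$seed, warn_clamp = FALSE)
  }
}

write_manifest <- function(cfg, ds, outdir, reports) {
  manifest <- list(
    name = cfg$name %||% "experiment",
    config = cfg[setdiff(names(cfg), c(".path", ".md5"))],
    config_md5 = cfg$.md5,
    input_md5 = as.list(attr(ds, "checksums") %||% stats::setNames(list(), character())),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("lbmodel")),
    reports = reports)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

write_audit <- function(preds, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(preds)), function(i) {
      sub <- attr(preds, "subsets")[[preds$test_id[i]]]
      list(test_id = preds$test_id[i], truth = preds$truth[i],
           predicted = preds$predicted[i], score = preds$score[i],
           clamped = preds$clamped[i],
           selected_low_ids = sub$low_ids, selected_hi_ids = sub$hi_ids)
    }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

clamped_sizes <- function(ds) {
  tab <- table(ds$labels)
  group_sizes(tab[["GroupLow"]], tab[["GroupHi"]])
}

#' Run one configured experiment
#'
#' Loads (or generates) the dataset, applies the configured preprocessing,
#' runs the local-balanced model under the configured protocol, and writes
#' the evaluation report (CSV + JSON), a per-sample audit trail of which
#' training samples classified which test sample, and the run manifest to
#' the output directory.
#'
#' @param config a config list from [lbm_load_config()] or a path to one.
#' @param outdir output directory; defaults to the config's `output` field
#'   or `"."`.
#' @return Invisibly, a list with the `report`, the `predictions` and the
#'   output `files`.
#' @export
lbm_run <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) lbm_load_config(config) else config
  outdir <- outdir %||% cfg$output %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds0 <- config_dataset(cfg)
  ds <- config_preprocess(cfg, ds0)
  base <- config_base(cfg)
  sizes <- if (is.null(cfg$sizes)) clamped_sizes(ds)
           else group_sizes(cfg$sizes$n_low, cfg$sizes$n_hi)
  preds <- run_protocol(cfg, ds, sizes, base)
  rep <- evaluate_predictions(preds, positive = cfg$positive %||% "GroupLow")
  files <- file.path(outdir, c("report.csv", "report.json", "audit.json"))
  write_report(list(local_balanced = rep), files[1], "csv")
  write_report(list(local_balanced = rep), files[2], "json")
  write_audit(preds, files[3])
  write_manifest(cfg, ds0, outdir, basename(files))
  invisible(list(report = rep, predictions = preds, files = files))
}

#' Run a base-versus-local-balanced comparison
#'
#' Runs the configured experiment twice under identical preprocessing and
#' seed: once with the base classifier alone (the clamped limit, in which
#' every training sample is used) and once with the configured group sizes.
#' Writes a side-by-side report so the effect of the local-balanced wrapper
#' can be read off directly.
#'
#' @inheritParams lbm_run
#' @return Invisibly, a list with `base` and `local_balanced` reports and
#'   the output `files`.
#' @export
lbm_compare <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) lbm_load_config(config) else config
  outdir <- outdir %||% cfg$output %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds0 <- config_dataset(cfg)
  ds <- config_preprocess(cfg, ds0)
  base <- config_base(cfg)
  sizes <- if (is.null(cfg$sizes)) clamped_sizes(ds)
           else group_sizes(cfg$sizes$n_low, cfg$sizes$n_hi)
  full <- if (cfg$protocol == "loo") clamped_sizes(ds) else {
    sp <- config_split(cfg, ds)
    clamped_sizes(subset_samples(ds, sp$train))
  }
  pos <- cfg$positive %||% "GroupLow"
  preds_base <- run_protocol(cfg, ds, full, base)
  preds_lb <- run_protocol(cfg, ds, sizes, base)
  reps <- list(base = evaluate_predictions(preds_base, positive = pos),
               local_balanced = evaluate_predictions(preds_lb, positive = pos))
  files <- file.path(outdir, c("compare.csv", "compare.json", "compare.md"))
  write_report(reps, files[1], "csv")
  write_report(reps, files[2], "json")
  write_report(reps, files[3], "markdown")
  write_manifest(cfg, ds0, outdir, basename(files))
  invisible(c(reps, list(files = files)))
}

#' Optimize group sizes for a configured experiment
#'
#' Evaluates every `n_low`/`n_hi` pair of the configured grid
#' (`grid: {n_low: [...], n_hi: [...]}`, crossed; or the default grid) by
#' leave-one-out AUC on the dataset (the training part, under
#' `train_test`), and writes the AUC table and the winning pair.
#'
#' @inheritParams lbm_run
#' @return Invisibly, the result of [optimize_group_sizes()] plus `files`.
#' @export
lbm_optimize <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) lbm_load_config(config) else config
  outdir <- outdir %||% cfg$output %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds0 <- config_dataset(cfg)
  ds <- config_preprocess(cfg, ds0)
  if (cfg$protocol == "train_test") {
    sp <- config_split(cfg, ds)
    ds <- subset_samples(ds, sp$train)
  }
  grid <- if (!is.null(cfg$grid))
    expand.grid(n_low = unlist(cfg$grid$n_low), n_hi = unlist(cfg$grid$n_hi))
  else default_size_grid(ds)
  res <- optimize_group_sizes(ds, config_base(cfg), grid, seed = cfg$seed)
  files <- file.path(outdir, c("sizes.json", "size_grid.csv"))
  jsonlite::write_json(list(n_low = res$best$n_low, n_hi = res$best$n_hi),
                       files[1], auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$table, files[2], row.names = FALSE)
  write_manifest(cfg, ds0, outdir, basename(files))
  invisible(c(res, list(files = files)))
}
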