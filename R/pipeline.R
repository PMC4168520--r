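#' Epoched multichannel EEG container
#'
#' @param data numeric 3-D array, trials x channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channels channel labels (normalized to upper case).
#' @param labels optional class label per trial.
#' @param subjects optional subject identifier per trial.
#' @return object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, fs, channels, labels = NULL, subjects = NULL) {
  if (length(dim(data)) != 3)
    stop("data must be a trials x channels x samples array")
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  if (dim(data)[2] != length(channels))
    stop(sprintf("channel labels (%d) do not match data channels (%d)",
                 length(channels), dim(data)[2]))
  if (!all(is.finite(data))) stop("EEG data contains non-finite values")
  if (!is.null(labels) && length(labels) != dim(data)[1])
    stop("labels length must equal the trial count")
  if (!is.null(subjects) && length(subjects) != dim(data)[1])
    stop("subjects length must equal the trial count")
  structure(list(data = data, fs = fs, channels = toupper(channels),
                 labels = labels, subjects = subjects),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  if (!is.null(x$labels))
    cat("classes:", paste(names(table(x$labels)), table(x$labels),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write epoched EEG as CSV plus a JSON metadata sidecar
#'
#' Long CSV layout: one row per (trial, channel) with columns `trial`,
#' `channel`, then the samples `s1..sN`.  The sidecar records sampling
#' rate, dimensions, channel labels, trial labels and subject ids.
#'
#' @param epochs an [epoched_eeg()].
#' @param data_path CSV path.
#' @param meta_path JSON path.
#' @return invisibly, the two paths.
#' @export
write_eeg <- function(epochs, data_path, meta_path) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  d <- dim(epochs$data)
  rows <- do.call(rbind, lapply(seq_len(d[1]), function(tr)
    epochs$data[tr, , , drop = TRUE]))
  if (d[2] == 1) rows <- matrix(rows, ncol = d[3])
  df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                   channel = rep(epochs$channels, d[1]),
                   rows, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("s", seq_len(d[3]))
  utils::write.csv(df, data_path, row.names = FALSE)
  meta <- list(fs = epochs$fs, n_trials = d[1], n_channels = d[2],
               n_samples = d[3], channels = epochs$channels,
               labels = epochs$labels, subjects = epochs$subjects)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(data = data_path, meta = meta_path))
}

#' Load epoched EEG written by [write_eeg()]
#'
#' Validates the declared dimensions against the CSV contents and rejects
#' non-finite samples.
#'
#' @param data_path CSV path.
#' @param meta_path JSON sidecar path.
#' @return an [epoched_eeg()].
#' @export
load_eeg <- function(data_path, meta_path) {
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.finite(meta$fs) || meta$fs <= 0)
    stop("metadata declares no valid sampling rate 'fs'")
  df <- utils::read.csv(data_path, check.names = FALSE)
  n_samples <- ncol(df) - 2
  if (n_samples != meta$n_samples)
    stop(sprintf("metadata declares %d samples but file has %d",
                 meta$n_samples, n_samples))
  if (nrow(df) != meta$n_trials * meta$n_channels)
    stop(sprintf("metadata declares %d trials x %d channels but file has %d rows",
                 meta$n_trials, meta$n_channels, nrow(df)))
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, 1]
    stop(sprintf("non-finite sample at trial %d, channel %s",
                 df$trial[bad], df$channel[bad]))
  }
  data <- array(0, c(meta$n_trials, meta$n_channels, n_samples))
  for (tr in seq_len(meta$n_trials)) {
    idx <- which(df$trial == tr)
    if (length(idx) != meta$n_channels)
      stop(sprintf("trial %d has %d channel rows, expected %d",
                   tr, length(idx), meta$n_channels))
    data[tr, , ] <- vals[idx, , drop = FALSE]
  }
  epoched_eeg(data, fs = meta$fs, channels = toupper(meta$channels),
              labels = meta$labels, subjects = meta$subjects)
}

## Fold assignment: stratified by class; grouped by subject when present
## (all trials of a subject share a fold, subjects stratified by group).
make_folds <- function(labels, k, seed = NULL, subjects = NULL) {
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    if (is.null(subjects)) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < k)
          stop(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                       cl, length(idx), k))
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      subj <- unique(subjects)
      subj_lab <- labels[match(subj, subjects)]
      sf <- integer(length(subj))
      for (cl in unique(subj_lab)) {
        idx <- which(subj_lab == cl)
        sf[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      fold <- sf[match(subjects, subj)]
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the MKL classifier
#'
#' Splits the feature rows into k stratified folds (subject-wise grouped
#' folds when subject ids are present, so no subject appears in both a
#' training and a test split), fits a one-versus-rest MKL-SVM on each
#' training portion (feature standardization fitted on the training folds
#' only) and reports per-fold and mean test accuracy.
#'
#' @param features a [feature_matrix()].
#' @param k number of folds (5 gives the 80/20 train/test split).
#' @param specs kernel bank specification.
#' @param settings [mkl_settings()].
#' @param seed fold-assignment seed.
#' @param standardize,normalize_kernels passed to [mkl_fit()].
#' @return object of class `cv_result`: `fold_accuracy`, `mean_accuracy`,
#'   `confusion` (table of truth x prediction), `folds`, `seed`,
#'   `settings`, and the pooled `kernel_weights` of every fitted binary
#'   model.
#' @export
kfold_cv <- function(features, k = 5, specs = default_kernel_bank(),
                     settings = mkl_settings(), seed = 1,
                     standardize = TRUE, normalize_kernels = TRUE) {
  stopifnot(inherits(features, "feature_matrix"))
  if (k < 2) stop("k must be at least 2")
  fold <- make_folds(features$labels, k, seed = seed,
                     subjects = features$subjects)
  y <- features$labels
  pred <- rep(NA_character_, length(y))
  acc <- numeric(k)
  weights <- list()
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) { acc[f] <- NA_real_; next }
    model <- fit_ovr(features$values[tr, , drop = FALSE], y[tr],
                     specs = specs, settings = settings,
                     standardize = standardize,
                     normalize_kernels = normalize_kernels)
    ph <- predict_ovr(model, features$values[te, , drop = FALSE])
    pred[te] <- as.character(ph)
    acc[f] <- mean(as.character(ph) == as.character(y[te]))
    weights[[f]] <- kernel_weight_report(model)
  }
  structure(list(fold_accuracy = acc,
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 confusion = table(truth = as.character(y),
                                   prediction = pred),
                 predictions = pred, folds = fold, k = k, seed = seed,
                 settings = settings,
                 kernel_weights = do.call(rbind, weights)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV, mean accuracy %.4f\n",
              x$k, x$mean_accuracy))
  cat("fold accuracies:", paste(sprintf("%.3f", x$fold_accuracy),
                                collapse = " "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Paired comparison of two classifiers' fold accuracies
#'
#' Thin wrapper around a paired t-test (standard statistic, not a
#' methodological contribution) for comparing per-fold accuracies of two
#' classifier variants run on identical folds.
#'
#' @param acc_a,acc_b per-fold accuracy vectors of equal length.
#' @return the `htest` object.
#' @export
paired_accuracy_test <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b))
  stats::t.test(acc_a, acc_b, paired = TRUE)
}

#' Serialize a fitted binary MKL model to JSON
#'
#' Stores kernel specs, weights, multipliers, bias, support-vector
#' indices, the (standardized) training snapshot and the normalization
#' constants, sufficient to reconstruct the decision function exactly.
#'
#' @param model an `mkl_model`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
save_mkl_model <- function(model, path) {
  stopifnot(inherits(model, "mkl_model"))
  payload <- list(
    specs = lapply(model$specs, unclass),
    d = model$d, alpha = model$dual$alpha, b = model$dual$b,
    sv_index = model$dual$sv_index,
    X_train = model$X_train, y_train = model$y_train,
    standardizer = model$standardizer,
    kernel_scale = model$kernel_scale,
    normalize_kernels = model$normalize_kernels,
    J = model$J, gap = model$gap, converged = model$converged,
    settings = unclass(model$settings))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @describeIn save_mkl_model load a model saved by `save_mkl_model`.
#' @export
load_mkl_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(nrow(p$specs)), function(i) {
    row <- as.list(p$specs[i, ])
    do.call(kernel_spec, c(list(family = row$family),
                           row[!vapply(row, is.na, logical(1)) &
                               names(row) != "family"]))
  })
  st <- if (is.null(p$standardizer)) NULL else
    list(center = p$standardizer$center, scale = p$standardizer$scale)
  structure(list(
    d = p$d, dual = list(alpha = p$alpha, b = p$b, sv_index = p$sv_index),
    specs = specs, X_train = as.matrix(p$X_train), y_train = p$y_train,
    standardizer = st, kernel_scale = p$kernel_scale,
    normalize_kernels = p$normalize_kernels,
    J = p$J, gap = p$gap, converged = p$converged,
    settings = do.call(mkl_settings,
                       p$settings[names(p$settings) != "seed"])),
    class = "mkl_model")
}

#' Run a complete experiment from a configuration
#'
#' Ties the stages together: generate (or load) epochs, extract features
#' along the requested path (`"wpe"` band entropies or `"granger"`
#' theta-band directed connectivity on region averages), run the k-fold
#' MKL cross-validation, and optionally write the artifacts (feature CSV,
#' CV summary JSON, pooled kernel-weight table, run manifest with a config
#' hash).  Deterministic for a fixed config and seed.
#'
#' @param config named list (or path to a JSON file) with entries:
#'   `path` ("wpe" or "granger"); `data` (either
#'   `list(source = "file", data_path =, meta_path =)` or
#'   `list(source = "synth", ...)` generator arguments); `kernels`
#'   (optional `degrees`, `widths`); `C`, `gap_tol`, `folds`, `seed`;
#'   wpe extras `band_scheme`, `entropy_normalized`; granger extras
#'   `var_order`, `band`, `region_map` (logical: average channels into
#'   regions first, default TRUE for multi-region montages).
#' @param out_dir optional output directory for artifacts.
#' @return list with `cv` (the [kfold_cv()] result), `features`,
#'   `weights`, `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  path <- match.arg(config$path, c("wpe", "granger"))
  seed <- config$seed %||% 1

  data_cfg <- config$data %||% stop("config$data is required")
  epochs <- if (identical(data_cfg$source, "file")) {
    load_eeg(data_cfg$data_path, data_cfg$meta_path)
  } else if (identical(data_cfg$source, "synth")) {
    if (path == "wpe") {
      specs <- lapply(data_cfg$classes, function(cl)
        do.call(mental_task_spec, cl))
      gen_mental_eeg(specs, data_cfg$trials_per_class %||% 40,
                     seed = child_seed(seed, 1))
    } else {
      gen_two_group_study(
        subjects_per_group = data_cfg$subjects_per_group %||% 13,
        trials_per_subject = data_cfg$trials_per_subject %||% 8,
        jitter_sd = data_cfg$jitter_sd %||% 0.1,
        seed = child_seed(seed, 1))
    }
  } else stop("config$data$source must be 'file' or 'synth'")

  features <- if (path == "wpe") {
    map <- band_map(epochs$fs, config$band_scheme %||% "literal")
    wpe_features(epochs, map = map,
                 normalized = config$entropy_normalized %||% TRUE)
  } else {
    ep <- if (isTRUE(config$region_map %||%
                       (length(epochs$channels) > 5)))
      region_average(epochs) else epochs
    gc_features(ep, band = config$band %||% c(4, 8),
                p = config$var_order %||% 5)
  }

  specs <- default_kernel_bank(
    degrees = config$kernels$degrees %||% 1:3,
    widths = config$kernels$widths %||% c(0.5, 1, 2, 5, 7, 10, 12, 15, 17, 20))
  settings <- mkl_settings(C = config$C %||% 100,
                           gap_tol = config$gap_tol %||% 0.01)
  cv <- kfold_cv(features, k = config$folds %||% 5, specs = specs,
                 settings = settings, seed = child_seed(seed, 2))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(label = features$labels, features$values,
                                check.names = FALSE),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cv$kernel_weights),
                     file.path(out_dir, "kernel_weights.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(mean_accuracy = cv$mean_accuracy,
           fold_accuracy = cv$fold_accuracy, k = cv$k, seed = seed),
      file.path(out_dir, "cv_summary.json"), auto_unbox = TRUE, digits = NA)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    manifest <- list(
      package = "neuromkl",
      version = as.character(utils::packageVersion("neuromkl")),
      r_version = R.version.string,
      config_md5 = unname(tools::md5sum(cfg_path)),
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(cv = cv, features = features, weights = cv$kernel_weights,
       config = config)
}
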