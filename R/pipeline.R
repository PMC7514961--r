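# End-to-end orchestration: fixed-order feature assembly (16 subband norms,
# then entropy, then fractal dimension), the seeded train/test protocol with
# cross-validated hyperparameter selection, and the CSV formats shared with
# the command-line interface.

FEATURE_SETS <- c("wavelet" = 16L, "wavelet+entropy" = 17L,
                  "wavelet+entropy+fractal" = 18L)

resolve_feature_set <- function(feature_set) {
  if (is.numeric(feature_set)) {
    i <- match(as.integer(feature_set), FEATURE_SETS)
    if (is.na(i)) stop("`feature_set` must be 16, 17 or 18", call. = FALSE)
    return(names(FEATURE_SETS)[i])
  }
  match.arg(feature_set, names(FEATURE_SETS))
}

#' Extract the feature vector of one record
#'
#' Windows the record to `window_n` samples, then computes, in fixed order:
#' the 16 two-norms of the level-4 wavelet-packet nodes, the wavelet energy
#' entropy (17th entry), and the box-counting fractal dimension (18th
#' entry), truncated to the requested nested feature set.
#'
#' @param record A [heart_sound_record()].
#' @param feature_set `"wavelet"` (16), `"wavelet+entropy"` (17) or
#'   `"wavelet+entropy+fractal"` (18); the numbers are accepted too.
#' @param window_n Analysis window length in samples (default 10000, i.e.
#'   5 s at 2000 Hz).
#' @param wavelet,level Wavelet-packet settings (default db6, level 4).
#' @param i_max Number of dyadic box-counting scales; `NULL` for the
#'   [box_dimension()] default.
#' @return An object of class `feature_vector`: fields `record_id`, `values`
#'   (named numeric vector), `feature_set`, `label`.
#' @export
extract_features <- function(record, feature_set = "wavelet+entropy+fractal",
                             window_n = 10000L, wavelet = "db6", level = 4L,
                             i_max = NULL) {
  stopifnot(inherits(record, "heart_sound_record"))
  feature_set <- resolve_feature_set(feature_set)
  win <- window_record(record, window_n)
  if (sum(win$samples^2) == 0) {
    stop(sprintf("record '%s': zero-energy window (entropy undefined)",
                 record$record_id), call. = FALSE)
  }
  table <- wpt_decompose(win, wavelet = wavelet, level = level)
  values <- node_norms(table)
  names(values) <- sprintf("f%d", seq_along(values))
  if (feature_set %in% c("wavelet+entropy", "wavelet+entropy+fractal")) {
    h <- energy_entropy(energy_spectrum(table))
    values <- c(values, stats::setNames(h, sprintf("f%d", length(values) + 1L)))
  }
  if (feature_set == "wavelet+entropy+fractal") {
    db <- box_dimension(win, i_max = i_max)$slope
    values <- c(values, stats::setNames(db, sprintf("f%d", length(values) + 1L)))
  }
  structure(
    list(record_id = win$record_id, values = values,
         feature_set = feature_set, label = win$label),
    class = "feature_vector"
  )
}

#' Extract features for a list of records
#'
#' @param records List of [heart_sound_record()]s.
#' @param ... Passed to [extract_features()].
#' @return A data.frame with columns `record_id`, `f1`..`fK`, `label`
#'   (`NA` where unset).
#' @export
extract_feature_matrix <- function(records, ...) {
  rows <- lapply(records, function(r) {
    fv <- extract_features(r, ...)
    df <- as.data.frame(as.list(fv$values))
    df <- cbind(data.frame(record_id = fv$record_id, stringsAsFactors = FALSE), df)
    df$label <- if (is.null(fv$label)) NA_character_ else fv$label
    df
  })
  do.call(rbind, rows)
}

label_to_pm <- function(label) {
  ifelse(label == "abnormal", 1, -1)
}

feature_columns <- function(df) {
  grep("^f[0-9]+$", names(df), value = TRUE)
}

#' Write / read a feature CSV
#'
#' Plain CSV with columns `record_id`, `f1`..`fK`, `label`.
#'
#' @param features Data frame from [extract_feature_matrix()].
#' @param path File path.
#' @return The path (write) or the data frame (read).
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"record_id" %in% names(df) || length(feature_columns(df)) == 0L) {
    stop(sprintf("'%s' is not a feature CSV (need record_id, f1..fK)", path),
         call. = FALSE)
  }
  df
}

#' Read a record-label CSV
#'
#' Two-column CSV `record_id,label`. Labels may be `normal`/`abnormal` or
#' the -1/1 convention of the challenge database (1 = abnormal, mapped to
#' the positive class).
#'
#' @param path File path.
#' @return Data frame with character columns `record_id` and `label`.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("record_id", "label") %in% names(df))) {
    stop(sprintf("'%s' must have columns record_id,label", path), call. = FALSE)
  }
  lab <- as.character(df$label)
  lab[lab %in% c("1", "+1")] <- "abnormal"
  lab[lab == "-1"] <- "normal"
  if (!all(lab %in% c("normal", "abnormal"))) {
    stop("labels must be normal/abnormal (or -1/1)", call. = FALSE)
  }
  data.frame(record_id = as.character(df$record_id), label = lab,
             stringsAsFactors = FALSE)
}

#' Experiment configuration
#'
#' Collects every knob of [run_experiment()]. An explicit `split_seed` is
#' mandatory: the train/test split is random and refusing to default it
#' keeps runs reproducible by construction.
#'
#' @param feature_set Feature set (16/17/18 or names; see
#'   [extract_features()]).
#' @param classifier `"twsvm"` or `"reference-svm"` (an established SVM used
#'   purely as a comparison baseline; requires the e1071 package).
#' @param hyper_grid Hyperparameter grid for [cross_validate()]; default the
#'   single point c1 = c2 = sigma1 = sigma2 = 3.5.
#' @param n_train Training-set size; default 200 when the dataset has at
#'   least 350 records, otherwise a proportional 4/7 of the data.
#' @param window_n,wavelet,level,i_max Feature-extraction settings.
#' @param folds Cross-validation folds (default 10).
#' @param split_seed,cv_seed Integer seeds for the train/test split and the
#'   fold assignment.
#' @param out_dir Optional directory for artifacts (features CSV, model
#'   file, report CSV, log); `NULL` writes nothing.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(feature_set = "wavelet+entropy+fractal",
                              classifier = c("twsvm", "reference-svm"),
                              hyper_grid = data.frame(c1 = 3.5, c2 = 3.5,
                                                      sigma1 = 3.5, sigma2 = 3.5),
                              n_train = NULL, window_n = 10000L,
                              wavelet = "db6", level = 4L, i_max = NULL,
                              folds = 10L, split_seed, cv_seed = 1L,
                              out_dir = NULL) {
  if (missing(split_seed)) {
    stop("`split_seed` is required: the train/test split is random and must be reproducible",
         call. = FALSE)
  }
  structure(
    list(feature_set = resolve_feature_set(feature_set),
         classifier = match.arg(classifier),
         hyper_grid = hyper_grid, n_train = n_train, window_n = window_n,
         wavelet = wavelet, level = level, i_max = i_max, folds = folds,
         split_seed = as.integer(split_seed), cv_seed = as.integer(cv_seed),
         out_dir = out_dir),
    class = "experiment_config"
  )
}

config_hash <- function(config) {
  flat <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  # small stable rolling hash; enough to tag artifacts with their config
  h <- 0
  for (b in utf8ToInt(flat)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a full classification experiment
#'
#' Extracts features for all records, makes a stratified seeded train/test
#' split (200 training records when at least 350 are available, mirroring
#' the usual 200/150 protocol), selects hyperparameters by stratified
#' cross-validation on the training set only, fits the final model on the
#' full training set, and evaluates on the held-out test records.
#'
#' @param records List of labelled [heart_sound_record()]s (both classes
#'   present), or a feature data.frame from [extract_feature_matrix()].
#' @param config An [experiment_config()].
#' @return A list of class `experiment_result`: `report` (test-set
#'   [metric_report()]), `confusion`, `model`, `cv`, `train_ids`,
#'   `test_ids`, `config`, `config_hash`, and `predictions` (data frame with
#'   `record_id`, `predicted_label`, `d1`, `d2`).
#' @export
run_experiment <- function(records, config) {
  stopifnot(inherits(config, "experiment_config"))

  if (is.data.frame(records)) {
    features <- records
  } else {
    features <- extract_feature_matrix(
      records, feature_set = config$feature_set, window_n = config$window_n,
      wavelet = config$wavelet, level = config$level, i_max = config$i_max)
  }
  if (any(is.na(features$label))) {
    stop("all records must be labelled for an experiment", call. = FALSE)
  }
  y <- label_to_pm(features$label)
  if (!any(y == 1) || !any(y == -1)) {
    stop("both classes must be present", call. = FALSE)
  }
  X <- as.matrix(features[, feature_columns(features)])
  n <- nrow(X)

  n_train <- config$n_train
  if (is.null(n_train)) n_train <- if (n >= 350L) 200L else round(n * 4 / 7)
  if (n_train < 2L || n_train >= n) stop("degenerate train/test split", call. = FALSE)

  # stratified split: training fraction applied within each class
  train_idx <- with_seed(config$split_seed, {
    idx <- integer(0)
    for (cls in c(-1, 1)) {
      members <- which(y == cls)
      take <- round(length(members) * n_train / n)
      take <- min(max(take, 1L), length(members) - 1L)
      idx <- c(idx, sample(members, take))
    }
    sort(idx)
  })
  test_idx <- setdiff(seq_len(n), train_idx)

  if (config$classifier == "twsvm") {
    cv <- cross_validate(X[train_idx, , drop = FALSE], y[train_idx],
                         folds = config$folds, hyper_grid = config$hyper_grid,
                         seed = config$cv_seed)
    hp <- cv$best
    model <- twsvm_fit(X[train_idx, , drop = FALSE], y[train_idx],
                       c1 = hp$c1, c2 = hp$c2,
                       sigma1 = hp$sigma1, sigma2 = hp$sigma2)
    dist <- decision_distances(model, X[test_idx, , drop = FALSE])
    pred <- ifelse(dist[, "d1"] < dist[, "d2"], 1, -1)
  } else {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      stop("classifier 'reference-svm' needs the e1071 package", call. = FALSE)
    }
    cv <- NULL
    model <- e1071::svm(X[train_idx, , drop = FALSE],
                        factor(y[train_idx], levels = c(-1, 1)),
                        kernel = "radial", scale = TRUE)
    pred <- as.numeric(as.character(predict(model, X[test_idx, , drop = FALSE])))
    dist <- matrix(NA_real_, nrow = length(pred), ncol = 2,
                   dimnames = list(NULL, c("d1", "d2")))
  }

  cm <- confusion(pred, y[test_idx])
  report <- metric_report(cm)
  predictions <- data.frame(
    record_id = features$record_id[test_idx],
    predicted_label = ifelse(pred == 1, "abnormal", "normal"),
    d1 = dist[, "d1"], d2 = dist[, "d2"], stringsAsFactors = FALSE)

  result <- structure(
    list(report = report, confusion = cm, model = model, cv = cv,
         train_ids = features$record_id[train_idx],
         test_ids = features$record_id[test_idx],
         predictions = predictions, config = config,
         config_hash = config_hash(config)),
    class = "experiment_result"
  )
  if (!is.null(config$out_dir)) write_experiment_artifacts(result, features)
  result
}

write_experiment_artifacts <- function(result, features) {
  dir_ <- result$config$out_dir
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash=%s split_seed=%d cv_seed=%d",
                   result$config_hash, result$config$split_seed,
                   result$config$cv_seed)

  f_path <- file.path(dir_, "features.csv")
  writeLines(stamp, f_path)
  suppressWarnings(utils::write.table(
    features, f_path, sep = ",", row.names = FALSE, append = TRUE, qmethod = "double"))

  if (inherits(result$model, "twsvm_model")) {
    twsvm_save(result$model, file.path(dir_, "model.rds"))
  }

  r_path <- file.path(dir_, "report.csv")
  writeLines(stamp, r_path)
  suppressWarnings(utils::write.table(
    report_table(list(test = result$report)), r_path, sep = ",",
    row.names = FALSE, append = TRUE))

  p_path <- file.path(dir_, "predictions.csv")
  writeLines(stamp, p_path)
  suppressWarnings(utils::write.table(
    result$predictions, p_path, sep = ",", row.names = FALSE, append = TRUE))

  log_path <- file.path(dir_, "run.log")
  writeLines(c(stamp, utils::capture.output(utils::str(unclass(result$config))),
               utils::capture.output(print(result$report))), log_path)
  invisible(dir_)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s / %s, %d train / %d test\n",
              x$config$classifier, x$config$feature_set,
              length(x$train_ids), length(x$test_ids)))
  print(x$report)
  invisible(x)
}
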