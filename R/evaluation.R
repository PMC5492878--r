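#' Pipeline configuration
#'
#' Bundles every tunable of the detection pipeline: the feature set, whether
#' the Kalman pre-filter runs, the filter parameters, window geometry, the
#' classifier family and its hyper-parameters, and the window decision rule.
#'
#' @param feature_set `"FS9"`, `"FS7"` or `"FS3"`, see [feature_set()].
#' @param kalman Run the Kalman pre-filter (default `TRUE`).
#' @param classifier `"bayes_net"` (default) or `"naive_bayes"` (Gaussian).
#' @param width_seconds Sliding-window duration in seconds (default 2, i.e.
#'   200 samples at 100 Hz).
#' @param step_samples Slide step for `window_select = "all"` (default 1).
#' @param window_select Which window(s) represent a recording during
#'   training/evaluation: `"center"` (default; one window centred on the
#'   recording, avoiding near-duplicate overlapping windows being counted as
#'   independent instances), `"start"`, or `"all"` (every step-`step_samples`
#'   window).
#' @param rule Window decision rule, see [classify_window()].
#' @param bins,alpha,max_parents Bayes-network hyper-parameters, see
#'   [train_bayes_network()].
#' @param accel_params,gyro_params [kalman_params()] for the pre-filter.
#' @param angle_from Compute the trunk angle from `"filtered"` (default) or
#'   `"raw"` accelerations when the filter is on.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_set = "FS9",
                            kalman = TRUE,
                            classifier = c("bayes_net", "naive_bayes"),
                            width_seconds = 2,
                            step_samples = 1L,
                            window_select = c("center", "start", "all"),
                            rule = c("mean_log_posterior", "majority"),
                            bins = 10L,
                            alpha = 0.5,
                            max_parents = 1L,
                            accel_params = default_kalman_params("accel"),
                            gyro_params = default_kalman_params("gyro"),
                            angle_from = c("filtered", "raw")) {
  feature_set(feature_set)  # validates the name
  structure(list(feature_set = feature_set, kalman = kalman,
                 classifier = match.arg(classifier),
                 width_seconds = width_seconds,
                 step_samples = as.integer(step_samples),
                 window_select = match.arg(window_select),
                 rule = match.arg(rule),
                 bins = as.integer(bins), alpha = alpha,
                 max_parents = as.integer(max_parents),
                 accel_params = accel_params, gyro_params = gyro_params,
                 angle_from = match.arg(angle_from)),
            class = "pipeline_config")
}

#' Turn labelled streams into window instances
#'
#' Runs the front half of the pipeline on each recording: optional Kalman
#' filtering, per-sample feature vectors for the configured feature set, and
#' window extraction per `window_select`.
#'
#' @param streams List of labelled [imu_stream()]s.
#' @param config A [pipeline_config()].
#' @return List of `imu_window` instances (one per recording for
#'   `"center"`/`"start"`, possibly many for `"all"`).
#' @export
prepare_instances <- function(streams, config = pipeline_config()) {
  out <- lapply(streams, function(s) {
    width <- window_duration(stream_fs(s), config$width_seconds)
    if (nrow(s) < width) {
      stop(sprintf("recording of %d samples is shorter than one %d-sample window",
                   nrow(s), width))
    }
    proc <- if (config$kalman) {
      filter_stream(s, config$accel_params, config$gyro_params)
    } else s
    m <- make_feature_vectors(proc, config$feature_set)
    if (config$kalman && config$angle_from == "raw" && "theta" %in% colnames(m)) {
      m[, "theta"] <- trunk_angle(s$ax, s$ay, s$az)
    }
    if (config$window_select == "all") {
      slide(m, width = width, step = config$step_samples)
    } else {
      start <- if (config$window_select == "center") {
        (nrow(m) - width) %/% 2L
      } else 0L
      list(structure(list(start_index = as.integer(start),
                          elements = m[(start + 1L):(start + width), ,
                                       drop = FALSE],
                          label = stream_label(s)),
                     class = "imu_window"))
    }
  })
  unlist(out, recursive = FALSE)
}

# Train the configured classifier on stacked window samples.
train_pipeline_model <- function(instances, config) {
  x <- do.call(rbind, lapply(instances, `[[`, "elements"))
  y <- rep(vapply(instances, `[[`, "", "label"),
           times = vapply(instances, function(w) nrow(w$elements), integer(1)))
  if (config$classifier == "bayes_net") {
    train_bayes_network(x, y, max_parents = config$max_parents,
                        bins = config$bins, alpha = config$alpha)
  } else {
    train_naive_bayes(x, y, likelihood = "gaussian")
  }
}

#' Tabulate a confusion matrix
#'
#' @param true,predicted Character vectors of true and predicted labels.
#' @param classes Class universe fixing row/column order.
#' @return A `classes x classes` integer matrix of counts, rows = true
#'   class, columns = predicted class.
#' @export
confusion_table <- function(true, predicted, classes = activity_classes()) {
  m <- unclass(table(factor(true, levels = classes),
                     factor(predicted, levels = classes)))
  names(dimnames(m)) <- NULL
  m
}

#' Detection metrics from a confusion table
#'
#' Computes the metric set used to summarise six-class fall-detection
#' experiments:
#' * `accuracy`: fraction of instances whose predicted class equals the true
#'   class (six-class accuracy);
#' * `sensitivity`: fraction of true falls (either fall subtype) predicted
#'   as *any* fall class -- confusing the two fall subtypes still alarms, so
#'   it counts as detection here even though it is an error for six-class
#'   accuracy;
#' * `specificity`: fraction of true ADLs predicted as any ADL class;
#' * `tp_rate`/`fp_rate`: the fall-vs-ADL binarisation's true/false-positive
#'   rates (`tp_rate = sensitivity`, `fp_rate = 1 - specificity`);
#' * `per_class`: per-class accuracy (diagonal over row totals).
#'
#' @param table Confusion matrix from [confusion_table()] (rows = true).
#' @return A list of class `metric_report`.
#' @export
confusion_to_metrics <- function(table) {
  table <- as.matrix(table)
  if (sum(table) == 0) stop("empty input: confusion table has zero total")
  classes <- rownames(table)
  falls <- intersect(classes, fall_classes())
  adls <- setdiff(classes, falls)
  sens <- if (length(falls) && sum(table[falls, ]) > 0) {
    sum(table[falls, falls]) / sum(table[falls, ])
  } else NA_real_
  spec <- if (length(adls) && sum(table[adls, ]) > 0) {
    sum(table[adls, adls]) / sum(table[adls, ])
  } else NA_real_
  structure(list(
    accuracy = sum(diag(table)) / sum(table),
    sensitivity = sens,
    specificity = spec,
    tp_rate = sens,
    fp_rate = 1 - spec,
    per_class = diag(table) / rowSums(table),
    confusion = table
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% | fall sensitivity %.2f%% | specificity %.2f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  pc <- sprintf("%s %.0f%%", names(x$per_class), 100 * x$per_class)
  cat("per-class:", paste(pc, collapse = ", "), "\n")
  invisible(x)
}

# Stratified fold assignment at the recording level: within each class,
# recordings are shuffled and dealt to folds round-robin, so per-class fold
# sizes differ by at most one.
assign_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  set.seed(mix_seed(seed, 7L))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop(sprintf("config error: class '%s' has %d recordings, fewer than k = %d folds",
                   cls, length(idx), k))
    }
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of the pipeline
#'
#' Evaluates the full pipeline by k-fold cross-validation stratified at the
#' recording level: no recording contributes windows to both the training and
#' the test side of any fold.  Per fold, the classifier is trained on the
#' stacked per-sample feature vectors of the training recordings' windows and
#' each test recording's window is classified with the configured decision
#' rule; confusions accumulate over folds.  Deterministic given `seed`.
#'
#' @param streams List of labelled [imu_stream()]s, at least `k` per class.
#' @param config A [pipeline_config()].
#' @param k Number of folds, default 10.
#' @param seed Integer seed for the fold shuffle.
#' @param folds Optional precomputed fold assignment (integer per stream),
#'   e.g. to pair ablation runs on identical folds.
#' @return List with `confusion` (aggregate [confusion_table()]), `metrics`
#'   ([confusion_to_metrics()]), `fold_confusions` and `folds`.
#' @export
cross_validate <- function(streams, config = pipeline_config(), k = 10L,
                           seed = 17, folds = NULL) {
  labels <- vapply(streams, function(s) stream_label(s) %||% NA_character_, "")
  if (anyNA(labels)) stop("all streams must be labelled for cross-validation")
  if (is.null(folds)) folds <- assign_folds(labels, k, seed)
  k <- max(folds)
  instances <- prepare_instances(streams, config)
  inst_fold <- rep(folds, times = vapply(seq_along(streams), function(i) {
    if (config$window_select == "all") {
      width <- window_duration(stream_fs(streams[[i]]), config$width_seconds)
      length(seq(0L, nrow(streams[[i]]) - width, by = config$step_samples))
    } else 1L
  }, integer(1)))
  classes <- intersect(activity_classes(), unique(labels))
  if (length(classes) == 0L) classes <- sort(unique(labels))
  total <- matrix(0L, length(classes), length(classes),
                  dimnames = list(classes, classes))
  fold_tables <- vector("list", k)
  for (f in seq_len(k)) {
    train <- instances[inst_fold != f]
    test <- instances[inst_fold == f]
    model <- train_pipeline_model(train, config)
    pred <- vapply(test, function(w) classify_window(model, w, config$rule), "")
    truth <- vapply(test, `[[`, "", "label")
    fold_tables[[f]] <- confusion_table(truth, pred, classes)
    total <- total + fold_tables[[f]]
  }
  list(confusion = total,
       metrics = confusion_to_metrics(total),
       fold_confusions = fold_tables,
       folds = folds)
}

#' Paired ablation comparison
#'
#' Cross-validates several pipeline configurations over *identical* fold
#' assignments, so metric differences are attributable to configuration
#' alone.  Typical ablations: feature sets (`FS9`/`FS7`/`FS3`) and the
#' Kalman pre-filter (on/off).
#'
#' @param streams Labelled recordings.
#' @param configs Named list of [pipeline_config()]s.
#' @param k,seed As in [cross_validate()].
#' @return A list with `table` (a data frame: one row per config with
#'   accuracy, sensitivity, specificity, tp/fp rates) and `runs` (the full
#'   [cross_validate()] results).
#' @export
ablation_report <- function(streams, configs, k = 10L, seed = 17) {
  if (length(configs) < 1L) stop("empty input: at least one config required")
  if (is.null(names(configs))) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  labels <- vapply(streams, function(s) stream_label(s) %||% NA_character_, "")
  folds <- assign_folds(labels, k, seed)
  runs <- lapply(configs, function(cfg) {
    cross_validate(streams, cfg, k = k, seed = seed, folds = folds)
  })
  tab <- do.call(rbind, lapply(names(runs), function(nm) {
    m <- runs[[nm]]$metrics
    data.frame(config = nm, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               tp_rate = m$tp_rate, fp_rate = m$fp_rate)
  }))
  list(table = tab, runs = runs)
}
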