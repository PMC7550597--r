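#' SVM hyperparameter configuration
#'
#' @param kernel Kernel name for [e1071::svm()] (default `"radial"`).
#' @param cost Soft-margin cost C (default 1).
#' @param gamma RBF kernel width; `NULL` (default) selects it by the median
#'   heuristic on the standardized training rows
#'   (`gamma = 1 / (2 * median pairwise squared distance)`).
#' @param class_weights `"inverse"` (default) weights classes inversely to
#'   their training frequency (abnormal peaks are typically the minority);
#'   `"none"` disables weighting; or a named numeric vector.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = "radial", cost = 1, gamma = NULL,
                       class_weights = "inverse") {
  stopifnot(cost > 0)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 class_weights = class_weights),
            class = "svm_config")
}

# median-heuristic RBF width on (standardized) rows; deterministic subsample
.median_gamma <- function(x, max_rows = 500) {
  n <- nrow(x)
  if (n > max_rows)
    x <- x[round(seq(1, n, length.out = max_rows)), , drop = FALSE]
  d2 <- as.numeric(stats::dist(x))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) return(1 / ncol(x))
  1 / (2 * m)
}

.class_weights <- function(labels, spec) {
  if (is.numeric(spec)) return(spec)
  if (identical(spec, "none")) return(NULL)
  tab <- table(labels)
  w <- as.numeric(sum(tab) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

# shared trainer for both classifier levels
.train_svm <- function(features, labels, feature_names, level, cfg) {
  labels <- factor(labels, levels = c("normal", "abnormal"))
  if (nrow(features) != length(labels))
    stop("feature rows and labels differ in length")
  if (nlevels(droplevels(labels)) < 2)
    stop("training labels contain a single class; cannot fit the ",
         level, "-level SVM")
  x <- as.matrix(features[, feature_names, drop = FALSE])
  if (anyNA(x)) stop("training features contain missing values")
  # constant columns carry no information and cannot be standardized; they
  # are flagged and excluded from the model (recorded in meta$dropped)
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  feature_names <- setdiff(feature_names, dropped)
  if (length(feature_names) == 0)
    stop("all feature columns are constant on the training set")
  x <- x[, feature_names, drop = FALSE]
  stats <- fit_standardizer(x)
  xs <- apply_standardizer(stats, x)
  gamma <- if (is.null(cfg$gamma)) .median_gamma(xs) else cfg$gamma
  model <- e1071::svm(x = xs, y = labels, type = "C-classification",
                      kernel = cfg$kernel, cost = cfg$cost, gamma = gamma,
                      class.weights = .class_weights(labels, cfg$class_weights),
                      scale = FALSE)
  structure(list(level = level, stats = stats, model = model,
                 feature_names = feature_names,
                 hyper = list(kernel = cfg$kernel, cost = cfg$cost,
                              gamma = gamma),
                 meta = list(n = nrow(xs), classes = table(labels),
                             dropped = dropped)),
            class = "cat_classifier")
}

#' @export
print.cat_classifier <- function(x, ...) {
  cat(sprintf("<cat_classifier> %s-level SVM (%s kernel, C=%g, gamma=%.4g)\n",
              x$level, x$hyper$kernel, x$hyper$cost, x$hyper$gamma))
  cat(sprintf("  trained on %d rows: %s\n", x$meta$n,
              paste(names(x$meta$classes), x$meta$classes,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Score new rows with a trained classifier
#'
#' Applies the training standardization, then the fitted SVM. The decision
#' score is the signed distance from the separating boundary with abnormal
#' as the positive direction.
#'
#' @param object A `cat_classifier`.
#' @param newdata Data frame containing the training feature columns.
#' @param ... Unused.
#' @return Data frame with `label` (factor normal/abnormal) and `score`.
#' @export
predict.cat_classifier <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss) > 0)
    stop("newdata is missing feature column(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  xs <- apply_standardizer(object$stats, x)
  pr <- stats::predict(object$model, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- as.numeric(dv[, 1])
  # e1071 orients the decision value toward the first class in the column name
  if (grepl("^normal/", colnames(dv)[1])) score <- -score
  data.frame(label = factor(as.character(pr), levels = c("normal", "abnormal")),
             score = score)
}

#' Save / load a trained classifier
#'
#' Plain RDS serialization; reloaded models give bit-identical predictions.
#'
#' @param model A `cat_classifier`.
#' @param path File path.
#' @return `path` (save) or the classifier (load).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "cat_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "cat_classifier")) stop("not a serialized cat_classifier")
  m
}

#' Train the peak-level SVM
#'
#' Fits a binary SVM on the 14 peak variables, taking expert peak
#' assessments as the outcome. The first-peak `delta` is imputed with the
#' signal's median peak distance ([complete_features()]); standardization is
#' fitted on the training rows and stored with the model.
#'
#' @param features Cohort feature table ([quantify_cohort()] output).
#' @param labels Peak label vector aligned with `features` rows, or a label
#'   table with `cell_id`, `peak_index`, `label` to be joined.
#' @param cfg An [svm_config()].
#' @return A `cat_classifier` with `level = "peak"`.
#' @export
train_peak_svm <- function(features, labels, cfg = svm_config()) {
  features <- complete_features(features)
  labels <- .align_peak_labels(features, labels)
  .train_svm(features, labels, PEAK_FEATURES, "peak", cfg)
}

.align_peak_labels <- function(features, labels) {
  if (is.data.frame(labels)) {
    key_f <- paste(features$cell_id, features$peak_index, sep = "\r")
    key_l <- paste(labels$cell_id, labels$peak_index, sep = "\r")
    idx <- match(key_f, key_l)
    if (anyNA(idx))
      stop("label table is missing ", sum(is.na(idx)), " peak key(s)")
    labels$label[idx]
  } else labels
}

#' Leave-one-signal-out predictions of the peak-level SVM
#'
#' For every signal in turn, all of its peaks form the held-out fold and a
#' peak-level SVM is trained on the peaks of all other signals;
#' standardization (and the median-heuristic kernel width) are refitted
#' inside each fold on that fold's training rows only, so no information
#' from the held-out signal leaks into its own predictions.
#'
#' @param features Cohort feature table.
#' @param labels Peak labels (vector aligned to rows, or a label table).
#' @param cfg An [svm_config()].
#' @return Data frame `cell_id`, `peak_index`, `label`, `score` covering
#'   every peak, in the input row order.
#' @export
loocv_peak_predictions <- function(features, labels, cfg = svm_config()) {
  features <- complete_features(features)
  lab <- .align_peak_labels(features, labels)
  ids <- unique(features$cell_id)
  if (length(ids) < 3)
    stop("leave-one-signal-out needs at least 3 signals")
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    test <- features$cell_id == ids[k]
    model <- tryCatch(
      .train_svm(features[!test, , drop = FALSE], lab[!test],
                 PEAK_FEATURES, "peak", cfg),
      error = function(e) stop("fold '", ids[k], "': ", conditionMessage(e)))
    pr <- predict(model, features[test, , drop = FALSE])
    out[[k]] <- cbind(features[test, c("cell_id", "peak_index")], pr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(paste(res$cell_id, res$peak_index),
                  paste(features$cell_id, features$peak_index))), ]
}

#' Names of the 6 cell-level variables
#' @export
CELL_FEATURES <- c("analytical_cell_label", "svm_cell_label",
                   "prop_abnormal", "var_A", "var_delta", "var_R")

#' Build per-signal cell feature vectors
#'
#' Aggregates the two peak-assessment sources and the within-signal
#' variability measures into the 6 predictors of the cell-level SVM:
#' `analytical_cell_label` and `svm_cell_label` (any-abnormal over the
#' respective peak labels, encoded 0/1), `prop_abnormal` (fraction of
#' SVM-predicted abnormal peaks), and the sample variances of peak amplitude
#' (`max(A_l, A_r)`), of the defined peak distances, and of peak areas.
#'
#' @param features Cohort feature table (raw `delta`, first peak `NA`).
#' @param analytical Per-peak analytical assessment table
#'   ([assess_cohort_analytical()]).
#' @param svm_pred Per-peak SVM prediction table ([loocv_peak_predictions()]
#'   or [predict.cat_classifier()] output with keys).
#' @return Data frame with `cell_id` and the columns of [CELL_FEATURES].
#' @export
build_cell_features <- function(features, analytical, svm_pred) {
  ids <- unique(features$cell_id)
  rows <- lapply(ids, function(id) {
    f <- features[features$cell_id == id, , drop = FALSE]
    a <- analytical[analytical$cell_id == id, , drop = FALSE]
    s <- svm_pred[svm_pred$cell_id == id, , drop = FALSE]
    if (nrow(a) != nrow(f) || nrow(s) != nrow(f))
      stop("signal '", id, "': peak counts disagree between sources (",
           nrow(f), " features, ", nrow(a), " analytical, ", nrow(s), " svm)")
    data.frame(
      cell_id = id,
      analytical_cell_label = as.numeric(any(a$label == "abnormal")),
      svm_cell_label = as.numeric(any(s$label == "abnormal")),
      prop_abnormal = mean(s$label == "abnormal"),
      var_A = stats::var(pmax(f$A_l, f$A_r)),
      # a signal with two peaks has a single inter-peak interval: no rhythm
      # variability is observable, so its variance is taken as 0
      var_delta = if (sum(!is.na(f$delta)) >= 2)
        stats::var(f$delta[!is.na(f$delta)]) else 0,
      var_R = stats::var(f$R),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Train the cell-level SVM
#'
#' Fits a binary SVM on the 6 cell variables (the two binary labels are
#' standardized together with the continuous variables), taking expert cell
#' assessments as the outcome.
#'
#' @param cell_features Output of [build_cell_features()].
#' @param labels Cell label vector aligned with rows, or a cell label table
#'   with `cell_id`, `label`.
#' @param cfg An [svm_config()].
#' @return A `cat_classifier` with `level = "cell"`.
#' @export
train_cell_svm <- function(cell_features, labels, cfg = svm_config()) {
  labels <- .align_cell_labels(cell_features, labels)
  .train_svm(cell_features, labels, CELL_FEATURES, "cell", cfg)
}

.align_cell_labels <- function(cell_features, labels) {
  if (is.data.frame(labels)) {
    idx <- match(cell_features$cell_id, labels$cell_id)
    if (anyNA(idx)) stop("cell label table is missing ", sum(is.na(idx)),
                         " cell id(s)")
    labels$label[idx]
  } else labels
}

#' Leave-one-signal-out predictions of the cell-level SVM
#'
#' One cell per fold; standardization refitted per fold.
#'
#' @inheritParams train_cell_svm
#' @return Data frame `cell_id`, `label`, `score`.
#' @export
loocv_cell_predictions <- function(cell_features, labels, cfg = svm_config()) {
  lab <- .align_cell_labels(cell_features, labels)
  n <- nrow(cell_features)
  if (n < 3) stop("leave-one-signal-out needs at least 3 cells")
  out <- vector("list", n)
  for (k in seq_len(n)) {
    model <- tryCatch(
      .train_svm(cell_features[-k, , drop = FALSE], lab[-k],
                 CELL_FEATURES, "cell", cfg),
      error = function(e) stop("fold '", cell_features$cell_id[k], "': ",
                               conditionMessage(e)))
    pr <- predict(model, cell_features[k, , drop = FALSE])
    out[[k]] <- cbind(cell_features[k, "cell_id", drop = FALSE], pr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score new signals with the trained cascade
#'
#' Runs the full chain on raw traces: peak detection and filtering, feature
#' quantification, rule-based assessment, peak-level SVM scoring (with the
#' stored training standardization), cell feature construction, and
#' cell-level SVM scoring. Signals excluded by the minimum-peak filter are
#' reported with `status = "excluded"` rather than dropped silently.
#'
#' @param peak_model Trained peak-level `cat_classifier`.
#' @param cell_model Trained cell-level `cat_classifier`.
#' @param traces Named list of [calcium_trace()] objects.
#' @param det_cfg A [detection_config()].
#' @param rule_cfg A [rule_config()].
#' @return List with `cells` (data frame `cell_id`, `label`, `score`,
#'   `n_peaks`, `prop_abnormal`, `status`), `peaks` (per-peak SVM
#'   predictions), `analytical` (per-peak rule assessments) and `features`
#'   (the peak feature table) for provenance.
#' @export
predict_cells <- function(peak_model, cell_model, traces,
                          det_cfg = detection_config(),
                          rule_cfg = rule_config()) {
  det <- detect_cohort(traces, det_cfg)
  empty <- data.frame(cell_id = character(0), label = character(0),
                      score = numeric(0), n_peaks = integer(0),
                      prop_abnormal = numeric(0), status = character(0))
  if (length(det$peaks) == 0) {
    exc <- det$excluded
    if (nrow(exc) > 0)
      empty <- data.frame(cell_id = exc$cell_id, label = NA_character_,
                          score = NA_real_, n_peaks = exc$n_peaks,
                          prop_abnormal = NA_real_, status = "excluded")
    return(list(cells = empty, peaks = NULL, analytical = NULL,
                features = NULL))
  }
  features <- quantify_cohort(traces, det$peaks)
  analytical <- assess_cohort_analytical(features, rule_cfg)
  pp <- predict(peak_model, complete_features(features))
  peak_pred <- cbind(features[, c("cell_id", "peak_index")], pp)
  cf <- build_cell_features(features, analytical, peak_pred)
  cp <- predict(cell_model, cf)
  cells <- data.frame(cell_id = cf$cell_id,
                      label = as.character(cp$label),
                      score = cp$score,
                      n_peaks = as.integer(table(features$cell_id)[cf$cell_id]),
                      prop_abnormal = cf$prop_abnormal,
                      status = "scored", stringsAsFactors = FALSE)
  if (nrow(det$excluded) > 0)
    cells <- rbind(cells,
                   data.frame(cell_id = det$excluded$cell_id,
                              label = NA_character_, score = NA_real_,
                              n_peaks = det$excluded$n_peaks,
                              prop_abnormal = NA_real_, status = "excluded",
                              stringsAsFactors = FALSE))
  list(cells = cells, peaks = peak_pred, analytical = analytical,
       features = features)
}
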