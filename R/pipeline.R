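#' Expert-style cell labels restricted to analyzable signals
#'
#' @keywords internal
.retained_cells <- function(cells, peaks) {
  cells[cells$cell_id %in% names(peaks), , drop = FALSE]
}

# polynomial rolling fingerprint of a string, for tagging artifacts with
# the configuration that produced them
.config_fingerprint <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full training / test study on synthetic cohorts
#'
#' Replays the complete workflow: generate a training and an independent
#' test cohort, detect and filter peaks, quantify the 14 peak variables,
#' assess peaks with the analytical rules, obtain leave-one-signal-out
#' peak-level SVM predictions, build cell variables, validate the
#' cell-level SVM by leave-one-signal-out on the training cohort, then
#' train final peak- and cell-level models on all training data and score
#' the test cohort. Expert labels are played by the generator's ground
#' truth. All evaluation uses abnormal as the positive class.
#'
#' @param seed Integer seed driving both cohorts (test cohort uses
#'   `seed + 1`).
#' @param n_train,n_test Cohort sizes (defaults 200 and 54).
#' @param gen_cfg Optional [generator_config()] template; its `n_signals`
#'   and `seed` are overridden per cohort.
#' @param det_cfg,rule_cfg,svm_cfg Stage configurations.
#' @param out_dir Optional directory: when given, stage outputs are written
#'   as CSV/JSON artifacts together with the effective configuration and
#'   its fingerprint.
#' @param verbose Log progress to stderr.
#' @return List with `peak_eval_analytical`, `peak_eval_svm` (training
#'   peaks), `cell_eval_train_analytical`, `cell_eval_train_svm` (LOOCV),
#'   `cell_eval_test_analytical`, `cell_eval_test_svm`, the trained
#'   `peak_model` and `cell_model`, and the intermediate tables.
#' @export
run_pipeline <- function(seed = 1, n_train = 200, n_test = 54,
                         gen_cfg = NULL,
                         det_cfg = detection_config(),
                         rule_cfg = rule_config(),
                         svm_cfg = svm_config(),
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  base_cfg <- if (is.null(gen_cfg)) generator_config() else gen_cfg

  make_cfg <- function(n, s, prefix) {
    cfg <- base_cfg
    cfg$n_signals <- n; cfg$seed <- s; cfg$id_prefix <- prefix
    cfg
  }
  say("generating cohorts (", n_train, " train / ", n_test, " test)")
  train <- generate_cohort(make_cfg(n_train, seed, "train"))
  test <- generate_cohort(make_cfg(n_test, seed + 1, "test"))

  say("detecting peaks")
  det_train <- detect_cohort(train$traces, det_cfg, verbose)
  feats_train <- quantify_cohort(train$traces, det_train$peaks)
  peak_labels_train <- label_detected_peaks(
    train$peaks, feats_train[, c("cell_id", "peak_index", "max_idx")])
  cells_train <- .retained_cells(train$cells, det_train$peaks)

  say("analytical assessment")
  ana_train <- assess_cohort_analytical(feats_train, rule_cfg)
  ana_cell_train <- stats::aggregate(
    label ~ cell_id, data = ana_train,
    FUN = function(l) as.character(assess_cell_analytical(l)))

  say("peak-level SVM leave-one-signal-out")
  loocv_peaks <- loocv_peak_predictions(feats_train, peak_labels_train, svm_cfg)

  peak_eval_analytical <- evaluate_predictions(ana_train$label,
                                               peak_labels_train$label)
  peak_eval_svm <- evaluate_predictions(loocv_peaks$label,
                                        peak_labels_train$label,
                                        loocv_peaks$score)

  say("cell-level SVM leave-one-signal-out")
  cell_feats_train <- build_cell_features(feats_train, ana_train, loocv_peaks)
  truth_train <- cells_train$label[match(cell_feats_train$cell_id,
                                         cells_train$cell_id)]
  loocv_cells <- loocv_cell_predictions(cell_feats_train, truth_train, svm_cfg)
  cell_eval_train_svm <- evaluate_predictions(loocv_cells$label, truth_train,
                                              loocv_cells$score)
  ana_lab_train <- ana_cell_train$label[match(cell_feats_train$cell_id,
                                              ana_cell_train$cell_id)]
  cell_eval_train_analytical <- evaluate_predictions(ana_lab_train, truth_train)

  say("training final models and scoring the test cohort")
  peak_model <- train_peak_svm(feats_train, peak_labels_train, svm_cfg)
  cell_model <- train_cell_svm(cell_feats_train, truth_train, svm_cfg)
  pred_test <- predict_cells(peak_model, cell_model, test$traces,
                             det_cfg, rule_cfg)
  scored <- pred_test$cells[pred_test$cells$status == "scored", ]
  truth_test <- test$cells$label[match(scored$cell_id, test$cells$cell_id)]
  cell_eval_test_svm <- evaluate_predictions(scored$label, truth_test,
                                             scored$score)
  ana_cell_test <- stats::aggregate(
    label ~ cell_id, data = pred_test$analytical,
    FUN = function(l) as.character(assess_cell_analytical(l)))
  ana_lab_test <- ana_cell_test$label[match(scored$cell_id,
                                            ana_cell_test$cell_id)]
  cell_eval_test_analytical <- evaluate_predictions(ana_lab_test, truth_test)

  res <- list(
    peak_eval_analytical = peak_eval_analytical,
    peak_eval_svm = peak_eval_svm,
    cell_eval_train_analytical = cell_eval_train_analytical,
    cell_eval_train_svm = cell_eval_train_svm,
    cell_eval_test_analytical = cell_eval_test_analytical,
    cell_eval_test_svm = cell_eval_test_svm,
    peak_model = peak_model, cell_model = cell_model,
    train = train, test = test,
    features_train = feats_train, peak_labels_train = peak_labels_train,
    analytical_train = ana_train, loocv_peaks = loocv_peaks,
    cell_features_train = cell_feats_train, loocv_cells = loocv_cells,
    excluded_train = det_train$excluded, predictions_test = pred_test,
    seed = seed)

  if (!is.null(out_dir)) .write_artifacts(res, out_dir, base_cfg, det_cfg,
                                          rule_cfg, svm_cfg)
  res
}

.report_list <- function(e) {
  list(n = e$n, tp = e$tp, fp = e$fp, tn = e$tn, fn = e$fn,
       accuracy = e$accuracy, sensitivity = e$sensitivity,
       specificity = e$specificity, auc = e$auc)
}

.write_artifacts <- function(res, out_dir, gen_cfg, det_cfg, rule_cfg,
                             svm_cfg) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_all <- list(generator = unclass(gen_cfg), detection = unclass(det_cfg),
                  rules = unclass(rule_cfg), svm = unclass(svm_cfg),
                  seed = res$seed)
  cfg_json <- jsonlite::toJSON(cfg_all, auto_unbox = TRUE, digits = NA,
                               null = "null", pretty = TRUE)
  fp <- .config_fingerprint(as.character(cfg_json))
  writeLines(as.character(cfg_json), file.path(out_dir, "config.json"))
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE, quote = FALSE)
  write_traces(res$train$traces, file.path(out_dir, "traces_train.csv"))
  write_traces(res$test$traces, file.path(out_dir, "traces_test.csv"))
  w(res$features_train, "features_train.csv")
  w(res$peak_labels_train, "expert_peak_labels_train.csv")
  w(res$analytical_train, "analytical_peaks_train.csv")
  w(res$loocv_peaks, "svm_loocv_peaks_train.csv")
  w(res$cell_features_train, "cell_features_train.csv")
  w(res$loocv_cells, "svm_loocv_cells_train.csv")
  w(res$excluded_train, "excluded_signals_train.csv")
  w(res$predictions_test$cells, "predictions_test.csv")
  report <- list(
    config_fingerprint = fp,
    peak_level_train = list(
      analytical = .report_list(res$peak_eval_analytical),
      svm_loocv = .report_list(res$peak_eval_svm)),
    cell_level_train = list(
      analytical = .report_list(res$cell_eval_train_analytical),
      svm_loocv = .report_list(res$cell_eval_train_svm)),
    cell_level_test = list(
      analytical = .report_list(res$cell_eval_test_analytical),
      svm = .report_list(res$cell_eval_test_svm)))
  writeLines(as.character(jsonlite::toJSON(report, auto_unbox = TRUE,
                                           digits = NA, null = "null",
                                           pretty = TRUE)),
             file.path(out_dir, "evaluation.json"))
  invisible(out_dir)
}
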