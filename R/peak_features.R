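#' Names of the 14 peak-level variables
#'
#' Amplitudes (`A_l`, `A_r`, `A_d`), durations (`D_l`, `D_r`), first- and
#' second-derivative extrema (`Dy_max`, `Dy_min`, `D2y_max`, `D2y_min`), peak
#' area (`R`), inter-peak distance (`delta`), sub-durations
#' (`delta_l2Dymax`, `delta_m2Dymin`) and the per-signal median peak distance
#' (`Peak_distance_median`).
#'
#' @export
PEAK_FEATURES <- c("A_l", "A_r", "A_d", "D_l", "D_r",
                   "Dy_max", "Dy_min", "D2y_max", "D2y_min", "R",
                   "delta", "delta_l2Dymax", "delta_m2Dymin",
                   "Peak_distance_median")

#' Quantify the peak variables of one detected peak
#'
#' All durations are in seconds (dt = 1/sampling_hz); derivative extrema in
#' AU/s and AU/s^2; `Dy_min` and `D2y_min` are stored as absolute values.
#' `R` is the trapezoidal integral of the raw intensity from peak left to
#' peak right (AU.s), without baseline subtraction. `delta` is the time from
#' the previous peak maximum to this one, `NA` when `prev_peak` is missing
#' (the first peak of a signal). `Peak_distance_median` is a per-signal
#' quantity and is left `NA` here; use [quantify_signal()] for complete rows.
#'
#' @param trace A [calcium_trace()].
#' @param peak One-row data frame (or list) with `left_idx`, `max_idx`,
#'   `right_idx` (1-based, within the trace).
#' @param prev_peak The previous peak's boundary, or `NULL`.
#' @return One-row data frame with the columns of [PEAK_FEATURES].
#' @export
quantify_peak <- function(trace, peak, prev_peak = NULL) {
  y <- trace$intensities
  n <- length(y)
  dt <- 1 / trace$sampling_hz
  l <- peak$left_idx; m <- peak$max_idx; r <- peak$right_idx
  if (l < 1 || r > n || !(l < m && m < r))
    stop("invalid peak boundary (", l, ",", m, ",", r, ") on trace of length ", n)
  dy <- .deriv(y, dt)
  d2y <- .deriv(dy, dt)
  rise <- l:m; fall <- m:r
  dy_argmax <- l - 1L + which.max(dy[rise])
  dy_argmin <- m - 1L + which.min(dy[fall])
  data.frame(
    A_l = y[m] - y[l],
    A_r = y[m] - y[r],
    A_d = (y[m] - y[l]) - (y[m] - y[r]),
    D_l = (m - l) * dt,
    D_r = (r - m) * dt,
    Dy_max = max(dy[rise]),
    Dy_min = abs(min(dy[fall])),
    D2y_max = max(d2y[rise]),
    D2y_min = abs(min(d2y[fall])),
    R = pracma::trapz((l:r - 1L) * dt, y[l:r]),
    delta = if (is.null(prev_peak)) NA_real_ else (m - prev_peak$max_idx) * dt,
    delta_l2Dymax = (dy_argmax - l) * dt,
    delta_m2Dymin = (dy_argmin - m) * dt,
    Peak_distance_median = NA_real_)
}

#' Quantify all peaks of one signal
#'
#' Computes the per-peak variables and fills `Peak_distance_median` with the
#' median of the signal's defined `delta` values, identical on every row.
#' The first peak's `delta` stays `NA`; see [complete_features()].
#'
#' @param trace A [calcium_trace()].
#' @param peaks Boundary data frame from detection, >= 2 rows.
#' @return Data frame with `cell_id`, `peak_index`, the boundary columns and
#'   the 14 feature columns; one row per peak.
#' @export
quantify_signal <- function(trace, peaks) {
  if (nrow(peaks) < 2)
    stop("signal '", trace$cell_id,
         "' has fewer than 2 peaks; it should have been excluded upstream")
  rows <- vector("list", nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    rows[[k]] <- quantify_peak(trace, peaks[k, ],
                               if (k > 1) peaks[k - 1, ] else NULL)
  }
  feat <- do.call(rbind, rows)
  feat$Peak_distance_median <- stats::median(feat$delta, na.rm = TRUE)
  cbind(data.frame(cell_id = trace$cell_id, peak_index = seq_len(nrow(peaks))),
        peaks, feat, row.names = NULL)
}

#' Quantify all signals of a cohort
#'
#' @param traces Named list of traces.
#' @param peaks Named list of boundary data frames (same names), e.g.
#'   `detect_cohort(traces)$peaks`.
#' @return Row-bound feature table over all signals.
#' @export
quantify_cohort <- function(traces, peaks) {
  out <- do.call(rbind, lapply(names(peaks), function(id)
    quantify_signal(traces[[id]], peaks[[id]])))
  rownames(out) <- NULL
  out
}

#' Impute the first-peak delta for model input
#'
#' Classifiers need a complete 14-column matrix; the first peak of each
#' signal has no preceding maximum, so its `delta` is imputed with the
#' signal's `Peak_distance_median`. The rule-based assessment uses the raw
#' table and skips the phase test for first peaks natively, so imputation
#' never reaches the rule engine.
#'
#' @param features Feature table from [quantify_cohort()].
#' @return The table with `delta` imputed.
#' @export
complete_features <- function(features) {
  i <- is.na(features$delta)
  features$delta[i] <- features$Peak_distance_median[i]
  features
}

#' Fit a column standardizer on training rows
#'
#' Stores per-column mean and sample (n-1) standard deviation.
#'
#' @param x Numeric matrix or data frame of training rows.
#' @return Object of class `standardizer`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  zero <- names(sd)[sd == 0 | !is.finite(sd)]
  if (length(zero) > 0)
    stop("zero-variance column(s): ", paste(zero, collapse = ", "))
  structure(list(mean = mu, sd = sd, features = colnames(x)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param stats A `standardizer` from [fit_standardizer()].
#' @param x Matrix or data frame with the same columns as the training set.
#' @return Standardized numeric matrix.
#' @export
apply_standardizer <- function(stats, x) {
  x <- as.matrix(x)
  if (!identical(colnames(x), stats$features))
    stop("column names/order differ from the training set; expected: ",
         paste(stats$features, collapse = ", "))
  scale(x, center = stats$mean, scale = stats$sd)[, , drop = FALSE]
}
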