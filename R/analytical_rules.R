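#' Rule thresholds of the analytical abnormality assessment
#'
#' @param amp_frac Amplitude rules: a peak is abnormal when its max amplitude
#'   (max of `A_l`, `A_r`) falls below this fraction (default 0.5) of the
#'   signal-mean max amplitude (first peak, or chained after an abnormal
#'   peak) or of the most recent normal peak's max amplitude.
#' @param asym_frac Asymmetry rule: a peak passing the amplitude rules is
#'   abnormal when its min amplitude is below this fraction (default 0.85)
#'   of its max amplitude.
#' @param phase_frac Irregular-phase rule tolerance (default 0.9), a fraction
#'   of the signal's median peak distance.
#' @param phase_mode `"deviation"` (default) flags peaks whose distance from
#'   the previous peak deviates from the median by more than
#'   `phase_frac * median` in either direction; `"literal"` flags peaks whose
#'   distance simply exceeds `phase_frac * median` (the one-sided threshold
#'   form). The deviation form is the default because a one-sided 90%
#'   threshold would flag about half the peaks of a perfectly rhythmic
#'   signal; see the package vignette.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(amp_frac = 0.5, asym_frac = 0.85, phase_frac = 0.9,
                        phase_mode = c("deviation", "literal")) {
  phase_mode <- match.arg(phase_mode)
  stopifnot(amp_frac > 0, amp_frac < 1, asym_frac >= 0, phase_frac >= 0)
  structure(list(amp_frac = amp_frac, asym_frac = asym_frac,
                 phase_frac = phase_frac, phase_mode = phase_mode),
            class = "rule_config")
}

#' Rule-based peak abnormality assessment of one signal
#'
#' Peaks are evaluated left to right. Writing `maxamp = max(A_l, A_r)` and
#' `minamp = min(A_l, A_r)`:
#' \enumerate{
#'   \item The first peak is abnormal if `maxamp < amp_frac *` the mean
#'     `maxamp` over the signal.
#'   \item A later peak is abnormal if the preceding peak is abnormal and its
#'     `maxamp` is below `amp_frac *` the signal mean, or if its `maxamp` is
#'     below `amp_frac *` the max amplitude of the most recent peak labeled
#'     normal (so runs of consecutive small peaks are all caught).
#'   \item A peak with normal amplitude is abnormal if asymmetric:
#'     `minamp < asym_frac * maxamp`.
#'   \item A symmetric, amplitude-normal, non-first peak is abnormal if its
#'     peak distance `delta` is irregular relative to the signal's median
#'     peak distance (see [rule_config()] `phase_mode`).
#' }
#' Otherwise the peak is normal.
#'
#' @param signal_features Feature rows of one signal, as returned by
#'   [quantify_signal()] (raw `delta`: first peak `NA`), in peak order.
#' @param cfg A [rule_config()].
#' @return Data frame `cell_id`, `peak_index`, `label`
#'   (factor normal/abnormal), `fired_rule` (`none`, `amplitude_first`,
#'   `amplitude_chain`, `amplitude_drop`, `asymmetry`, `irregular_phase`)
#'   and `source = "analytical"`.
#' @export
assess_peaks_analytical <- function(signal_features, cfg = rule_config()) {
  f <- signal_features
  if (length(unique(f$cell_id)) > 1)
    stop("assess_peaks_analytical expects the peaks of a single signal")
  if (nrow(f) < 2) stop("need >= 2 peaks to assess a signal")
  f <- f[order(f$peak_index), , drop = FALSE]
  maxamp <- pmax(f$A_l, f$A_r)
  minamp <- pmin(f$A_l, f$A_r)
  mean_max <- mean(maxamp)
  med <- f$Peak_distance_median[1]
  n <- nrow(f)
  rule <- rep("none", n)
  abnormal <- logical(n)
  last_normal_amp <- NA_real_
  for (i in seq_len(n)) {
    if (i == 1L) {
      if (maxamp[1] < cfg$amp_frac * mean_max) rule[1] <- "amplitude_first"
    } else if (abnormal[i - 1L] && maxamp[i] < cfg$amp_frac * mean_max) {
      rule[i] <- "amplitude_chain"
    } else if (!is.na(last_normal_amp) &&
               maxamp[i] < cfg$amp_frac * last_normal_amp) {
      rule[i] <- "amplitude_drop"
    }
    if (rule[i] == "none" && minamp[i] < cfg$asym_frac * maxamp[i])
      rule[i] <- "asymmetry"
    if (rule[i] == "none" && i > 1L && !is.na(f$delta[i])) {
      irregular <- if (cfg$phase_mode == "deviation")
        abs(f$delta[i] - med) > cfg$phase_frac * med
      else
        f$delta[i] > cfg$phase_frac * med
      if (irregular) rule[i] <- "irregular_phase"
    }
    abnormal[i] <- rule[i] != "none"
    if (!abnormal[i]) last_normal_amp <- maxamp[i]
  }
  data.frame(cell_id = f$cell_id, peak_index = f$peak_index,
             label = factor(ifelse(abnormal, "abnormal", "normal"),
                            levels = c("normal", "abnormal")),
             fired_rule = rule, source = "analytical",
             stringsAsFactors = FALSE)
}

#' Rule-based assessment for every signal of a cohort
#'
#' @param features Cohort feature table from [quantify_cohort()].
#' @param cfg A [rule_config()].
#' @return Row-bound per-peak assessment table.
#' @export
assess_cohort_analytical <- function(features, cfg = rule_config()) {
  out <- do.call(rbind, lapply(split(features, features$cell_id),
                               assess_peaks_analytical, cfg = cfg))
  rownames(out) <- NULL
  out[order(match(out$cell_id, unique(features$cell_id)), out$peak_index), ]
}

#' Cell-level label from per-peak assessments
#'
#' A cell is abnormal iff it contains at least one abnormal peak.
#'
#' @param peak_labels Factor/character vector of peak labels of one cell.
#' @return Factor of length 1 with levels normal/abnormal.
#' @export
assess_cell_analytical <- function(peak_labels) {
  if (length(peak_labels) == 0) stop("no assessed peaks for this cell")
  factor(if (any(peak_labels == "abnormal")) "abnormal" else "normal",
         levels = c("normal", "abnormal"))
}
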