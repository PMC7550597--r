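#' Configuration of the synthetic transient generator
#'
#' The generator emulates single-cell Ca2+ transient fluorescence traces:
#' a baseline with slow linear drift, a quasi-periodic train of transient
#' templates (logistic upstroke much faster than the exponential decay) and
#' additive Gaussian noise, sampled at 5 Hz over 12-32 s recordings.
#' Abnormal signals carry exactly one injected defect type, drawn per signal
#' from `defect_probs`; the remaining probability mass produces normal
#' signals. Defects map onto the phenotypes an expert flags:
#' \describe{
#'   \item{small_amplitude}{one or two transients scaled to 25-38% of the
#'     cell's amplitude (amplitude rules).}
#'   \item{asymmetric_decay}{one transient fails to return to baseline: a
#'     persistent elevated diastolic level after that peak (asymmetry rule).}
#'   \item{irregular_phase}{a skipped beat: one inter-peak interval about
#'     2.2x the cell's period (irregular-phase rule).}
#'   \item{baseline_oscillation}{a sinusoidal diastolic oscillation across
#'     the whole recording; every peak is labeled abnormal.}
#'   \item{spontaneous_release_bump}{a small slow release event between two
#'     transients; the preceding peak is labeled abnormal.}
#' }
#'
#' @param n_signals Number of signals (cells) to generate.
#' @param duration_range Recording length range in seconds (uniform draw).
#' @param sampling_hz Frames per second (default 5).
#' @param baseline Diastolic fluorescence level (AU).
#' @param drift_amp Maximum total linear baseline drift over a recording (AU).
#' @param amp_mean,amp_sd Per-cell mean transient amplitude distribution
#'   (AU); draws are clamped to at least `amp_min`.
#' @param amp_min Lower clamp on the per-cell amplitude (AU).
#' @param amp_within_sd Within-cell peak-to-peak amplitude SD (AU).
#' @param rise_tau Upstroke time constant (s) of the logistic rise.
#' @param decay_tau Decay time constant (s); must exceed `rise_tau`.
#' @param period_mean,period_jitter Beat period mean and jitter SD (s).
#' @param noise_sd Additive Gaussian noise SD (AU).
#' @param defect_probs Named probabilities of the five defect types; must
#'   sum to at most 1.
#' @param small_amp_range Amplitude fraction range of small-amplitude
#'   defect peaks.
#' @param asym_step_frac Persistent diastolic elevation of the
#'   asymmetric-decay defect, as a fraction of the peak amplitude.
#' @param phase_gap_frac Extra gap of the skipped beat, in periods.
#' @param osc_amp,osc_period Diastolic oscillation amplitude (AU) and
#'   period (s).
#' @param bump_frac Spontaneous-release bump amplitude as a fraction of the
#'   cell amplitude.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param id_prefix Prefix for generated cell ids.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_signals = 200,
                             duration_range = c(12, 32),
                             sampling_hz = 5,
                             baseline = 50,
                             drift_amp = 5,
                             amp_mean = 450, amp_sd = 50, amp_min = 350,
                             amp_within_sd = 8,
                             rise_tau = 0.25, decay_tau = 0.30,
                             period_mean = 2.6, period_jitter = 0.1,
                             noise_sd = 1.5,
                             defect_probs = c(small_amplitude = 0.15,
                                              asymmetric_decay = 0.15,
                                              irregular_phase = 0.15,
                                              baseline_oscillation = 0.10,
                                              spontaneous_release_bump = 0.05),
                             small_amp_range = c(0.26, 0.38),
                             asym_step_frac = 0.30,
                             phase_gap_frac = 1.2,
                             osc_amp = 18, osc_period = 3,
                             bump_frac = 0.08,
                             seed = NULL,
                             id_prefix = "cell") {
  stopifnot(n_signals >= 1, length(duration_range) == 2,
            duration_range[1] > 0, diff(duration_range) >= 0,
            sampling_hz > 0, rise_tau > 0, decay_tau > rise_tau,
            period_mean > 0, period_jitter >= 0, noise_sd >= 0,
            all(defect_probs >= 0), sum(defect_probs) <= 1)
  types <- c("small_amplitude", "asymmetric_decay", "irregular_phase",
             "baseline_oscillation", "spontaneous_release_bump")
  if (!all(names(defect_probs) %in% types))
    stop("unknown defect type(s): ",
         paste(setdiff(names(defect_probs), types), collapse = ", "))
  # the shortest recording must accommodate at least 2 beats
  if (duration_range[1] - 1.2 - 1.0 < 2 * period_mean)
    stop("duration_range and period_mean cannot fit 2 peaks per signal")
  structure(as.list(environment())[c(
    "n_signals", "duration_range", "sampling_hz", "baseline", "drift_amp",
    "amp_mean", "amp_sd", "amp_min", "amp_within_sd", "rise_tau", "decay_tau",
    "period_mean", "period_jitter", "noise_sd", "defect_probs",
    "small_amp_range", "asym_step_frac", "phase_gap_frac", "osc_amp",
    "osc_period", "bump_frac", "seed", "id_prefix")],
    class = "generator_config")
}

# transient template: logistic rise x exponential decay, unit peak height.
# Returns list(g = function(s), s_max = time of the template maximum).
.make_template <- function(rise_tau, decay_tau) {
  s0 <- 3.5 * rise_tau
  raw <- function(s) stats::plogis((s - s0) / rise_tau) *
    exp(-pmax(s - s0, 0) / decay_tau)
  grid <- seq(0, s0 + 4 * decay_tau, by = 0.001)
  v <- raw(grid)
  gmax <- max(v)
  list(g = function(s) raw(s) / gmax, s_max = grid[which.max(v)])
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces traces together with per-peak and per-cell ground-truth labels
#' derived from the injected defects (not from any assessment algorithm, so
#' the rule engine and classifiers can be tested against them).
#'
#' @param cfg A [generator_config()].
#' @return List with `traces` (named list of [calcium_trace()]), `peaks`
#'   (data frame `cell_id`, `peak_index`, `time`, `max_idx`, `amp`, `label`,
#'   `defect`), `cells` (data frame `cell_id`, `label`, `defect`) and
#'   `config`.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tmpl <- .make_template(cfg$rise_tau, cfg$decay_tau)
  types <- names(cfg$defect_probs)
  traces <- list()
  peak_rows <- list()
  cell_rows <- list()
  for (i in seq_len(cfg$n_signals)) {
    id <- sprintf("%s%03d", cfg$id_prefix, i)
    duration <- stats::runif(1, cfg$duration_range[1], cfg$duration_range[2])
    n <- round(duration * cfg$sampling_hz)
    t <- (seq_len(n) - 1) / cfg$sampling_hz
    a0 <- max(cfg$amp_min, stats::rnorm(1, cfg$amp_mean, cfg$amp_sd))
    defect <- sample(c(types, "none"), 1,
                     prob = c(cfg$defect_probs, 1 - sum(cfg$defect_probs)))

    # quasi-periodic beat times
    limit <- duration - 1.0
    times <- stats::runif(1, 1.2, 1.2 + cfg$period_mean)
    repeat {
      nxt <- times[length(times)] + cfg$period_mean +
        stats::rnorm(1, 0, cfg$period_jitter)
      if (nxt > limit) break
      times <- c(times, nxt)
    }
    K <- length(times)
    amps <- a0 + stats::rnorm(K, 0, cfg$amp_within_sd)
    plab <- rep("normal", K)

    if (defect == "irregular_phase" && K >= 4) {
      k <- max(2L, floor(K / 2))
      gap <- cfg$phase_gap_frac * cfg$period_mean
      times[k:K] <- times[k:K] + gap
      keep <- times <= limit
      times <- times[keep]; amps <- amps[keep]; plab <- plab[keep]
      K <- length(times)
      if (K >= k) plab[k] <- "abnormal"
      else defect <- "none"    # the skipped beat fell off the recording
    } else if (defect == "irregular_phase") {
      defect <- "none"          # too few beats to skip one
    }
    if (defect == "small_amplitude") {
      ks <- sample(K, min(K - 1, sample(1:2, 1)))
      amps[ks] <- amps[ks] *
        stats::runif(length(ks), cfg$small_amp_range[1], cfg$small_amp_range[2])
      plab[ks] <- "abnormal"
    }
    asym_k <- bump_k <- integer(0)
    if (defect == "asymmetric_decay") {
      asym_k <- sample(K, 1)
      plab[asym_k] <- "abnormal"
    }
    if (defect == "spontaneous_release_bump") {
      bump_k <- sample(K - 1, 1)
      plab[bump_k] <- "abnormal"
    }
    if (defect == "baseline_oscillation") plab[] <- "abnormal"

    # clean signal: baseline + drift + transients + defect components
    y <- cfg$baseline + stats::runif(1, -cfg$drift_amp, cfg$drift_amp) *
      t / duration
    for (k in seq_len(K))
      y <- y + amps[k] * tmpl$g(t - (times[k] - tmpl$s_max))
    if (length(asym_k) == 1)
      y <- y + cfg$asym_step_frac * amps[asym_k] *
        stats::plogis((t - times[asym_k] - 0.5) / 0.25)
    if (length(bump_k) == 1) {
      bt <- (times[bump_k] + times[bump_k + 1]) / 2
      y <- y + cfg$bump_frac * a0 * stats::plogis((t - bt) / 0.4) *
        exp(-pmax(t - bt, 0) / 0.8)
    }
    if (defect == "baseline_oscillation")
      y <- y + cfg$osc_amp *
        sin(2 * pi * t / cfg$osc_period + stats::runif(1, 0, 2 * pi))

    # ground-truth maxima: discrete argmax of the clean signal near each beat
    half <- min(0.45, cfg$period_mean / 2 - 0.1)
    gt_idx <- vapply(times, function(tk) {
      w <- which(t >= tk - half & t <= tk + half)
      w[which.max(y[w])]
    }, integer(1))

    if (cfg$noise_sd > 0) y <- y + stats::rnorm(n, 0, cfg$noise_sd)

    traces[[id]] <- calcium_trace(y, cell_id = id,
                                  sampling_hz = cfg$sampling_hz,
                                  source_tag = "synthetic")
    peak_rows[[id]] <- data.frame(
      cell_id = id, peak_index = seq_len(K), time = times, max_idx = gt_idx,
      amp = amps, label = plab, defect = defect, stringsAsFactors = FALSE)
    cell_rows[[id]] <- data.frame(
      cell_id = id,
      label = if (any(plab == "abnormal")) "abnormal" else "normal",
      defect = defect, stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peak_rows)
  cells <- do.call(rbind, cell_rows)
  rownames(peaks) <- rownames(cells) <- NULL
  peaks$label <- factor(peaks$label, levels = c("normal", "abnormal"))
  cells$label <- factor(cells$label, levels = c("normal", "abnormal"))
  list(traces = traces, peaks = peaks, cells = cells, config = cfg)
}

#' Transfer ground-truth labels onto detected peaks
#'
#' Matches each detected peak to the nearest ground-truth maximum of the
#' same cell; detected peaks within `max_offset` frames of a truth maximum
#' inherit its label, unmatched detections (e.g. a spurious event picked up
#' by the detector) are labeled abnormal.
#'
#' @param truth_peaks `peaks` table from [generate_cohort()].
#' @param detected Detected-peak table from [peaks_to_table()] (or a
#'   feature table with `cell_id`, `peak_index`, `max_idx`).
#' @param max_offset Matching tolerance in frames (default 3).
#' @return Label table `cell_id`, `peak_index`, `label` aligned with
#'   `detected` rows.
#' @export
label_detected_peaks <- function(truth_peaks, detected, max_offset = 3) {
  lab <- character(nrow(detected))
  for (r in seq_len(nrow(detected))) {
    tp <- truth_peaks[truth_peaks$cell_id == detected$cell_id[r], ]
    if (nrow(tp) == 0) { lab[r] <- "abnormal"; next }
    d <- abs(tp$max_idx - detected$max_idx[r])
    lab[r] <- if (min(d) <= max_offset)
      as.character(tp$label[which.min(d)]) else "abnormal"
  }
  data.frame(cell_id = detected$cell_id, peak_index = detected$peak_index,
             label = factor(lab, levels = c("normal", "abnormal")),
             stringsAsFactors = FALSE)
}
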