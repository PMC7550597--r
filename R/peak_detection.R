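#' Peak detection configuration
#'
#' Thresholds of the sequential derivative-screening peak detector and the
#' post-detection exclusion rules.
#'
#' @param t_up Start-of-peak threshold on the first derivative (AU/s,
#'   default 30): the first frame whose derivative exceeds `t_up` opens a peak.
#' @param rt_up End-of-peak threshold (AU/s, default 2): after the maximum,
#'   the first frame with a positive derivative exceeding `rt_up` closes the
#'   peak; the allowance above zero tolerates small noisy fluctuations during
#'   the decay. `rt_up = 0` closes at the first strictly positive derivative.
#' @param first_peak_asym_frac First-peak exclusion: drop the first peak when
#'   its left amplitude is below this fraction of its right amplitude (0.5)
#'   \emph{and} the intensity at its maximum is below
#'   `first_peak_intensity_floor`.
#' @param first_peak_intensity_floor Absolute intensity floor (AU, default 5)
#'   for the first-peak exclusion.
#' @param noise_amp_frac Noise-peak exclusion: drop peaks whose amplitude
#'   (max of left/right amplitude) is below this fraction (0.15) of the
#'   largest peak amplitude in the signal.
#' @param min_peaks Signals with fewer surviving peaks than this (default 2)
#'   are excluded from analysis.
#' @param drop_partial_last If `TRUE`, a trailing peak whose end is never
#'   reached before the recording stops is discarded; if `FALSE` (default)
#'   it is truncated at the last frame.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(t_up = 30, rt_up = 2,
                             first_peak_asym_frac = 0.5,
                             first_peak_intensity_floor = 5,
                             noise_amp_frac = 0.15,
                             min_peaks = 2,
                             drop_partial_last = FALSE) {
  stopifnot(t_up > 0, rt_up >= 0,
            first_peak_asym_frac > 0, first_peak_asym_frac < 1,
            noise_amp_frac > 0, noise_amp_frac < 1,
            min_peaks >= 0)
  structure(list(t_up = t_up, rt_up = rt_up,
                 first_peak_asym_frac = first_peak_asym_frac,
                 first_peak_intensity_floor = first_peak_intensity_floor,
                 noise_amp_frac = noise_amp_frac,
                 min_peaks = min_peaks,
                 drop_partial_last = drop_partial_last),
            class = "detection_config")
}

# central difference in the interior, one-sided at the two ends
.deriv <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  if (n > 2)
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d
}

#' First derivative of a trace
#'
#' Central differences at interior frames, one-sided differences at the two
#' endpoints, in AU per second (dt = 1/sampling_hz).
#'
#' @param trace A [calcium_trace()] of length >= 3.
#' @return A list of class `derivative_series` with elements `values`,
#'   `order` (1) and `sampling_hz`.
#' @export
first_derivative <- function(trace) {
  if (length(trace$intensities) < 3)
    stop("trace must have at least 3 frames to differentiate")
  structure(list(values = .deriv(trace$intensities, 1 / trace$sampling_hz),
                 order = 1L, sampling_hz = trace$sampling_hz),
            class = "derivative_series")
}

#' Second derivative of a trace
#'
#' The first-derivative operator applied twice (AU/s^2).
#'
#' @inheritParams first_derivative
#' @return A `derivative_series` with `order = 2`.
#' @export
second_derivative <- function(trace) {
  d1 <- first_derivative(trace)
  structure(list(values = .deriv(d1$values, 1 / trace$sampling_hz),
                 order = 2L, sampling_hz = trace$sampling_hz),
            class = "derivative_series")
}

#' Detect transient peaks by sequential derivative screening
#'
#' Scanning left to right: the first frame whose first derivative exceeds
#' `t_up` is the peak left; the first later frame with a negative derivative
#' bounds the rise, and the peak maximum is placed at the intensity argmax on
#' that rise; the first frame after the sign change whose derivative is
#' positive and exceeds `rt_up` is the peak right. The scan then resumes one
#' frame past the peak right. A trailing peak whose right boundary is never
#' reached is truncated at the final frame (or discarded when
#' `cfg$drop_partial_last` is `TRUE`).
#'
#' Frame indices are 1-based throughout (R convention).
#'
#' @param trace A [calcium_trace()] of length >= 3.
#' @param cfg A [detection_config()].
#' @return Data frame with columns `left_idx`, `max_idx`, `right_idx`
#'   (possibly zero rows). Peaks are ordered and non-overlapping.
#' @export
detect_peaks <- function(trace, cfg = detection_config()) {
  y <- trace$intensities
  n <- length(y)
  if (n < 3) stop("trace must have at least 3 frames")
  dy <- .deriv(y, 1 / trace$sampling_hz)
  left <- integer(0); mx <- integer(0); right <- integer(0)
  i <- 1L
  while (i <= n) {
    up <- which(dy[i:n] > cfg$t_up)
    if (length(up) == 0) break
    l <- i + up[1] - 1L
    if (l >= n) break
    neg <- which(dy[(l + 1L):n] < 0)
    if (length(neg) == 0) break            # still rising at end of recording
    s <- l + neg[1]                        # first frame with negative derivative
    m <- l + which.max(y[(l + 1L):s])      # intensity argmax after peak left
    rpos <- if (s < n) which(dy[(s + 1L):n] > cfg$rt_up & dy[(s + 1L):n] > 0)
            else integer(0)
    if (length(rpos) == 0) {
      if (!cfg$drop_partial_last && n > m) {
        left <- c(left, l); mx <- c(mx, m); right <- c(right, n)
      }
      break
    }
    r <- s + rpos[1]
    left <- c(left, l); mx <- c(mx, m); right <- c(right, r)
    i <- r + 1L
  }
  data.frame(left_idx = left, max_idx = mx, right_idx = right)
}

# left/right amplitudes of each boundary on a trace
.peak_amps <- function(y, peaks) {
  data.frame(A_l = y[peaks$max_idx] - y[peaks$left_idx],
             A_r = y[peaks$max_idx] - y[peaks$right_idx])
}

#' Apply the first-peak and noise-peak exclusion rules
#'
#' The first detected peak is dropped when it is asymmetric (left amplitude
#' below `first_peak_asym_frac` of the right amplitude) \emph{and} the
#' intensity at its maximum is below `first_peak_intensity_floor` — the
#' signature of a transient already in progress when acquisition started.
#' Then any peak whose amplitude (max of left/right amplitude) is below
#' `noise_amp_frac` of the largest amplitude among the originally detected
#' peaks is dropped as noise. Order is preserved.
#'
#' @param trace The trace the peaks were detected on.
#' @param peaks Data frame from [detect_peaks()].
#' @param cfg A [detection_config()].
#' @return The retained subset of `peaks`.
#' @export
filter_peaks <- function(trace, peaks, cfg = detection_config()) {
  if (nrow(peaks) == 0) return(peaks)
  y <- trace$intensities
  amps <- .peak_amps(y, peaks)
  amp <- pmax(amps$A_l, amps$A_r)
  keep <- rep(TRUE, nrow(peaks))
  if (amps$A_l[1] < cfg$first_peak_asym_frac * amps$A_r[1] &&
      y[peaks$max_idx[1]] < cfg$first_peak_intensity_floor)
    keep[1] <- FALSE
  keep[amp < cfg$noise_amp_frac * max(amp)] <- FALSE
  peaks[keep, , drop = FALSE]
}

#' Detect and filter peaks for a collection of traces
#'
#' Runs [detect_peaks()] and [filter_peaks()] on each trace, then excludes
#' signals with fewer than `cfg$min_peaks` surviving peaks (signals with no
#' peak or a single peak carry too little rhythm information to assess).
#'
#' @param traces Named list of [calcium_trace()] objects.
#' @param cfg A [detection_config()].
#' @param verbose Log per-signal exclusions to stderr.
#' @return List with `peaks` (named list of boundary data frames for retained
#'   signals) and `excluded` (data frame `cell_id`, `n_peaks`, `reason`).
#' @export
detect_cohort <- function(traces, cfg = detection_config(), verbose = FALSE) {
  peaks <- list()
  exc_id <- character(0); exc_n <- integer(0); exc_why <- character(0)
  for (id in names(traces)) {
    p <- filter_peaks(traces[[id]], detect_peaks(traces[[id]], cfg), cfg)
    if (nrow(p) < cfg$min_peaks) {
      exc_id <- c(exc_id, id); exc_n <- c(exc_n, nrow(p))
      exc_why <- c(exc_why, sprintf("only %d peak(s) after filtering (min %d)",
                                    nrow(p), cfg$min_peaks))
      if (verbose)
        message("excluding signal '", id, "': ", exc_why[length(exc_why)])
    } else {
      peaks[[id]] <- p
    }
  }
  list(peaks = peaks,
       excluded = data.frame(cell_id = exc_id, n_peaks = exc_n,
                             reason = exc_why, stringsAsFactors = FALSE))
}

#' Export detected boundaries as a flat table
#'
#' @param peaks Named list of boundary data frames (from [detect_cohort()]).
#' @return Data frame `cell_id`, `peak_index`, `left_idx`, `max_idx`,
#'   `right_idx` with 1-based peak indices.
#' @export
peaks_to_table <- function(peaks) {
  rows <- lapply(names(peaks), function(id) {
    p <- peaks[[id]]
    if (nrow(p) == 0) return(NULL)
    cbind(data.frame(cell_id = id, peak_index = seq_len(nrow(p))), p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = character(0), peak_index = integer(0),
                      left_idx = integer(0), max_idx = integer(0),
                      right_idx = integer(0))
  rownames(out) <- NULL
  out
}
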