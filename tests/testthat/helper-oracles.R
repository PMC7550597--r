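# Independent reference implementations used as oracles. These deliberately
# use a different code structure (vectorised which() scans over candidate
# indices) than the package's sequential detector.

# central/one-sided first derivative, duplicated here so the oracle does not
# depend on package internals
oracle_deriv <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d
}

# brute-force peak scan: enumerate candidate left/turn/right indices with
# which() and greedily chain them left to right
oracle_detect <- function(y, hz, t_up = 30, rt_up = 2,
                          drop_partial_last = FALSE) {
  n <- length(y)
  dy <- oracle_deriv(y, 1 / hz)
  ups <- which(dy > t_up)
  negs <- which(dy < 0)
  rights <- which(dy > rt_up & dy > 0)
  out <- NULL
  cursor <- 1L
  repeat {
    l <- ups[ups >= cursor][1]
    if (is.na(l) || l >= n) break
    s <- negs[negs > l][1]
    if (is.na(s)) break
    m <- ((l + 1L):s)[which.max(y[(l + 1L):s])]
    r <- rights[rights > s][1]
    if (is.na(r)) {
      if (!drop_partial_last && n > m)
        out <- rbind(out, c(l, m, n))
      break
    }
    out <- rbind(out, c(l, m, r))
    cursor <- r + 1L
  }
  if (is.null(out))
    return(data.frame(left_idx = integer(0), max_idx = integer(0),
                      right_idx = integer(0)))
  data.frame(left_idx = out[, 1], max_idx = out[, 2], right_idx = out[, 3])
}

# random traces that exercise both threshold crossings and quiet stretches
random_trace <- function(n = NULL) {
  if (is.null(n)) n <- sample(20:80, 1)
  kind <- sample(3, 1)
  y <- switch(kind,
    cumsum(rnorm(n, 0, sample(c(1, 5, 15), 1))),                 # random walk
    50 * sin(seq(0, sample(2:8, 1) * pi, length.out = n)) +
      rnorm(n, 0, 5),                                            # oscillation
    {                                                            # spike train
      base <- rnorm(n, 0, 2)
      for (k in sample(2:4, 1)) {
        at <- sample(3:(n - 2), 1)
        base[at] <- base[at] + sample(c(30, 80, 200), 1)
      }
      base
    })
  calcium_trace(y + 100, cell_id = "rnd", sampling_hz = 5)
}

# probability that a random abnormal score exceeds a random normal score,
# counting ties as 1/2 (pairwise mid-rank AUC)
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == "abnormal"]
  neg <- scores[truth == "normal"]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# hand-built feature rows for the rule engine: only the columns the rules
# read need realistic values
rule_fixture <- function(A_l, A_r, delta, med = NULL) {
  stopifnot(length(A_l) == length(A_r), length(A_l) == length(delta))
  if (is.null(med)) med <- stats::median(delta, na.rm = TRUE)
  k <- length(A_l)
  data.frame(cell_id = "fx", peak_index = seq_len(k), A_l = A_l, A_r = A_r,
             delta = delta, Peak_distance_median = med)
}

zero_defects <- c(small_amplitude = 0, asymmetric_decay = 0,
                  irregular_phase = 0, baseline_oscillation = 0,
                  spontaneous_release_bump = 0)

# small standard cohorts reused across tests
clean_cohort <- function(n = 12, seed = 42, noise = 0)
  generate_cohort(generator_config(n_signals = n, noise_sd = noise,
                                   defect_probs = zero_defects, seed = seed))

# run detection + quantification and return the labelled feature table
prepared_cohort <- function(n = 20, seed = 1) {
  co <- generate_cohort(generator_config(n_signals = n, seed = seed))
  det <- detect_cohort(co$traces)
  feats <- quantify_cohort(co$traces, det$peaks)
  labels <- label_detected_peaks(
    co$peaks, feats[, c("cell_id", "peak_index", "max_idx")])
  list(cohort = co, det = det, feats = feats, labels = labels)
}
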