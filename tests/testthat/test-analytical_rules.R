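test_that("single rule firings match the stated thresholds", {
  # first peak well below half of the signal-mean max amplitude
  f <- rule_fixture(A_l = c(40, 100, 100, 100, 100),
                    A_r = c(40, 100, 100, 100, 100),
                    delta = c(NA, 2, 2, 2, 2))
  a <- assess_peaks_analytical(f)
  expect_equal(as.character(a$label[1]), "abnormal")
  expect_equal(a$fired_rule[1], "amplitude_first")
  expect_true(all(a$label[-1] == "normal"))

  # asymmetry: 80 < 0.85 * 100
  f2 <- rule_fixture(A_l = c(100, 100), A_r = c(100, 80), delta = c(NA, 2))
  a2 <- assess_peaks_analytical(f2)
  expect_equal(a2$fired_rule, c("none", "asymmetry"))

  # fully rhythmic, equal amplitudes: nothing fires
  f3 <- rule_fixture(A_l = rep(100, 6), A_r = rep(100, 6),
                     delta = c(NA, rep(2, 5)))
  expect_true(all(assess_peaks_analytical(f3)$label == "normal"))
})

test_that("the full decision table reproduces hand-traced labels", {
  # Eight peaks exercising every branch. Median delta = 2; mean max
  # amplitude = (100+100+30+30+100+100+100+100)/8 = 82.5.
  #  1: normal reference
  #  2: asymmetry at exactly 85% (85 < 0.85*100 is FALSE): normal
  #  3: small vs preceding normal peak (30 < 0.5*100): abnormal
  #  4: chained small (preceding abnormal, 30 < 0.5*82.5): abnormal
  #  5: recovers (100 not < 0.5*82.5, not < 0.5*100): normal
  #  6: phase deviation at exactly the 90% tolerance (|3.8-2| = 1.8,
  #     not > 0.9*2): normal
  #  7: phase deviation just above tolerance (|3.81-2| > 1.8): abnormal
  #  8: asymmetry just below 85% (84.9 < 85): abnormal
  f <- rule_fixture(
    A_l  = c(100, 100, 30, 30, 100, 100, 100, 100),
    A_r  = c(100,  85, 28, 28, 100, 100, 100, 84.9),
    delta = c(NA, 2, 2, 2, 2, 3.8, 3.81, 2),
    med = 2)
  a <- assess_peaks_analytical(f)
  expect_equal(as.character(a$label),
               c("normal", "normal", "abnormal", "abnormal", "normal",
                 "normal", "abnormal", "abnormal"))
  expect_equal(a$fired_rule,
               c("none", "none", "amplitude_drop", "amplitude_chain",
                 "none", "none", "irregular_phase", "asymmetry"))
})

test_that("a run of small peaks is measured against the last normal peak", {
  # peaks 2-4 are all ~40% of peak 1; with the most-recent-normal reference
  # every one of them is caught even though each matches its direct
  # predecessor
  f <- rule_fixture(A_l = c(100, 40, 40, 40), A_r = c(100, 40, 40, 40),
                    delta = c(NA, 2, 2, 2), med = 2)
  a <- assess_peaks_analytical(f)
  expect_equal(as.character(a$label),
               c("normal", "abnormal", "abnormal", "abnormal"))
  # forward order matters: reversing the rows changes the outcome
  frev <- rule_fixture(A_l = rev(c(100, 40, 40, 40)),
                       A_r = rev(c(100, 40, 40, 40)),
                       delta = c(NA, 2, 2, 2), med = 2)
  arev <- assess_peaks_analytical(frev)
  expect_false(identical(as.character(arev$label),
                         rev(as.character(a$label))))
})

test_that("rule outcomes are invariant to intensity scaling", {
  co <- prepared_cohort(n = 8, seed = 3)
  for (id in unique(co$feats$cell_id)[1:4]) {
    f <- co$feats[co$feats$cell_id == id, ]
    a0 <- assess_peaks_analytical(f)
    f2 <- f
    for (v in c("A_l", "A_r", "A_d", "Dy_max", "Dy_min", "D2y_max",
                "D2y_min", "R"))
      f2[[v]] <- 7.3 * f2[[v]]
    expect_identical(assess_peaks_analytical(f2)$label, a0$label)
  }
})

test_that("extreme thresholds disable their rules", {
  f <- rule_fixture(A_l = c(100, 100, 100), A_r = c(100, 40, 100),
                    delta = c(NA, 9, 2), med = 2)
  relaxed <- assess_peaks_analytical(
    f, rule_config(asym_frac = 1e-9, phase_frac = 1e9))
  expect_true(all(relaxed$label == "normal"))
  strict <- assess_peaks_analytical(f)
  expect_true(any(strict$label == "abnormal"))
})

test_that("the literal one-sided phase reading is available behind a flag", {
  # every delta equals the median: the deviation form never fires, the
  # literal form (delta > 0.9 * median) flags every non-first peak
  f <- rule_fixture(A_l = rep(100, 4), A_r = rep(100, 4),
                    delta = c(NA, 2, 2, 2), med = 2)
  dev <- assess_peaks_analytical(f, rule_config(phase_mode = "deviation"))
  lit <- assess_peaks_analytical(f, rule_config(phase_mode = "literal"))
  expect_true(all(dev$label == "normal"))
  expect_equal(as.character(lit$label),
               c("normal", rep("abnormal", 3)))
  expect_true(all(lit$fired_rule[-1] == "irregular_phase"))
})

test_that("cell labels aggregate peak labels by any-abnormal", {
  expect_equal(as.character(assess_cell_analytical(
    c("normal", "normal", "normal"))), "normal")
  expect_equal(as.character(assess_cell_analytical(
    c("normal", "abnormal", "normal"))), "abnormal")
  expect_error(assess_cell_analytical(character(0)), "no assessed peaks")

  # generator ground truth: an all-abnormal arrhythmic trace
  p <- zero_defects; p["small_amplitude"] <- 1
  co <- generate_cohort(generator_config(n_signals = 4, noise_sd = 0,
                                         defect_probs = p, seed = 13))
  det <- detect_cohort(co$traces)
  f <- quantify_cohort(co$traces, det$peaks)
  a <- assess_cohort_analytical(f)
  lab <- tapply(a$label, a$cell_id,
                function(l) as.character(assess_cell_analytical(l)))
  expect_true(all(lab == "abnormal"))
})
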