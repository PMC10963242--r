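make_fid <- function(x = 1, y = 0.4, z = 0.55, t1 = 0.15, t2 = 0.3, t3 = 0.45,
                     tpi = 0.9, w = 0.2, A1 = 0.05, A2 = 0.06, A3 = 0.07) {
  structure(list(ok = TRUE, x = x, y = y, z = z, t1 = t1, t2 = t2, t3 = t3,
                 tpi = tpi, w = w, A1 = A1, A2 = A2, A3 = A3, A2_A1 = A2 / A1,
                 baseline = 0,
                 indices = c(systolic = 10L, notch = 20L, diastolic = 30L)),
            class = "ppg_fiducials")
}

make_dfid <- function(ta1 = 0.1, tb1 = 0.08, te1 = 0.4, tl1 = 0.8,
                      a2 = 50, b2 = -30, e2 = 10, ta2 = 0.05, tb2 = 0.2) {
  structure(list(ok = TRUE, a1 = 5, b1 = -4, e1 = 0.5, l1 = 0,
                 ta1 = ta1, tb1 = tb1, te1 = te1, tl1 = tl1,
                 a2 = a2, b2 = b2, e2 = e2, ta2 = ta2, tb2 = tb2),
            class = "ppg_deriv_fiducials")
}

make_spectral <- function() {
  structure(list(f_base = 1.2, s_base = 100, f_2nd = 2.4, s_2nd = 50,
                 f_3rd = 3.6, s_3rd = 25), class = "spectral_peaks")
}

test_that("differentiation matches closed forms", {
  fs <- 1000
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  d1 <- differentiate(sin(2 * pi * tt), 1, fs = fs)
  expect_lt(max(abs(d1[2:999] - 2 * pi * cos(2 * pi * tt[2:999]))), 1e-3)
  ramp <- 3 * tt + 1
  expect_lt(max(abs(differentiate(ramp, 1, fs = fs) - 3)), 1e-9)
  expect_lt(max(abs(differentiate(ramp, 2, fs = fs))), 1e-6)
  # the first derivative crosses zero at the systolic peak
  cb <- clean_best_cycle(seed = 3)
  d1c <- differentiate(cb$cycle, 1)
  i_sys <- which.max(cb$cycle$samples)
  zc <- which(d1c[-length(d1c)] > 0 & d1c[-1] <= 0)
  expect_lte(min(abs(zc - i_sys)), 1)
  expect_error(differentiate(c(1, 2, 3), 1, fs = 10), "too short")
})

test_that("time-domain fiducials recover the generator's landmarks", {
  for (hr in c(62, 72, 88)) {
    cb <- clean_best_cycle(heart_rate = hr, seed = hr)
    fid <- locate_fiducials(cb$cycle)
    expect_true(fid$ok)
    tb <- cb$truth$beats
    k <- which.min(abs(tb$onset_time - cb$onset_t))
    expect_lt(abs(fid$t1 + cb$onset_t - tb$t_sys[k]), 0.002)
    expect_lt(abs(fid$t2 + cb$onset_t - tb$t_notch[k]), 0.002)
    expect_lt(abs(fid$t3 + cb$onset_t - tb$t_dia[k]), 0.002)
    # preprocessing min-max normalizes, so truth amplitudes rescale by the
    # clean waveform's range
    R <- diff(range(cb$truth$clean))
    onset_val <- cb$truth$clean[round(tb$onset_time[k] * 1000) + 1]
    expect_lt(abs(fid$x - (tb$x[k] - onset_val) / R) / fid$x, 0.01)
    expect_lt(abs(fid$z - (tb$z[k] - onset_val) / R) / fid$z, 0.02)
    expect_lt(abs(fid$y - (tb$y[k] - onset_val) / R) / fid$y, 0.02)
  }
})

test_that("beats without a diastolic wave are flagged, not landmarked", {
  # single-bump beats: no notch, no diastolic peak
  gr <- generate_record(beat_config(diastolic_amplitude_ratio = 1e-3,
                                    notch_depth_ratio = 1e-3),
                        no_noise(), seed = 5)
  rec <- preprocess_record(gr$record)
  cycles <- segment_cycles(rec, detect_systolic_peaks(rec))
  fid <- locate_fiducials(select_best_cycle(cycles))
  expect_false(isTRUE(fid$ok))
  expect_true(nchar(fid$reason) > 0)
})

test_that("width is b/2 for a symmetric triangular pulse", {
  fs <- 1000
  b <- 0.4  # base in seconds
  half_n <- round(b * fs / 2)
  tri <- c(seq(0, 1, length.out = half_n + 1), seq(1, 0, length.out = half_n + 1)[-1])
  cyc <- ppg_cycle(tri, 1L, fs)
  fid <- structure(list(ok = TRUE, x = 1, baseline = 0,
                        indices = c(systolic = half_n + 1L,
                                    notch = length(tri) - 2L)),
                   class = "ppg_fiducials")
  wa <- width_and_areas(cyc, fid)
  expect_equal(wa$w, b / 2, tolerance = 1e-6)
})

test_that("areas are additive and match Gaussian closed forms", {
  cb <- clean_best_cycle(seed = 9)
  fid <- locate_fiducials(cb$cycle)
  wa <- width_and_areas(cb$cycle, fid)
  s <- cb$cycle$samples - fid$baseline
  n <- length(s)
  total <- sum((s[-1] + s[-n]) / 2) / cb$cycle$fs
  expect_equal(wa$A1 + wa$A2 + wa$A3, total, tolerance = 1e-9)
  expect_true(all(c(wa$A1, wa$A2, wa$A3) > 0))
  # closed-form oracle: integrals of the generating Gaussian bumps
  bc <- cb$truth$beat
  T <- 60 / bc$heart_rate
  amps <- c(bc$systolic_amplitude,
            0.9 * bc$notch_depth_ratio * bc$systolic_amplitude,
            0.85 * bc$diastolic_amplitude_ratio * bc$systolic_amplitude)
  mus <- c(bc$systolic_time_fraction, bc$notch_time_fraction,
           bc$diastolic_time_fraction) * T
  sds <- c(0.095, 0.18, 0.085) * T
  gauss_area <- function(a, b) {
    tot <- 0
    for (k in -1:3) for (j in 1:3)
      tot <- tot + amps[j] * sds[j] * sqrt(2 * pi) *
        (pnorm((b - (k * T + mus[j])) / sds[j]) -
         pnorm((a - (k * T + mus[j])) / sds[j]))
    tot
  }
  # the cycle lives on the normalized scale: subtract the clean onset value
  # and divide by the clean range
  t0 <- cb$onset_t
  R <- diff(range(cb$truth$clean))
  onset_val <- cb$truth$clean[round(t0 * 1000) + 1]
  a1_oracle <- (gauss_area(t0, t0 + fid$t1) - onset_val * fid$t1) / R
  a2_oracle <- (gauss_area(t0 + fid$t1, t0 + fid$t2) -
                onset_val * (fid$t2 - fid$t1)) / R
  a3_oracle <- (gauss_area(t0 + fid$t2, t0 + fid$tpi) -
                onset_val * (fid$tpi - fid$t2)) / R
  expect_equal(wa$A1, a1_oracle, tolerance = 0.01)
  expect_equal(wa$A2, a2_oracle, tolerance = 0.01)
  expect_equal(wa$A3, a3_oracle, tolerance = 0.01)
})

test_that("derivative landmarks sit at the calculus positions", {
  # single Gaussian bump: PPG' extrema at mu -/+ sigma
  g <- gaussian_cycle(mu = 0.3, s = 0.06)
  d1 <- differentiate(g, 1)
  expect_lt(abs((which.max(d1) - 1) / 1000 - (0.3 - 0.06)), 0.002)
  expect_lt(abs((which.min(d1) - 1) / 1000 - (0.3 + 0.06)), 0.002)
  # full synthetic beat: a1 precedes the systolic peak, b1 follows it
  cb <- clean_best_cycle(seed = 13)
  fid <- locate_fiducials(cb$cycle)
  dfid <- locate_derivative_fiducials(cb$cycle)
  expect_true(dfid$ok)
  expect_lt(dfid$ta1, fid$t1)
  expect_gt(dfid$ta1 + dfid$tb1, fid$t1)  # b1 time = ta1 + tb1
  expect_lt(dfid$ta2, dfid$tb2)
  expect_gt(dfid$a2, 0)
  expect_lte(dfid$b2, 0)
  expect_gt(dfid$tl1, dfid$te1)
})

test_that("spectral peaks recover a harmonic stack and the beat rate", {
  fs <- 1000
  dur <- 4.096  # 4096 samples: the probe frequencies sit on exact FFT bins
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  df <- fs / 4096
  f1 <- 5 * df; f2 <- 10 * df; f3 <- 15 * df  # 1.221, 2.441, 3.662 Hz
  x <- sin(2 * pi * f1 * tt) + 0.5 * sin(2 * pi * f2 * tt) +
    0.25 * sin(2 * pi * f3 * tt)
  sp <- spectral_features(ppg_record(x, fs, preprocessed = TRUE))
  expect_lt(abs(sp$f_base - f1), df)
  expect_lt(abs(sp$f_2nd - f2), df)
  expect_lt(abs(sp$f_3rd - f3), df)
  expect_equal(sp$s_2nd / sp$s_base, 0.5, tolerance = 0.05)
  expect_equal(sp$s_3rd / sp$s_base, 0.25, tolerance = 0.05)
  # 72 bpm beat train: fundamental within one bin of 1.2 Hz
  gr <- clean_record(seed = 2)
  sp2 <- spectral_features(preprocess_record(gr$record))
  expect_lt(abs(sp2$f_base - 1.2), 1000 / 4096)
  # DC-only record has no in-band peak
  expect_error(spectral_features(ppg_record(rep(1, 2100), 1000,
                                            preprocessed = TRUE)), "peaks")
})

test_that("feature arithmetic follows the printed definitions", {
  fv <- assemble_feature_vector(make_fid(), make_dfid(), make_spectral(),
                                list(age = 57, sex = "female"))
  expect_equal(unname(fv["y_over_x"]), 0.4)
  expect_equal(unname(fv["x_minus_y_over_x"]), 0.6)
  expect_equal(unname(fv["z_over_x"]), 0.55)
  expect_equal(unname(fv["y_minus_x_over_x"]), -0.6)
  expect_equal(unname(fv["delta_t"]), 0.3)
  expect_equal(unname(fv["delta_t_over_tpi"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(fv["t1_over_tpi"]), 1 / 6, tolerance = 1e-12)
  expect_equal(unname(fv["ipa"]), 0.07 / 0.11)
  expect_equal(unname(fv["svri"]), 0.13 / 0.05)
  expect_equal(unname(fv["t1_over_x"]), 0.15)
  expect_equal(unname(fv["dia_falling_slope"]), 0.4 / 0.45)
  expect_equal(unname(fv["ta1_plus_ta2_over_tpi"]), 0.15 / 0.9)
  expect_equal(unname(fv["gender"]), 0)
  expect_equal(unname(fv["age"]), 57)
  expect_equal(unname(attr(fv, "aux")["A2_A1"]), 0.06 / 0.05)
  # the physical slope convention flips slot 16
  fv2 <- assemble_feature_vector(make_fid(), make_dfid(), make_spectral(),
                                 list(age = 57, gender = 1),
                                 slope_convention = "physical")
  expect_equal(unname(fv2["t1_over_x"]), 1 / 0.15)
})

test_that("the vector has 48 slots partitioned 21 + 8 + 11 + 6 + 2", {
  nm <- ppg_feature_names()
  expect_length(nm, 48)
  grp <- attr(nm, "group")
  expect_identical(as.vector(table(grp)[c("ppg", "d1", "d2", "fft", "demographic")]),
                   c(21L, 8L, 11L, 6L, 2L))
  fv <- assemble_feature_vector(make_fid(), make_dfid(), make_spectral(),
                                list(age = 40, sex = "male"))
  expect_length(fv, 48)
  expect_identical(names(fv), as.character(nm))
  expect_true(all(is.finite(fv)))
})

test_that("degenerate geometry is rejected by feature name", {
  expect_error(assemble_feature_vector(make_fid(x = 0), make_dfid(),
                                       make_spectral(), list(age = 40, gender = 1)),
               "y_over_x")
  expect_error(assemble_feature_vector(make_fid(), make_dfid(a2 = 0),
                                       make_spectral(), list(age = 40, gender = 1)),
               "b2_over_a2")
  expect_error(assemble_feature_vector(make_fid(t3 = 0.897), make_dfid(),
                                       make_spectral(), list(age = 40, gender = 1)),
               "5 ms")
})

test_that("amplitude ratios are scale invariant and amplitudes scale", {
  cb <- clean_best_cycle(seed = 21)
  sp <- make_spectral()
  subj <- list(age = 50, gender = 1)
  build <- function(cy) {
    fid <- locate_fiducials(cy)
    wa <- width_and_areas(cy, fid)
    fid[names(wa)] <- wa
    assemble_feature_vector(fid, locate_derivative_fiducials(cy), sp, subj)
  }
  f1 <- build(cb$cycle)
  for (cc in c(0.5, 3)) {
    cyc <- ppg_cycle(cc * cb$cycle$samples, cb$cycle$onset_index, cb$cycle$fs)
    f2 <- build(cyc)
    ratio_slots <- c("y_over_x", "x_minus_y_over_x", "z_over_x",
                     "y_minus_x_over_x", "b2_over_a2", "e2_over_a2",
                     "b2_plus_e2_over_a2")
    expect_equal(f2[ratio_slots], f1[ratio_slots], tolerance = 1e-9)
    expect_equal(unname(f2[c("x", "y", "z")]), cc * unname(f1[c("x", "y", "z")]),
                 tolerance = 1e-9)
    time_slots <- c("t1", "t2", "t3", "tpi", "ta1", "tb1", "ta2", "tb2")
    expect_equal(f2[time_slots], f1[time_slots], tolerance = 1e-12)
  }
})

test_that("time features dilate with the beat period, time ratios do not", {
  sp <- make_spectral(); subj <- list(age = 50, gender = 1)
  # cut one exact onset-to-onset beat from the analytic waveform so the
  # slow cycle is a perfect 2x time dilation of the fast one
  build <- function(hr) {
    fs <- 1000
    T <- 60 / hr
    tt <- seq(0, T - 1 / fs, by = 1 / fs) + T  # second beat, neighbours felt
    cyc <- ppg_cycle(ppgbp:::render_beat_train(beat_config(heart_rate = hr), tt),
                     onset_index = 1L, fs = fs)
    fid <- locate_fiducials(cyc)
    wa <- width_and_areas(cyc, fid)
    fid[names(wa)] <- wa
    assemble_feature_vector(fid, locate_derivative_fiducials(cyc), sp, subj)
  }
  f1 <- build(100)
  f2 <- build(50)  # period exactly doubled, same waveform shape
  k <- 2
  time_slots <- c("t1", "t2", "t3", "delta_t", "tpi", "w", "ta1", "tb1",
                  "te1", "tl1", "ta2", "tb2")
  expect_equal(unname(f2[time_slots]) / unname(f1[time_slots]),
               rep(k, length(time_slots)), tolerance = 0.02)
  ratio_slots <- c("t1_over_tpi", "t2_over_tpi", "t3_over_tpi",
                   "delta_t_over_tpi", "ta1_over_tpi", "tb1_over_tpi",
                   "te1_over_tpi", "tl1_over_tpi", "ta2_over_tpi",
                   "tb2_over_tpi", "ta1_plus_ta2_over_tpi",
                   "tb1_plus_tb2_over_tpi")
  expect_equal(f2[ratio_slots], f1[ratio_slots], tolerance = 0.02)
})

test_that("slot 14 and 15 recompute consistently from the same areas", {
  fid <- make_fid(A1 = 0.041, A2 = 0.057, A3 = 0.089)
  fv <- assemble_feature_vector(fid, make_dfid(), make_spectral(),
                                list(age = 30, gender = 0))
  A1 <- 0.041; A2 <- 0.057; A3 <- 0.089
  expect_equal(unname(fv["ipa"]), A3 / (A1 + A2), tolerance = 1e-12)
  expect_equal(unname(fv["svri"]), (A2 + A3) / A1, tolerance = 1e-12)
})

test_that("noiseless end-to-end features match ground-truth-derived values", {
  set.seed(60)
  for (i in 1:8) {
    hr <- runif(1, 58, 90)
    gr <- clean_record(heart_rate = hr, seed = 600 + i)
    rec <- preprocess_record(gr$record)
    cy <- segment_cycles(rec, detect_systolic_peaks(rec))
    best <- select_best_cycle(cy)
    fid <- locate_fiducials(best)
    expect_true(fid$ok)
    onset_t <- (best$onset_index - 1) / 1000
    tb <- gr$truth$beats
    k <- which.min(abs(tb$onset_time - onset_t))
    R <- diff(range(gr$truth$clean))
    onset_val <- gr$truth$clean[round(tb$onset_time[k] * 1000) + 1]
    truth <- c(x = (tb$x[k] - onset_val) / R, y = (tb$y[k] - onset_val) / R,
               z = (tb$z[k] - onset_val) / R,
               t1 = tb$t_sys[k] - tb$onset_time[k],
               t2 = tb$t_notch[k] - tb$onset_time[k],
               t3 = tb$t_dia[k] - tb$onset_time[k])
    got <- c(x = fid$x, y = fid$y, z = fid$z,
             t1 = fid$t1, t2 = fid$t2, t3 = fid$t3)
    expect_lt(max(abs(got - truth) / abs(truth)), 0.02)
    expect_equal(fid$y / fid$x, truth[["y"]] / truth[["x"]], tolerance = 0.02)
  }
})
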