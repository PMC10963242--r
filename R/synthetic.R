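#' Synthetic beat morphology configuration
#'
#' Parameterizes one PPG pulse as a sum of three Gaussian bumps per beat:
#' a narrow systolic wave, a broad shoulder under the dicrotic notch region
#' and a diastolic wave. Amplitudes of the diastolic wave and the notch
#' shoulder are expressed as fractions of the systolic amplitude; landmark
#' times as fractions of the beat period (60 / heart rate).
#'
#' The realized landmark amplitudes and times of the summed waveform differ
#' slightly from the configured fractions because the bumps overlap; ground
#' truth therefore records the landmarks of the rendered noiseless waveform
#' itself (see [generate_record()]).
#'
#' @param heart_rate Beats per minute, in \[40, 180\].
#' @param systolic_amplitude Systolic bump amplitude, arbitrary units.
#' @param diastolic_amplitude_ratio Diastolic over systolic amplitude (y/x),
#'   in (0, 1).
#' @param notch_depth_ratio Notch-shoulder over systolic amplitude (z/x),
#'   in (0, 1). Set to 0 together with `diastolic_amplitude_ratio = 0` to
#'   build notch-free ("unfit") beats.
#' @param systolic_time_fraction,notch_time_fraction,diastolic_time_fraction
#'   Bump centers as fractions of the beat period; must be strictly
#'   increasing within (0, 1).
#' @param width_fractions Gaussian standard deviations of the three bumps as
#'   fractions of the beat period.
#'
#' @return A list of class `beat_config`.
#' @export
beat_config <- function(heart_rate = 72,
                        systolic_amplitude = 1,
                        diastolic_amplitude_ratio = 0.45,
                        notch_depth_ratio = 0.36,
                        systolic_time_fraction = 0.22,
                        notch_time_fraction = 0.44,
                        diastolic_time_fraction = 0.58,
                        width_fractions = c(0.095, 0.18, 0.085)) {
  if (!is.numeric(heart_rate) || heart_rate < 40 || heart_rate > 180)
    stop("invalid beat_config: heart_rate must lie in [40, 180] beats/min")
  if (systolic_amplitude <= 0)
    stop("invalid beat_config: systolic_amplitude must be positive")
  if (diastolic_amplitude_ratio < 0 || diastolic_amplitude_ratio >= 1)
    stop("invalid beat_config: diastolic_amplitude_ratio must lie in [0, 1)")
  if (notch_depth_ratio < 0 || notch_depth_ratio >= 1)
    stop("invalid beat_config: notch_depth_ratio must lie in [0, 1)")
  fr <- c(systolic_time_fraction, notch_time_fraction, diastolic_time_fraction)
  if (any(fr <= 0) || any(fr >= 1) || any(diff(fr) <= 0))
    stop("invalid beat_config: time fractions must satisfy ",
         "0 < systolic < notch < diastolic < 1")
  if (length(width_fractions) != 3L || any(width_fractions <= 0))
    stop("invalid beat_config: width_fractions must be 3 positive values")
  structure(list(heart_rate = heart_rate,
                 systolic_amplitude = systolic_amplitude,
                 diastolic_amplitude_ratio = diastolic_amplitude_ratio,
                 notch_depth_ratio = notch_depth_ratio,
                 systolic_time_fraction = systolic_time_fraction,
                 notch_time_fraction = notch_time_fraction,
                 diastolic_time_fraction = diastolic_time_fraction,
                 width_fractions = width_fractions),
            class = "beat_config")
}

#' Additive noise configuration for synthetic PPG
#'
#' Models the three disturbance classes seen on raw fingertip PPG: slow
#' baseline drift (respiration/motion), a powerline tone and broadband
#' sensor noise.
#'
#' @param baseline_drift_amplitude Drift amplitude (units of the clean
#'   waveform); `baseline_drift_frequency` must be below 0.5 Hz.
#' @param baseline_drift_frequency Drift frequency in Hz.
#' @param powerline_amplitude,powerline_frequency Mains interference tone
#'   (e.g. 50 Hz).
#' @param white_noise_sd Standard deviation of i.i.d. Gaussian noise.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(baseline_drift_amplitude = 0.05,
                         baseline_drift_frequency = 0.25,
                         powerline_amplitude = 0.02,
                         powerline_frequency = 50,
                         white_noise_sd = 0.01) {
  amps <- c(baseline_drift_amplitude, powerline_amplitude, white_noise_sd)
  if (any(amps < 0))
    stop("invalid noise_config: amplitudes must be non-negative")
  if (baseline_drift_frequency <= 0 || baseline_drift_frequency >= 0.5)
    stop("invalid noise_config: baseline_drift_frequency must lie in (0, 0.5) Hz")
  if (powerline_frequency <= 0)
    stop("invalid noise_config: powerline_frequency must be positive")
  structure(list(baseline_drift_amplitude = baseline_drift_amplitude,
                 baseline_drift_frequency = baseline_drift_frequency,
                 powerline_amplitude = powerline_amplitude,
                 powerline_frequency = powerline_frequency,
                 white_noise_sd = white_noise_sd),
            class = "noise_config")
}

#' Zero-noise configuration shortcut
#' @return A [noise_config()] with all amplitudes 0.
#' @export
no_noise <- function() {
  noise_config(baseline_drift_amplitude = 0, powerline_amplitude = 0,
               white_noise_sd = 0)
}

# Clean (noise-free) waveform for a tiled beat train evaluated at times tt.
# Beats start at k*T (pre-systolic minimum); Gaussian tails of neighbouring
# beats are summed so the waveform is smooth across onsets.
render_beat_train <- function(beat, tt) {
  T <- 60 / beat$heart_rate
  x <- beat$systolic_amplitude
  amps <- c(x,
            0.9 * beat$notch_depth_ratio * x,
            0.85 * beat$diastolic_amplitude_ratio * x)
  mus <- c(beat$systolic_time_fraction,
           beat$notch_time_fraction,
           beat$diastolic_time_fraction) * T
  sds <- beat$width_fractions * T
  out <- numeric(length(tt))
  for (k in -1:ceiling(max(tt) / T)) {
    for (j in 1:3) {
      if (amps[j] > 0)
        out <- out + amps[j] * exp(-(tt - (k * T + mus[j]))^2 / (2 * sds[j]^2))
    }
  }
  out
}

# Landmarks (systolic max, notch min, diastolic max) of the clean waveform,
# one row per beat whose systolic peak falls inside the record; `complete`
# marks beats whose full period fits. Times in seconds from record start.
beat_landmarks <- function(clean, fs, heart_rate, duration) {
  T <- 60 / heart_rate
  n_beats <- ceiling(duration / T)
  out <- NULL
  d <- diff(clean)
  sgn <- diff(sign(d))
  maxima <- which(sgn < 0) + 1L
  minima <- which(sgn > 0) + 1L
  for (k in seq_len(n_beats) - 1L) {
    lo <- floor(k * T * fs) + 1L
    hi <- min(length(clean), floor((k + 1) * T * fs) + 1L)
    mx <- maxima[maxima >= lo & maxima <= hi]
    if (length(mx) == 0L) next
    i_sys <- mx[which.max(clean[mx])]
    onset_lo <- max(1L, i_sys - as.integer(round(T * fs)))
    i_onset <- onset_lo + which.min(clean[onset_lo:i_sys]) - 1L
    mn_after <- minima[minima > i_sys & minima <= hi]
    mx_after <- maxima[maxima > i_sys & maxima <= hi]
    i_notch <- if (length(mn_after)) mn_after[1L] else NA_integer_
    i_dia <- if (!is.na(i_notch) && length(mx_after[mx_after > i_notch]))
      mx_after[mx_after > i_notch][1L] else NA_integer_
    out <- rbind(out, data.frame(
      beat = k + 1L,
      complete = (k + 1) * T <= duration + 1e-9,
      onset_time = (i_onset - 1L) / fs,
      t_sys = (i_sys - 1L) / fs, x = clean[i_sys],
      t_notch = if (is.na(i_notch)) NA_real_ else (i_notch - 1L) / fs,
      z = if (is.na(i_notch)) NA_real_ else clean[i_notch],
      t_dia = if (is.na(i_dia)) NA_real_ else (i_dia - 1L) / fs,
      y = if (is.na(i_dia)) NA_real_ else clean[i_dia]))
  }
  out
}

#' Generate one synthetic PPG record with ground truth
#'
#' Renders a tiled beat train (sum of three Gaussian bumps per beat; beats
#' start at the pre-systolic minimum and the duration truncates the last
#' partial beat), adds the configured noise, and returns both the record and
#' the true landmark table of the noiseless waveform.
#'
#' @param beat A [beat_config()].
#' @param noise A [noise_config()]; use [no_noise()] for a clean record.
#' @param fs Sampling rate in Hz.
#' @param duration Record duration in seconds; the record has
#'   `round(fs * duration)` samples.
#' @param seed Optional integer seed; the same seed reproduces the record
#'   bit for bit.
#' @param subject_id,segment_id Identifiers stored on the record.
#'
#' @return A list with `record` (a [ppg_record()]) and `truth`, itself a list
#'   holding `beats` (per-beat landmark times/amplitudes of the clean
#'   waveform), `clean` (the noiseless samples), `beat` and `noise` configs.
#' @export
generate_record <- function(beat = beat_config(), noise = noise_config(),
                            fs = 1000, duration = 2.1, seed = NULL,
                            subject_id = "S1", segment_id = 1L) {
  stopifnot(inherits(beat, "beat_config"), inherits(noise, "noise_config"))
  if (fs <= 0) stop("'fs' must be positive")
  if (duration <= 0) stop("'duration' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(fs * duration)
  tt <- (seq_len(n) - 1L) / fs
  clean <- render_beat_train(beat, tt)
  drift_phase <- stats::runif(1, 0, 2 * pi)
  mains_phase <- stats::runif(1, 0, 2 * pi)
  samples <- clean +
    noise$baseline_drift_amplitude *
      sin(2 * pi * noise$baseline_drift_frequency * tt + drift_phase) +
    noise$powerline_amplitude *
      sin(2 * pi * noise$powerline_frequency * tt + mains_phase) +
    stats::rnorm(n, 0, noise$white_noise_sd)
  truth <- list(beats = beat_landmarks(clean, fs, beat$heart_rate, duration),
                clean = clean, beat = beat, noise = noise, fs = fs)
  list(record = ppg_record(samples, fs, subject_id, segment_id),
       truth = truth)
}

# Default blood-pressure sampler: SBP/DBP drawn from the clinical cohort
# distribution (SBP 127 +/- 20 in [80, 174]; DBP 71 +/- 11 in [42, 104],
# correlated with SBP), with a 15 mmHg minimum pulse pressure.
default_bp_sampler <- function(n) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  sbp <- pmin(pmax(127 + 20 * z1, 80), 174)
  dbp <- pmin(pmax(71 + 11 * (0.6 * z1 + 0.8 * z2), 42), 104)
  dbp <- pmin(dbp, sbp - 15)
  data.frame(sbp = sbp, dbp = dbp)
}

# Monotone map from a subject's true BP to beat morphology. Documented hooks:
# heart rate increases with MAP; diastolic amplitude ratio (y/x, the
# augmentation index analogue) increases and the systolic time fraction
# decreases with SBP; the notch shoulder rises and the diastolic wave comes
# earlier with DBP.
bp_to_morphology <- function(sbp, dbp) {
  map <- (2 * dbp + sbp) / 3
  hr <- 70 + 0.30 * (map - 87)
  yr <- 0.45 + 0.0030 * (sbp - 127)
  t1f <- 0.225 - 0.00045 * (sbp - 127)
  zr <- pmin(0.355 + 0.0022 * (dbp - 71), yr + 0.05)
  t3f <- 0.585 - 0.0008 * (dbp - 71)
  list(heart_rate = hr, yr = yr, t1f = t1f, zr = zr, t3f = t3f)
}

#' Generate a synthetic PPG cohort with reference blood pressures
#'
#' Draws per-subject reference SBP/DBP, maps them to beat morphology through
#' a fixed monotone rule (see Details), renders `segments_per_subject`
#' records per subject with small per-segment morphology jitter, and stores
#' reference pressures as the true pressures plus measurement noise of
#' standard deviation `bp_noise_sd` (the cuff-device error floor).
#'
#' @details The morphology hooks are: heart rate rises with MAP
#'   (0.3 bpm/mmHg); the diastolic amplitude ratio rises (0.003/mmHg) and the
#'   systolic time fraction falls with SBP; the notch shoulder amplitude
#'   rises and the diastolic wave time falls with DBP. These make the
#'   extracted waveform features informative about BP, so feature-to-BP
#'   recovery can be tested end to end.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param segments_per_subject Records per subject (default 3).
#' @param fs,duration Passed to [generate_record()].
#' @param noise A [noise_config()] applied to every record.
#' @param bp_sampler Function `n -> data.frame(sbp, dbp)`; must yield
#'   SBP > DBP. Default: clinical-cohort distribution (see above).
#' @param bp_noise_sd Standard deviation (mmHg) of the reference-device
#'   error added to the stored SBP/DBP labels; default 3.
#' @param seed Integer seed governing all randomness of the cohort.
#'
#' @return A list with `records` (list of [ppg_record()]), `subjects`
#'   (data.frame: subject_id, age, sex, height, weight, sbp, dbp, map),
#'   `truth` (per-record ground-truth list, plus `true_bp` with the
#'   noise-free pressures) — MAP always equals (2 DBP + SBP)/3 of the stored
#'   values.
#' @export
generate_cohort <- function(n_subjects, segments_per_subject = 3,
                            fs = 1000, duration = 2.1,
                            noise = noise_config(),
                            bp_sampler = default_bp_sampler,
                            bp_noise_sd = 3, seed = 1L) {
  if (n_subjects < 1) stop("'n_subjects' must be >= 1")
  set.seed(seed)
  bp <- bp_sampler(n_subjects)
  if (any(bp$sbp <= bp$dbp))
    stop("bp_sampler yielded SBP <= DBP")
  age <- round(pmin(pmax(stats::rnorm(n_subjects, 57, 15), 21), 85))
  sex <- ifelse(stats::runif(n_subjects) < 0.48, "male", "female")
  height <- round(stats::rnorm(n_subjects, 161, 8))
  weight <- round(stats::rnorm(n_subjects, 60, 11))
  sbp_ref <- bp$sbp + stats::rnorm(n_subjects, 0, bp_noise_sd)
  dbp_ref <- bp$dbp + stats::rnorm(n_subjects, 0, bp_noise_sd)
  dbp_ref <- pmin(dbp_ref, sbp_ref - 10)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    age = age, sex = sex, height = height, weight = weight,
    sbp = sbp_ref, dbp = dbp_ref, map = (2 * dbp_ref + sbp_ref) / 3,
    stringsAsFactors = FALSE)
  morph <- bp_to_morphology(bp$sbp, bp$dbp)
  records <- list(); truth <- list()
  for (i in seq_len(n_subjects)) {
    for (s in seq_len(segments_per_subject)) {
      bc <- beat_config(
        heart_rate = min(max(morph$heart_rate[i] + stats::rnorm(1, 0, 0.8), 45), 170),
        diastolic_amplitude_ratio = min(max(morph$yr[i] + stats::rnorm(1, 0, 0.006), 0.05), 0.95),
        notch_depth_ratio = min(max(morph$zr[i] + stats::rnorm(1, 0, 0.004), 0.05), 0.95),
        systolic_time_fraction = morph$t1f[i] + stats::rnorm(1, 0, 0.0015),
        diastolic_time_fraction = morph$t3f[i] + stats::rnorm(1, 0, 0.002))
      gr <- generate_record(bc, noise, fs = fs, duration = duration,
                            subject_id = subjects$subject_id[i], segment_id = s)
      key <- sprintf("%s_%d", subjects$subject_id[i], s)
      records[[key]] <- gr$record
      truth[[key]] <- gr$truth
    }
  }
  list(records = records, subjects = subjects,
       truth = list(records = truth,
                    true_bp = data.frame(subject_id = subjects$subject_id,
                                         sbp = bp$sbp, dbp = bp$dbp,
                                         map = (2 * bp$dbp + bp$sbp) / 3),
                    bp_noise_sd = bp_noise_sd,
                    morphology_map = "see bp_to_morphology"))
}

#' Write a synthetic cohort to disk in the ingest layout
#'
#' One `<subject>_<segment>.txt` file per record (one sample per row) plus
#' `subjects.csv` with columns subject_id, sex, age, height, weight, sbp,
#' dbp. The layout round-trips through [read_ppg_record()] /
#' [read_subject_table()].
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (rec in cohort$records) {
    p <- file.path(dir, sprintf("%s_%d.txt", rec$subject_id, rec$segment_id))
    writeLines(format(rec$samples, digits = 17, trim = TRUE, scientific = FALSE), p)
    paths <- c(paths, p)
  }
  sp <- file.path(dir, "subjects.csv")
  utils::write.csv(
    cohort$subjects[, c("subject_id", "sex", "age", "height", "weight", "sbp", "dbp")],
    sp, row.names = FALSE)
  invisible(c(paths, sp))
}
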