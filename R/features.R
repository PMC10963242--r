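#' Canonical names of the 48 feature slots
#'
#' Slots 1-21 come from the PPG waveform itself, 22-29 from its first
#' derivative, 30-40 from its second derivative, 41-46 from the magnitude
#' spectrum, and 47-48 are the subject's age and encoded gender
#' (female = 0, male = 1).
#'
#' @return Character vector of length 48. The `"group"` attribute maps each
#'   slot to `"ppg"`, `"d1"`, `"d2"`, `"fft"` or `"demographic"`.
#' @export
ppg_feature_names <- function() {
  nm <- c(
    "x", "y", "z", "tpi",
    "y_over_x", "x_minus_y_over_x", "z_over_x", "y_minus_x_over_x",
    "t1", "t2", "t3", "delta_t", "w", "ipa", "svri",
    "t1_over_x", "dia_falling_slope",
    "t1_over_tpi", "t2_over_tpi", "t3_over_tpi", "delta_t_over_tpi",
    "ta1", "tb1", "te1", "tl1",
    "ta1_over_tpi", "tb1_over_tpi", "te1_over_tpi", "tl1_over_tpi",
    "b2_over_a2", "e2_over_a2", "b2_plus_e2_over_a2",
    "ta2", "tb2", "ta2_over_tpi", "tb2_over_tpi",
    "ta1_plus_ta2_over_tpi", "tb1_plus_tb2_over_tpi",
    "te1_plus_t2_over_tpi", "tl1_plus_t3_over_tpi",
    "f_base", "s_base", "f_2nd", "s_2nd", "f_3rd", "s_3rd",
    "age", "gender")
  attr(nm, "group") <- c(rep("ppg", 21), rep("d1", 8), rep("d2", 11),
                         rep("fft", 6), rep("demographic", 2))
  nm
}

#' Numerical differentiation of a PPG cycle
#'
#' First order: central differences scaled by the sampling rate (units 1/s),
#' one-sided at the ends. Second order: the standard three-point second
#' difference (units 1/s^2), with the end values replicated from the nearest
#' interior point. Length always equals the input length.
#'
#' @param cycle A [ppg_cycle()] or a numeric vector (then `fs` is required).
#' @param order 1 or 2.
#' @param fs Sampling rate, taken from the cycle when given.
#' @return Numeric vector, same length as the input.
#' @export
differentiate <- function(cycle, order = 1, fs = NULL) {
  x <- if (inherits(cycle, "ppg_cycle")) cycle$samples else as.numeric(cycle)
  if (inherits(cycle, "ppg_cycle")) fs <- cycle$fs
  if (is.null(fs)) stop("'fs' required when passing a bare vector")
  n <- length(x)
  if (n < 5L) stop("cycle too short to differentiate (need >= 5 samples)")
  if (order == 1) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
    d[1] <- (x[2] - x[1]) * fs
    d[n] <- (x[n] - x[n - 1]) * fs
    d
  } else if (order == 2) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * fs^2
    d[1] <- d[2]; d[n] <- d[n - 1]
    d
  } else stop("'order' must be 1 or 2")
}

# Failure result shared by the fiducial locators.
fiducial_failure <- function(reason, class) {
  structure(list(ok = FALSE, reason = reason), class = class)
}

#' Locate the time-domain fiducial points of a PPG cycle
#'
#' The systolic peak (amplitude x at time t1) is the cycle's global maximum.
#' The dicrotic notch (z, t2) is the most prominent local minimum in the
#' window (t1, t1 + `notch_window` * (tpi - t1)); if no local minimum
#' exists, the maximum of the smoothed second derivative in that window is
#' used as fallback. The diastolic peak (y, t3) is the first local maximum
#' after the notch, falling back to the first downward zero crossing of the
#' second derivative. Amplitudes are measured relative to the cycle-onset
#' value; times from the cycle onset in seconds.
#'
#' Cycles without a detectable notch or diastolic wave are returned flagged
#' (`ok = FALSE` with a reason) rather than yielding bogus landmarks — such
#' waveforms are the "unfit" class that quality screening targets.
#'
#' @param cycle A [ppg_cycle()].
#' @param notch_window Fraction of the post-systolic cycle searched for the
#'   notch (default 0.6; prevents capturing the end-of-cycle trough).
#' @return A list of class `ppg_fiducials`: `ok`, amplitudes `x`, `y`, `z`,
#'   times `t1`, `t2`, `t3`, `tpi`, sample `indices`, onset `baseline`.
#' @export
locate_fiducials <- function(cycle, notch_window = 0.6) {
  stopifnot(inherits(cycle, "ppg_cycle"))
  s <- cycle$samples
  n <- length(s)
  fs <- cycle$fs
  base <- s[1L]
  i1 <- which.max(s)
  if (i1 == 1L || i1 == n)
    return(fiducial_failure("systolic peak not interior", "ppg_fiducials"))
  hi <- i1 + floor(notch_window * (n - i1))
  if (hi - i1 < 3L)
    return(fiducial_failure("no-notch", "ppg_fiducials"))
  w <- (i1 + 1L):hi
  mins <- find_peaks(-s[w], min_prominence = 0)
  if (length(mins)) {
    # prominence of minima: depth below the lower of the flanking maxima
    prom <- vapply(mins, function(p) {
      seg <- s[w]
      min(max(seg[1:p]), max(seg[p:length(seg)])) - seg[p]
    }, numeric(1))
    i2 <- w[mins[which.max(prom)]]
  } else {
    d2s <- moving_average_centered(differentiate(cycle, 2), 11L)
    i2 <- w[which.max(d2s[w])]
  }
  after <- if (i2 + 1L <= n - 1L) (i2 + 1L):(n - 1L) else integer(0)
  maxs <- if (length(after) >= 3L) find_peaks(s[after], min_prominence = 0) else integer(0)
  if (length(maxs)) {
    i3 <- after[maxs[1L]]
  } else {
    d2s <- moving_average_centered(differentiate(cycle, 2), 11L)
    zc <- which(d2s[after[-length(after)]] > 0 & d2s[after[-1L]] <= 0)
    if (!length(zc))
      return(fiducial_failure("no-diastolic-peak", "ppg_fiducials"))
    i3 <- after[zc[1L]]
  }
  out <- list(ok = TRUE,
              x = s[i1] - base, z = s[i2] - base, y = s[i3] - base,
              t1 = (i1 - 1L) / fs, t2 = (i2 - 1L) / fs, t3 = (i3 - 1L) / fs,
              tpi = cycle$tpi, baseline = base,
              indices = c(systolic = i1, notch = i2, diastolic = i3))
  if (!(out$t1 > 0 && out$t1 < out$t2 && out$t2 < out$t3 && out$t3 < out$tpi))
    return(fiducial_failure("landmark ordering violated", "ppg_fiducials"))
  if (out$x < out$z || out$x < out$y)
    return(fiducial_failure("systolic peak not dominant", "ppg_fiducials"))
  structure(out, class = "ppg_fiducials")
}

#' Pulse width and partial areas of a PPG cycle
#'
#' `w` is the full width (in seconds) at half the systolic amplitude,
#' measured on the onset-baseline-corrected waveform with linear
#' interpolation between samples. `A1`, `A2`, `A3` are trapezoidal areas of
#' the corrected waveform from onset to t1, t1 to t2, and t2 to the cycle
#' end; they share their boundary samples so A1 + A2 + A3 equals the total
#' area exactly.
#'
#' @param cycle A [ppg_cycle()].
#' @param fid A valid [locate_fiducials()] result.
#' @return List with `w`, `A1`, `A2`, `A3` and the auxiliary ratio `A2_A1`.
#' @export
width_and_areas <- function(cycle, fid) {
  stopifnot(inherits(cycle, "ppg_cycle"), inherits(fid, "ppg_fiducials"))
  if (!isTRUE(fid$ok)) stop("fiducials are flagged: ", fid$reason)
  s <- cycle$samples - fid$baseline
  n <- length(s)
  fs <- cycle$fs
  i1 <- fid$indices[["systolic"]]
  i2 <- fid$indices[["notch"]]
  half <- fid$x / 2
  left <- which(s[1:(i1 - 1L)] < half & s[2:i1] >= half)
  if (!length(left)) stop("half-amplitude not crossed on the rising flank")
  il <- max(left)
  tl <- (il - 1L + (half - s[il]) / (s[il + 1L] - s[il])) / fs
  right <- which(s[i1:(n - 1L)] >= half & s[(i1 + 1L):n] < half)
  if (!length(right)) stop("half-amplitude not crossed on the falling flank")
  ir <- i1 + right[1L] - 1L
  tr <- (ir - 1L + (s[ir] - half) / (s[ir] - s[ir + 1L])) / fs
  trapz <- function(idx) sum((s[idx[-1L]] + s[idx[-length(idx)]]) / 2) / fs
  A1 <- trapz(1:i1); A2 <- trapz(i1:i2); A3 <- trapz(i2:n)
  list(w = tr - tl, A1 = A1, A2 = A2, A3 = A3, A2_A1 = A2 / A1)
}

#' Locate fiducial points on the PPG derivatives
#'
#' On the first derivative (PPG'): `a1` is the global maximum (steepest
#' systolic upstroke, time `ta1` from the cycle onset), `b1` the global
#' minimum after it (`tb1` = elapsed time from a1 to b1), `e1` the first
#' local maximum after b1 (time `te1` from the onset), and `l1` the last
#' zero crossing of PPG' in the cycle (time `tl1`, linearly interpolated).
#' On the second derivative (PPG''), smoothed by an 11-sample moving
#' average, the reference point `l2` is the cycle onset: `a2` is the early
#' systolic maximum (before the systolic peak), `b2` the following minimum,
#' `e2` the largest maximum after b2 within the first 85% of the cycle;
#' `ta2`/`tb2` are measured from l2.
#'
#' @param cycle A [ppg_cycle()].
#' @param smooth_window Moving-average length applied to PPG'' before
#'   landmark detection (default 11 samples).
#' @return A list of class `ppg_deriv_fiducials` with `ok`, first-derivative
#'   amplitudes/times `a1`, `b1`, `e1`, `l1`, `ta1`, `tb1`, `te1`, `tl1` and
#'   second-derivative `a2`, `b2`, `e2`, `ta2`, `tb2`.
#' @export
locate_derivative_fiducials <- function(cycle, smooth_window = 11L) {
  stopifnot(inherits(cycle, "ppg_cycle"))
  fs <- cycle$fs
  n <- length(cycle$samples)
  d1 <- differentiate(cycle, 1)
  d2 <- moving_average_centered(differentiate(cycle, 2), smooth_window)
  i_a1 <- which.max(d1)
  if (i_a1 >= n - 2L)
    return(fiducial_failure("PPG' peak at cycle edge", "ppg_deriv_fiducials"))
  i_b1 <- i_a1 + which.min(d1[(i_a1 + 1L):n])
  after_b1 <- if (i_b1 + 1L <= n) (i_b1 + 1L):n else integer(0)
  e1_peaks <- if (length(after_b1) >= 3L) find_peaks(d1[after_b1], 0) else integer(0)
  if (!length(e1_peaks))
    return(fiducial_failure("no e1 landmark on PPG'", "ppg_deriv_fiducials"))
  i_e1 <- after_b1[e1_peaks[1L]]
  zc <- which(sign(d1[-n]) * sign(d1[-1L]) < 0)
  if (!length(zc))
    return(fiducial_failure("no zero crossing on PPG'", "ppg_deriv_fiducials"))
  iz <- zc[length(zc)]
  tl1 <- (iz - 1L + d1[iz] / (d1[iz] - d1[iz + 1L])) / fs
  # second derivative: a-wave before the systolic peak, b-wave after it
  i_sys <- which.max(cycle$samples)
  if (i_sys < 3L)
    return(fiducial_failure("systolic peak at cycle edge", "ppg_deriv_fiducials"))
  i_a2 <- which.max(d2[1:i_sys])
  if (i_a2 + 1L > n)
    return(fiducial_failure("no b2 landmark on PPG''", "ppg_deriv_fiducials"))
  i_b2 <- i_a2 + which.min(d2[(i_a2 + 1L):n])
  hi_e2 <- floor(0.85 * n)
  if (i_b2 + 1L > hi_e2)
    return(fiducial_failure("no e2 landmark on PPG''", "ppg_deriv_fiducials"))
  i_e2 <- i_b2 + which.max(d2[(i_b2 + 1L):hi_e2])
  out <- list(ok = TRUE,
              a1 = d1[i_a1], b1 = d1[i_b1], e1 = d1[i_e1], l1 = 0,
              ta1 = (i_a1 - 1L) / fs,
              tb1 = (i_b1 - i_a1) / fs,
              te1 = (i_e1 - 1L) / fs,
              tl1 = tl1,
              a2 = d2[i_a2], b2 = d2[i_b2], e2 = d2[i_e2],
              ta2 = (i_a2 - 1L) / fs, tb2 = (i_b2 - 1L) / fs,
              indices = c(a1 = i_a1, b1 = i_b1, e1 = i_e1,
                          a2 = i_a2, b2 = i_b2, e2 = i_e2))
  if (!(out$ta1 > 0 && out$tb1 > 0 && out$ta2 < out$tb2))
    return(fiducial_failure("derivative landmark ordering violated",
                            "ppg_deriv_fiducials"))
  structure(out, class = "ppg_deriv_fiducials")
}

#' Spectral peak features of a PPG record
#'
#' Computes the magnitude spectrum of the mean-removed full record (zero
#' padded to the next power of two, no window), finds the largest magnitude
#' peak within `band` (the fundamental, `f_base`), and the next two local
#' spectral maxima above it in ascending frequency.
#'
#' The full 2.1-s segment, not the single best cycle, is used: at one cycle
#' of data the harmonic structure would be unresolvable.
#'
#' @param record A preprocessed [ppg_record()].
#' @param band Search band in Hz (default 0.5-12, the plausible heart-rate
#'   band below the filter cutoff).
#' @return List of class `spectral_peaks`: `f_base`, `s_base`, `f_2nd`,
#'   `s_2nd`, `f_3rd`, `s_3rd`.
#' @export
spectral_features <- function(record, band = c(0.5, 12)) {
  stopifnot(inherits(record, "ppg_record"))
  x <- record$samples - mean(record$samples)
  n <- length(x)
  nfft <- 2^ceiling(log2(n))
  mag <- Mod(stats::fft(c(x, numeric(nfft - n))))[1:(nfft %/% 2 + 1L)]
  freq <- (0:(nfft %/% 2)) * record$fs / nfft
  in_band <- which(freq >= band[1] & freq <= band[2])
  if (length(in_band) < 5L) stop("spectral band too narrow at this record length")
  # prominence floor: ignore leakage ripple below 5% of the strongest
  # in-band component
  pk <- find_peaks(mag[in_band], min_prominence = 0.05 * max(mag[in_band]))
  if (length(pk) < 3L)
    stop("fewer than three spectral peaks in the ", band[1], "-", band[2],
         " Hz band")
  pk_idx <- in_band[pk]
  i_base <- pk_idx[which.max(mag[pk_idx])]
  above <- pk_idx[pk_idx > i_base]
  if (length(above) < 2L)
    stop("fewer than two spectral peaks above the fundamental")
  structure(list(f_base = freq[i_base], s_base = mag[i_base],
                 f_2nd = freq[above[1L]], s_2nd = mag[above[1L]],
                 f_3rd = freq[above[2L]], s_3rd = mag[above[2L]]),
            class = "spectral_peaks")
}

#' Assemble the canonical 48-slot feature vector
#'
#' Combines time-domain fiducials (with width/areas merged in), derivative
#' fiducials, spectral peaks and subject demographics into the named
#' 48-slot vector; every ratio is computed exactly per its printed
#' definition (see [ppg_feature_names()]).
#'
#' Two conventions are worth noting. Slot 14 (`ipa`) is A3/(A1+A2); the
#' closely related A2/A1 ratio is attached as the `"aux"` attribute so
#' selection outputs can be mapped to either naming. Slot 16 is t1/x, the
#' printed form of the "systolic peak rising slope"; set
#' `slope_convention = "physical"` for x/t1 instead.
#'
#' @param fid A valid [locate_fiducials()] result with `w`, `A1`-`A3` merged
#'   in (see [width_and_areas()]).
#' @param dfid A valid [locate_derivative_fiducials()] result.
#' @param spectral A [spectral_features()] result.
#' @param subject A list or one-row data.frame with `age` and `sex`
#'   (`"male"`/`"female"`) or already-encoded `gender` (0/1).
#' @param slope_convention `"as_printed"` (t1/x) or `"physical"` (x/t1).
#' @return Named numeric vector of length 48 (class `ppg_features`) with
#'   attributes `group`, `aux` (A2/A1) and `provenance`.
#' @export
assemble_feature_vector <- function(fid, dfid, spectral, subject,
                                    slope_convention = c("as_printed", "physical")) {
  slope_convention <- match.arg(slope_convention)
  if (!isTRUE(fid$ok)) stop("fiducials flagged: ", fid$reason)
  if (!isTRUE(dfid$ok)) stop("derivative fiducials flagged: ", dfid$reason)
  if (is.null(fid$w)) stop("fiducials lack width/areas; run width_and_areas()")
  gender <- if (!is.null(subject$gender)) as.numeric(subject$gender)
            else if (identical(subject$sex, "male")) 1 else 0
  age <- as.numeric(subject$age)
  div <- function(num, den, feature) {
    if (abs(den) < .Machine$double.eps)
      stop("zero denominator computing feature '", feature, "'")
    num / den
  }
  if (fid$tpi - fid$t3 < 0.005)
    stop("cycle rejected: t3 within 5 ms of tpi (feature 'dia_falling_slope' ",
         "denominator degenerate)")
  v <- c(
    x = fid$x, y = fid$y, z = fid$z, tpi = fid$tpi,
    y_over_x = div(fid$y, fid$x, "y_over_x"),
    x_minus_y_over_x = div(fid$x - fid$y, fid$x, "x_minus_y_over_x"),
    z_over_x = div(fid$z, fid$x, "z_over_x"),
    y_minus_x_over_x = div(fid$y - fid$x, fid$x, "y_minus_x_over_x"),
    t1 = fid$t1, t2 = fid$t2, t3 = fid$t3,
    delta_t = fid$t3 - fid$t1,
    w = fid$w,
    ipa = div(fid$A3, fid$A1 + fid$A2, "ipa"),
    svri = div(fid$A2 + fid$A3, fid$A1, "svri"),
    t1_over_x = if (slope_convention == "as_printed")
      div(fid$t1, fid$x, "t1_over_x") else div(fid$x, fid$t1, "t1_over_x"),
    dia_falling_slope = div(fid$y, fid$tpi - fid$t3, "dia_falling_slope"),
    t1_over_tpi = div(fid$t1, fid$tpi, "t1_over_tpi"),
    t2_over_tpi = div(fid$t2, fid$tpi, "t2_over_tpi"),
    t3_over_tpi = div(fid$t3, fid$tpi, "t3_over_tpi"),
    delta_t_over_tpi = div(fid$t3 - fid$t1, fid$tpi, "delta_t_over_tpi"),
    ta1 = dfid$ta1, tb1 = dfid$tb1, te1 = dfid$te1, tl1 = dfid$tl1,
    ta1_over_tpi = div(dfid$ta1, fid$tpi, "ta1_over_tpi"),
    tb1_over_tpi = div(dfid$tb1, fid$tpi, "tb1_over_tpi"),
    te1_over_tpi = div(dfid$te1, fid$tpi, "te1_over_tpi"),
    tl1_over_tpi = div(dfid$tl1, fid$tpi, "tl1_over_tpi"),
    b2_over_a2 = div(dfid$b2, dfid$a2, "b2_over_a2"),
    e2_over_a2 = div(dfid$e2, dfid$a2, "e2_over_a2"),
    b2_plus_e2_over_a2 = div(dfid$b2 + dfid$e2, dfid$a2, "b2_plus_e2_over_a2"),
    ta2 = dfid$ta2, tb2 = dfid$tb2,
    ta2_over_tpi = div(dfid$ta2, fid$tpi, "ta2_over_tpi"),
    tb2_over_tpi = div(dfid$tb2, fid$tpi, "tb2_over_tpi"),
    ta1_plus_ta2_over_tpi = div(dfid$ta1 + dfid$ta2, fid$tpi, "ta1_plus_ta2_over_tpi"),
    tb1_plus_tb2_over_tpi = div(dfid$tb1 + dfid$tb2, fid$tpi, "tb1_plus_tb2_over_tpi"),
    te1_plus_t2_over_tpi = div(dfid$te1 + fid$t2, fid$tpi, "te1_plus_t2_over_tpi"),
    tl1_plus_t3_over_tpi = div(dfid$tl1 + fid$t3, fid$tpi, "tl1_plus_t3_over_tpi"),
    f_base = spectral$f_base, s_base = spectral$s_base,
    f_2nd = spectral$f_2nd, s_2nd = spectral$s_2nd,
    f_3rd = spectral$f_3rd, s_3rd = spectral$s_3rd,
    age = age, gender = gender)
  stopifnot(identical(names(v), as.character(ppg_feature_names())))
  if (any(!is.finite(v)))
    stop("non-finite feature value(s): ",
         paste(names(v)[!is.finite(v)], collapse = ", "))
  structure(v, class = "ppg_features",
            group = attr(ppg_feature_names(), "group"),
            aux = c(A2_A1 = fid$A2_A1))
}

#' Extract the 48-slot feature vector from one record
#'
#' Convenience wrapper running the whole single-record chain: optional
#' preprocessing, systolic peak detection, cycle segmentation, best-cycle
#' selection, time-domain and derivative fiducials, width/areas, spectral
#' peaks and assembly.
#'
#' @param record A [ppg_record()].
#' @param subject Subject row (needs `age` and `sex` or `gender`).
#' @param spec [filter_spec()] used when the record is not yet preprocessed.
#' @param ... Passed to [assemble_feature_vector()].
#' @return A list with `ok`; on success `features` (the 48-vector) and
#'   `cycle`; on failure a `reason` string.
#' @export
extract_features <- function(record, subject, spec = filter_spec(), ...) {
  res <- try({
    rec <- if (record$preprocessed) record else preprocess_record(record, spec)
    peaks <- detect_systolic_peaks(rec)
    cycles <- segment_cycles(rec, peaks)
    best <- select_best_cycle(cycles)
    fid <- locate_fiducials(best)
    if (!isTRUE(fid$ok)) stop("cycle flagged: ", fid$reason)
    wa <- width_and_areas(best, fid)
    fid[names(wa)] <- wa
    dfid <- locate_derivative_fiducials(best)
    if (!isTRUE(dfid$ok)) stop("cycle flagged: ", dfid$reason)
    spct <- spectral_features(rec)
    fv <- assemble_feature_vector(fid, dfid, spct, subject, ...)
    attr(fv, "provenance") <- list(subject_id = record$subject_id,
                                   segment_id = record$segment_id)
    list(ok = TRUE, features = fv, cycle = best)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    list(ok = FALSE, reason = trimws(conditionMessage(attr(res, "condition"))))
  else res
}

#' Build the feature matrix for a cohort
#'
#' Runs [extract_features()] over every record, joining each row to its
#' subject's demographics and reference pressures. Records whose cycles
#' cannot be fully landmarked are skipped and logged.
#'
#' @param records List of [ppg_record()] objects.
#' @param subjects Subject table (as from [read_subject_table()] or
#'   [generate_cohort()]).
#' @param spec [filter_spec()] for preprocessing.
#' @param ... Passed to [extract_features()].
#' @return A data.frame with `subject_id`, `segment_id`, the 48 feature
#'   columns and `sbp`, `dbp`, `map`. The `"failures"` attribute logs
#'   skipped records.
#' @export
extract_feature_matrix <- function(records, subjects, spec = filter_spec(), ...) {
  rows <- list(); fails <- list()
  for (rec in records) {
    subj <- subjects[subjects$subject_id == rec$subject_id, , drop = FALSE]
    if (nrow(subj) != 1L) {
      fails[[length(fails) + 1L]] <- data.frame(
        subject_id = rec$subject_id, segment_id = rec$segment_id,
        reason = "subject not in table")
      next
    }
    fx <- extract_features(rec, subj, spec = spec, ...)
    if (!fx$ok) {
      fails[[length(fails) + 1L]] <- data.frame(
        subject_id = rec$subject_id, segment_id = rec$segment_id,
        reason = fx$reason)
      next
    }
    row <- as.data.frame(as.list(unclass(fx$features)))
    row <- cbind(data.frame(subject_id = rec$subject_id,
                            segment_id = rec$segment_id), row)
    row$sbp <- subj$sbp; row$dbp <- subj$dbp
    row$map <- if (!is.null(subj$map)) subj$map else compute_map(subj$sbp, subj$dbp)
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("no record yielded a complete feature vector")
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(subject_id = character(0), segment_id = integer(0),
               reason = character(0))
  out
}
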