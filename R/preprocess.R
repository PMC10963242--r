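#' Filter bank specification
#'
#' Describes one low-pass denoising method for PPG records. Four methods are
#' supported: a Butterworth IIR filter (the default; applied forward and
#' backward so fiducial timings are not phase-shifted), a centered moving
#' average, a windowed-sinc FIR filter, and wavelet (db4) detail
#' soft-thresholding.
#'
#' @param method One of `"butterworth"`, `"moving_average"`, `"fir"`,
#'   `"dwt"`.
#' @param cutoff Low-pass cutoff in Hz (must be below fs/2 when applied).
#'   Default 12 Hz, the upper edge of the acquisition band-pass of typical
#'   fingertip probes.
#' @param order Butterworth order (default 7).
#' @param window Moving-average window length in samples; default
#'   `round(fs / cutoff)` at apply time (first spectral null at the cutoff).
#' @param taps FIR filter order (default 64).
#' @param wavelet Wavelet name; only `"db4"` is built in.
#' @param level Decomposition depth for `"dwt"`; default covers all detail
#'   bands above the cutoff.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(method = c("butterworth", "moving_average", "fir", "dwt"),
                        cutoff = 12, order = 7, window = NULL, taps = 64,
                        wavelet = "db4", level = NULL) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("'cutoff' must be positive")
  if (order < 1) stop("'order' must be >= 1")
  if (!is.null(window) && window < 1) stop("'window' must be >= 1 sample")
  if (wavelet != "db4") stop("only the db4 wavelet is built in")
  structure(list(method = method, cutoff = cutoff, order = order,
                 window = window, taps = taps, wavelet = wavelet,
                 level = level),
            class = "filter_spec")
}

#' Min-max normalization of a PPG signal
#'
#' Maps samples to \[0, 1\] via (s - min) / (max - min), preserving order.
#'
#' @param x Numeric vector with max(x) > min(x).
#' @return Vector of the same length with minimum 0 and maximum 1.
#' @export
normalize_ppg <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite samples")
  if (rng[2] <= rng[1])
    stop("cannot normalize a constant signal (zero denominator)")
  (x - rng[1]) / (rng[2] - rng[1])
}

# One causal pass with steady-state initialization: the filter history is
# seeded as if the first sample had been applied forever, so a constant
# input passes without transient (the same device scipy's filtfilt uses).
filter_ss <- function(b, a, x) {
  nb <- length(b); na <- length(a)
  x0 <- x[1L]
  init.x <- rep(x0, max(nb - 1L, 0L))
  dc_gain <- sum(b) / sum(a)
  init.y <- rep(x0 * dc_gain, max(na - 1L, 0L))
  as.numeric(signal::filter(b, a, x, init.x = init.x, init.y = init.y))
}

# Zero-phase IIR/FIR application: odd-reflection padding (3 filter lengths),
# steady-state-initialized forward pass, time reversal, backward pass.
# Keeps landmark times unshifted.
filtfilt_reflect <- function(b, a, x) {
  n <- length(x)
  pl <- min(3L * max(length(a), length(b)), n - 1L)
  front <- 2 * x[1] - x[seq(pl + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - pl)]
  xx <- c(front, x, back)
  y <- filter_ss(b, a, xx)
  y <- rev(filter_ss(b, a, rev(y)))
  y[(pl + 1L):(pl + n)]
}

# Centered moving average with reflection padding (zero phase, unit mass).
moving_average_centered <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  front <- if (half_l >= 1L) x[seq(half_l + 1L, 2L)] else numeric(0)
  back <- if (half_r >= 1L) x[seq(n - 1L, n - half_r)] else numeric(0)
  xx <- c(front, x, back)
  as.numeric(stats::filter(xx, rep(1 / w, w), sides = 2))[seq(half_l + 1L, half_l + n)]
}

# --- db4 discrete wavelet transform (periodic), used for detail
# soft-thresholding. Daubechies-4 scaling coefficients.
db4_lo <- c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
            0.0328830116668852, -0.0105974017850690)

periodic_conv_down <- function(x, h) {
  n <- length(x); L <- length(h)
  idx <- outer(seq(1, n, by = 2), 0:(L - 1), `+`)
  idx <- ((idx - 1) %% n) + 1
  matrix(x[idx], ncol = L) %*% h
}

periodic_up_conv <- function(c_half, h, n) {
  up <- numeric(n)
  up[seq(1, n, by = 2)] <- c_half
  L <- length(h)
  out <- numeric(n)
  for (k in 0:(L - 1)) {
    out <- out + h[k + 1] * up[((seq_len(n) - 1 - k) %% n) + 1]
  }
  out
}

dwt_denoise <- function(x, fs, cutoff, level = NULL) {
  n0 <- length(x)
  lo <- db4_lo
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  # levels whose detail band [fs/2^(j+1), fs/2^j] lies above the cutoff
  if (is.null(level)) level <- max(1L, floor(log2(fs / cutoff)) - 1L)
  n <- 2^ceiling(log2(n0))
  pad <- n - n0
  xx <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  approx_x <- xx
  details <- vector("list", level)
  for (j in seq_len(level)) {
    details[[j]] <- as.numeric(periodic_conv_down(approx_x, hi))
    approx_x <- as.numeric(periodic_conv_down(approx_x, lo))
  }
  # level-wise universal soft threshold (robust to band-limited noise such
  # as a mains tone that concentrates in one detail level)
  soft <- function(d) {
    thr <- stats::mad(d, center = 0) * sqrt(2 * log(n))
    sign(d) * pmax(abs(d) - thr, 0)
  }
  rec <- approx_x
  for (j in rev(seq_len(level))) {
    m <- 2L * length(rec)
    rec <- periodic_up_conv(rec, lo, m) + periodic_up_conv(soft(details[[j]]), hi, m)
  }
  rec[seq_len(n0)]
}

#' Low-pass filter a PPG signal
#'
#' Applies the method described by a [filter_spec()]. Output length always
#' equals input length; the Butterworth and FIR paths are zero-phase
#' (forward-backward application with odd-reflection padding).
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered samples, same length as `x`.
#' @export
filter_signal <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= fs / 2)
    stop("cutoff (", spec$cutoff, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz")
  switch(spec$method,
    butterworth = {
      bw <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "low")
      filtfilt_reflect(bw$b, bw$a, x)
    },
    fir = {
      b <- signal::fir1(spec$taps, spec$cutoff / (fs / 2), type = "low")
      filtfilt_reflect(as.numeric(b), 1, x)
    },
    moving_average = {
      w <- if (is.null(spec$window)) max(1L, round(fs / spec$cutoff)) else spec$window
      moving_average_centered(x, w)
    },
    dwt = dwt_denoise(x, fs, spec$cutoff, spec$level)
  )
}

#' Preprocess a PPG record (normalize, then filter)
#'
#' Applies min-max normalization followed by the configured low-pass filter,
#' the order used throughout the pipeline. The filter spec is stored on the
#' returned record as provenance.
#'
#' @param record A [ppg_record()] (typically one that passed
#'   [screen_cohort()]).
#' @param spec A [filter_spec()].
#' @return A preprocessed [ppg_record()].
#' @export
preprocess_record <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "ppg_record"))
  y <- filter_signal(normalize_ppg(record$samples), record$fs, spec)
  ppg_record(y, record$fs, record$subject_id, record$segment_id,
             preprocessed = TRUE, filter = spec)
}
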