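#' Construct a single PPG cycle
#'
#' One beat, onset-to-onset, cut from a parent record. `tpi` (the pulse
#' interval, feature 4) is the cycle length over the sampling rate.
#'
#' @param samples Cycle samples (onset sample first).
#' @param onset_index 1-based index of the onset in the parent record.
#' @param fs Sampling rate in Hz.
#' @return An object of class `ppg_cycle`.
#' @export
ppg_cycle <- function(samples, onset_index, fs) {
  if (length(samples) < 5L) stop("cycle too short")
  structure(list(samples = as.numeric(samples),
                 onset_index = as.integer(onset_index),
                 fs = fs, tpi = length(samples) / fs),
            class = "ppg_cycle")
}

#' @export
print.ppg_cycle <- function(x, ...) {
  cat(sprintf("<ppg_cycle> %d samples @ %g Hz, tpi = %.3f s (onset index %d)\n",
              length(x$samples), x$fs, x$tpi, x$onset_index))
  invisible(x)
}

# Local maxima with topographic prominence. Returns indices sorted by
# position; 'prominence' per peak is the drop to the highest of the two
# key saddles (standard definition, edges treated as walls).
find_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # treat flat tops: use sign of first nonzero difference on each side
  s <- sign(d)
  s_nz <- s
  for (i in seq(length(s_nz) - 1L, 1L)) if (s_nz[i] == 0) s_nz[i] <- s_nz[i + 1L]
  cand <- which(diff(s_nz) < 0) + 1L
  cand <- cand[cand > 1L & cand < n]
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(p) {
    # walk left until a higher point; key saddle = min along the way
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > x[p])
    lmin <- if (length(higher_l)) min(x[(max(higher_l) + 1L):(p - 1L)])
            else min(left)
    right <- x[(p + 1L):n]
    higher_r <- which(right > x[p])
    rmin <- if (length(higher_r)) min(x[(p + 1L):(p + min(higher_r) - 1L)])
            else min(right)
    x[p] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  prom <- prom[prom >= min_prominence]
  if (length(keep) <= 1L || min_distance <= 1L) return(keep)
  # enforce minimum separation, keeping the more prominent peak
  ord <- order(-prom)
  taken <- logical(length(keep))
  for (i in ord) {
    if (any(taken & abs(keep - keep[i]) < min_distance)) next
    taken[i] <- TRUE
  }
  sort(keep[taken])
}

# Pulse-period estimate (in samples) from the autocorrelation peak within
# the physiological range [60/180, 60/40] s; NA when no peak stands out.
estimate_period <- function(x, fs) {
  lo <- as.integer(round(60 / 180 * fs))
  hi <- min(as.integer(round(60 / 40 * fs)), length(x) - 2L)
  if (hi <= lo + 2L) return(NA_integer_)
  ac <- stats::acf(x, lag.max = hi, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  seg <- ac[(lo + 1L):(hi + 1L)]  # ac[k+1] is lag k
  pk <- find_peaks(seg, min_prominence = 0)
  if (!length(pk)) return(NA_integer_)
  lo + pk[which.max(seg[pk])] - 1L
}

#' Detect systolic peaks in a preprocessed record
#'
#' Finds local maxima with prominence at least `min_prominence` (on the
#' \[0, 1\]-normalized scale). Diastolic waves can carry non-trivial
#' prominence too, so the pulse period is estimated from the record's
#' autocorrelation and peaks closer together than 55% of it (never less
#' than `min_separation_s`, default 60/180 s — a 180 beats/min ceiling) are
#' culled, keeping the more prominent peak of each conflicting pair.
#'
#' @param record A preprocessed [ppg_record()].
#' @param min_prominence Minimum peak prominence (default 0.1).
#' @param min_separation_s Hard minimum peak separation in seconds.
#' @return Integer vector of peak indices, ascending; empty (with a warning)
#'   when no usable peak exists.
#' @export
detect_systolic_peaks <- function(record, min_prominence = 0.1,
                                  min_separation_s = 60 / 180) {
  stopifnot(inherits(record, "ppg_record"))
  x <- record$samples
  if (stats::sd(x) == 0) {
    warning("flat record: no systolic peaks")
    return(integer(0))
  }
  sep <- as.integer(round(min_separation_s * record$fs))
  period <- estimate_period(x, record$fs)
  if (!is.na(period)) sep <- max(sep, as.integer(round(0.55 * period)))
  peaks <- find_peaks(x, min_prominence, sep)
  if (length(peaks) == 0L)
    warning("no systolic peak found; record unusable")
  peaks
}

#' Segment a record into single-period PPG cycles
#'
#' Cycle onsets are the minima between consecutive systolic peaks; a leading
#' (trailing) onset is additionally searched within one estimated pulse
#' interval before the first (after the last) peak so that records holding
#' only two full beats still yield a complete cycle. Each returned cycle
#' spans onset to next onset (first sample inclusive, next onset exclusive),
#' contains exactly one detected peak, and its duration is constrained to
#' the physiological pulse-interval range \[60/180, 60/40\] s; partial beats
#' at the edges are dropped.
#'
#' @param record A preprocessed [ppg_record()].
#' @param peaks Peak indices from [detect_systolic_peaks()].
#' @return List of [ppg_cycle()] objects in temporal order (possibly empty,
#'   with a warning).
#' @export
segment_cycles <- function(record, peaks) {
  stopifnot(inherits(record, "ppg_record"))
  x <- record$samples
  n <- length(x)
  fs <- record$fs
  if (length(peaks) < 1L) {
    warning("no peaks: no cycles")
    return(list())
  }
  ipi <- if (length(peaks) >= 2L) stats::median(diff(peaks)) else round(0.8 * fs)
  onsets <- integer(0)
  lead_lo <- max(1L, peaks[1L] - as.integer(round(1.05 * ipi)))
  if (peaks[1L] - lead_lo >= 3L) {
    w <- lead_lo:(peaks[1L] - 1L)
    onsets <- c(onsets, w[which.min(x[w])])
  }
  if (length(peaks) >= 2L) {
    for (i in seq_len(length(peaks) - 1L)) {
      w <- (peaks[i] + 1L):(peaks[i + 1L] - 1L)
      onsets <- c(onsets, w[which.min(x[w])])
    }
  }
  # trailing onset only when a full period of data follows the last peak,
  # so truncated final beats never form a cycle
  if (peaks[length(peaks)] + as.integer(round(0.9 * ipi)) <= n) {
    tail_hi <- min(n, peaks[length(peaks)] + as.integer(round(1.05 * ipi)))
    w <- (peaks[length(peaks)] + 1L):tail_hi
    cand <- w[which.min(x[w])]
    if (cand < tail_hi) onsets <- c(onsets, cand)  # reject boundary minima
  }
  onsets <- sort(unique(onsets))
  if (length(onsets) < 2L) {
    warning("fewer than two onsets: no complete cycle")
    return(list())
  }
  cycles <- list()
  for (i in seq_len(length(onsets) - 1L)) {
    o1 <- onsets[i]; o2 <- onsets[i + 1L]
    inside <- peaks[peaks > o1 & peaks < o2]
    len <- o2 - o1
    if (length(inside) != 1L) next
    if (len / fs < 60 / 180 || len / fs > 60 / 40) next
    if (length(peaks) >= 2L && (len < 0.7 * ipi || len > 1.3 * ipi)) next
    cycles[[length(cycles) + 1L]] <- ppg_cycle(x[o1:(o2 - 1L)], o1, fs)
  }
  if (length(cycles) == 0L) warning("no complete physiological cycle found")
  cycles
}

#' Select the best PPG cycle
#'
#' The best cycle is the one with the largest systolic amplitude, measured
#' as the cycle maximum minus the cycle-onset value (robust to residual
#' baseline drift). Ties are broken by the earliest onset.
#'
#' @param cycles List of [ppg_cycle()] from [segment_cycles()].
#' @return The selected [ppg_cycle()].
#' @export
select_best_cycle <- function(cycles) {
  if (length(cycles) == 0L) stop("no cycles: record unusable")
  amp <- vapply(cycles, function(cy) max(cy$samples) - cy$samples[1L], numeric(1))
  cycles[[which.max(amp)]]  # which.max returns the first (earliest) maximum
}
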