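#' Construct a PPG record
#'
#' A `ppg_record` holds one fingertip PPG segment: a numeric sample vector,
#' its sampling rate and the subject/segment identifiers linking it to the
#' subject table. Records in the target acquisition layout are 2.1 s long at
#' 1 kHz (2100 samples), but any length of at least two samples is accepted.
#'
#' @param samples Numeric vector of amplitude values (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier (coerced to character).
#' @param segment_id Segment identifier within the subject (default 1).
#' @param preprocessed Logical; has the record been normalized and filtered?
#' @param filter The [filter_spec()] applied, if any (provenance).
#'
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs, subject_id = "S1", segment_id = 1L,
                       preprocessed = FALSE, filter = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a PPG record needs at least 2 samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("PPG record contains non-finite samples (first at row ",
         which(!is.finite(samples))[1L], ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive sampling rate in Hz")
  structure(
    list(samples = samples, fs = fs,
         subject_id = as.character(subject_id),
         segment_id = as.integer(segment_id),
         preprocessed = isTRUE(preprocessed), filter = filter),
    class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> subject %s segment %d: %d samples @ %g Hz (%.3f s)%s\n",
              x$subject_id, x$segment_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (x$preprocessed) ", preprocessed" else ""))
  invisible(x)
}

#' Read one PPG segment from a plain-text file
#'
#' Files hold one numeric sample per row, the layout used by the PPG-BP
#' fingertip database (`<subject>_<segment>.txt`). No resampling is done;
#' samples are returned in file order.
#'
#' @param path Path to the text file.
#' @param fs Sampling rate of the stored samples in Hz (default 1000).
#' @param subject_id,segment_id Identifiers; if missing they are parsed from
#'   a `<subject>_<segment>` file name when possible.
#'
#' @return A [ppg_record()].
#' @export
read_ppg_record <- function(path, fs = 1000, subject_id = NULL, segment_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error in '", path, "': file is empty")
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("format error in '", path, "': non-numeric value at row ", bad,
         " ('", lines[bad], "')")
  }
  stem <- sub("\\.[^.]*$", "", basename(path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1L]]
  if (is.null(subject_id))
    subject_id <- if (length(parts) >= 2L) paste(parts[-length(parts)], collapse = "_") else stem
  if (is.null(segment_id)) {
    seg <- suppressWarnings(as.integer(parts[length(parts)]))
    segment_id <- if (length(parts) >= 2L && !is.na(seg)) seg else 1L
  }
  ppg_record(vals, fs = fs, subject_id = subject_id, segment_id = segment_id)
}

#' Read a subject table
#'
#' Expects a CSV with header columns `subject_id, sex, age, height, weight,
#' sbp, dbp` (extra columns are kept). Mean arterial pressure is derived per
#' MAP = (2 DBP + SBP) / 3 and appended as `map`.
#'
#' @param path CSV path.
#' @return A data.frame with one row per subject, including `map`.
#' @export
read_subject_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "height", "weight", "sbp", "dbp")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("subject table is missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$sbp <= tab$dbp))
    stop("subject table has SBP <= DBP for subject(s): ",
         paste(tab$subject_id[tab$sbp <= tab$dbp], collapse = ", "))
  if (any(tab$age <= 0)) stop("subject table has non-positive age")
  tab$subject_id <- as.character(tab$subject_id)
  tab$map <- compute_map(tab$sbp, tab$dbp)
  tab
}

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' MAP = (2 DBP + SBP) / 3, the standard weighting reflecting the heart
#' spending roughly two thirds of the cardiac cycle in diastole.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg (vectorized).
#' @return MAP in mmHg.
#' @export
compute_map <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)))
    stop("non-finite blood pressure value")
  if (any(dbp <= 0)) stop("DBP must be positive")
  if (any(sbp <= dbp)) stop("SBP must exceed DBP")
  (2 * dbp + sbp) / 3
}

#' Skewness signal-quality index
#'
#' Scores a PPG segment by the skewness of its amplitude distribution (the
#' population third standardized moment). Good PPG pulses spend most of the
#' cycle near the diastolic baseline with a brief systolic upstroke, so their
#' amplitude histogram is right-skewed; flat, clipped or artifact-dominated
#' segments are not. A segment is fit when the index is at or above
#' `threshold`.
#'
#' @param record A [ppg_record()].
#' @param threshold Minimum skewness considered fit. The default 0 accepts
#'   any right-skewed segment; see the methods vignette for calibration
#'   notes.
#' @return A list of class `quality_verdict` with `sqi`, `fit`, `threshold`
#'   and `reason` ("ok", "below-threshold" or "zero-variance").
#' @export
skewness_sqi <- function(record, threshold = 0) {
  stopifnot(inherits(record, "ppg_record"))
  x <- record$samples
  if (stats::sd(x) == 0) {
    v <- list(sqi = NA_real_, fit = FALSE, threshold = threshold,
              reason = "zero-variance")
    return(structure(v, class = "quality_verdict"))
  }
  sk <- e1071::skewness(x, type = 1)  # population form m3 / m2^(3/2)
  structure(list(sqi = sk, fit = sk >= threshold, threshold = threshold,
                 reason = if (sk >= threshold) "ok" else "below-threshold"),
            class = "quality_verdict")
}

#' Screen a cohort of records by signal quality
#'
#' Applies [skewness_sqi()] to every record and partitions the input into
#' kept records and a rejection log.
#'
#' @param records A list of [ppg_record()] objects.
#' @param threshold SQI threshold passed to [skewness_sqi()].
#' @return A list with `kept` (records with `fit = TRUE`) and `rejected`, a
#'   data.frame logging `subject_id`, `segment_id`, `sqi` and `reason` for
#'   every rejected record. An empty kept set is legal.
#' @export
screen_cohort <- function(records, threshold = 0) {
  if (length(records) == 0L) stop("'records' is empty")
  verdicts <- lapply(records, skewness_sqi, threshold = threshold)
  fit <- vapply(verdicts, function(v) v$fit, logical(1))
  rejected <- data.frame(
    subject_id = vapply(records[!fit], function(r) r$subject_id, character(1)),
    segment_id = vapply(records[!fit], function(r) r$segment_id, integer(1)),
    sqi = vapply(verdicts[!fit], function(v) as.numeric(v$sqi), numeric(1)),
    reason = vapply(verdicts[!fit], function(v) v$reason, character(1)),
    stringsAsFactors = FALSE)
  list(kept = records[fit], rejected = rejected, threshold = threshold)
}
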