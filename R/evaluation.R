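#' Regression performance indices for BP estimation
#'
#' Computes the six standard indices on paired actual/estimated pressures,
#' with the error defined as actual minus estimated throughout:
#' R^2 = 1 - SSE/SST, MAE, MSE, RMSE = sqrt(MSE), ME (mean error) and STD,
#' the error standard deviation about ME with the n - 1 denominator.
#'
#' @param actual,estimated Numeric vectors of equal length (>= 2), mmHg.
#' @return A list of class `eval_metrics`: `n`, `r2`, `mae`, `mse`, `rmse`,
#'   `me`, `std`, `bp_bar` (mean of `actual`). `r2` is `NA` (with a message
#'   in `r2_note`) when `actual` is constant.
#' @export
regression_metrics <- function(actual, estimated) {
  if (length(actual) != length(estimated))
    stop("'actual' and 'estimated' must have the same length")
  if (length(actual) < 2L) stop("need at least 2 pairs")
  if (!all(is.finite(actual)) || !all(is.finite(estimated)))
    stop("non-finite values")
  err <- actual - estimated
  n <- length(err)
  sst <- sum((actual - mean(actual))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(err^2) / sst
  structure(list(
    n = n,
    r2 = r2,
    r2_note = if (sst == 0) "R^2 undefined: constant actual values" else NULL,
    mae = mean(abs(err)),
    mse = mean(err^2),
    rmse = sqrt(mean(err^2)),
    me = mean(err),
    std = sqrt(sum((err - mean(err))^2) / (n - 1)),
    bp_bar = mean(actual)), class = "eval_metrics")
}

#' AAMI compliance check
#'
#' A device passes the AAMI criterion when the absolute mean error is at
#' most `max_me` mmHg, the error standard deviation at most `max_std` mmHg,
#' and at least `min_subjects` subjects contributed. Boundary values pass
#' (the limits are inclusive).
#'
#' @param me Mean error (mmHg), actual minus estimated.
#' @param std Error standard deviation (mmHg, n - 1 denominator).
#' @param n_subjects Number of distinct subjects.
#' @param max_me,max_std,min_subjects The AAMI limits (5, 8, 85).
#' @return A list of class `aami_verdict`: `pass` plus the failed criteria
#'   in `reasons` (empty when passing).
#' @export
aami_check <- function(me, std, n_subjects,
                       max_me = 5, max_std = 8, min_subjects = 85) {
  reasons <- character(0)
  if (abs(me) > max_me)
    reasons <- c(reasons, sprintf("|ME| = %.3f exceeds %g mmHg", abs(me), max_me))
  if (std > max_std)
    reasons <- c(reasons, sprintf("STD = %.3f exceeds %g mmHg", std, max_std))
  if (n_subjects < min_subjects)
    reasons <- c(reasons, sprintf("%d subjects below the required %d",
                                  n_subjects, min_subjects))
  structure(list(pass = length(reasons) == 0L, reasons = reasons,
                 me = me, std = std, n_subjects = n_subjects,
                 limits = c(max_me = max_me, max_std = max_std,
                            min_subjects = min_subjects)),
            class = "aami_verdict")
}

#' BHS grading of absolute errors
#'
#' Grades the estimator by the cumulative percentage of absolute errors
#' within 5, 10 and 15 mmHg: Grade A requires (60, 85, 95)%, B (50, 75,
#' 90)%, C (40, 65, 85)%; anything below C is graded D. The awarded grade is
#' the best one whose three thresholds are all met.
#'
#' @param actual,estimated Paired pressures (mmHg).
#' @param thresholds Error thresholds in mmHg (default 5, 10, 15).
#' @param grade_table Named list of required cumulative percentages per
#'   grade, in decreasing stringency.
#' @return List of class `bhs_grade`: `cumulative` (named %, one per
#'   threshold) and `grade` ("A", "B", "C" or "D").
#' @export
bhs_grade <- function(actual, estimated, thresholds = c(5, 10, 15),
                      grade_table = list(A = c(60, 85, 95),
                                         B = c(50, 75, 90),
                                         C = c(40, 65, 85))) {
  if (length(actual) != length(estimated))
    stop("'actual' and 'estimated' must have the same length")
  if (length(actual) < 1L) stop("need at least 1 pair")
  abs_err <- abs(actual - estimated)
  cum <- vapply(thresholds, function(th) 100 * mean(abs_err <= th), numeric(1))
  names(cum) <- paste0("within_", thresholds, "mmHg")
  grade <- "D"
  for (g in names(grade_table)) {
    if (all(cum >= grade_table[[g]])) { grade <- g; break }
  }
  structure(list(cumulative = cum, grade = grade, thresholds = thresholds,
                 grade_table = grade_table),
            class = "bhs_grade")
}

#' Bland-Altman agreement analysis
#'
#' Differences follow the package-wide sign convention actual minus
#' estimated; the limits of agreement are md +/- 1.96 sd, where md is the
#' mean difference and sd its n - 1 standard deviation.
#'
#' @param actual,estimated Paired pressures (mmHg).
#' @return List of class `bland_altman`: `md`, `sd`, `lower`, `upper`,
#'   `fraction_inside` (share of points within the limits) and the
#'   per-pair `means`/`differences` for plotting.
#' @export
bland_altman <- function(actual, estimated) {
  if (length(actual) != length(estimated))
    stop("'actual' and 'estimated' must have the same length")
  if (length(actual) < 2L) stop("need at least 2 pairs")
  d <- actual - estimated
  md <- mean(d)
  sd_d <- stats::sd(d)
  lower <- md - 1.96 * sd_d
  upper <- md + 1.96 * sd_d
  structure(list(md = md, sd = sd_d, lower = lower, upper = upper,
                 fraction_inside = mean(d >= lower & d <= upper),
                 means = (actual + estimated) / 2, differences = d),
            class = "bland_altman")
}

#' Full evaluation report for one model/target
#'
#' Bundles [regression_metrics()], [aami_check()], [bhs_grade()] and
#' [bland_altman()] for one (actual, estimated) pairing.
#'
#' @param actual,estimated Paired pressures (mmHg).
#' @param n_subjects Number of distinct subjects behind the pairs (defaults
#'   to the number of pairs).
#' @param target Label ("SBP", "MAP", "DBP").
#' @return A list of class `eval_report` with `target`, `metrics`, `aami`,
#'   `bhs`, `bland_altman`.
#' @export
eval_report <- function(actual, estimated, n_subjects = length(actual),
                        target = "BP") {
  m <- regression_metrics(actual, estimated)
  structure(list(target = target, metrics = m,
                 aami = aami_check(m$me, m$std, n_subjects),
                 bhs = bhs_grade(actual, estimated),
                 bland_altman = bland_altman(actual, estimated)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<eval_report> %s (n = %d)\n", x$target, m$n))
  cat(sprintf("  R2 %.3f | MAE %.2f | RMSE %.2f | MSE %.2f | ME %.3f | STD %.3f mmHg\n",
              m$r2, m$mae, m$rmse, m$mse, m$me, m$std))
  cat(sprintf("  AAMI: %s%s\n", if (x$aami$pass) "pass" else "FAIL",
              if (length(x$aami$reasons))
                paste0(" (", paste(x$aami$reasons, collapse = "; "), ")") else ""))
  cat(sprintf("  BHS: grade %s (%.0f%% / %.0f%% / %.0f%% within 5/10/15 mmHg)\n",
              x$bhs$grade, x$bhs$cumulative[1], x$bhs$cumulative[2],
              x$bhs$cumulative[3]))
  cat(sprintf("  Bland-Altman: md %.3f, limits [%.3f, %.3f] mmHg\n",
              x$bland_altman$md, x$bland_altman$lower, x$bland_altman$upper))
  invisible(x)
}

#' Convert an evaluation report to a one-row data.frame
#' @param report An [eval_report()].
#' @return One-row data.frame of the headline numbers.
#' @export
report_row <- function(report) {
  m <- report$metrics
  data.frame(target = report$target, n = m$n, r2 = m$r2, mae = m$mae,
             rmse = m$rmse, mse = m$mse, me = m$me, std = m$std,
             aami_pass = report$aami$pass, bhs_grade = report$bhs$grade,
             within5 = report$bhs$cumulative[1L],
             within10 = report$bhs$cumulative[2L],
             within15 = report$bhs$cumulative[3L],
             ba_lower = report$bland_altman$lower,
             ba_upper = report$bland_altman$upper,
             stringsAsFactors = FALSE, row.names = NULL)
}
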