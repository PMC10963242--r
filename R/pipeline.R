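#' Pipeline configuration
#'
#' Bundles every stage's settings with defaults reproducing the reference
#' configuration: skewness SQI screening at threshold 0, 7th-order
#' Butterworth low-pass at 12 Hz, ReliefF selection (15/16/15 features for
#' SBP/MAP/DBP), SVR with C = 100 and epsilon = 0.1, subject-grouped 80/20
#' split with 10-fold cross-validation.
#'
#' @param source `"synthetic"` or a directory holding `<subject>_<segment>.txt`
#'   records plus `subjects.csv`.
#' @param n_subjects,segments_per_subject Cohort size when `source` is
#'   synthetic.
#' @param noise [noise_config()] for the synthetic source.
#' @param sqi_threshold Skewness SQI threshold.
#' @param filter A [filter_spec()].
#' @param selection `"relieff"`, `"cfs"` or `"none"` (all 48 features).
#' @param subset_sizes Named vector (sbp, map, dbp) of subset sizes;
#'   defaults per [default_subset_sizes()].
#' @param model A [model_spec()].
#' @param seed Pipeline seed; fans out deterministically to cohort
#'   generation, splitting and model fitting.
#' @param output_dir Optional directory; when given, every intermediate
#'   table is persisted as CSV/JSON together with a manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(source = "synthetic", n_subjects = 60,
                            segments_per_subject = 3,
                            noise = noise_config(),
                            sqi_threshold = 0,
                            filter = filter_spec(),
                            selection = c("relieff", "cfs", "none"),
                            subset_sizes = NULL,
                            model = model_spec("svr"),
                            seed = 1L, output_dir = NULL) {
  selection <- match.arg(selection)
  if (is.null(subset_sizes) && selection != "none")
    subset_sizes <- default_subset_sizes(selection)
  structure(list(source = source, n_subjects = n_subjects,
                 segments_per_subject = segments_per_subject, noise = noise,
                 sqi_threshold = sqi_threshold, filter = filter,
                 selection = selection, subset_sizes = subset_sizes,
                 model = model, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full BP-estimation pipeline
#'
#' Stages, in order: load or synthesize records; skewness-SQI screening;
#' normalization and filtering; beat detection and best-cycle selection;
#' 48-slot feature extraction; per-target feature selection; subject-grouped
#' split, cross-validated training; held-out-test evaluation against the
#' AAMI and BHS criteria. One [eval_report()] is produced per target (SBP,
#' MAP, DBP).
#'
#' @param config A [pipeline_config()].
#' @return A list with `features` (extraction data.frame), `screening`,
#'   `selection` (per target), `models`, `reports`, `predictions`,
#'   `summary` (one row per target) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(config$source, "synthetic")) {
    cohort <- generate_cohort(config$n_subjects,
                              config$segments_per_subject,
                              noise = config$noise, seed = config$seed)
    records <- cohort$records
    subjects <- cohort$subjects
  } else {
    files <- list.files(config$source, pattern = "\\.txt$", full.names = TRUE)
    if (!length(files)) stop("no .txt records found in ", config$source)
    records <- lapply(files, read_ppg_record)
    subjects <- read_subject_table(file.path(config$source, "subjects.csv"))
  }
  screened <- screen_cohort(records, config$sqi_threshold)
  if (!length(screened$kept)) stop("screening rejected every record")
  feat <- extract_feature_matrix(screened$kept, subjects, spec = config$filter)
  targets <- c(sbp = "SBP", map = "MAP", dbp = "DBP")
  split <- make_split(feat$subject_id, seed = config$seed + 1L)
  fnames <- as.character(ppg_feature_names())
  tr_rows <- feat$subject_id %in% split$train
  selections <- list(); models <- list(); reports <- list(); preds <- list()
  for (tg in names(targets)) {
    y <- feat[[tg]]
    sel <- switch(config$selection,
      none = list(selected = fnames, method = "none", target = targets[[tg]]),
      cfs = cfs_select(feat[tr_rows, fnames], y[tr_rows],
                       target_size = config$subset_sizes[[tg]],
                       target = targets[[tg]]),
      relieff = {
        w <- relieff_weights(feat[tr_rows, fnames], y[tr_rows])
        relieff_select(w, config$subset_sizes[[tg]], target = targets[[tg]])
      })
    spec <- config$model
    spec$seed <- config$seed + 2L
    model <- train_bp_model(feat, y, feat$subject_id, spec, split,
                            feature_names = sel$selected,
                            target = targets[[tg]])
    te_rows <- feat$subject_id %in% split$test
    est <- predict(model, feat[te_rows, , drop = FALSE])
    reports[[tg]] <- eval_report(y[te_rows], est,
                                 n_subjects = length(split$test),
                                 target = targets[[tg]])
    preds[[tg]] <- data.frame(subject_id = feat$subject_id[te_rows],
                              segment_id = feat$segment_id[te_rows],
                              actual = y[te_rows], estimated = est)
    selections[[tg]] <- sel
    models[[tg]] <- model
  }
  summary_tab <- do.call(rbind, lapply(reports, report_row))
  rownames(summary_tab) <- NULL
  out <- list(features = feat, screening = screened$rejected,
              selection = selections, models = models, reports = reports,
              predictions = preds, summary = summary_tab, split = split,
              manifest = list(seed = config$seed,
                              selection = config$selection,
                              model_family = config$model$family,
                              filter = config$filter$method,
                              n_records_in = length(records),
                              n_records_kept = length(screened$kept),
                              n_rows = nrow(feat),
                              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  if (!is.null(config$output_dir)) persist_pipeline(out, config)
  out
}

persist_pipeline <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  wp <- function(df, name) {
    p <- file.path(config$output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  files <- c(
    wp(result$features, "features.csv"),
    wp(result$screening, "rejections.csv"),
    wp(result$summary, "summary.csv"))
  for (tg in names(result$selection)) {
    sel <- result$selection[[tg]]
    if (!is.null(sel$ranking))
      files <- c(files, wp(sel$ranking, sprintf("selection_%s.csv", tg)))
    files <- c(files, wp(result$predictions[[tg]],
                         sprintf("predictions_%s.csv", tg)))
  }
  mpath <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(c(result$manifest, list(files = basename(files))),
                       mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, mpath))
}
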