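#' Regression model specification
#'
#' Captures one of the four nonlinear regression families with its default
#' hyperparameters: SVR (RBF kernel, C = 100, epsilon = 0.1), random forest
#' (150 trees, max depth 13), decision tree (min samples per leaf 17, max
#' depth 12, min samples to split 5) and k-nearest-neighbour regression
#' (K = 51, Euclidean distance; the kd-tree `leaf_size` of 45 is recorded
#' but has no effect on brute-force neighbour search). Defaults can be
#' overridden through `params`, and `grid` (a named list of value vectors)
#' requests a grid search scored by subject-grouped cross-validated MAE.
#'
#' @param family `"svr"`, `"rfr"`, `"dtr"` or `"knr"`.
#' @param params Named list overriding the family defaults.
#' @param grid Optional named list of hyperparameter vectors to search.
#' @param seed Integer seed for the stochastic families.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("svr", "rfr", "dtr", "knr"),
                       params = list(), grid = NULL, seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    svr = list(cost = 100, epsilon = 0.1, gamma = NULL),
    rfr = list(num_trees = 150L, max_depth = 13L),
    dtr = list(min_samples_leaf = 17L, max_depth = 12L, min_samples_split = 5L),
    knr = list(k = 51L, leaf_size = 45L))
  bad <- setdiff(names(params), names(defaults))
  if (length(bad))
    stop("unknown parameter(s) for ", family, ": ", paste(bad, collapse = ", "))
  defaults[names(params)] <- params
  num <- unlist(Filter(is.numeric, defaults))
  if (any(num <= 0)) stop("hyperparameters must be positive")
  if (!is.null(grid)) {
    bad <- setdiff(names(grid), names(defaults))
    if (length(bad))
      stop("unknown grid parameter(s): ", paste(bad, collapse = ", "))
  }
  structure(list(family = family, params = defaults, grid = grid,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Subject-grouped train/test split with cross-validation folds
#'
#' Splits subjects (never individual segments) into a training and a test
#' set, then partitions the training subjects into `n_folds`
#' cross-validation folds. All segments of one subject always land on the
#' same side of every split, preventing identity leakage.
#'
#' @param subject_ids Character vector of subject IDs (duplicates allowed;
#'   the unique set is split).
#' @param seed Integer seed; the same seed reproduces the plan.
#' @param test_fraction Fraction of subjects held out (default 0.2).
#' @param n_folds Number of CV folds over the training subjects (default 10).
#' @return A list of class `split_plan`: `train`, `test` (subject IDs) and
#'   `folds` (named integer fold assignment for the training subjects).
#' @export
make_split <- function(subject_ids, seed = 1L, test_fraction = 0.2,
                       n_folds = 10L) {
  ids <- unique(as.character(subject_ids))
  n <- length(ids)
  if (n < 12L) stop("need at least 12 subjects to split")
  set.seed(seed)
  shuffled <- sample(ids)
  n_test <- max(1L, round(test_fraction * n))
  test <- sort(shuffled[seq_len(n_test)])
  train <- sort(shuffled[-seq_len(n_test)])
  if (length(train) < n_folds)
    stop("fewer training subjects (", length(train), ") than folds (", n_folds, ")")
  folds <- rep_len(seq_len(n_folds), length(train))[sample.int(length(train))]
  names(folds) <- train
  structure(list(train = train, test = test, folds = folds,
                 n_folds = n_folds, seed = as.integer(seed)),
            class = "split_plan")
}

# Fit one family on an already-standardized matrix. A constant response is
# degenerate for every family (SVR in particular has no support vectors
# then), so it short-circuits to a constant predictor.
fit_family <- function(family, Xs, y, params, seed) {
  if (stats::sd(y) == 0)
    return(structure(list(value = y[1L]), class = "ppgbp_constant"))
  set.seed(seed)
  switch(family,
    svr = e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
                     cost = params$cost, epsilon = params$epsilon,
                     gamma = if (is.null(params$gamma)) 1 / ncol(Xs) else params$gamma,
                     scale = FALSE),
    rfr = ranger::ranger(y = y, x = as.data.frame(Xs),
                         num.trees = params$num_trees,
                         max.depth = params$max_depth, seed = seed),
    dtr = rpart::rpart(y ~ ., data = data.frame(as.data.frame(Xs), y = y),
                       method = "anova",
                       control = rpart::rpart.control(
                         minbucket = params$min_samples_leaf,
                         maxdepth = params$max_depth,
                         minsplit = params$min_samples_split, cp = 0)),
    knr = caret::knnreg(as.data.frame(Xs), y, k = params$k))
}

predict_family <- function(family, fit, Xs) {
  if (inherits(fit, "ppgbp_constant"))
    return(rep(fit$value, nrow(Xs)))
  switch(family,
    svr = as.numeric(stats::predict(fit, Xs)),
    rfr = as.numeric(stats::predict(fit, data = as.data.frame(Xs))$predictions),
    dtr = as.numeric(stats::predict(fit, newdata = as.data.frame(Xs))),
    knr = as.numeric(stats::predict(fit, as.data.frame(Xs))))
}

#' Train a blood-pressure regressor with grouped cross-validation
#'
#' Standardizes features (center/scale fitted on the training rows of each
#' fold only, so validation data never leaks into the scaling), runs
#' 10-fold subject-grouped cross-validation for every hyperparameter
#' combination in the spec's grid (or just the defaults), picks the
#' combination with the lowest mean CV MAE, and refits it on all training
#' rows. Test-set rows (subjects in `split$test`) are never touched.
#'
#' @param features Feature data.frame or matrix (instances in rows; only
#'   the columns in `feature_names` are used).
#' @param y Response vector (mmHg), aligned with the rows.
#' @param subject_ids Subject ID per row (for fold grouping).
#' @param spec A [model_spec()].
#' @param split A [split_plan()] over the subjects.
#' @param feature_names Columns to train on (default: all columns of
#'   `features`).
#' @param target Label stored on the model.
#' @return A `bp_model`: family, fitted object, scaling, feature names, the
#'   chosen `best_params`, and `cv` (data.frame fold/params/MAE/RMSE).
#' @export
train_bp_model <- function(features, y, subject_ids, spec, split,
                           feature_names = colnames(features), target = "BP") {
  stopifnot(inherits(spec, "model_spec"), inherits(split, "split_plan"))
  X <- as.matrix(as.data.frame(features)[, feature_names, drop = FALSE])
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop("non-finite feature value at row ", bad[1L], ", column '",
         feature_names[bad[2L]], "'")
  }
  subject_ids <- as.character(subject_ids)
  tr_rows <- which(subject_ids %in% split$train)
  if (!length(tr_rows)) stop("no training rows under this split")
  combos <- if (is.null(spec$grid)) list(spec$params) else {
    gr <- expand.grid(spec$grid, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(gr)), function(i) {
      p <- spec$params
      p[names(gr)] <- as.list(gr[i, , drop = FALSE])
      p
    })
  }
  clamp_warned <- FALSE
  clamp_k <- function(params, n_avail) {
    if (spec$family == "knr" && params$k >= n_avail) {
      if (!clamp_warned) {
        warning("K = ", params$k, " >= training size ", n_avail,
                "; clamping to ", n_avail - 1L)
        clamp_warned <<- TRUE
      }
      params$k <- n_avail - 1L
    }
    params
  }
  cv_rows <- list()
  mean_mae <- numeric(length(combos))
  for (ci in seq_along(combos)) {
    params <- combos[[ci]]
    maes <- rmses <- numeric(split$n_folds)
    for (f in seq_len(split$n_folds)) {
      val_subj <- names(split$folds)[split$folds == f]
      fit_rows <- tr_rows[!(subject_ids[tr_rows] %in% val_subj)]
      val_rows <- tr_rows[subject_ids[tr_rows] %in% val_subj]
      ctr <- colMeans(X[fit_rows, , drop = FALSE])
      scl <- apply(X[fit_rows, , drop = FALSE], 2, stats::sd)
      scl[scl == 0] <- 1
      Xf <- sweep(sweep(X[fit_rows, , drop = FALSE], 2, ctr), 2, scl, "/")
      Xv <- sweep(sweep(X[val_rows, , drop = FALSE], 2, ctr), 2, scl, "/")
      pf <- clamp_k(params, length(fit_rows))
      fit <- fit_family(spec$family, Xf, y[fit_rows], pf, spec$seed + f)
      pred <- predict_family(spec$family, fit, Xv)
      err <- y[val_rows] - pred
      maes[f] <- mean(abs(err)); rmses[f] <- sqrt(mean(err^2))
    }
    mean_mae[ci] <- mean(maes)
    cv_rows[[ci]] <- data.frame(
      combo = ci,
      params = paste(names(params), unlist(lapply(params, format)),
                     sep = "=", collapse = ","),
      fold = seq_len(split$n_folds), mae = maes, rmse = rmses,
      stringsAsFactors = FALSE)
  }
  best <- which.min(mean_mae)
  params <- clamp_k(combos[[best]], length(tr_rows))
  ctr <- colMeans(X[tr_rows, , drop = FALSE])
  scl <- apply(X[tr_rows, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X[tr_rows, , drop = FALSE], 2, ctr), 2, scl, "/")
  fit <- fit_family(spec$family, Xs, y[tr_rows], params, spec$seed)
  structure(list(family = spec$family, fit = fit, center = ctr, scale = scl,
                 features = feature_names, best_params = params,
                 cv = do.call(rbind, cv_rows), target = target,
                 seed = spec$seed, n_train = length(tr_rows)),
            class = "bp_model")
}

#' Predict blood pressure from a trained model
#'
#' @param object A `bp_model` from [train_bp_model()].
#' @param newdata Data.frame or matrix holding at least the feature columns
#'   the model was trained on.
#' @param ... Unused.
#' @return Numeric vector of BP estimates in mmHg, one per row.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  missing_cols <- setdiff(object$features, colnames(nd))
  if (length(missing_cols))
    stop("newdata lacks feature column(s): ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(nd[, object$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  predict_family(object$family, object$fit, Xs)
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> %s for %s: %d features, %d training rows, CV MAE %.2f mmHg\n",
              toupper(x$family), x$target, length(x$features), x$n_train,
              min(tapply(x$cv$mae, x$cv$combo, mean))))
  invisible(x)
}
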