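#' Correlation-based feature-subset fitness
#'
#' For every unordered instance pair (i, j) the response distance is
#' Ey = y_i - y_j, and the feature-space distance is the root mean square of
#' the per-feature differences over the candidate subset, signed by Ey
#' (negative when Ey < 0). The fitness R_cfs is the Pearson correlation
#' between the signed feature distances and the response distances across
#' all pairs; subsets whose feature geometry mirrors the response geometry
#' score near 1.
#'
#' Features are standardized (zero mean, unit variance) before the distance
#' so that seconds, ratios and spectral magnitudes weigh equally; constant
#' features contribute zero distance.
#'
#' @param X Numeric matrix or data.frame, instances in rows.
#' @param y Numeric response (one value per row of `X`).
#' @param subset Columns (names or indices) forming the candidate subset;
#'   default all columns.
#' @return R_cfs in \[-1, 1\]; 0 (with a warning) when either distance
#'   vector is constant.
#' @export
cfs_fitness <- function(X, y, subset = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 instances")
  if (length(y) != nrow(X)) stop("'y' length must match rows of 'X'")
  if (stats::sd(y) == 0) stop("'y' is constant")
  if (is.null(subset)) subset <- seq_len(ncol(X))
  Xs <- standardize_columns(X[, subset, drop = FALSE])
  pr <- pair_indices(nrow(X))
  Ey <- y[pr$i] - y[pr$j]
  D <- (Xs[pr$i, , drop = FALSE] - Xs[pr$j, , drop = FALSE])^2
  EX <- ifelse(Ey >= 0, 1, -1) * sqrt(rowMeans(D))
  if (stats::sd(EX) == 0 || stats::sd(Ey) == 0) {
    warning("constant pair-distance vector; R_cfs defined as 0")
    return(0)
  }
  stats::cor(EX, Ey)
}

# all unordered pairs i < j
pair_indices <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  list(i = i, j = j)
}

standardize_columns <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1  # constant features carry zero distance
  sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
}

#' Greedy forward correlation-based feature selection
#'
#' Starts from the empty set and repeatedly adds the feature whose addition
#' most increases [cfs_fitness()], stopping when no addition improves the
#' fitness by more than `tol` — or exactly at `target_size` features when
#' that is given. Ties are broken deterministically by the lower slot index.
#'
#' @param X Feature matrix (instances in rows, named columns).
#' @param y Response vector.
#' @param target_size Optional subset size to reach exactly.
#' @param tol Minimum fitness gain to continue when `target_size` is absent.
#' @param target Label stored on the result (e.g. "SBP").
#' @return A `selection_result`: list with `target`, `method`, `ranking`
#'   (data.frame rank/feature/score giving the greedy addition order and the
#'   fitness after each addition), `selected` and `size`.
#' @export
cfs_select <- function(X, y, target_size = NULL, tol = 1e-6, target = "BP") {
  X <- as.matrix(X)
  p <- ncol(X)
  if (!is.null(target_size) && (target_size < 1 || target_size > p))
    stop("'target_size' out of range")
  # precompute per-feature squared pair differences once
  Xs <- standardize_columns(X)
  pr <- pair_indices(nrow(X))
  Ey <- y[pr$i] - y[pr$j]
  sgn <- ifelse(Ey >= 0, 1, -1)
  D <- (Xs[pr$i, , drop = FALSE] - Xs[pr$j, , drop = FALSE])^2
  fitness_of <- function(cols) {
    EX <- sgn * sqrt(rowSums(D[, cols, drop = FALSE]) / length(cols))
    if (stats::sd(EX) == 0) return(0)
    stats::cor(EX, Ey)
  }
  selected <- integer(0)
  scores <- numeric(0)
  best_fit <- -Inf
  repeat {
    remaining <- setdiff(seq_len(p), selected)
    if (!length(remaining)) break
    cand_fit <- vapply(remaining, function(k) fitness_of(c(selected, k)),
                       numeric(1))
    k_best <- remaining[which.max(cand_fit)]  # first max = lowest slot index
    fit_best <- max(cand_fit)
    if (is.null(target_size) && fit_best - best_fit <= tol && length(selected) > 0)
      break
    selected <- c(selected, k_best)
    scores <- c(scores, fit_best)
    best_fit <- fit_best
    if (!is.null(target_size) && length(selected) >= target_size) break
  }
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("F", seq_len(p))
  structure(list(target = target, method = "CFS",
                 ranking = data.frame(rank = seq_along(selected),
                                      feature = nm[selected],
                                      score = scores,
                                      stringsAsFactors = FALSE),
                 selected = nm[selected],
                 size = length(selected)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s / %s: %d features\n",
              x$method, x$target, x$size))
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' ReliefF feature weights
#'
#' Instance-based feature weighting: all weights start at zero; for each of
#' `m` sampled target instances the weight of every feature is decreased by
#' its difference to the nearest hit(s) and increased by its difference to
#' the nearest miss(es), each divided by `m` (and by `k_neighbors` when
#' averaging several neighbours). Features are min-max scaled to \[0, 1\]
#' beforehand so the continuous difference |v1 - v2| is already
#' range-normalized and every weight stays in \[-1, 1\].
#'
#' With a continuous response (blood pressure) the hit/miss notion is made
#' precise by response-difference quantiles: instances whose |y_t - y| falls
#' below the `hit_quantile` of all pairwise response differences count as
#' same-response (hit candidates), those above `miss_quantile` as
#' different-response (miss candidates). A response with few distinct values
#' (binary/categorical) falls back to the classic equal/unequal rule.
#'
#' @param X Feature matrix (instances in rows, named columns).
#' @param y Response vector.
#' @param m Number of sampled target instances (default: all, giving a
#'   deterministic weight vector).
#' @param k_neighbors Neighbours averaged per side (default 1, the single
#'   nearest hit and miss).
#' @param diff_mode `"continuous"` (|v1 - v2| on the \[0,1\] scale, default)
#'   or `"binary"` (0 when equal within 1e-9, else 1).
#' @param hit_quantile,miss_quantile Response-difference quantiles defining
#'   hits and misses for continuous responses.
#' @param seed Optional seed for the instance sampling.
#' @return Named numeric vector of feature weights.
#' @export
relieff_weights <- function(X, y, m = nrow(X), k_neighbors = 1L,
                            diff_mode = c("continuous", "binary"),
                            hit_quantile = 0.1, miss_quantile = 0.9,
                            seed = NULL) {
  diff_mode <- match.arg(diff_mode)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("'y' length must match rows of 'X'")
  if (m > n) stop("'m' cannot exceed the number of instances (", n, ")")
  if (k_neighbors >= n) stop("'k_neighbors' must be below the number of instances")
  if (!is.null(seed)) set.seed(seed)
  rng <- apply(X, 2, function(v) diff(range(v)))
  scl <- rng; scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, apply(X, 2, min), "-"), 2, scl, "/")
  targets <- if (m == n) seq_len(n) else sample.int(n, m)
  categorical <- length(unique(y)) <= max(2L, ceiling(sqrt(n) / 2))
  if (!categorical) {
    dy <- abs(y[pair_indices(n)$i] - y[pair_indices(n)$j])
    hit_thr <- stats::quantile(dy, hit_quantile, names = FALSE)
    miss_thr <- stats::quantile(dy, miss_quantile, names = FALSE)
  }
  delta <- function(a, b) {
    if (diff_mode == "continuous") abs(a - b)
    else as.numeric(abs(a - b) > 1e-9)
  }
  w <- numeric(p)
  for (t_idx in targets) {
    others <- setdiff(seq_len(n), t_idx)
    same <- if (categorical) others[y[others] == y[t_idx]]
            else others[abs(y[others] - y[t_idx]) <= hit_thr]
    diffr <- if (categorical) others[y[others] != y[t_idx]]
             else others[abs(y[others] - y[t_idx]) >= miss_thr]
    d2 <- rowSums(sweep(Xs[others, , drop = FALSE], 2, Xs[t_idx, ], "-")^2)
    names(d2) <- others
    if (length(same)) {
      hits <- same[order(d2[as.character(same)])][seq_len(min(k_neighbors, length(same)))]
      for (h in hits)
        w <- w - delta(Xs[t_idx, ], Xs[h, ]) / (m * length(hits))
    }
    if (length(diffr)) {
      misses <- diffr[order(d2[as.character(diffr)])][seq_len(min(k_neighbors, length(diffr)))]
      for (ms in misses)
        w <- w + delta(Xs[t_idx, ], Xs[ms, ]) / (m * length(misses))
    }
  }
  nm <- colnames(X)
  names(w) <- if (is.null(nm)) paste0("F", seq_len(p)) else nm
  w
}

#' Select the top-weighted features from ReliefF weights
#'
#' @param weights Named weight vector from [relieff_weights()].
#' @param target_size Number of features to keep.
#' @param target Label stored on the result.
#' @return A `selection_result` (see [cfs_select()]); ties in weight are
#'   broken by the lower slot index.
#' @export
relieff_select <- function(weights, target_size, target = "BP") {
  p <- length(weights)
  if (target_size > p) stop("'target_size' exceeds the number of features")
  ord <- order(-weights, seq_len(p))
  keep <- ord[seq_len(target_size)]
  nm <- names(weights)
  if (is.null(nm)) nm <- paste0("F", seq_len(p))
  structure(list(target = target, method = "ReliefF",
                 ranking = data.frame(rank = seq_len(target_size),
                                      feature = nm[keep],
                                      score = unname(weights[keep]),
                                      stringsAsFactors = FALSE),
                 selected = nm[keep],
                 size = as.integer(target_size)),
            class = "selection_result")
}

#' Per-target default subset sizes
#'
#' Default sizes used by the pipeline: CFS keeps 15 features for SBP and 16
#' for MAP and DBP; ReliefF keeps 15 for SBP and DBP and 16 for MAP.
#'
#' @param method `"cfs"` or `"relieff"`.
#' @return Named integer vector with elements `sbp`, `map`, `dbp`.
#' @export
default_subset_sizes <- function(method = c("relieff", "cfs")) {
  method <- match.arg(method)
  if (method == "cfs") c(sbp = 15L, map = 16L, dbp = 16L)
  else c(sbp = 15L, map = 16L, dbp = 15L)
}
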