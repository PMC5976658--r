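#' Permutation test for the decoding gain of an added synergy
#'
#' Tests whether the decoding performance of a model owes anything to one
#' added component: the coefficients belonging to the added synergy are
#' shuffled across trials (jointly, preserving their marginal distribution,
#' while all other coefficients stay attached to their trials) and decoding
#' is repeated, building a null distribution of performance without
#' trial-aligned information in that component. The one-sided p-value with
#' add-one correction is `(1 + #[null >= observed]) / (n_perm + 1)`.
#'
#' When `baseline` (the smaller model's decoding performance) is supplied,
#' the quantity under test is the gain over it: an observed performance at
#' or below the baseline is never a significant gain (`p = 1`), whatever
#' the permutation null looks like. This guards against the degenerate case
#' where the added component is collinear with existing ones (the fit split
#' a real synergy in two): shuffling such a component destroys shared
#' amplitude information and produces an arbitrarily low null even though
#' the enlarged model decodes no better than the smaller one.
#'
#' @param features full feature matrix of the larger model (trials x d).
#' @param added_cols column indices of the added component's coefficients.
#' @param labels per-trial class labels.
#' @param n_perm number of permutations (default 200).
#' @param seed seed for the permutation draws.
#' @param baseline percent correct of the model without the added
#'   component (optional; see above).
#' @return list with `observed` (percent correct), `null` (numeric vector),
#'   `p_value`, `baseline`.
#' @export
decoding_gain_test <- function(features, added_cols, labels, n_perm = 200L,
                               seed = 1L, baseline = NULL) {
  X <- as.matrix(features)
  stopifnot(all(added_cols >= 1), all(added_cols <= ncol(X)))
  observed <- decode_loocv(X, labels)$percent_correct
  if (!is.null(baseline) && observed <= baseline) {
    return(list(observed = observed, null = numeric(0), p_value = 1,
                baseline = baseline))
  }
  L <- nrow(X)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    Xp <- X
    Xp[, added_cols] <- X[sample.int(L), added_cols, drop = FALSE]
    decode_loocv(Xp, labels)$percent_correct
  }, numeric(1)))
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       baseline = baseline)
}

#' Select the numbers of temporal and spatial synergies by decoding gain
#'
#' Fits the space-by-time model over the `(K, N)` grid and returns the
#' smallest pair — scanning by total `K + N`, then lexicographically — such
#' that adding one more temporal or one more spatial synergy yields no
#' significant gain in decoding the full movement identity (permutation
#' test on the added component's coefficients, `p > alpha` for every
#' available one-step increment).
#'
#' @param data an [emg_dataset()] whose labels contain a `movement_id`
#'   column (or pass `labels` explicitly).
#' @param Kmax,Nmax grid bounds (paper default 10 x 10).
#' @param alpha significance level, strictly between 0 and 1.
#' @param n_perm permutations per tested increment.
#' @param restarts,tol,max_iter passed to [fit_space_by_time()].
#' @param seed master seed (fits and permutations derive from it).
#' @param labels per-trial class labels (defaults to `movement_id`).
#' @return list of class `model_order`: `K`, `N`, `performance` (decoding
#'   percent correct at the selected order), `tested` (data frame of
#'   candidate/neighbour p-values), `boundary` flag (TRUE when the grid was
#'   exhausted without a plateau).
#' @export
select_model_order <- function(data, Kmax = 10L, Nmax = 10L, alpha = 0.05,
                               n_perm = 200L, restarts = 10L, tol = 1e-8,
                               max_iter = 200L, seed = 1L, labels = NULL) {
  stopifnot(inherits(data, "emg_dataset"), Kmax >= 1, Nmax >= 1)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie strictly in (0, 1)")
  if (is.null(labels)) {
    if (!"movement_id" %in% names(data$labels)) {
      stop("data$labels must contain movement_id (or pass labels explicitly)")
    }
    labels <- data$labels$movement_id
  }
  cache <- new.env(parent = emptyenv())
  get_fit <- function(K, N) {
    key <- paste(K, N)
    if (is.null(cache[[key]])) {
      cache[[key]] <- fit_space_by_time(
        data, K, N, restarts = restarts, tol = tol, max_iter = max_iter,
        seed = seed + 97L * K + 11L * N)
    }
    cache[[key]]
  }
  # columns of the flattened K x N coefficient matrix for one component
  temporal_cols <- function(K, N, i) i + (seq_len(N) - 1L) * K
  spatial_cols <- function(K, N, j) seq_len(K) + (j - 1L) * K

  perf_cache <- new.env(parent = emptyenv())
  get_perf <- function(K, N) {
    key <- paste(K, N)
    if (is.null(perf_cache[[key]])) {
      perf_cache[[key]] <- decode_loocv(
        synergy_features(get_fit(K, N)$model, mode = "full"),
        labels)$percent_correct
    }
    perf_cache[[key]]
  }

  grid <- expand.grid(K = seq_len(Kmax), N = seq_len(Nmax))
  grid <- grid[order(grid$K + grid$N, grid$K, grid$N), , drop = FALSE]
  tested <- list()
  for (g in seq_len(nrow(grid))) {
    K <- grid$K[g]; N <- grid$N[g]
    base <- get_perf(K, N)
    ok <- TRUE
    if (K < Kmax) {
      Xb <- synergy_features(get_fit(K + 1L, N)$model, mode = "full")
      tst <- decoding_gain_test(Xb, temporal_cols(K + 1L, N, K + 1L), labels,
                                n_perm = n_perm, seed = seed + 7L * g,
                                baseline = base)
      tested[[length(tested) + 1L]] <- data.frame(
        K = K, N = N, increment = "temporal", p_value = tst$p_value,
        baseline = base, observed = tst$observed)
      if (tst$p_value <= alpha) ok <- FALSE
    }
    if (ok && N < Nmax) {
      Xb <- synergy_features(get_fit(K, N + 1L)$model, mode = "full")
      tst <- decoding_gain_test(Xb, spatial_cols(K, N + 1L, N + 1L), labels,
                                n_perm = n_perm, seed = seed + 7L * g + 3L,
                                baseline = base)
      tested[[length(tested) + 1L]] <- data.frame(
        K = K, N = N, increment = "spatial", p_value = tst$p_value,
        baseline = base, observed = tst$observed)
      if (tst$p_value <= alpha) ok <- FALSE
    }
    if (ok) {
      return(structure(list(K = K, N = N, performance = base,
                            tested = do.call(rbind, tested),
                            boundary = FALSE),
                       class = "model_order"))
    }
  }
  warning("grid exhausted without a decoding plateau; returning (Kmax, Nmax)")
  structure(list(K = Kmax, N = Nmax, performance = get_perf(Kmax, Nmax),
                 tested = do.call(rbind, tested), boundary = TRUE),
            class = "model_order")
}

#' @export
print.model_order <- function(x, ...) {
  cat(sprintf("Selected model order: K = %d temporal, N = %d spatial (%.1f%% movement decoding)%s\n",
              x$K, x$N, x$performance,
              if (x$boundary) " [grid boundary]" else ""))
  invisible(x)
}
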