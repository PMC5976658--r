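#' Fit the space-by-time decomposition to single-trial EMG
#'
#' Factorises every trial matrix `M^l` (time bins x muscles) as
#' `W_t A^l W_s`, with `W_t` the shared temporal synergies (columns), `W_s`
#' the shared spatial synergies (rows), and `A^l` the trial-specific
#' non-negative activation coefficients. The total squared Frobenius
#' reconstruction error is minimised by block-coordinate descent with exact
#' non-negative coordinate updates (objective non-increasing at every
#' iteration); to escape local minima the optimisation is restarted from
#' `restarts` random initialisations (50 by default) and the solution with
#' the lowest reconstruction error is returned.
#'
#' The factorisation is scale-indeterminate, so the returned model is
#' normalised: columns of `W_t` and rows of `W_s` have unit Euclidean norm
#' and all scale is absorbed into the coefficients.
#'
#' @param data an [emg_dataset()] (entries must be finite and non-negative).
#' @param K,N number of temporal and spatial synergies (`1 <= K <= T`,
#'   `1 <= N <= M`).
#' @param restarts number of random initialisations (default 50).
#' @param tol relative objective decrease below which a restart stops
#'   (default 1e-8).
#' @param max_iter iteration cap per restart (default 500); if reached, the
#'   result carries a `converged = FALSE` flag and a warning is raised.
#' @param seed master seed; restart `r` uses `seed + r - 1`.
#' @param sweeps inner coordinate sweeps per block per iteration.
#' @return object of class `sbt_fit` with elements `model` (class
#'   `sbt_model`: `Wt` `T x K`, `Ws` `N x M`, `A` array `L x K x N`,
#'   `objective`, `trace`, `restarts`, `seed`, `converged`), `vaf` and
#'   `reconstruction_error`.
#' @export
fit_space_by_time <- function(data, K, N, restarts = 50L, tol = 1e-8,
                              max_iter = 500L, seed = 1L, sweeps = 2L) {
  stopifnot(inherits(data, "emg_dataset"))
  T_bins <- data$T_bins; M <- data$M; L <- data$L
  if (K < 1 || K > T_bins || N < 1 || N > M) {
    stop("require 1 <= K <= T and 1 <= N <= M")
  }
  Mdat <- array(0, dim = c(T_bins, M, L))
  for (l in seq_len(L)) {
    tr <- data$trials[[l]]
    if (anyNA(tr) || any(!is.finite(tr)) || any(tr < 0)) {
      stop("data must be finite and non-negative")
    }
    Mdat[, , l] <- tr
  }
  scale <- sqrt(mean(Mdat^2) / (K * N) + 1e-12)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(seed + r - 1L, list(
      Wt = matrix(runif(T_bins * K), T_bins, K),
      Ws = matrix(runif(N * M), N, M),
      A = array(runif(K * N * L) * scale, dim = c(K, N, L))
    ))
    fit <- sbt_fit_cpp(Mdat, init$Wt, init$Ws, init$A,
                       max_iter = max_iter, tol = tol, sweeps = sweeps)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!best$converged) {
    warning("best restart reached max_iter without meeting the tolerance")
  }
  model <- normalize_sbt(best, L = L, restarts = restarts, seed = seed)
  err <- best$objective
  structure(list(model = model, vaf = compute_vaf(model, data),
                 reconstruction_error = err),
            class = "sbt_fit")
}

# Unit-norm convention: columns of Wt and rows of Ws have norm 1, scale in A.
normalize_sbt <- function(fit, L, restarts, seed) {
  Wt <- fit$Wt; Ws <- fit$Ws
  K <- ncol(Wt); N <- nrow(Ws)
  nt <- sqrt(colSums(Wt^2))
  ns <- sqrt(rowSums(Ws^2))
  nt_safe <- ifelse(nt > 0, nt, 1)
  ns_safe <- ifelse(ns > 0, ns, 1)
  Wt <- sweep(Wt, 2, nt_safe, "/")
  Ws <- sweep(Ws, 1, ns_safe, "/")
  A <- array(0, dim = c(L, K, N))
  for (l in seq_len(L)) {
    A[l, , ] <- diag(nt, K, K) %*% fit$A[, , l] %*% diag(ns, N, N)
  }
  structure(list(Wt = Wt, Ws = Ws, A = A, K = K, N = N,
                 objective = fit$objective, trace = fit$trace,
                 iterations = fit$iterations, converged = fit$converged,
                 restarts = restarts, seed = seed),
            class = "sbt_model")
}

#' Reconstruct trials from a space-by-time model
#'
#' @param model an `sbt_model`.
#' @param l trial index, or `NULL` for a list of all reconstructions.
#' @return `T x M` matrix (or list of them).
#' @export
reconstruct_trials <- function(model, l = NULL) {
  one <- function(i) model$Wt %*% model$A[i, , , drop = TRUE] %*% model$Ws
  if (model$K == 1 || model$N == 1) {
    one <- function(i) model$Wt %*% matrix(model$A[i, , ], model$K, model$N) %*% model$Ws
  }
  if (is.null(l)) lapply(seq_len(dim(model$A)[1]), one) else one(l)
}

#' Variance accounted for by a space-by-time model
#'
#' `VAF = 1 - sum_l ||M^l - Wt A^l Ws||^2 / sum_l ||M^l - mbar||^2`, with
#' `mbar` the mean trial pattern across all trials and `||.||` the
#' Frobenius norm. VAF is 1 exactly when the reconstruction is exact and
#' can be negative for models worse than the mean pattern.
#'
#' @param model an `sbt_model`.
#' @param data the [emg_dataset()] the model was fitted to (or any dataset
#'   of matching dimensions and trial count).
#' @return scalar VAF in `(-Inf, 1]`.
#' @export
compute_vaf <- function(model, data) {
  stopifnot(inherits(data, "emg_dataset"))
  L <- data$L
  stopifnot(dim(model$A)[1] == L,
            nrow(model$Wt) == data$T_bins, ncol(model$Ws) == data$M)
  mbar <- Reduce(`+`, data$trials) / L
  err <- 0
  tot <- 0
  for (l in seq_len(L)) {
    R <- data$trials[[l]] - reconstruct_trials(model, l)
    err <- err + sum(R^2)
    tot <- tot + sum((data$trials[[l]] - mbar)^2)
  }
  if (tot == 0) {
    stop("VAF undefined: all trials are identical (zero total variance)")
  }
  1 - err / tot
}

#' @export
print.sbt_model <- function(x, ...) {
  cat(sprintf("Space-by-time model: K = %d temporal x N = %d spatial synergies, %d trials\n",
              x$K, x$N, dim(x$A)[1]))
  cat(sprintf("  objective %.6g after %d iterations (%d restarts, converged: %s)\n",
              x$objective, x$iterations, x$restarts, x$converged))
  invisible(x)
}

#' @export
print.sbt_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  VAF = %.4f\n", x$vaf))
  invisible(x)
}
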