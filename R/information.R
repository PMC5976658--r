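#' Plug-in mutual information of a confusion-count table
#'
#' Treats the counts as samples of the joint distribution of the true class
#' `t` and the predicted class `t^p` and evaluates
#' `I = sum_{t,t^p} P(t, t^p) log2 [ P(t, t^p) / (P(t) P(t^p)) ]`
#' with the convention `0 * log(.) = 0`. A perfect decoder of `V`
#' equiprobable classes reaches `log2 V` bits; an independent one 0 bits.
#'
#' @param counts square non-negative count matrix (true classes in rows,
#'   predicted in columns), with positive total.
#' @return mutual information in bits.
#' @export
mutual_information_plugin <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts))
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("counts must have a positive total")
  P <- counts / n
  pt <- rowSums(P)
  pp <- colSums(P)
  E <- outer(pt, pp)
  nz <- P > 0
  sum(P[nz] * log2(P[nz] / E[nz]))
}

#' Maximum task information of a V-valued parameter
#'
#' @param V number of distinct values (>= 2).
#' @return `log2(V)` bits (e.g. 6.17 bits for the 72 movements, 3.17 bits
#'   for 9 targets, 3 bits for the 8 directions, 1.59 bits for 3 classes).
#' @export
max_information <- function(V) {
  stopifnot(V >= 2)
  log2(V)
}

#' Information as a percentage of the maximum
#'
#' @param info information in bits (>= 0).
#' @param V number of classes of the parameter.
#' @param round_display round to integer percent (the reporting style used
#'   throughout; default TRUE).
#' @return percentage of `log2 V`.
#' @export
percent_of_max <- function(info, V, round_display = TRUE) {
  stopifnot(info >= 0)
  p <- 100 * info / max_information(V)
  if (round_display) round(p) else p
}

#' Panzeri-Treves bias-corrected information of a confusion matrix
#'
#' The plug-in estimator of mutual information is biased upward when trials
#' are limited. The Panzeri-Treves correction estimates that bias from the
#' number of occupied response bins:
#' `bias = [ sum_t (Rt_t - 1) - (Rt - 1) ] / (2 N ln 2)` bits, where `Rt_t`
#' is the number of non-zero predicted-class bins in row `t`, `Rt` the
#' number of non-zero bins of the predicted-class marginal (naive counting
#' of occupied bins), and `N` the total trial count. The corrected estimate
#' is the plug-in value minus the bias, floored at zero for reporting (the
#' unfloored value is retained).
#'
#' @param counts square non-negative count matrix (true x predicted).
#' @return object of class `info_result`: `info_bits` (plug-in),
#'   `bias_bits`, `corrected_bits` (floored at 0), `corrected_unfloored`,
#'   `max_bits = log2 V`, `percent_of_max` (integer, from the floored
#'   corrected value) and `n_trials`.
#' @export
pt_corrected_information <- function(counts) {
  counts <- as.matrix(counts)
  plugin <- mutual_information_plugin(counts)
  n <- sum(counts)
  V <- nrow(counts)
  r_rows <- rowSums(counts > 0)
  r_marg <- sum(colSums(counts) > 0)
  bias <- (sum(pmax(r_rows - 1, 0)) - (r_marg - 1)) / (2 * n * log(2))
  corrected <- plugin - bias
  structure(list(info_bits = plugin, bias_bits = bias,
                 corrected_bits = max(corrected, 0),
                 corrected_unfloored = corrected,
                 max_bits = max_information(V),
                 percent_of_max = percent_of_max(max(corrected, 0), V),
                 n_trials = n),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("Task information: %.2f bits (plug-in %.2f, bias %.4f), %d%% of %.2f bits max\n",
              x$corrected_bits, x$info_bits, x$bias_bits,
              x$percent_of_max, x$max_bits))
  invisible(x)
}
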