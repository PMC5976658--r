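#' @keywords internal
"_PACKAGE"

#' @useDynLib emgsynergy, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx as.dist cor cutree hclust qbinom rgamma rlnorm
#'   rnorm runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# All permutations of 1..n (n small; used for synergy matching).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Match estimated synergies to reference synergies
#'
#' Finds the permutation of the estimated synergies that maximises the mean
#' Pearson correlation with the reference set, by exhaustive enumeration
#' (the number of synergies is small by design). Used to resolve the
#' permutation indeterminacy of the factorisation when comparing a fitted
#' model to a planted ground truth.
#'
#' @param est,ref matrices with synergies in columns (same dimensions).
#' @return list with `perm` (index into columns of `est` for each reference
#'   column) and `cor` (per-reference-synergy correlation under that
#'   permutation).
#' @export
match_synergies <- function(est, ref) {
  stopifnot(ncol(est) == ncol(ref), nrow(est) == nrow(ref))
  K <- ncol(ref)
  if (K > 7L) stop("exhaustive matching supported for at most 7 synergies")
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)
  }
  cmat <- matrix(0, K, K)  # cmat[i, j] = cor(ref i, est j)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) cmat[i, j] <- safe_cor(ref[, i], est[, j])
  }
  best <- NULL
  best_val <- -Inf
  for (p in all_perms(K)) {
    v <- sum(cmat[cbind(seq_len(K), p)])
    if (v > best_val) {
      best_val <- v
      best <- p
    }
  }
  list(perm = best, cor = cmat[cbind(seq_len(K), best)])
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return the adjusted Rand index (1 for identical partitions up to
#'   relabelling, approximately 0 for independent partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (mx - expected)
}
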