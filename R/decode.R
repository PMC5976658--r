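#' Extract per-synergy activation-coefficient features
#'
#' For decoding, each temporal synergy `i` is represented on every trial by
#' the `N` coefficients combining it with the spatial synergies
#' (`A[l, i, 1..N]`); each spatial synergy `j` by the `K` coefficients
#' combining it with the temporal synergies (`A[l, 1..K, j]`); the full
#' model by all `K x N` coefficients flattened.
#'
#' @param model an `sbt_model` (or any list with an `A` array `L x K x N`).
#' @param index synergy index (ignored for `mode = "full"`).
#' @param mode `"temporal"`, `"spatial"` or `"full"`.
#' @return numeric feature matrix with `L` rows and `N`, `K` or `K*N`
#'   columns; attribute `"feature_origin"` records the slice taken.
#' @export
synergy_features <- function(model, index = NULL,
                             mode = c("temporal", "spatial", "full")) {
  mode <- match.arg(mode)
  A <- model$A
  d <- dim(A)
  X <- switch(mode,
    temporal = {
      if (is.null(index) || index < 1 || index > d[2]) {
        stop("temporal synergy index out of range")
      }
      matrix(A[, index, ], d[1], d[3])
    },
    spatial = {
      if (is.null(index) || index < 1 || index > d[3]) {
        stop("spatial synergy index out of range")
      }
      matrix(A[, , index], d[1], d[2])
    },
    full = matrix(A, d[1], d[2] * d[3])
  )
  attr(X, "feature_origin") <- list(mode = mode, index = index)
  X
}

#' Chance level of a V-way discrimination
#'
#' @param V number of classes (>= 2).
#' @return percent correct expected by chance, `100 / V` (11 percent for
#'   the 9-way discriminations, 33 percent for the 3-way ones).
#' @export
chance_level <- function(V) {
  stopifnot(V >= 2)
  100 / V
}

#' Decode class labels from features by LDA with leave-one-out CV
#'
#' Trains, for every trial, a linear discriminant classifier (shared pooled
#' covariance, empirical class priors) on the remaining trials and predicts
#' the held-out label. The pooled covariance is shrunk towards the identity
#' (`lambda = 1e-3 * trace / d`) whenever its condition number exceeds
#' `1e8`, so collinear feature sets never crash the decoder. Prediction
#' ties are broken deterministically towards the lowest class index.
#' Classes with a single trial cannot be held out meaningfully and are
#' skipped with a warning.
#'
#' The leave-one-out loop uses rank-one downdating of the pooled scatter
#' (Sherman-Morrison), so the full covariance is inverted only once.
#'
#' @param features numeric matrix, trials in rows.
#' @param labels vector/factor of class labels (at least 2 classes, each
#'   with at least 2 trials to participate).
#' @param seed kept for interface stability; the decoder is deterministic
#'   and the seed is only recorded.
#' @return object of class `decoding_result`: `percent_correct`,
#'   `confusion` (class `confusion_matrix` with integer `counts`,
#'   row-stochastic `D`, `class_labels`, `n_trials`), `predictions`, and
#'   `task_parameter` (filled by callers).
#' @export
decode_loocv <- function(features, labels, seed = NULL) {
  X <- as.matrix(features)
  y <- factor(labels)
  L <- nrow(X)
  stopifnot(length(y) == L, nlevels(y) >= 2)
  d <- ncol(X)
  lev <- levels(y)
  V <- length(lev)
  yi <- as.integer(y)
  n_c <- tabulate(yi, V)
  if (any(n_c == 0)) stop("every class must have at least one trial")
  singletons <- which(n_c == 1)
  if (length(singletons)) {
    warning("class(es) with a single trial skipped in LOOCV: ",
            paste(lev[singletons], collapse = ", "))
  }

  Mu <- matrix(0, V, d)                      # class means
  for (c in seq_len(V)) {
    Mu[c, ] <- colMeans(X[yi == c, , drop = FALSE])
  }
  S <- crossprod(X) - crossprod(sqrt(n_c) * Mu)    # pooled scatter
  nu <- max(L - 1 - V, 1)                    # training-fold df
  Sigma <- S / nu
  lambda <- 0
  tr <- sum(diag(Sigma))
  if (tr == 0) {
    lambda <- 1e-8
  } else {
    ev <- tryCatch(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NULL)
    if (is.null(ev) || min(ev) <= 0 || max(ev) / min(ev) > 1e8) {
      lambda <- 1e-3 * tr / d
    }
  }
  Binv <- solve(Sigma + lambda * diag(d))    # base inverse, df = L - 1 - V

  pred <- integer(L)
  for (l in seq_len(L)) {
    c0 <- yi[l]
    if (n_c[c0] < 2) {
      pred[l] <- NA_integer_
      next
    }
    x <- X[l, ]
    v <- x - Mu[c0, ]
    beta <- n_c[c0] / (n_c[c0] - 1) / nu     # S' = S - (n/(n-1)) v v'
    Bv <- Binv %*% v
    denom <- 1 - beta * sum(v * Bv)
    W <- Binv + (beta / denom) * tcrossprod(Bv)   # (Sigma' + lambda I)^{-1}
    Mu2 <- Mu
    Mu2[c0, ] <- (n_c[c0] * Mu[c0, ] - x) / (n_c[c0] - 1)
    priors <- n_c
    priors[c0] <- priors[c0] - 1
    priors <- priors / (L - 1)
    WM <- W %*% t(Mu2)                        # d x V
    scores <- drop(x %*% WM) - 0.5 * colSums(t(Mu2) * WM) + log(priors)
    pred[l] <- which.max(scores)              # first max: lowest class index
  }

  keep <- !is.na(pred)
  counts <- matrix(0L, V, V, dimnames = list(true = lev, predicted = lev))
  tab <- table(factor(yi[keep], levels = seq_len(V)),
               factor(pred[keep], levels = seq_len(V)))
  counts[, ] <- as.integer(tab)
  n_trials <- sum(keep)
  D <- counts / pmax(rowSums(counts), 1)
  confusion <- structure(list(counts = counts, D = D, class_labels = lev,
                              n_trials = n_trials),
                         class = "confusion_matrix")
  structure(list(percent_correct = 100 * sum(diag(counts)) / n_trials,
                 confusion = confusion,
                 predictions = factor(lev[pred], levels = lev),
                 lambda = lambda, seed = seed, task_parameter = NULL),
            class = "decoding_result")
}

#' Decode the 72-class movement from every synergy of a model
#'
#' Convenience wrapper producing the per-synergy full-movement confusion
#' matrices that functional-similarity clustering consumes.
#'
#' @param model an `sbt_model` (or list with an `A` coefficient array).
#' @param labels per-trial class labels (typically the movement id).
#' @param mode `"temporal"` or `"spatial"`.
#' @return list of `decoding_result`, one per synergy of the given mode.
#' @export
decode_synergies <- function(model, labels, mode = c("temporal", "spatial")) {
  mode <- match.arg(mode)
  n <- if (mode == "temporal") dim(model$A)[2] else dim(model$A)[3]
  lapply(seq_len(n), function(i) {
    r <- decode_loocv(synergy_features(model, i, mode), labels)
    r$task_parameter <- "movement"
    r
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("LOOCV linear-discriminant decoding: %.1f%% correct (%d trials, %d classes, chance %.1f%%)\n",
              x$percent_correct, x$confusion$n_trials,
              length(x$confusion$class_labels),
              chance_level(length(x$confusion$class_labels))))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix: %d classes, %d trials\n",
              length(x$class_labels), x$n_trials))
  print(round(x$D, 3))
  invisible(x)
}
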