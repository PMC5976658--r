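#' Construct an EMG dataset of single-trial activation matrices
#'
#' The canonical container for preprocessed single-trial EMG: a list of `L`
#' non-negative `T x M` matrices (time bins by muscles) plus a per-trial
#' label table carrying the task-parameter record of each trial.
#'
#' @param trials list of `T x M` non-negative numeric matrices, all with the
#'   same dimensions.
#' @param labels data frame with one row per trial; must contain a
#'   `trial_id` column and the task-parameter columns (see
#'   [task_parameter_names()]) when used for decoding.
#' @return object of class `emg_dataset` with elements `trials`, `labels`,
#'   `T_bins`, `M`, `L`.
#' @export
emg_dataset <- function(trials, labels = NULL) {
  stopifnot(is.list(trials), length(trials) >= 1)
  d <- dim(trials[[1]])
  for (tr in trials) {
    if (!is.matrix(tr) || !identical(dim(tr), d)) {
      stop("all trials must be matrices of identical dimensions")
    }
    if (anyNA(tr) || any(!is.finite(tr))) stop("trial matrices must be finite")
    if (any(tr < 0)) stop("trial matrices must be non-negative")
  }
  if (is.null(labels)) {
    labels <- data.frame(trial_id = seq_along(trials))
  }
  stopifnot(nrow(labels) == length(trials))
  structure(list(trials = trials, labels = labels,
                 T_bins = d[1], M = d[2], L = length(trials)),
            class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf("EMG dataset: %d trials of %d time bins x %d muscles\n",
              x$L, x$T_bins, x$M))
  if (!is.null(x$labels) && "movement_id" %in% names(x$labels)) {
    cat(sprintf("  %d distinct movements\n",
                length(unique(x$labels$movement_id))))
  }
  invisible(x)
}
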