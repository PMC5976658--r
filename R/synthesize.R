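#' Synthesize a single-subject EMG dataset from a planted model
#'
#' Generates `reps` repetitions of each of the 72 movements. Each trial is
#' `W_t A^l W_s` with `A^l` drawn by [sample_trial_coefficients()], plus
#' additive Gaussian noise truncated at zero (rectified EMG envelopes cannot
#' be negative). With `emg_noise_sd = 0` the dataset is exactly the planted
#' factorisation, trial by trial.
#'
#' @param truth a [make_ground_truth()] object.
#' @param design a [build_task_design()] object.
#' @param reps_per_movement repetitions of each movement (paper protocol:
#'   30, giving 72 x 30 = 2160 trials).
#' @param seed integer seed governing coefficient and noise draws.
#' @param emg_noise_sd overrides the model's additive noise sd if given.
#' @param raw if `TRUE`, also generate continuous raw-like traces per trial
#'   (see [synthesize_raw_trial()]) for preprocessing tests.
#' @param raw_rate sampling rate (Hz) of the raw traces.
#' @return object of class `synthetic_dataset`: `emg` (an [emg_dataset()]),
#'   `truth`, `coefficients` (array `L x K x N` of the planted trial
#'   coefficients) and optionally `raw_trials`.
#' @export
synthesize_dataset <- function(truth, design = build_task_design(),
                               reps_per_movement = 30L, seed = 1L,
                               emg_noise_sd = NULL, raw = FALSE,
                               raw_rate = 1000) {
  stopifnot(inherits(truth, "ground_truth"), reps_per_movement >= 1)
  if (is.null(emg_noise_sd)) emg_noise_sd <- truth$emg_noise_sd
  Wt <- truth$temporal_synergies
  Ws <- truth$spatial_synergies
  mov <- design$movements
  L <- nrow(mov) * reps_per_movement
  with_seed(seed, {
    trials <- vector("list", L)
    raw_trials <- if (raw) vector("list", L) else NULL
    A <- array(0, dim = c(L, truth$K, truth$N))
    idx <- rep(seq_len(nrow(mov)), each = reps_per_movement)
    for (l in seq_len(L)) {
      m <- mov[idx[l], , drop = FALSE]
      Al <- sample_trial_coefficients(truth, m)
      A[l, , ] <- Al
      E <- Wt %*% Al %*% Ws
      if (emg_noise_sd > 0) {
        E <- E + matrix(rnorm(length(E), sd = emg_noise_sd), nrow(E))
        E[E < 0] <- 0
      }
      trials[[l]] <- E
      if (raw) raw_trials[[l]] <- synthesize_raw_trial(E, rate = raw_rate)
    }
    labels <- cbind(data.frame(trial_id = seq_len(L),
                               movement_id = mov$movement[idx]),
                    mov[idx, task_parameter_names(), drop = FALSE])
    rownames(labels) <- NULL
    structure(list(emg = emg_dataset(trials, labels), truth = truth,
                   coefficients = A, raw_trials = raw_trials,
                   seed = as.integer(seed), emg_noise_sd = emg_noise_sd),
              class = "synthetic_dataset")
  })
}

#' Generate a continuous raw-like trial from a binned activation matrix
#'
#' Produces the continuous signals the preprocessing stage expects: for each
#' muscle a zero-mean broadband carrier (white noise) amplitude-modulated by
#' the trial's activation envelope, preceded and followed by near-silent
#' rest periods, plus a bell-shaped (minimum-jerk) fingertip-speed trace
#' whose above-threshold extent delimits the movement. The envelope is
#' placed on the analysis window (100 ms before speed onset through movement
#' end), so running the preprocessing pipeline on the output should recover
#' the planted envelope up to carrier noise.
#'
#' @param activation `T x M` non-negative matrix (the planted envelope).
#' @param rate sampling rate in Hz.
#' @param move_duration movement duration in seconds.
#' @param pre,post rest durations (s) before onset and after end.
#' @param rest_level small envelope floor during rest.
#' @return list with `emg` (samples x M matrix), `speed` (numeric vector)
#'   and `rate`.
#' @export
synthesize_raw_trial <- function(activation, rate = 1000, move_duration = 1.0,
                                 pre = 0.4, post = 0.2, rest_level = 0.01) {
  T_bins <- nrow(activation)
  M <- ncol(activation)
  n_pre <- round(pre * rate)
  n_mov <- round(move_duration * rate)
  n_post <- round(post * rate)
  n <- n_pre + n_mov + n_post
  # minimum-jerk tangential speed over the movement, zero at rest
  tau <- seq(0, 1, length.out = n_mov)
  speed <- c(rep(0, n_pre), 30 * tau^2 - 60 * tau^3 + 30 * tau^4, rep(0, n_post))
  # analysis window = (onset - 100 ms, end); map the 50-bin envelope onto it
  w0 <- n_pre - round(0.1 * rate) + 1L
  w1 <- n_pre + n_mov
  win_len <- w1 - w0 + 1L
  env <- matrix(rest_level, n, M)
  bin_t <- seq(0, 1, length.out = T_bins)
  samp_t <- seq(0, 1, length.out = win_len)
  for (m in seq_len(M)) {
    env[w0:w1, m] <- approx(bin_t, activation[, m], xout = samp_t)$y
  }
  carrier <- matrix(rnorm(n * M), n, M)
  list(emg = env * carrier, speed = speed, rate = rate)
}

#' Synthesize a multi-subject collection with a shared tuning map
#'
#' Each "subject" keeps the temporal synergies and task-tuning map of the
#' base ground truth but has freshly drawn spatial synergy loadings (see
#' [redraw_spatial_synergies()]). Across subjects, spatial synergy `j`
#' therefore encodes the same task parameter everywhere while its muscle
#' loadings differ — the planted functional clusters that the clustering
#' module should recover.
#'
#' @param truth base [make_ground_truth()] model (subject 1 uses it as is).
#' @param n_subjects number of subjects.
#' @param reps_per_movement,design,seed as in [synthesize_dataset()].
#' @param ... passed to [synthesize_dataset()].
#' @return list of `synthetic_dataset` objects, one per subject.
#' @export
synthesize_subjects <- function(truth, n_subjects, design = build_task_design(),
                                reps_per_movement = 30L, seed = 1L, ...) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(s) {
    tr <- if (s == 1L) truth else redraw_spatial_synergies(truth, seed + 1000L * s)
    synthesize_dataset(tr, design = design,
                       reps_per_movement = reps_per_movement,
                       seed = seed + s, ...)
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic EMG dataset (seed %d, noise sd %.3g):\n",
              x$seed, x$emg_noise_sd))
  print(x$emg)
  invisible(x)
}
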