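#' Construct a ground-truth space-by-time model with task tuning
#'
#' Builds a planted generative model for synthetic single-trial EMG: `K`
#' non-negative temporal synergies (unimodal bumps with staggered peaks
#' covering the movement duration), `N` sparse non-negative spatial
#' synergies (each with one dominant muscle), and a tuning map that assigns
#' every temporal synergy a "temporal" task parameter (start target for the
#' earliest synergy, movement direction for the transient middle ones, end
#' target for the latest) and every spatial synergy a "spatial" parameter
#' (bar- or height-related), together with strictly positive per-class mean
#' gains. Trial coefficients are later drawn around those gains, so task
#' identity is recoverable from the activation coefficients of the tuned
#' synergies and from them only.
#'
#' @param K,N number of temporal and spatial synergies (>= 1).
#' @param T_bins number of time bins per trial (default 50; must be at
#'   least `2 * K` so the bumps fit).
#' @param M number of muscles (default 30; must be >= `N`).
#' @param seed integer seed; the construction is deterministic given it.
#' @param coefficient_noise_sigma sigma of the multiplicative lognormal
#'   trial-to-trial variability of the activation coefficients (default 0.2).
#' @param emg_noise_sd standard deviation of the additive (truncated at 0)
#'   Gaussian EMG noise (default 0.05, on the scale of unit-amplitude
#'   activations).
#' @param gain_range_temporal,gain_range_spatial range over which the
#'   per-class mean gains of tuned synergies are evenly spread. Temporal
#'   synergies modulate moderately across task classes (default 0.7-1.3,
#'   about 2x: phasic bursts occur in every movement) while spatial synergy
#'   recruitment varies strongly with target location (default 0.3-1.7,
#'   over 5x: postural demands differ widely between targets).
#' @param min_gain_gap minimum spacing between per-class mean gains of a
#'   tuned synergy (default 0.05); violated spacings are rejected.
#' @param design task design used to enumerate parameter classes.
#' @return object of class `ground_truth`: temporal synergies
#'   (`T_bins x K`), spatial synergies (`N x M`), the tuning map, noise
#'   parameters and seed.
#' @export
make_ground_truth <- function(K, N, T_bins = 50L, M = 30L, seed = 1L,
                              coefficient_noise_sigma = 0.2,
                              emg_noise_sd = 0.05,
                              gain_range_temporal = c(0.7, 1.3),
                              gain_range_spatial = c(0.3, 1.7),
                              min_gain_gap = 0.05,
                              design = build_task_design()) {
  stopifnot(K >= 1, N >= 1)
  if (T_bins < 2 * K) stop("T_bins must be at least 2*K so the temporal bumps fit")
  if (M < N) stop("M must be at least N (one dominant muscle per spatial synergy)")
  with_seed(seed, {
    # temporal synergies: truncated-Gaussian bumps, width T/(2K), peaks
    # staggered over [1, T]
    width <- T_bins / (2 * K)
    peaks <- round(seq(width, T_bins - width + 1, length.out = K))
    peaks <- pmin(pmax(peaks, 1), T_bins)
    if (anyDuplicated(peaks)) peaks <- round(seq(1, T_bins, length.out = K))
    grid <- seq_len(T_bins)
    Wt <- vapply(peaks, function(p) exp(-0.5 * ((grid - p) / width)^2),
                 numeric(T_bins))
    Wt[Wt < 1e-4] <- 0

    # spatial synergies: sparse gamma loadings, one boosted dominant muscle
    Ws <- matrix(rgamma(N * M, shape = 0.4, rate = 2), nrow = N)
    Ws[Ws < 0.05] <- 0
    dominant <- sample.int(M, N)
    for (j in seq_len(N)) Ws[j, dominant[j]] <- max(Ws[j, ]) + 1

    temporal_pool <- temporal_tuning_assignment(K)
    spatial_pool <- c("start_bar", "start_height", "end_bar", "end_height",
                      "horizontal_direction", "vertical_direction")
    spatial_params <- spatial_pool[((seq_len(N) - 1L) %% length(spatial_pool)) + 1L]

    gains_for <- function(param, range) {
      classes <- design$parameters[[param]]
      V <- length(classes)
      g <- seq(range[1], range[2], length.out = V)
      if (V > 1 && diff(range) / (V - 1) < min_gain_gap) {
        stop("gain range too narrow for ", V, " classes at min_gain_gap = ",
             min_gain_gap)
      }
      setNames(sample(g), classes)  # permute so same-parameter synergies differ
    }
    tuning <- list(
      temporal = lapply(temporal_pool, function(p)
        list(parameter = p, gains = gains_for(p, gain_range_temporal))),
      spatial = lapply(spatial_params, function(p)
        list(parameter = p, gains = gains_for(p, gain_range_spatial)))
    )
    structure(list(
      temporal_synergies = Wt,
      spatial_synergies = Ws,
      tuning = tuning,
      coefficient_noise_sigma = coefficient_noise_sigma,
      emg_noise_sd = emg_noise_sd,
      K = K, N = N, T_bins = T_bins, M = M,
      peaks = peaks, dominant_muscles = dominant,
      seed = as.integer(seed)
    ), class = "ground_truth")
  })
}

# Early synergies encode the movement start, middle/transient ones the
# direction, late ones the end target.
temporal_tuning_assignment <- function(K) {
  if (K == 1L) return("start_target")
  if (K == 2L) return(c("start_target", "end_target"))
  c("start_target", rep("direction", K - 2L), "end_target")
}

#' Redraw the spatial synergies of a ground-truth model
#'
#' Emulates a new "subject": the spatial synergy loadings are redrawn from
#' the sparse prior with a fresh seed (new dominant muscles) while the
#' temporal synergies and, crucially, the task-tuning map and its per-class
#' gains are kept. Synergies of the resulting subjects therefore share
#' function (they encode the same task distinctions) while differing in
#' shape, which is precisely the situation functional-similarity clustering
#' is designed to handle.
#'
#' @param truth a [make_ground_truth()] object.
#' @param seed integer seed for the new loadings.
#' @return a new `ground_truth` object.
#' @export
redraw_spatial_synergies <- function(truth, seed) {
  stopifnot(inherits(truth, "ground_truth"))
  with_seed(seed, {
    N <- truth$N; M <- truth$M
    Ws <- matrix(rgamma(N * M, shape = 0.4, rate = 2), nrow = N)
    Ws[Ws < 0.05] <- 0
    dominant <- sample.int(M, N)
    for (j in seq_len(N)) Ws[j, dominant[j]] <- max(Ws[j, ]) + 1
    truth$spatial_synergies <- Ws
    truth$dominant_muscles <- dominant
    truth$seed <- as.integer(seed)
    truth
  })
}

#' Sample single-trial activation coefficients from the planted tuning
#'
#' Coefficient (i, j) for a movement is the product of temporal synergy i's
#' mean gain for the movement's class of its tuned parameter, spatial
#' synergy j's mean gain likewise, and a multiplicative lognormal noise term
#' `exp(N(0, sigma^2))`. With `sigma = 0` the coefficients equal the class
#' means exactly; two movements that agree on every tuned parameter produce
#' identical mean coefficients.
#'
#' @param truth a [make_ground_truth()] object.
#' @param movement a one-row task-parameter record (a row of
#'   `design$movements` or the output of [derive_task_parameters()]).
#' @param seed optional seed (NULL uses the current RNG stream).
#' @return a `K x N` matrix of strictly positive coefficients.
#' @export
sample_trial_coefficients <- function(truth, movement, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  draw <- function() {
    tg <- vapply(truth$tuning$temporal, function(tt)
      tt$gains[[as.character(movement[[tt$parameter]])]], numeric(1))
    sg <- vapply(truth$tuning$spatial, function(ss)
      ss$gains[[as.character(movement[[ss$parameter]])]], numeric(1))
    mu <- outer(tg, sg)
    sig <- truth$coefficient_noise_sigma
    eps <- if (sig > 0) {
      matrix(rlnorm(truth$K * truth$N, meanlog = 0, sdlog = sig),
             truth$K, truth$N)
    } else {
      1
    }
    mu * eps
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Mean (noise-free) activation coefficients for a movement
#'
#' @inheritParams sample_trial_coefficients
#' @return `K x N` matrix of per-class mean gains (the sigma = 0 limit of
#'   [sample_trial_coefficients()]).
#' @export
mean_trial_coefficients <- function(truth, movement) {
  sig <- truth$coefficient_noise_sigma
  truth$coefficient_noise_sigma <- 0
  on.exit(truth$coefficient_noise_sigma <- sig)
  sample_trial_coefficients(truth, movement)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground-truth space-by-time model: K = %d temporal, N = %d spatial (T = %d bins, M = %d muscles)\n",
              x$K, x$N, x$T_bins, x$M))
  cat("Temporal tuning:",
      paste(vapply(x$tuning$temporal, `[[`, "", "parameter"), collapse = ", "),
      "\n")
  cat("Spatial tuning: ",
      paste(vapply(x$tuning$spatial, `[[`, "", "parameter"), collapse = ", "),
      "\n")
  invisible(x)
}
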