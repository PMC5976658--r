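# ---- IIR filtering primitives -----------------------------------------
# No DSP package is assumed; Butterworth design via the bilinear transform
# and zero-phase (forward-backward) application with reflected padding are
# implemented here. Orders are small (4th by default) so the polynomial
# (b, a) form is numerically adequate.

# Butterworth digital filter coefficients. w is the cutoff as a fraction of
# the Nyquist frequency (0 < w < 1); type "low" or "high".
butter_coefficients <- function(order, w, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, w > 0, w < 1)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # analog prototype poles
  fs2 <- 4                                               # 2 * fs with fs = 2
  warped <- fs2 * tan(pi * w / 2)
  if (type == "low") {
    pa <- warped * p
    zd <- rep(-1 + 0i, order)          # zeros at Nyquist
    ref <- 1 + 0i                      # unit gain at DC (z = 1)
  } else {
    pa <- warped / p
    zd <- rep(1 + 0i, order)           # zeros at DC
    ref <- -1 + 0i                     # unit gain at Nyquist (z = -1)
  }
  pd <- (fs2 + pa) / (fs2 - pa)        # bilinear transform
  a <- Re(poly_from_roots(pd))
  b <- Re(poly_from_roots(zd))
  # normalise to unit gain at the reference frequency
  g <- sum(b * ref^(rev(seq_along(b)) - 1)) / sum(a * ref^(rev(seq_along(a)) - 1))
  b <- b / Re(g)
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Causal IIR filter (direct form, zero initial conditions), vectorised via
# stats::filter: MA part by convolution, AR part recursively.
iir_filter <- function(x, b, a) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nb:(length(x) + nb - 1)]
  if (length(a) > 1) {
    u <- as.numeric(stats::filter(u, -a[-1], method = "recursive"))
  }
  u
}

# Zero-phase filtering: odd-reflection padding, filter forward and backward.
filtfilt_bw <- function(x, b, a, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 3L * 50L * max(length(a), length(b)))
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- iir_filter(c(pre, x, post), b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[(pad + 1):(pad + n)]
}

# ---- Spec-facing preprocessing operations ------------------------------

#' Detect the movement window from a fingertip-speed trace
#'
#' Movement onset `t0` is the first sample at which the speed reaches
#' `fraction` of its maximum and the end `t_end` the last such sample; the
#' analysis window starts 100 ms before onset (clipped at the trace start).
#' Times are in seconds from the first sample (sample k is at `(k-1)/rate`).
#'
#' @param speed numeric speed trace (non-negative, strictly positive max).
#' @param rate sampling rate in Hz.
#' @param fraction threshold as a fraction of the maximum speed
#'   (default 0.05, i.e. 5 percent of peak speed).
#' @return list of class `movement_window` with `t0`, `t_end`,
#'   `analysis_start` (seconds) and the corresponding sample indices.
#' @export
detect_movement_window <- function(speed, rate, fraction = 0.05) {
  stopifnot(rate > 0, fraction > 0, fraction <= 1)
  mx <- max(speed)
  if (!is.finite(mx) || mx <= 0) {
    stop("invalid trial: speed trace has no strictly positive maximum")
  }
  above <- which(speed >= fraction * mx)
  i0 <- above[1]
  i1 <- above[length(above)]
  t0 <- (i0 - 1) / rate
  t_end <- (i1 - 1) / rate
  a_start <- max(0, t0 - 0.1)
  structure(list(t0 = t0, t_end = t_end, analysis_start = a_start,
                 onset_sample = i0, end_sample = i1,
                 analysis_start_sample = max(1L, i0 - as.integer(round(0.1 * rate))),
                 rate = rate),
            class = "movement_window")
}

#' Filter and rectify a raw EMG trace into a smooth envelope
#'
#' High-pass filters the signal at `hp` Hz (removes offsets and motion
#' artifacts), full-wave rectifies, then low-pass filters at `lp` Hz with a
#' zero-phase (forward-backward) Butterworth filter to obtain the
#' activation envelope. Both filters are 4th-order Butterworth applied
#' forward-backward, so no phase distortion is introduced at either stage.
#' The envelope is clipped at zero (the low-pass step can undershoot
#' slightly near sharp transients).
#'
#' @param emg numeric vector or samples-by-channels matrix.
#' @param rate sampling rate (Hz); must exceed twice the high-pass cutoff.
#' @param hp,lp high-/low-pass cutoff frequencies in Hz (defaults 20 and 3).
#' @param order Butterworth order (default 4).
#' @return envelope of the same shape as `emg`, entrywise non-negative.
#' @export
filter_rectify <- function(emg, rate, hp = 20, lp = 3, order = 4) {
  if (rate <= 2 * hp) {
    stop("sampling rate must exceed twice the high-pass cutoff (", 2 * hp, " Hz)")
  }
  hpc <- butter_coefficients(order, hp / (rate / 2), "high")
  lpc <- butter_coefficients(order, lp / (rate / 2), "low")
  one <- function(x) {
    y <- filtfilt_bw(x, hpc$b, hpc$a)
    y <- abs(y)
    y <- filtfilt_bw(y, lpc$b, lpc$a)
    pmax(y, 0)
  }
  if (is.matrix(emg)) apply(emg, 2, one) else one(emg)
}

#' Time-normalize an envelope to a fixed number of bins
#'
#' The envelope over the analysis window is linearly resampled to a uniform
#' 1000-step grid and each of `bins` equal consecutive segments is reduced
#' to its trapezoidal integral, yielding the fixed-duration waveform used by
#' the decomposition. For a constant envelope all bins are equal; bin sums
#' add up to the trapezoidal integral of the whole resampled envelope.
#'
#' @param envelope numeric vector (envelope samples over the window) or a
#'   samples-by-channels matrix.
#' @param bins number of output bins (default 50).
#' @param steps length of the intermediate uniform grid (default 1000
#'   resampling steps, i.e. 1000 intervals).
#' @return numeric vector of length `bins` (or a `bins x channels` matrix).
#' @export
resample_integrate <- function(envelope, bins = 50L, steps = 1000L) {
  one <- function(x) {
    if (length(x) < 2) stop("analysis window must contain at least 2 samples")
    # steps intervals => steps + 1 grid points; bins must divide steps
    stopifnot(steps %% bins == 0)
    g <- approx(seq_along(x), x, n = steps + 1L)$y
    per <- steps / bins
    h <- 1 / steps
    vapply(seq_len(bins), function(s) {
      seg <- g[((s - 1L) * per + 1L):(s * per + 1L)]
      sum((seg[-1] + seg[-length(seg)]) / 2) * h
    }, numeric(1))
  }
  if (is.matrix(envelope)) apply(envelope, 2, one) else one(envelope)
}

#' Normalize trial waveforms by each muscle's experiment-wide maximum
#'
#' Divides every muscle's signal by the maximum value that muscle attains
#' across all trials of the dataset, so each muscle's amplitude is in
#' `[0, 1]` with maximum exactly 1 somewhere in the experiment. The
#' operation is idempotent and invariant to per-muscle gain. Muscles that
#' are zero everywhere are flagged and left at zero.
#'
#' @param trials list of `T x M` non-negative matrices (one per trial).
#' @param labels optional per-trial label table passed through.
#' @return an [emg_dataset()]; attribute `"zero_muscles"` lists indices of
#'   all-zero muscles, if any.
#' @export
amplitude_normalize <- function(trials, labels = NULL) {
  M <- ncol(trials[[1]])
  mx <- rep(0, M)
  for (tr in trials) mx <- pmax(mx, apply(tr, 2, max))
  zero <- which(mx == 0)
  if (length(zero)) {
    warning("muscle(s) with all-zero signal left unscaled: ",
            paste(zero, collapse = ", "))
    mx[zero] <- 1
  }
  scaled <- lapply(trials, function(tr) sweep(tr, 2, mx, "/"))
  out <- emg_dataset(scaled, labels)
  attr(out, "zero_muscles") <- zero
  out
}

#' Flag amplitude-outlier trials
#'
#' Automatic stand-in for visual artifact screening: a trial is flagged
#' when, for any muscle, its maximum exceeds the third quartile of that
#' muscle's per-trial maxima by more than `k` interquartile ranges across
#' the dataset.
#'
#' @param trials list of `T x M` matrices.
#' @param k IQR multiplier (default 3).
#' @return logical vector, `TRUE` for flagged trials.
#' @export
flag_outlier_trials <- function(trials, k = 3) {
  mx <- t(vapply(trials, function(tr) apply(tr, 2, max),
                 numeric(ncol(trials[[1]]))))
  flagged <- rep(FALSE, length(trials))
  for (m in seq_len(ncol(mx))) {
    q <- stats::quantile(mx[, m], c(0.25, 0.75), names = FALSE)
    flagged <- flagged | (mx[, m] > q[2] + k * (q[2] - q[1]))
  }
  flagged
}

#' Run the full preprocessing pipeline on raw trials
#'
#' For each raw trial: detect the movement window from the speed trace,
#' compute the rectified low-pass envelope of every EMG channel, restrict to
#' the analysis window (100 ms before onset through movement end),
#' time-normalize to `bins` bins, and finally normalize amplitudes by each
#' muscle's experiment-wide maximum.
#'
#' @param raw_trials list of raw trials, each a list with `emg`
#'   (samples x M matrix), `speed` (vector) and `rate` (Hz), as produced by
#'   [synthesize_raw_trial()].
#' @param labels optional label table (one row per trial).
#' @param bins number of time bins (default 50).
#' @param hp,lp filter cutoffs in Hz.
#' @param window_fraction speed threshold fraction (default 0.05).
#' @param flag_outliers if `TRUE`, attach a logical attribute
#'   `"outlier_trials"` marking amplitude-outlier trials (see
#'   [flag_outlier_trials()]); off by default.
#' @return an [emg_dataset()] of `bins x M` trial matrices.
#' @export
preprocess_trials <- function(raw_trials, labels = NULL, bins = 50L,
                              hp = 20, lp = 3, window_fraction = 0.05,
                              flag_outliers = FALSE) {
  proc <- lapply(raw_trials, function(rt) {
    win <- detect_movement_window(rt$speed, rt$rate, window_fraction)
    env <- filter_rectify(rt$emg, rt$rate, hp = hp, lp = lp)
    idx <- win$analysis_start_sample:win$end_sample
    resample_integrate(env[idx, , drop = FALSE], bins = bins)
  })
  out <- amplitude_normalize(proc, labels)
  if (flag_outliers) {
    attr(out, "outlier_trials") <- flag_outlier_trials(out$trials)
  }
  out
}
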