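test_that("compute_vaf matches hand-computed values on tiny fixtures", {
  # two 2x2 trials, hand-built rank-1 model
  t1 <- matrix(c(1, 0, 0, 1), 2, 2)
  t2 <- matrix(c(0, 1, 1, 0), 2, 2)
  data <- emg_dataset(list(t1, t2))
  Wt <- matrix(c(1, 0), 2, 1)
  Ws <- matrix(c(1, 0), 1, 2)
  A <- array(1, dim = c(2, 1, 1))
  model <- list(Wt = Wt, Ws = Ws, A = A, K = 1, N = 1)
  # reconstruction for both trials is [[1,0],[0,0]]
  # errors: trial1: 0+0+0+1 = 1 ; trial2: 1+1+1+0 = 3 ; total 4
  # mean pattern mbar = [[.5,.5],[.5,.5]]; each trial deviates by 4*0.25 = 1
  expect_equal(compute_vaf(model, data), 1 - 4 / 2)
  # reconstruction == data gives VAF 1
  perfect <- list(Wt = diag(2), Ws = diag(2), K = 2, N = 2,
                  A = array(c(t1, t2)[c(1, 5, 2, 6, 3, 7, 4, 8)],
                            dim = c(2, 2, 2)))
  expect_equal(compute_vaf(perfect, data), 1)
  # reconstruction == mbar gives VAF 0
  mbar_model <- list(Wt = matrix(c(1, 1), 2, 1) / sqrt(2),
                     Ws = matrix(c(1, 1), 1, 2) / sqrt(2),
                     K = 1, N = 1, A = array(1, dim = c(2, 1, 1)))
  expect_equal(compute_vaf(mbar_model, data), 0, tolerance = 1e-12)
  # identical trials: zero variance is an error
  expect_error(compute_vaf(model, emg_dataset(list(t1, t1))), "undefined")
})

test_that("fitting is monotone, non-negative and deterministic", {
  fx <- small_synthetic(K = 2, N = 2, T_bins = 12, M = 8, reps = 1,
                        emg_noise_sd = 0.05, seed = 3)
  fit <- suppressWarnings(
    fit_space_by_time(fx$ds$emg, 2, 2, restarts = 2, seed = 5, max_iter = 80))
  m <- fit$model
  expect_true(all(m$Wt >= 0) && all(m$Ws >= 0) && all(m$A >= 0))
  # objective trace monotone non-increasing
  expect_true(all(diff(m$trace) <= 1e-8 * m$trace[1]))
  # unit-norm convention
  expect_equal(unname(sqrt(colSums(m$Wt^2))), rep(1, 2), tolerance = 1e-9)
  expect_equal(unname(sqrt(rowSums(m$Ws^2))), rep(1, 2), tolerance = 1e-9)
  # determinism under the same seed
  fit2 <- suppressWarnings(
    fit_space_by_time(fx$ds$emg, 2, 2, restarts = 2, seed = 5, max_iter = 80))
  expect_equal(fit2$model$Wt, m$Wt, tolerance = 1e-12)
  expect_equal(fit2$reconstruction_error, fit$reconstruction_error)
  # invalid data rejected
  bad <- fx$ds$emg
  bad$trials[[1]][1, 1] <- -1
  expect_error(fit_space_by_time(bad, 2, 2, restarts = 1), "non-negative")
  expect_error(fit_space_by_time(fx$ds$emg, 0, 2), "K")
})

test_that("rank-1 data is fit exactly at K = N = 1", {
  set.seed(8)
  u <- runif(10)
  v <- runif(6)
  trials <- lapply(c(1, 2.5, 0.7), function(s) s * tcrossprod(u, v))
  data <- emg_dataset(trials)
  fit <- fit_space_by_time(data, 1, 1, restarts = 3, seed = 2, max_iter = 200)
  expect_gt(fit$vaf, 1 - 1e-6)
  # oracle: best rank-1 non-negative fit of a single positive trial is the
  # (scaled) SVD leading pair; compare reconstruction on trial 1
  expect_equal(reconstruct_trials(fit$model, 1), trials[[1]],
               tolerance = 1e-4)
})

test_that("noiseless planted factors are recovered", {
  # full spatial scale so loadings are identifiable; reduced reps/restarts
  design <- build_task_design()
  truth <- make_ground_truth(2, 3, T_bins = 50, M = 30, seed = 1,
                             emg_noise_sd = 0)
  ds <- synthesize_dataset(truth, design, reps_per_movement = 2, seed = 2,
                           emg_noise_sd = 0)
  fit <- suppressWarnings(
    fit_space_by_time(ds$emg, 2, 3, restarts = 4, seed = 3, max_iter = 400))
  expect_gt(fit$vaf, 0.999)
  mt <- match_synergies(fit$model$Wt, truth$temporal_synergies)
  ms <- match_synergies(t(fit$model$Ws), t(truth$spatial_synergies))
  expect_true(all(mt$cor >= 0.95))
  expect_true(all(ms$cor >= 0.95))
})

test_that("model-order selection finds a planted low-rank plateau", {
  design <- build_task_design()
  truth <- make_ground_truth(2, 2, T_bins = 20, M = 12, seed = 4,
                             coefficient_noise_sigma = 0.05,
                             emg_noise_sd = 0.1,
                             gain_range_temporal = c(0.3, 1.7),
                             gain_range_spatial = c(0.3, 1.7))
  ds <- synthesize_dataset(truth, design, reps_per_movement = 6, seed = 5)
  sel <- suppressWarnings(
    select_model_order(ds$emg, Kmax = 3, Nmax = 3, alpha = 0.05,
                       n_perm = 33, restarts = 3, max_iter = 150, seed = 6))
  expect_equal(c(sel$K, sel$N), c(2, 2))
  expect_false(sel$boundary)
  # shuffled labels: no decoding gain anywhere, returns (1, 1)
  shuffled <- local({
    set.seed(9)
    sample(ds$emg$labels$movement_id)
  })
  sel_null <- suppressWarnings(
    select_model_order(ds$emg, Kmax = 2, Nmax = 2, alpha = 0.05,
                       n_perm = 25, restarts = 2, max_iter = 100, seed = 7,
                       labels = shuffled))
  expect_equal(c(sel_null$K, sel_null$N), c(1, 1))
  # degenerate alpha rejected
  expect_error(select_model_order(ds$emg, alpha = 1), "alpha")
})
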