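test_that("ground-truth construction obeys its contracts", {
  truth <- make_ground_truth(4, 5, T_bins = 50, M = 30, seed = 1)
  expect_true(all(truth$temporal_synergies >= 0))
  expect_true(all(truth$spatial_synergies >= 0))
  expect_equal(length(truth$peaks), 4)
  expect_true(all(diff(truth$peaks) > 0))  # strictly increasing peak bins
  # per-class gains strictly positive and pairwise distinct
  for (tt in c(truth$tuning$temporal, truth$tuning$spatial)) {
    expect_true(all(tt$gains > 0))
    expect_gt(min(diff(sort(tt$gains))), 0.04)
  }
  # determinism
  truth2 <- make_ground_truth(4, 5, T_bins = 50, M = 30, seed = 1)
  expect_identical(truth, truth2)
  # infeasible shapes rejected
  expect_error(make_ground_truth(10, 3, T_bins = 15), "T_bins")
  expect_error(make_ground_truth(2, 12, M = 10), "M must")
})

test_that("trial coefficients follow the tuning map", {
  design <- build_task_design()
  truth <- make_ground_truth(3, 4, T_bins = 20, M = 12, seed = 2,
                             coefficient_noise_sigma = 0, design = design)
  m1 <- design$movements[1, ]
  A1 <- sample_trial_coefficients(truth, m1)
  expect_true(all(A1 > 0))
  expect_equal(A1, mean_trial_coefficients(truth, m1))
  # coefficients change only where a tuned parameter's class changes
  m2 <- design$movements[2, ]  # same start target as movement 1
  A2 <- sample_trial_coefficients(truth, m2)
  tpar <- vapply(truth$tuning$temporal, `[[`, "", "parameter")
  spar <- vapply(truth$tuning$spatial, `[[`, "", "parameter")
  for (i in seq_len(truth$K)) {
    for (j in seq_len(truth$N)) {
      changed <- !identical(m1[[tpar[i]]], m2[[tpar[i]]]) ||
        !identical(m1[[spar[j]]], m2[[spar[j]]])
      if (changed) {
        expect_false(isTRUE(all.equal(A1[i, j], A2[i, j])))
      } else {
        expect_equal(A1[i, j], A2[i, j])
      }
    }
  }
})

test_that("lognormal coefficient noise has the stated moments", {
  design <- build_task_design()
  truth <- make_ground_truth(2, 2, T_bins = 10, M = 6, seed = 3,
                             coefficient_noise_sigma = 0.2, design = design)
  m <- design$movements[5, ]
  mu <- mean_trial_coefficients(truth, m)
  n <- 10000
  draws <- with(list(), {
    set.seed(42)
    replicate(n, sample_trial_coefficients(truth, m)[1, 1])
  })
  # log a ~ N(log mu, sigma^2): sample mean of logs within 3 SE
  se <- 0.2 / sqrt(n)
  expect_lt(abs(mean(log(draws)) - log(mu[1, 1])), 3 * se)
  expect_lt(abs(sd(log(draws)) - 0.2), 0.01)
})

test_that("synthesized datasets honour the protocol and the planted model", {
  fx <- small_synthetic(K = 2, N = 2, T_bins = 10, M = 6, reps = 2,
                        emg_noise_sd = 0)
  ds <- fx$ds
  expect_equal(ds$emg$L, 144)
  expect_true(all(vapply(ds$emg$trials, function(tr) all(tr >= 0), logical(1))))
  # labels aligned and complete
  expect_equal(names(ds$emg$labels),
               c("trial_id", "movement_id", task_parameter_names()))
  expect_equal(as.integer(table(ds$emg$labels$movement_id)), rep(2L, 72))
  # noiseless trials equal the planted factorisation exactly
  for (l in c(1, 50, 144)) {
    recon <- fx$truth$temporal_synergies %*% ds$coefficients[l, , ] %*%
      fx$truth$spatial_synergies
    expect_equal(ds$emg$trials[[l]], recon, tolerance = 1e-12)
  }
  # planted model has VAF exactly 1 on its own noiseless data
  model <- truth_as_model(fx$truth, ds$coefficients)
  expect_equal(compute_vaf(model, ds$emg), 1, tolerance = 1e-12)
})

test_that("synthesis is deterministic and noise respects non-negativity", {
  fx1 <- small_synthetic(K = 2, N = 2, T_bins = 10, M = 6, reps = 1,
                         emg_noise_sd = 0.1, seed = 7)
  fx2 <- small_synthetic(K = 2, N = 2, T_bins = 10, M = 6, reps = 1,
                         emg_noise_sd = 0.1, seed = 7)
  expect_identical(fx1$ds$emg$labels, fx2$ds$emg$labels)
  expect_identical(fx1$ds$emg$trials, fx2$ds$emg$trials)
  expect_true(all(vapply(fx1$ds$emg$trials, min, numeric(1)) >= 0))
})

test_that("redrawn subjects share tuning but not loadings", {
  truth <- make_ground_truth(3, 4, T_bins = 20, M = 30, seed = 5)
  truth2 <- redraw_spatial_synergies(truth, seed = 99)
  expect_identical(truth$tuning, truth2$tuning)
  expect_identical(truth$temporal_synergies, truth2$temporal_synergies)
  expect_false(identical(truth$spatial_synergies, truth2$spatial_synergies))
})
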