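test_that("functional similarity matrix has the stated structure", {
  set.seed(1)
  D1 <- matrix(runif(16), 4, 4)
  D1 <- D1 / rowSums(D1)
  D2 <- D1[c(2, 1, 3, 4), ]           # permuted rows
  sim <- functional_similarity_matrix(list(D1, D1, D2))
  expect_equal(diag(sim$r), rep(1, 3))
  expect_equal(sim$r, t(sim$r))
  expect_equal(sim$r[1, 2], 1)         # identical matrices correlate at 1
  # hand-evaluated Pearson on the vectorised matrices
  expect_equal(sim$r[1, 3], cor(as.vector(D1), as.vector(D2)),
               tolerance = 1e-12)
  # vectorisation length: 72 classes -> 5184 elements
  cms <- replicate(2, {
    m <- matrix(runif(72 * 72), 72, 72)
    m / rowSums(m)
  }, simplify = FALSE)
  expect_equal(functional_similarity_matrix(cms)$vector_length, 5184)
  # degenerate constant confusion: similarity undefined, recorded NA
  flat <- matrix(1 / 4, 4, 4)
  simd <- functional_similarity_matrix(list(D1, flat))
  expect_true(is.na(simd$r[1, 2]))
})

test_that("complete-linkage tree matches hand and brute-force oracles", {
  # 3-item hand case: d(1,2)=0.1, d(1,3)=0.9, d(2,3)=0.8
  r3 <- 1 - rbind(c(0, 0.1, 0.9), c(0.1, 0, 0.8), c(0.9, 0.8, 0))
  diag(r3) <- 1
  tree <- build_tree(r3)
  expect_equal(sort(tree$height), c(0.1, 0.9), tolerance = 1e-12)
  expect_true(all(diff(tree$height) >= 0))    # ultrametric monotonicity
  # brute-force oracle on random distance matrices up to 8 items
  set.seed(2)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.05, 1.9)
    D <- D + t(D)
    oracle <- oracle_complete_linkage(D)
    tr <- build_tree(1 - D)
    expect_equal(sort(tr$height), oracle$heights, tolerance = 1e-10)
    for (h in c(0.3, 0.8, 1.4)) {
      expect_true(same_partition(cutree(tr, h = h), oracle$cut(h)))
    }
  }
})

test_that("cut_and_summarize labels singletons and averages members", {
  r <- diag(1, 4)
  r[1, 2] <- r[2, 1] <- 0.9            # 1,2 tightly similar
  r[3, 4] <- r[4, 3] <- 0.85           # 3,4 similar
  r[1, 3] <- r[3, 1] <- r[1, 4] <- r[4, 1] <- 0.1
  r[2, 3] <- r[3, 2] <- r[2, 4] <- r[4, 2] <- 0.05
  tree <- build_tree(r)
  cm <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  cs <- cut_and_summarize(tree, cutoff = 0.5,
                          synergies = list(1:3, 1:3, c(5, 5, 5), c(7, 7, 7)),
                          confusions = list(cm, cm, cm, cm))
  expect_equal(cs$n_clusters, 2)
  expect_true(same_partition(ifelse(is.na(cs$assignments), 99,
                                    cs$assignments), c(1, 1, 2, 2)))
  # cluster of identical synergies averages to the member
  expect_equal(cs$summaries[[1]]$mean_synergy, 1:3)
  expect_equal(cs$summaries[[2]]$mean_synergy, c(6, 6, 6))
  # averaged confusion stays row-stochastic
  expect_equal(unname(rowSums(cs$summaries[[1]]$mean_confusion)), c(1, 1))
  # cutoff above the root: one cluster with everything
  cs_all <- cut_and_summarize(tree, cutoff = 2)
  expect_equal(cs_all$n_clusters, 1)
  expect_equal(sum(is.na(cs_all$assignments)), 0)
  # cutoff below all merges: everything unclustered, with a warning
  expect_warning(cs_none <- cut_and_summarize(tree, cutoff = 0.01),
                 "unclustered")
  expect_true(all(is.na(cs_none$assignments)))
})

test_that("functional clustering groups shared-tuning synergies across subjects", {
  # 3 subjects, same tuning map, redrawn spatial loadings; decode the
  # 72-class movement from the planted coefficients of each spatial synergy
  design <- build_task_design()
  truth <- make_ground_truth(4, 5, T_bins = 50, M = 30, seed = 21,
                             emg_noise_sd = 0.02, design = design)
  subs <- synthesize_subjects(truth, 3, design, reps_per_movement = 10,
                              seed = 22)
  confs <- list()
  grp <- integer(0)
  loadings <- list()
  for (s in seq_along(subs)) {
    model <- truth_as_model(subs[[s]]$truth, subs[[s]]$coefficients)
    confs <- c(confs,
               decode_synergies(model, subs[[s]]$emg$labels$movement_id,
                                "spatial"))
    grp <- c(grp, seq_len(5))
    loadings <- c(loadings, lapply(seq_len(5), function(j)
      subs[[s]]$truth$spatial_synergies[j, ]))
  }
  # same-tuning loadings are dissimilar in shape across subjects
  cross_cor <- c()
  for (j in 1:5) {
    for (a in 1:2) for (b in (a + 1):3) {
      cross_cor <- c(cross_cor, cor(loadings[[(a - 1) * 5 + j]],
                                    loadings[[(b - 1) * 5 + j]]))
    }
  }
  expect_lt(max(cross_cor), 0.5)
  cl <- cluster_synergies(confs, cutoff = 0.6)
  lab <- ifelse(is.na(cl$assignments), -seq_along(cl$assignments),
                cl$assignments)
  expect_equal(adjusted_rand_index(lab, grp), 1)
  # loading-shape clustering at the same cutoff does NOT recover the groups
  r_load <- cor(t(do.call(rbind, loadings)))
  cl_load <- cut_and_summarize(build_tree(r_load), cutoff = 0.6)
  lab_load <- ifelse(is.na(cl_load$assignments), -seq_along(cl_load$assignments),
                     cl_load$assignments)
  expect_lt(adjusted_rand_index(lab_load, grp), 1)
})
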