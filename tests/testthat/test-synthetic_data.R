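test_that("preset module frequencies are biased in the expected order", {
  f <- gen_module_frequencies(5, seed = 1)
  p <- setNames(f$frequency, f$fluorophore)
  expect_true(all(p > 0 & p < 1))
  expect_gt(p[["G"]], p[["A"]])  # mNeonGreen most recombinogenic
  expect_gt(p[["A"]], p[["K"]])
  expect_gt(p[["K"]], max(p[["T"]], p[["O"]]))  # mTFP1 and mKO2 lowest

  # deterministic given the seed
  expect_identical(f, gen_module_frequencies(5, seed = 1))
  expect_false(identical(f$frequency, gen_module_frequencies(5, seed = 9)$frequency))

  # explicit values pass through unchanged
  v <- gen_module_frequencies(5, values = c(0.5, 0.4, 0.3, 0.2, 0.1))
  expect_equal(v$frequency, c(0.5, 0.4, 0.3, 0.2, 0.1))

  # 15-bit preset labels three compartments
  f15 <- gen_module_frequencies(15, seed = 1)
  expect_equal(unique(f15$compartment), c("membrane", "nucleus", "golgi"))
})

test_that("cluster generation respects the activation rate and seed", {
  f <- gen_module_frequencies(5, seed = 3)
  full <- gen_cluster_table(f, brains = 3, lineages_per_brain = 40,
                            activation_rate = 1, seed = 5)
  expect_equal(nrow(full), 3 * 40)
  expect_equal(unname(table(full$brain_id)), rep(40L, 3), ignore_attr = TRUE)

  again <- gen_cluster_table(f, brains = 3, lineages_per_brain = 40,
                             activation_rate = 1, seed = 5)
  expect_identical(as.data.frame(full), as.data.frame(again))

  truth <- attr(full, "truth")
  expect_true(all(truth$labeled))
  expect_identical(sort(truth$code[truth$labeled]), sort(full$code))
})

test_that("module frequencies are recovered from a large synthetic table", {
  rec <- recovery_cluster_table()
  expect_gt(nrow(rec$clusters), 45000)
  est <- estimate_module_frequencies(rec$clusters)
  target <- conditional_marginals(rec$freqs$frequency)
  expect_true(all(abs(est$pooled - target) <= 0.01))
})

test_that("generated repeat rates match the analytic birthday expectation", {
  f <- gen_module_frequencies(5, seed = 3)
  dist <- build_code_distribution(f)
  clusters <- gen_cluster_table(f, brains = 30, lineages_per_brain = 80,
                                activation_rate = 1, seed = 6)
  per_brain <- cluster_collision_summary(clusters)$per_brain
  expect_equal(per_brain$n_clusters, rep(80L, 30))
  ana <- expected_collision_rate_general(dist, 80)$rate
  se <- sd(per_brain$repeat_rate) / sqrt(nrow(per_brain))
  expect_lt(abs(mean(per_brain$repeat_rate) - ana), 3 * se)
})

test_that("the sampled code distribution converges to the enumerated one", {
  d <- biased_dist_5()
  set.seed(61)
  draws <- sample_codes(d, 100000)
  emp <- as.numeric(table(factor(draws, levels = d$code))) / 100000
  tv <- sum(abs(emp - d$prob)) / 2
  expect_lt(tv, 0.02)
})

test_that("mixing matrices are diagonal-dominant with unit column sums", {
  M0 <- gen_mixing_matrix(C = 5, bleed = 0)
  expect_equal(unname(M0), diag(5), ignore_attr = TRUE)

  M <- gen_mixing_matrix(C = 8, bleed = 0.3)
  expect_equal(unname(colSums(M)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(M >= 0))
  expect_true(is.finite(attr(M, "kappa")))
  # each fluorophore keeps the majority of its signal in one channel
  expect_equal(unname(apply(M, 2, max)), rep(0.7, 5), tolerance = 1e-12)
})

test_that("labeled volumes are pure functions of seed and config", {
  a <- gen_labeled_volume(n_cells = 6, bleed = 0.1, noise_sd = 0.05, seed = 9,
                          cell_box = c(14, 10, 8))
  b <- gen_labeled_volume(n_cells = 6, bleed = 0.1, noise_sd = 0.05, seed = 9,
                          cell_box = c(14, 10, 8))
  expect_identical(a$volume, b$volume)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)

  c2 <- gen_labeled_volume(n_cells = 6, bleed = 0.1, noise_sd = 0.05, seed = 10,
                           cell_box = c(14, 10, 8))
  expect_false(identical(a$volume, c2$volume))

  expect_error(gen_labeled_volume(n_cells = 4, cell_box = c(6, 6, 6)),
               "too small")
})

test_that("the noiseless limit is called perfectly and traces stay in range", {
  vol <- gen_labeled_volume(n_cells = 12, bleed = 0, noise_sd = 0, seed = 12)
  calls <- call_codes_from_volume(vol$volume, vol$traces, vol$mixing,
                                  thresholds = 0.1)
  expect_identical(calls$code, vol$truth$code)

  dims <- dim(vol$volume)
  for (tr in vol$traces) {
    expect_true(all(tr$x >= 1 & tr$x <= dims[1]))
    expect_true(all(tr$y >= 1 & tr$y <= dims[2]))
    expect_true(all(tr$z >= 1 & tr$z <= dims[3]))
    expect_identical(tr$type[1], 1L)        # soma first
    expect_true(all(tr$type[-1] == 3L))     # then neurite
    expect_identical(tr$parent[1], -1L)
  }
})
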