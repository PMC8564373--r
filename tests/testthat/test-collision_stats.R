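test_that("the uniform closed form reproduces the design-capacity collision rates", {
  # 200 lineages against the 5-, 10-, and 15-bit pools
  expect_equal(percent1(expected_collision_rate_uniform(31, 200)$rate), 84.5)
  expect_equal(percent1(expected_collision_rate_uniform(1023, 200)$rate), 9.1)
  expect_equal(percent1(expected_collision_rate_uniform(32767, 200)$rate), 0.3)

  # a single draw cannot collide; zero draws define rate 0
  expect_equal(expected_collision_rate_uniform(1023, 1)$rate, 0)
  expect_equal(expected_collision_rate_uniform(1023, 0)$rate, 0)
})

test_that("the general analytic rate reduces to the closed form and to enumeration", {
  u <- uniform_code_distribution(5)
  expect_equal(expected_collision_rate_general(u, 200)$rate,
               expected_collision_rate_uniform(31, 200)$rate,
               tolerance = 1e-12)

  # point mass: 10 draws, 1 distinct code
  pm <- build_code_distribution(c(1, 0, 0, 0, 0))
  expect_equal(expected_collision_rate_general(pm, 10)$rate, 0.9)

  # two equiprobable codes, two draws: collide with probability 1/2,
  # E[distinct] = 1.5, rate = 0.25
  d2 <- new_toy_distribution(c(0.5, 0.5))
  expect_equal(expected_collision_rate_general(d2, 2)$rate, 0.25)
})

test_that("the analytic rate equals brute-force tuple enumeration on small pools", {
  set.seed(31)
  for (rep in 1:6) {
    b <- sample(2:4, 1)
    n <- sample(2:5, 1)
    probs <- runif(b)
    probs <- probs / sum(probs)
    d <- new_toy_distribution(probs)
    expect_equal(expected_collision_rate_general(d, n)$rate,
                 brute_force_collision_rate(probs, n),
                 tolerance = 1e-12)
  }
})

test_that("Monte Carlo collision rates agree with the analytic expectation", {
  # uniform 31-code pool at the full central-brain lineage count
  u <- uniform_code_distribution(5)
  s <- simulate_collision_rate(u, 200, reps = 2000, seed = 41)
  expect_lt(abs(s$rate - expected_collision_rate_uniform(31, 200)$rate),
            3 * s$se)

  # skewed distribution, oracle equivalence at 10,000 reps
  d <- biased_dist_5()
  g <- expected_collision_rate_general(d, 50)
  s2 <- simulate_collision_rate(d, 50, reps = 10000, seed = 42)
  expect_lt(abs(s2$rate - g$rate), 3 * s2$se)

  # one draw can never collide
  expect_equal(simulate_collision_rate(d, 1, reps = 100, seed = 1)$rate, 0)

  # seeded determinism
  a <- simulate_collision_rate(d, 30, reps = 500, seed = 7)
  b <- simulate_collision_rate(d, 30, reps = 500, seed = 7)
  expect_identical(a$rate, b$rate)
})

test_that("whitelisting a skewed pool lowers the collision rate", {
  d <- biased_dist_15()
  full <- expected_collision_rate_general(d, 200)$rate
  wl <- whitelist_exclude_top(d, 767)
  restricted <- expected_collision_rate_general(d, 200, whitelist = wl)$rate
  expect_lt(restricted, full)

  # and the simulated means agree within Monte Carlo error
  s_full <- simulate_collision_rate(d, 200, reps = 400, seed = 9)
  s_wl <- simulate_collision_rate(d, 200, reps = 400, seed = 9, whitelist = wl)
  expect_lt(s_wl$rate, s_full$rate + 3 * (s_full$se + s_wl$se))

  # the discard interpretation also runs and lands in [0, 1]
  s_d <- simulate_collision_rate(d, 100, reps = 50, seed = 9, whitelist = wl,
                                 whitelist_method = "discard")
  expect_gte(s_d$rate, 0)
  expect_lte(s_d$rate, 1)
})

test_that("collision rates are monotone in draws and pool size", {
  rates_n <- vapply(c(1, 10, 50, 200, 1000), function(n) {
    expected_collision_rate_uniform(1023, n)$rate
  }, numeric(1))
  expect_true(all(diff(rates_n) >= 0))

  rates_b <- vapply(c(31, 127, 1023, 32767), function(b) {
    expected_collision_rate_uniform(b, 200)$rate
  }, numeric(1))
  expect_true(all(diff(rates_b) <= 0))
})

test_that("the default replicate schedule follows the size tiers", {
  expect_identical(default_collision_reps(50), 100000L)
  expect_identical(default_collision_reps(99), 100000L)
  expect_identical(default_collision_reps(100), 1000L)
  expect_identical(default_collision_reps(1000), 1000L)
  expect_identical(default_collision_reps(5000), 10L)
})

test_that("cluster-level collision summaries count code sharing within brains", {
  one <- tibble::tibble(
    brain_id = "b1", cluster_id = 1:4,
    code = c("10000", "10000", "01000", "00100")
  )
  cs <- cluster_collision_summary(one)
  pb <- cs$per_brain
  expect_equal(pb$frac_unique, 0.5)
  expect_equal(pb$frac_pair, 0.5)
  expect_equal(pb$frac_multi, 0)
  expect_equal(pb$collision_rate, 0.5)
  expect_equal(pb$repeat_rate, 1 / 4)  # 4 clusters, 3 distinct codes

  all_distinct <- tibble::tibble(brain_id = "b1", cluster_id = 1:3,
                                 code = c("10000", "01000", "00100"))
  expect_equal(cluster_collision_summary(all_distinct)$per_brain$collision_rate, 0)

  mono <- tibble::tibble(brain_id = "b1", cluster_id = 1:5, code = "10000")
  pbm <- cluster_collision_summary(mono)$per_brain
  expect_equal(pbm$frac_multi, 1)
  expect_equal(pbm$collision_rate, 1)
})

test_that("sharing is assessed within each brain separately and fractions sum to 1", {
  set.seed(13)
  clusters <- gen_cluster_table(gen_module_frequencies(5, seed = 3),
                                brains = 4, lineages_per_brain = 60,
                                activation_rate = 0.9, seed = 13)
  cs <- cluster_collision_summary(clusters)$per_brain
  expect_equal(cs$frac_unique + cs$frac_pair + cs$frac_multi, rep(1, 4))

  oc <- code_occupancy_summary(clusters)$per_brain
  expect_equal(oc$frac_in1 + oc$frac_in2 + oc$frac_in3plus, rep(1, 4))

  # a code shared across two brains does not collide in either
  split <- tibble::tibble(brain_id = c("b1", "b2"), cluster_id = 1,
                          code = "10000")
  expect_equal(cluster_collision_summary(split)$per_brain$collision_rate, c(0, 0))
})

test_that("code occupancy counts clusters per distinct code", {
  tab <- tibble::tibble(brain_id = "b1", cluster_id = 1:4,
                        code = c("10000", "10000", "01000", "00100"))
  oc <- code_occupancy_summary(tab)$per_brain
  expect_equal(oc$n_codes, 3L)
  expect_equal(oc$frac_in1, 2 / 3)
  expect_equal(oc$frac_in2, 1 / 3)
  expect_equal(oc$frac_in3plus, 0)

  mono <- tibble::tibble(brain_id = "b1", cluster_id = 1:5, code = "10000")
  expect_equal(code_occupancy_summary(mono)$per_brain$frac_in3plus, 1)
})

test_that("the labeling rate is clusters over brains times lineages", {
  expect_equal(percent1(labeling_rate(lineages_per_brain = 200, n_brains = 6,
                                      n_clusters = 577)) , 48.1)
  expect_equal(round(100 * labeling_rate(lineages_per_brain = 200, n_brains = 6,
                                         n_clusters = 577), 2), 48.08)
  expect_equal(labeling_rate(lineages_per_brain = 200, n_brains = 6,
                             n_clusters = 0), 0)
  expect_equal(labeling_rate(lineages_per_brain = 10, n_brains = 3,
                             n_clusters = 30), 1)
  tab <- tibble::tibble(brain_id = rep(c("b1", "b2"), each = 3),
                        cluster_id = rep(1:3, 2), code = "10000")
  expect_equal(labeling_rate(tab, lineages_per_brain = 3), 1)
  expect_error(labeling_rate(tab, lineages_per_brain = 0), ">= 1")
})

test_that("cluster tables are validated", {
  bad <- tibble::tibble(brain_id = "b1", cluster_id = c(1, 1),
                        code = c("10000", "01000"))
  expect_error(cluster_collision_summary(bad), "unique")
  zero <- tibble::tibble(brain_id = "b1", cluster_id = 1, code = "00000")
  expect_error(cluster_collision_summary(zero), "all-zero")
})
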