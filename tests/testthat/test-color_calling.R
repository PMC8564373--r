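test_that("unmixing recovers abundances from clean mixtures", {
  M <- diag(5)
  y <- c(3, 1, 0, 2, 0.5)
  expect_equal(unmix(y, M), setNames(y, NULL), ignore_attr = TRUE)
  expect_equal(unname(unmix(rep(0, 5), M)), rep(0, 5))

  # bleed-through mixture, exact recovery of a single-fluorophore pixel
  Mb <- gen_mixing_matrix(C = 5, bleed = 0.3)
  a_true <- c(1, 0, 0, 0, 0)
  y2 <- as.vector(Mb %*% a_true)
  expect_equal(unname(unmix(y2, Mb)), a_true, tolerance = 1e-9)

  # matrix of pixels, more channels than fluorophores
  M8 <- gen_mixing_matrix(C = 8, bleed = 0.2)
  A_true <- matrix(runif(10 * 5), 10, 5)
  Y <- A_true %*% t(M8)
  expect_equal(unname(unmix(Y, M8)), A_true, tolerance = 1e-8)
})

test_that("nonnegative and clamped solvers differ only where negativity binds", {
  Mb <- gen_mixing_matrix(C = 5, bleed = 0.25)
  set.seed(51)
  A_true <- matrix(runif(50 * 5), 50, 5) * matrix(rbinom(250, 1, 0.5), 50, 5)
  Y <- A_true %*% t(Mb) + matrix(rnorm(250, 0, 0.02), 50, 5)
  Y[Y < 0] <- 0
  a_nnls <- unmix(Y, Mb, method = "nnls")
  a_ls <- unmix(Y, Mb, method = "ls")
  expect_true(all(a_nnls >= 0))
  expect_true(all(a_ls >= 0))
  # NNLS residuals are never worse than clamped least squares
  r_nnls <- rowSums((Y - a_nnls %*% t(Mb))^2)
  r_ls <- rowSums((Y - a_ls %*% t(Mb))^2)
  expect_true(all(r_nnls <= r_ls + 1e-10))
})

test_that("degenerate reference spectra are rejected with a condition report", {
  M <- cbind(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0), diag(5)[, 3:5])
  expect_error(unmix(rep(1, 5), M), "condition number")
  expect_error(validate_mixing_matrix(matrix(-1, 5, 5)), "nonnegative")
  expect_error(validate_mixing_matrix(cbind(diag(4), 0)), "all-zero")
})

test_that("unmixing then remixing reproduces noiseless input", {
  Mb <- gen_mixing_matrix(C = 6, bleed = 0.15)
  set.seed(52)
  A_true <- matrix(runif(20 * 5), 20, 5)
  Y <- A_true %*% t(Mb)
  A_hat <- unmix(Y, Mb)
  expect_equal(unname(A_hat %*% t(Mb)), Y, tolerance = 1e-9)
})

test_that("smoothing preserves constants and removes isolated impulses", {
  const <- matrix(2, 30, 5)
  expect_equal(smooth_trace(const), const, ignore_attr = TRUE)

  x <- rep(1, 31)
  x[16] <- 100  # single impulse
  sm <- smooth_trace(matrix(x, ncol = 1))
  expect_equal(as.vector(sm), rep(1, 31))
})

test_that("a rolling window engulfing the series yields the global mean", {
  short <- matrix(c(1, 2, 3, 10), ncol = 1)
  sm <- smooth_trace(short, roll_window = 10)
  expect_equal(as.vector(sm), rep(4, 4))
})

test_that("smoothing never widens a channel's range", {
  set.seed(53)
  for (rep in 1:10) {
    x <- matrix(rlnorm(40 * 3), 40, 3)
    sm <- smooth_trace(x)
    for (ch in 1:3) {
      expect_gte(min(sm[, ch]), min(x[, ch]) - 1e-12)
      expect_lte(max(sm[, ch]), max(x[, ch]) + 1e-12)
    }
  }
})

test_that("volume-backed smoothing takes 3x3x3 neighborhood medians", {
  vol <- array(1, dim = c(7, 7, 7, 2))
  vol[4, 4, 4, 1] <- 50  # impulse at the node itself
  coords <- matrix(c(4, 4, 4), 1, 3)
  sm <- smooth_trace(coords = coords, volume = vol)
  expect_equal(as.vector(sm), c(1, 1))  # median ignores the impulse

  expect_error(smooth_trace(coords = matrix(c(9, 4, 4), 1, 3), volume = vol),
               "node 1")
})

test_that("sum-normalization scales colors onto the simplex", {
  expect_equal(unname(normalize_channels(c(2, 1, 1, 0, 0))[1:5]),
               c(0.5, 0.25, 0.25, 0, 0), ignore_attr = TRUE)

  # scaling invariance
  v <- c(0.3, 0.1, 0, 0.2, 0.4)
  expect_equal(normalize_channels(5 * v)[1:5], normalize_channels(v)[1:5],
               ignore_attr = TRUE)

  # idempotence
  once <- normalize_channels(v)
  expect_equal(normalize_channels(once[1:5])[1:5], once[1:5], ignore_attr = TRUE)

  # zero vector is background, negative input is an error
  bg <- normalize_channels(rep(0, 5))
  expect_true(attr(bg, "background"))
  expect_true(all(is.na(bg[1:5])))
  expect_error(normalize_channels(c(-1, 1, 1, 1, 1)), "nonnegative")

  # pixels under the floor are flagged, others normalized
  m <- normalize_channels(rbind(c(10, 0, 0, 0, 0), rep(0.001, 5)), eps = 0.1)
  expect_identical(attr(m, "background"), c(FALSE, TRUE))
  expect_equal(m[1, ], c(1, 0, 0, 0, 0))
})

test_that("bits are called against fixed thresholds with ties ON", {
  calls <- call_bits(c(0.5, 0.45, 0.02, 0.02, 0.01), thresholds = 0.1)
  expect_identical(calls$code, "11000")

  # aggregate exactly at threshold counts as ON
  tie <- call_bits(c(0.1, 0.05, 0, 0, 0), thresholds = 0.1)
  expect_identical(tie$bits[1, ], c(1L, 0L, 0L, 0L, 0L))

  # margins report distance to threshold per channel
  expect_equal(calls$margins[1, 1], 0.4)
})

test_that("auto-thresholding separates two-population channels without miscalls", {
  set.seed(54)
  n <- 200
  bits_true <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  bits_true[rowSums(bits_true) == 0, 1] <- 1L
  agg <- matrix(rnorm(n * 5, 0.02, 0.003), n, 5)
  agg[bits_true == 1] <- rnorm(sum(bits_true), 0.4, 0.03)
  agg[agg < 0] <- 0
  calls <- call_bits(agg, thresholds = "auto")
  expect_identical(calls$bits, bits_true)
  expect_true(all(attr(calls$thresholds, "auto")))
})

test_that("unimodal channels fall back to the fixed threshold", {
  set.seed(55)
  agg <- cbind(rnorm(100, 0.4, 0.02), matrix(rnorm(400, 0.4, 0.02), 100, 4))
  agg[agg < 0] <- 0
  calls <- call_bits(agg, thresholds = "auto", fallback = 0.1)
  expect_equal(as.numeric(calls$thresholds), rep(0.1, 5))
})

test_that("aggregation drops background pixels and rejects unlabeled cells", {
  px <- rbind(c(0.5, 0.5, 0, 0, 0), c(NA, NA, NA, NA, NA),
              c(0.4, 0.6, 0, 0, 0))
  expect_equal(aggregate_cell(px), c(0.45, 0.55, 0, 0, 0))
  expect_error(aggregate_cell(px[2, , drop = FALSE]), "unlabeled")
})

test_that("soma/neurite consistency uses per-channel median differences", {
  s <- matrix(rep(c(0.5, 0.5, 0, 0, 0), each = 10), 10, 5)
  expect_equal(consistency_stats(s, s)$distance, 0)

  nrt <- matrix(rep(c(0.4, 0.6, 0, 0, 0), each = 10), 10, 5)
  cs <- consistency_stats(s, nrt)
  expect_equal(cs$per_channel, c(0.1, 0.1, 0, 0, 0))
  expect_equal(cs$distance, 0.1)

  expect_error(consistency_stats(s[0, ], nrt), "nonempty")
})

test_that("neurites map back to their own somas when colors are distinct", {
  set.seed(56)
  colors <- normalize_channels(matrix(runif(21 * 5, 0.05, 1), 21, 5))
  cells <- lapply(seq_len(21), function(i) {
    base <- colors[i, ]
    jitter <- function() {
      m <- pmax(matrix(rep(base, each = 15), 15, 5) +
                  matrix(rnorm(75, 0, 0.005), 15, 5), 0)
      m / rowSums(m)
    }
    list(soma = jitter(), neurite = jitter())
  })
  res <- neurite_assignment(cells)
  expect_equal(res$accuracy, 1)
})

test_that("the full pipeline recovers ground-truth codes from noisy volumes", {
  run <- noisy_volume_run()
  acc <- mean(run$calls$code == run$truth$code)
  expect_gte(acc, 0.95)

  clean <- noiseless_volume_run()
  expect_equal(mean(clean$calls$code == clean$truth$code), 1)
})
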