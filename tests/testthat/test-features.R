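test_that("delay embedding lays out lagged coordinates", {
  ps <- delay_embed(c(1, 2, 3, 4), m = 2, tau = 1)
  expect_equal(unclass(ps)[, ], cbind(c(1, 2, 3), c(2, 3, 4)), ignore_attr = TRUE)
  expect_equal(as.numeric(delay_embed(5:9, m = 1, tau = 3)), 5:9)
  expect_error(delay_embed(1:5, m = 3, tau = 3), "too short")
  set.seed(1)
  x <- rnorm(64)
  for (m in 1:4) {
    for (tau in 1:5) {
      expect_equal(nrow(delay_embed(x, m, tau)), 64 - (m - 1) * tau)
    }
  }
})

test_that("correlation dimension matches known geometries", {
  set.seed(2)
  line <- cbind(runif(500), 0.5) # 1-D set in the plane
  expect_equal(correlation_dimension(line), 1, tolerance = 0.1)
  square <- cbind(runif(500), runif(500))
  expect_equal(correlation_dimension(square), 2, tolerance = 0.15)
  expect_equal(correlation_dimension(matrix(1, 200, 2)), 0)
})

test_that("Higuchi fractal dimension spans smooth to noise", {
  expect_equal(higuchi_fd(seq(0, 1, length.out = 2000)), 1, tolerance = 0.05)
  set.seed(3)
  fd_noise <- mean(vapply(1:20, function(i) higuchi_fd(rnorm(4096)), 0))
  expect_equal(fd_noise, 2, tolerance = 0.1)
  fd_sine <- higuchi_fd(sin(2 * pi * 5 * seq(0, 1, length.out = 2000)))
  expect_gt(fd_sine, 1)
  expect_lt(fd_sine, 1.5)
})

test_that("largest Lyapunov exponent separates regular from chaotic", {
  t <- seq(0, 10, length.out = 1000)
  ps_sine <- delay_embed(sin(2 * pi * t), m = 2, tau = 10)
  expect_lt(abs(largest_lyapunov(ps_sine, fs = 1)), 0.05)
  # fully developed logistic map: exponent ln 2 per step
  x <- numeric(800)
  x[1] <- 0.3
  for (i in 1:799) x[i + 1] <- 4 * x[i] * (1 - x[i])
  ps <- delay_embed(x, m = 2, tau = 1)
  expect_equal(largest_lyapunov(ps, fs = 1, theiler = 2), log(2), tolerance = 0.1)
  set.seed(4)
  ps_noise <- delay_embed(rnorm(600), m = 2, tau = 1)
  expect_gt(largest_lyapunov(ps_noise, fs = 1), 0)
})

test_that("sample entropy matches brute-force template counting", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(60)
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.4)
    counts <- oracle_sampen(x, m, r * sd(x))
    expected <- if (counts["B"] == 0) 0 else -log(counts["A"] / counts["B"])
    if (counts["A"] == 0 && counts["B"] > 0) expected <- log(counts["B"])
    expect_equal(sample_entropy(x, m, r), unname(expected))
  }
})

test_that("sample entropy has the expected structural behavior", {
  expect_equal(sample_entropy(rep(3, 100)), 0)
  expect_equal(sample_entropy(rep(c(1, 2), 50), m = 2, r = 0.2), 0)
  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(200)
    expect_gte(sample_entropy(sample(x), 2, 0.2) + 1e-9,
               sample_entropy(sort(x), 2, 0.2))
  }
})

test_that("recurrence matrices match brute-force distance thresholding", {
  set.seed(7)
  ps <- matrix(rnorm(40), 20, 2)
  eps <- 0.8
  R <- recurrence_matrix(ps, eps)
  for (i in 1:20) {
    for (j in 1:20) {
      expect_equal(R[i, j],
                   as.integer(sqrt(sum((ps[i, ] - ps[j, ])^2)) <= eps))
    }
  }
  expect_true(all(recurrence_matrix(ps, 1e6) == 1))
  expect_equal(recurrence_matrix(matrix(1:10, 10, 1), 0), diag(10),
               ignore_attr = TRUE)
})

test_that("recurrence quantification equals the diagonal-scan oracle", {
  set.seed(8)
  for (i in 1:20) {
    ps <- matrix(rnorm(60), 30, 2)
    R <- recurrence_matrix(ps, runif(1, 0.3, 1.5))
    l_min <- sample(2:3, 1)
    expect_equal(rqa(R, l_min), oracle_rqa(R, l_min))
  }
  # frozen oracle values for the all-ones matrix
  allones <- matrix(1L, 10, 10)
  expect_equal(rqa(allones, 2), oracle_rqa(allones, 2))
  expect_equal(unname(rqa(allones, 2)["DET"]), 88 / 90)
  expect_equal(unname(rqa(allones, 2)["L"]), 5.5)
  expect_equal(unname(rqa(allones, 2)["ENT"]), log(8))
  expect_equal(rqa(diag(10L), 2),
               c(RR = 0, DET = 0, L = 0, ENT = 0))
})

test_that("periodic signals are more deterministic than noise at equal RR", {
  t <- seq(0, 20, length.out = 800)
  ps_sine <- delay_embed(sin(2 * pi * t), m = 3, tau = 8)
  set.seed(9)
  ps_noise <- delay_embed(rnorm(800), m = 3, tau = 8)
  rr_at <- function(ps, q) {
    d <- dist(ps)
    rqa(recurrence_matrix(ps, quantile(d, q)), 2)
  }
  expect_gt(rr_at(ps_sine, 0.05)["DET"], rr_at(ps_noise, 0.05)["DET"])
})

test_that("differential entropy follows the Gaussian closed form", {
  set.seed(10)
  x <- rnorm(10000)
  x <- (x - mean(x)) / sd(x)
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-9)
  expect_equal(differential_entropy(2 * x) - differential_entropy(x), log(2))
  y <- rnorm(10000, sd = 1.7)
  expect_equal(differential_entropy(y), 0.5 * log(2 * pi * exp(1) * 1.7^2),
               tolerance = 0.05)
})

test_that("features are offset-invariant and scale behaves as documented", {
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = c(0.6, -0.3)), 1200))
  p <- feature_params(max_points = 200)
  f1 <- emofuse:::channel_features(x, fs = 128, p)
  f2 <- emofuse:::channel_features(x + 100, fs = 128, p)
  expect_equal(f1, f2, tolerance = 1e-6)
  f3 <- emofuse:::channel_features(3 * x, fs = 128, p)
  # relative-tolerance statistics are scale-free; entropy shifts by log(scale)
  for (nm in c("CD", "FD", "LLE", "SpEn", "RR", "DET", "L", "ENT")) {
    expect_equal(unname(f3[nm]), unname(f1[nm]), tolerance = 1e-6)
  }
  expect_equal(unname(f3["DeEn"] - f1["DeEn"]), log(3), tolerance = 1e-9)
})

test_that("feature extraction produces a complete labeled table", {
  cfg <- sim_config(n_channels = 4, n_samples = 4000, n_trials_per_class = 1,
                    class_channel_map = list(Q1 = 1:2, Q2 = 2:3, Q3 = 3:4,
                                             Q4 = c(1, 4)),
                    seed = 12)
  es <- generate_epochs(cfg)
  ch <- channel_set(c(1, 3), cfg$channel_labels[c(1, 3)], "intersection")
  tbl <- extract_features(es, ch, feature_params(max_points = 150))
  expect_equal(nrow(tbl), 4)
  expect_length(feature_columns(tbl), 18) # 2 channels x 9 features
  expect_false(anyNA(tbl))
  tbl2 <- extract_features(es, ch, feature_params(max_points = 150))
  expect_identical(tbl, tbl2)
})
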