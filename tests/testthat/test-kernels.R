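test_that("base kernel formulas evaluate exactly", {
  lin <- kernel_spec(k_lin(), list(theta1 = 0))
  expect_equal(evaluate_kernel(lin, c(1, 2)),
               matrix(c(1, 2, 2, 4), 2), tolerance = 1e-12)

  rbf <- kernel_spec(k_rbf(), list(theta2 = 1.7, theta3 = 0.3))
  K <- evaluate_kernel(rbf, c(0, 0.4, 1))
  expect_equal(diag(K), rep(1.7^2, 3))
  expect_equal(K[1, 2], 1.7^2 * exp(-0.4^2 / (2 * 0.3^2)))

  per <- kernel_spec(k_per(), list(theta4 = 2, theta5 = 0.25, theta6 = 0.8))
  # a full period apart: sin(pi * theta5 / theta5) = 0, entry is theta4^2
  K <- evaluate_kernel(per, c(0, 0.25))
  expect_equal(K[1, 2], 4, tolerance = 1e-12)
})

test_that("sum and product nodes combine child matrices elementwise", {
  x <- seq(0, 1, length.out = 9)
  set.seed(42)
  for (i in 1:10) {
    p <- list(theta1 = runif(1, -1, 1), theta2 = runif(1, 0.1, 3),
              theta3 = runif(1, 0.05, 2), theta4 = runif(1, 0.1, 3),
              theta5 = runif(1, 0.1, 1), theta6 = runif(1, 0.1, 3))
    bases <- list(k_lin(), k_rbf(), k_per())
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      a <- bases[[pair[1]]]; b <- bases[[pair[2]]]
      Ka <- evaluate_kernel(kernel_spec(a, p), x)
      Kb <- evaluate_kernel(kernel_spec(b, p), x)
      expect_equal(evaluate_kernel(kernel_spec(k_sum(a, b), p), x),
                   Ka + Kb, tolerance = 1e-12)
      expect_equal(evaluate_kernel(kernel_spec(k_prod(a, b), p), x),
                   Ka * Kb, tolerance = 1e-12)
    }
  }
})

test_that("covariance matrices are symmetric and near-PSD before jitter", {
  x <- seq(0, 1, length.out = 25)
  set.seed(7)
  for (i in 1:12) {
    spec <- if (i %% 3 == 0) sample_spectral_spec() else sample_compositional_spec()
    K <- evaluate_kernel(spec, x)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("spectral mixture kernel matches its closed form", {
  spec <- kernel_spec(k_spectral(2),
                      list(w = c(1, 2), mu = c(1.5, 4), v = c(0.5, 3)))
  # tau = 0: cosine and Gaussian factors are 1, k(0) = sum of weights
  expect_equal(evaluate_spectral(spec, 0, 0)[1, 1], 3)
  # all weights zero gives the zero matrix
  z <- kernel_spec(k_spectral(2), list(w = c(0, 0), mu = c(1, 2), v = c(1, 1)))
  expect_equal(evaluate_spectral(z, seq(0, 1, 0.25)),
               matrix(0, 5, 5))
  # brute-force formula evaluation at 10 tau values
  taus <- seq(-0.9, 0.9, length.out = 10)
  K <- evaluate_spectral(spec, taus, 0)
  direct <- sapply(taus, function(tau)
    sum(c(1, 2) * exp(-2 * pi^2 * tau^2 * c(0.5, 3)) *
          cos(2 * pi * tau * c(1.5, 4))))
  expect_equal(drop(K), direct, tolerance = 1e-12)
  # stationarity: entries depend only on x - x'
  x <- seq(0, 1, length.out = 8)
  Kx <- evaluate_spectral(spec, x, x)
  for (off in 1:3) {
    band <- Kx[cbind(seq_len(8 - off), seq_len(8 - off) + off)]
    expect_equal(band, rep(band[1], length(band)), tolerance = 1e-12)
  }
})

test_that("parameter validation rejects invalid kernels", {
  expect_error(kernel_spec(k_rbf(), list(theta3 = -1)), "positive")
  expect_error(kernel_spec(k_per(), list(theta5 = 0)), "positive")
  expect_error(kernel_spec(k_lin(), list(noise_var = -0.1)), "noise_var")
  expect_error(k_spectral(1), "between 2 and 6")
  expect_error(k_spectral(7), "between 2 and 6")
  expect_error(kernel_spec(k_spectral(2), list(w = c(-1, 1), mu = c(1, 2),
                                               v = c(1, 1))), "weights")
  expect_error(kernel_spec(k_sum(k_lin(), k_lin())), "repeat")
  expect_error(evaluate_kernel(kernel_spec(k_lin()), c(0, NA)), "finite")
})

test_that("grammar enumeration matches an independent brute-force oracle", {
  g <- enumerate_grammar()
  labels <- names(g)
  # singletons present
  expect_true(all(c("LIN", "RBF", "PER") %in% labels))
  expect_equal(sum(labels %in% c("LIN", "RBF", "PER")), 3)
  # count and exact label set against the independent generator
  oracle <- oracle_enumerate()
  expect_equal(length(g), 17)
  expect_setequal(labels, oracle)
  # no duplicates, no repeated leaves
  expect_equal(anyDuplicated(labels), 0)
  for (e in g) {
    leaves <- strsplit(gsub("[()]", "", gsub("\\*", "+", expr_label(e))), "\\+")[[1]]
    expect_equal(anyDuplicated(leaves), 0)
    expect_lte(length(leaves), 3)
  }
  # stable across calls
  expect_identical(names(enumerate_grammar()), labels)
})

test_that("kernel specs round-trip through JSON losslessly", {
  specs <- list(
    kernel_spec(k_sum(k_prod(k_lin(), k_per()), k_rbf()),
                list(theta1 = 0.3141592653589793, theta2 = 1.23456789012345,
                     theta3 = 0.2, theta4 = 0.9, theta5 = 1 / 3, theta6 = 2,
                     noise_var = 1e-4)),
    kernel_spec(k_spectral(3),
                list(w = c(0.1, 2, 3), mu = c(0.5, 1.7, 4), v = c(1, 2, 3),
                     noise_var = 0.01)))
  for (s in specs) {
    s2 <- spec_from_json(spec_to_json(s))
    expect_identical(expr_label(s2$expr), expr_label(s$expr))
    expect_equal(s2$params, s$params, tolerance = 0)
  }
})
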