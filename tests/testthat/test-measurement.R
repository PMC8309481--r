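test_that("measurement counts follow the half-up rounding rule", {
  expect_equal(measurement_count(0.5, 10L), 5L)
  expect_equal(measurement_count(1.0, 12288L), 12288L)
  expect_equal(measurement_count(0.1, 12288L), 1229L)  # round(1228.8)
  expect_equal(measurement_count(1e-6, 100L), 1L)      # floor at one
  expect_error(measurement_count(0, 10L), "sr")
  expect_error(measurement_count(1.2, 10L), "sr")
  # monotone nondecreasing in sr at fixed n
  ms <- vapply(seq(0.01, 1, by = 0.01), measurement_count, 0L, n = 333L)
  expect_true(all(diff(ms) >= 0))
})

test_that("gaussian matrices are seeded, sized and statistically sane", {
  a <- gaussian_matrix(100L, 1000L, seed = 3L)
  b <- gaussian_matrix(100L, 1000L, seed = 3L)
  expect_identical(a$phi, b$phi)
  expect_equal(a$kind, "gaussian")
  g <- gaussian_matrix(200L, 2000L, seed = 1L)
  expect_lt(abs(mean(g$phi)), 4 / sqrt(200 * 2000))   # CLT bound
  expect_equal(dim(gaussian_matrix(1L, 1L, seed = 0L)$phi), c(1L, 1L))
  expect_error(gaussian_matrix(10L, 5L), "m <= n")
})

test_that("the sampler is an exactly linear selection-free projection", {
  # row-selection matrix picks out leading flattened entries
  n <- 48L
  phi <- diag(n)[1:5, ]
  x <- array(runif(4 * 4 * 3, -1, 1), c(4, 4, 3))
  y <- measure(phi, x)
  expect_equal(as.vector(y), flatten_images(x)[1, 1:5])

  # hand-computed product
  phi2 <- matrix(c(1, 0, 0, 2, 1, 0), 2, 3)
  expect_equal(as.vector(measure(phi2, c(1, 2, 3))), c(4, 4))

  # linearity over random inputs
  set.seed(9)
  phi3 <- matrix(rnorm(6 * 48), 6, 48)
  x1 <- array(runif(48, -1, 1), c(4, 4, 3))
  x2 <- array(runif(48, -1, 1), c(4, 4, 3))
  lhs <- measure(phi3, 0.3 * x1 + 1.7 * x2)
  rhs <- 0.3 * measure(phi3, x1) + 1.7 * measure(phi3, x2)
  expect_equal(lhs, rhs, tolerance = 1e-5)

  expect_error(measure(phi3, array(0, c(5, 5, 3))), "does not match")
})

test_that("restricted-eigenvalue diagnostics behave at the extremes", {
  set.seed(10)
  imgs <- matrix(runif(6 * 27, -1, 1), 6, 27)
  expect_equal(estimate_srec(diag(27), imgs)$gamma_hat, 1,
               tolerance = 1e-12)
  expect_equal(estimate_srec(matrix(0, 5, 27), imgs)$gamma_hat, 0)
  same <- imgs[c(1, 1, 1), ]
  expect_error(estimate_srec(diag(27), same), "identical")
  # row-orthonormal projection contracts: gamma in (0, 1]
  q <- qr.Q(qr(matrix(rnorm(27 * 9), 27, 9)))
  est <- estimate_srec(t(q), imgs)
  expect_lte(est$gamma_hat, 1 + 1e-12)
  expect_gt(est$gamma_hat, 0)
})

test_that("measurement matrices survive the binary+sidecar round trip", {
  dir <- withr::local_tempdir()
  phi <- gaussian_matrix(7L, 30L, seed = 2L)
  export_matrix(phi, file.path(dir, "phi"), seed = 2L)
  back <- import_matrix(file.path(dir, "phi"))
  expect_identical(back$phi, phi$phi)
  expect_equal(back$kind, "gaussian")
})
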