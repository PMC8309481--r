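test_that("GEMM convolution kernels agree with direct summation", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  W <- array(rnorm(5 * 5 * 3 * 4), c(5, 5, 3, 4))
  b <- rnorm(4)
  for (single in c(TRUE, FALSE)) {
    got <- gencs:::conv_fwd_cpp(x, W, b, 2L, 2L, single)
    tol <- if (single) 1e-5 else 1e-12
    expect_equal(got, naive_conv(x, W, b), tolerance = tol)
  }
  # transposed convolution is the adjoint of the strided convolution:
  # <conv(x), u> == <x, tconv(u)> for weight-transposed kernels
  # the same (k, k, Cin, Cout) array reads as a (k, k, Cout, Cin)
  # transposed-convolution weight
  u <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  cx <- gencs:::conv_fwd_cpp(x, W, rep(0, 4), 2L, 2L, FALSE)
  tu <- gencs:::tconv_fwd_cpp(u, W, rep(0, 3), 2L, 2L, 1L, FALSE)
  expect_equal(sum(cx * u), sum(x * tu), tolerance = 1e-10)
})

test_that("component parameter counts match the architectural arithmetic", {
  cfg <- model_config(side = 64L, channels = 3L, k = 100L, sr = 0.1,
                      width_base = 64L, seed = 0L)
  model <- init_model(cfg)
  np <- n_params(model)
  m <- 1229L
  expect_equal(np$sampler, m * 12288L)
  solver_expect <- (m * 1024 + 1024) + 2 * 1024 +
    (1024 * 512 + 512) + 2 * 512 +
    (512 * 256 + 256) + 2 * 256 +
    (256 * 200 + 200)
  expect_equal(np$solver, solver_expect)
  rebuilder_expect <- (100 * 8192 + 8192) +
    (25 * 512 * 256 + 256) + (25 * 256 * 128 + 128) +
    (25 * 128 * 64 + 64) + (25 * 64 * 3 + 3)
  expect_equal(np$rebuilder, rebuilder_expect)
  disc_expect <- (25 * 3 * 64 + 64) + (25 * 64 * 128 + 128) +
    (25 * 128 * 256 + 256) + (25 * 256 * 512 + 512) +
    (4 * 4 * 512 + 1)
  expect_equal(np$discriminator, disc_expect)
  expect_equal(np$total,
               np$sampler + np$solver + np$rebuilder + np$discriminator)
})

test_that("solver emits a latent distribution of the configured dimension", {
  model <- tiny_model(side = 16L, k = 5L, sr = 0.1, seed = 3L)
  y <- measure(model, tiny_batch(16L, 3L, seed = 4L))
  d <- solver_forward(model, y)
  expect_equal(dim(d$mu), c(3L, 5L))
  expect_equal(dim(d$logvar), c(3L, 5L))
  expect_true(all(is.finite(d$mu)))
  # eval mode is deterministic
  d2 <- solver_forward(model, y)
  expect_identical(d, d2)
  # zero output layer collapses to the standard normal
  nl <- length(model$solver$layers)
  model$solver$layers[[nl]]$params$W[] <- 0
  model$solver$layers[[nl]]$params$b[] <- 0
  d0 <- solver_forward(model, y)
  expect_true(all(d0$mu == 0) && all(d0$logvar == 0))
  expect_error(solver_forward(model, y[, 1:3]), "does not match")
})

test_that("reparameterised sampling is exact, seeded and unbiased", {
  d <- list(mu = matrix(1:6 / 2, 2, 3), logvar = matrix(-Inf, 2, 3))
  expect_equal(sample_latent(d, seed = 1L), d$mu)   # sigma -> 0 limit
  d2 <- list(mu = matrix(0, 1, 4), logvar = matrix(0, 1, 4))
  z1 <- sample_latent(d2, seed = 5L)
  z2 <- sample_latent(d2, seed = 5L)
  expect_identical(z1, z2)
  set.seed(6)
  draws <- replicate(10000, sum(sample_latent(list(mu = 0, logvar = 0))))
  expect_lt(abs(mean(draws)), 4 / sqrt(10000))
})

test_that("rebuilder maps latents to bounded images of the right shape", {
  model <- tiny_model(side = 16L, k = 4L, sr = 0.1, seed = 7L)
  set.seed(8)
  for (i in 1:100) {
    z <- rnorm(4, sd = 3)
    img <- rebuild(model, z)
    expect_equal(dim(img), c(16L, 16L, 3L, 1L))
    expect_true(all(abs(img) < 1))
  }
  expect_error(rebuild(model, rnorm(5)), "does not match")
})

test_that("discriminator returns calibrated probabilities and features", {
  model <- tiny_model(side = 16L, k = 4L, sr = 0.1, seed = 9L)
  x1 <- tiny_batch(16L, 1L, seed = 10L)
  x2 <- tiny_batch(16L, 1L, seed = 11L)
  r1 <- discriminate(model, x1)
  expect_gt(r1$prob, 0); expect_lt(r1$prob, 1)
  r1b <- discriminate(model, x1)
  expect_identical(r1, r1b)
  expect_equal(sum((r1$features - r1b$features)^2), 0)
  r2 <- discriminate(model, x2)
  expect_gt(sum((r1$features - r2$features)^2), 0)
})

test_that("the full pipeline is the composition of its parts", {
  model <- tiny_model(side = 16L, k = 4L, sr = 0.1, seed = 12L)
  x <- tiny_batch(16L, 2L, seed = 13L)
  xh <- pipeline_forward(model, x)
  expect_equal(dim(xh), dim(x))
  expect_identical(xh, pipeline_forward(model, x))
  mu <- solver_forward(model, measure(model, x))$mu
  expect_identical(xh, rebuild(model, mu))
})

test_that("frozen batch-norm statistics make eval outputs batch-independent", {
  model <- tiny_model(side = 16L, k = 4L, sr = 0.1, seed = 14L)
  # push some training batches through so running statistics are non-trivial
  set.seed(15)
  st <- train_step(model, tiny_batch(16L, 4L, seed = 16L))
  model <- st$model
  x <- tiny_batch(16L, 6L, seed = 17L)
  y <- measure(model, x)
  full <- solver_forward(model, y)$mu
  single <- t(vapply(seq_len(6),
                     function(i) solver_forward(model, y[i, , drop = FALSE])$mu[1, ],
                     numeric(4)))
  expect_equal(full, single, tolerance = 1e-12)
})
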