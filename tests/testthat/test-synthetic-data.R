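test_that("dataset generation honours the contract and is deterministic", {
  cfg <- synth_config("rosette", side = 32L, n_train = 4L, n_test = 2L,
                      seed = 7L)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$train), c(32L, 32L, 3L, 4L))
  expect_equal(dim(ds$test), c(32L, 32L, 3L, 2L))
  expect_true(all(is.finite(ds$train)))
  expect_true(all(ds$train >= -1 & ds$train <= 1))
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$train, ds2$train)
  expect_identical(ds$test, ds2$test)

  fc <- generate_dataset(synth_config("facelike", side = 32L,
                                      n_train = 3L, n_test = 1L, seed = 8L))
  expect_equal(dim(fc$train), c(32L, 32L, 3L, 3L))
  expect_true(all(fc$train >= -1 & fc$train <= 1))
})

test_that("invalid sides are rejected", {
  expect_error(synth_config("rosette", side = 24L), "power of two")
  expect_error(synth_config("rosette", side = 4L), "power of two")
  expect_error(model_config(side = 48L), "power of two")
})

test_that("scene images are far more correlated than white noise", {
  ds <- generate_dataset(synth_config("rosette", side = 32L,
                                      n_train = 200L, n_test = 1L,
                                      seed = 1L))
  set.seed(2)
  noise <- array(runif(32 * 32 * 3 * 200, -1, 1), c(32, 32, 3, 200))
  expect_gt(mean_pairwise_correlation(ds$train),
            mean_pairwise_correlation(noise))
})

test_that("linear world is exactly self-consistent and solvable in closed form", {
  w <- make_linear_world(64L, 4L, 16L, n_samples = 3L, noise_sd = 0,
                         seed = 0L)
  expect_equal(crossprod(w$A), diag(4), tolerance = 1e-12)
  expect_equal(qr(w$phi$phi %*% w$A)$rank, 4L)
  # measurements are exact projections of the signals
  expect_equal(w$y, tcrossprod(w$x, w$phi$phi), tolerance = 1e-12)
  # pseudoinverse recovers the true latents to machine precision
  z_hat <- linear_world_solve(w)
  expect_lt(max(abs(z_hat - w$z_star)) / max(abs(w$z_star)), 1e-10)
})

test_that("linear world rejects underdetermined latent dimensions", {
  expect_error(make_linear_world(64L, 20L, 16L), "underdetermined")
})

test_that("datasets survive a PNG round trip within quantisation error", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synth_config("rosette", side = 16L, n_train = 3L,
                                      n_test = 2L, seed = 4L))
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(dim(back$train), dim(ds$train))
  expect_lt(max(abs(back$train - ds$train)), 1 / 127.5 + 1e-9)
  expect_identical(back$config$kind, "rosette")
})
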