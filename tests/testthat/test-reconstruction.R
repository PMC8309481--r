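test_that("measurement-consistency loss matches hand arithmetic", {
  # one-dimensional world: Phi = [1], decoder doubles the latent
  model <- structure(list(
    sampler = list(phi = matrix(1), kind = "gaussian"),
    solver = structure(list(pinv = matrix(0.5), k = 1L),
                       class = "linear_solver"),
    rebuilder = structure(list(A = matrix(2)), class = "linear_rebuilder"),
    config = list(k = 1L)), class = "gencs_model")
  expect_equal(recon_loss(model, 3, 6), 0)
  expect_equal(recon_loss(model, 2, 6), 4)   # (6 - 4)^2
})

test_that("loss equals the directly computed residual norm on a network", {
  model <- tiny_model(side = 16L, k = 4L, sr = 0.08, precision = "double",
                      seed = 50L)
  set.seed(51)
  z <- matrix(rnorm(8), 2, 4)
  y <- matrix(rnorm(2 * model$config$m), 2)
  direct <- rowSums((tcrossprod(flatten_images(rebuild(model, z)),
                                model$sampler$phi) - y)^2)
  expect_equal(recon_loss(model, z, y), direct, tolerance = 1e-6)
})

test_that("optimisation descends and leaves every parameter untouched", {
  model <- tiny_model(side = 16L, k = 4L, sr = 0.1, precision = "single",
                      seed = 52L)
  x <- tiny_batch(16L, 1L, seed = 53L)
  y <- measure(model, x)[1, ]
  before <- serialize(model, NULL)
  rc <- reconstruct(y, model, recon_config(imax = 60L, init = "solver"))
  expect_identical(serialize(model, NULL), before)  # frozen-model contract
  expect_length(rc$loss, 61L)
  expect_lte(rc$final_loss, rc$init_loss)
  expect_equal(dim(rc$x_hat), c(16L, 16L, 3L))
  expect_error(recon_config(imax = -1L), "imax")
})

test_that("batch reconstruction summarises per-image metrics faithfully", {
  model <- tiny_model(side = 16L, k = 4L, sr = 0.1, precision = "single",
                      seed = 54L)
  imgs <- tiny_batch(16L, 10L, seed = 55L)
  br <- batch_reconstruct(imgs, model, recon_config(imax = 5L))
  expect_equal(nrow(br$per_image), 10L)
  expect_equal(dim(br$losses), c(6L, 10L))
  expect_equal(br$summary$psnr_mean, mean(br$per_image$psnr))
  expect_equal(br$summary$ssim_mean, mean(br$per_image$ssim))
  br2 <- batch_reconstruct(imgs, model, recon_config(imax = 5L))
  expect_identical(br$summary, br2$summary)
  # reconstruction through an externally supplied Gaussian matrix
  g <- gaussian_matrix(model$config$m, model$config$n, seed = 8L)
  brg <- batch_reconstruct(imgs, model, recon_config(imax = 5L),
                           matrix = g)
  expect_equal(nrow(brg$per_image), 10L)
  expect_false(identical(brg$summary$psnr_mean, br$summary$psnr_mean))
})

test_that("solver-initialised latents start near the linear-world optimum", {
  w <- make_linear_world(64L, 4L, 16L, n_samples = 5L, seed = 3L)
  lm <- linear_model(w)
  # with the closed-form solver, initialisation already attains the optimum
  rc <- reconstruct(w$y[2, ], lm, recon_config(imax = 0L, init = "solver"))
  expect_lt(rc$init_loss / sum(w$y[2, ]^2), 1e-20)
  # and random initialisation converges to the same latent
  rr <- reconstruct(w$y[2, ], lm,
                    recon_config(imax = 500L, init = "random", seed = 4L))
  z_ref <- linear_world_solve(w)[2, ]
  expect_lt(sqrt(sum((rr$z - z_ref)^2)) / sqrt(sum(z_ref^2)), 1e-2)
})
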