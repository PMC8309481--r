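test_that("loss formulas reproduce hand-evaluated values", {
  eps <- 1e-7
  expect_lt(discriminator_loss(1 - eps, eps), 1e-5)
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-9)
  # strictly decreasing in d_real at fixed d_fake
  ld <- vapply(seq(0.05, 0.95, 0.05), discriminator_loss, 0, d_fake = 0.3)
  expect_true(all(diff(ld) < 0))
  expect_error(discriminator_loss(1.2, 0.5), "0, 1")

  expect_equal(latent_loss(0, 0), 0)
  expect_equal(latent_loss(1, 0), 0.5)
  # per-coordinate calculus oracle: f(v) = (v - log v - 1)/2 >= 0 plus
  # mu^2/2, minimised exactly at mu = 0, sigma = 1
  set.seed(1)
  for (i in 1:50) {
    mu <- rnorm(4); v <- exp(rnorm(4))
    oracle <- sum((v - log(v) - 1) / 2) + sum(mu^2) / 2
    expect_equal(latent_loss(mu, log(v)), oracle, tolerance = 1e-10)
    expect_gte(latent_loss(mu, log(v)), 0)
  }
})

test_that("rebuilder and encoder losses assemble their printed terms", {
  eps <- 1e-7
  x <- array(0, c(2, 2, 3))
  xz <- x + 0.5                    # 12 pixels, uniform +0.5
  dout <- list(d_x = 0.5, d_xz = 0.5, d_xn = 1 - eps,
               f_x = matrix(0, 1, 4), f_xz = matrix(0, 1, 4))
  expect_equal(rebuilder_loss(x, xz, x, dout, loss_config(p = 1)), 6,
               tolerance = 1e-5)
  expect_equal(rebuilder_loss(x, x, x, dout, loss_config(p = 1)), 0,
               tolerance = 1e-5)
  # decreasing D(x_n) strictly increases the loss
  dlo <- dout; dlo$d_xn <- 0.2
  expect_gt(rebuilder_loss(x, xz, x, dlo, loss_config()),
            rebuilder_loss(x, xz, x, dout, loss_config()))

  expect_equal(encoder_loss(x, x, c(3, 4), c(0, 0), c(0, 0), dout,
                            loss_config()), 25)
  expect_equal(encoder_loss(x, x, c(0, 0), c(0, 0), c(0, 0), dout,
                            loss_config()), 0)
  # dropping the ||z||^2 term lowers the loss whenever z != 0
  no_z <- loss_config(weights = list(znorm = 0))
  expect_lt(encoder_loss(x, x, c(3, 4), c(0, 0), c(0, 0), dout, no_z),
            encoder_loss(x, x, c(3, 4), c(0, 0), c(0, 0), dout,
                         loss_config()))
  # p = 2 equals the squared norm, p = 1 the absolute sum
  set.seed(2)
  a <- array(runif(12, -1, 1), c(2, 2, 3))
  b <- array(runif(12, -1, 1), c(2, 2, 3))
  expect_equal(rebuilder_loss(a, b, a, dout, loss_config(p = 2)),
               sum((a - b)^2), tolerance = 1e-5)
  expect_equal(rebuilder_loss(a, b, a, dout, loss_config(p = 1)),
               sum(abs(a - b)), tolerance = 1e-5)
})

test_that("a training step updates exactly the live parameters", {
  x <- tiny_batch(8L, 2L, seed = 30L)
  for (mk in c("learned", "gaussian")) {
    model <- tiny_model(side = 8L, matrix_kind = mk, precision = "single",
                        seed = 31L)
    set.seed(32)
    st <- train_step(model, x)
    m2 <- st$model
    expect_false(identical(gencs:::net_params(model$discriminator),
                           gencs:::net_params(m2$discriminator)))
    expect_false(identical(gencs:::net_params(model$rebuilder),
                           gencs:::net_params(m2$rebuilder)))
    expect_false(identical(gencs:::net_params(model$solver),
                           gencs:::net_params(m2$solver)))
    if (mk == "learned") {
      expect_false(identical(model$sampler$phi, m2$sampler$phi))
    } else {
      expect_identical(model$sampler$phi, m2$sampler$phi)  # frozen
    }
    expect_true(all(is.finite(unlist(st$record))))
  }
})

test_that("training is deterministic given the seeds", {
  ds <- generate_dataset(synth_config("rosette", side = 8L, n_train = 8L,
                                      n_test = 1L, seed = 40L))
  run <- function() {
    model <- tiny_model(side = 8L, precision = "single", seed = 41L)
    train_model(ds$train, model, loss_config(p = 1),
                train_config(batch_size = 4L, epochs = 2L, seed = 42L))
  }
  a <- run(); b <- run()
  expect_identical(a$model$sampler$phi, b$model$sampler$phi)
  expect_identical(gencs:::net_params(a$model$rebuilder),
                   gencs:::net_params(b$model$rebuilder))
  expect_identical(a$history, b$history)
  # 2 epochs x ceiling(8/4) batches = 4 steps
  expect_equal(nrow(a$history), 4L)
})

test_that("desk-scale training converges: live adversary, shrinking error", {
  ab <- ablation_study()
  # per-variant medians of the discriminator loss stay positive and the
  # reconstruction term falls from the first to the last epoch
  for (h in ab$histories) {
    last <- max(h$epoch)
    expect_gt(median(h$L_D[h$epoch == last]), 0)
    expect_lt(mean(h$recon[h$epoch == last]),
              mean(h$recon[h$epoch == 1]))
  }
})
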