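test_that("psnr follows its definition and decreases with error", {
  x <- array(-0.5, c(6, 6, 3))
  expect_identical(psnr(x, x), Inf)
  errs <- seq(0.05, 0.9, by = 0.05)
  vals <- vapply(errs, function(e) psnr(x, x + e), 0)
  expect_true(all(diff(vals) < 0))
  # direct formula for a known uniform error
  e <- 0.25
  expect_equal(psnr(x, x + e), 10 * log10(255^2 / (127.5 * e)^2),
               tolerance = 1e-10)
  expect_error(psnr(x, array(0, c(5, 5, 3))), "shape")
})

test_that("global ssim variants behave at their fixed points", {
  # constant images with zero variance: standard variant is exactly 1
  x100 <- matrix(100 / 127.5 - 1, 12, 12)
  expect_equal(ssim(x100, x100, "standard_global"), 1)
  # as-printed variant lacks the factor 2 and follows its own formula
  c1 <- ssim_constants()$c1
  expect_equal(ssim(x100, x100, "as_printed"),
               (100^2 + c1) / (2 * 100^2 + c1), tolerance = 1e-12)
  set.seed(3)
  a <- matrix(runif(144, -1, 1), 12, 12)
  b <- matrix(runif(144, -1, 1), 12, 12)
  expect_equal(ssim(a, b, "standard_global"), ssim(b, a, "standard_global"))
  expect_lte(ssim(a, b, "standard_global"), 1)
})

test_that("windowed ssim equals a direct per-window computation", {
  g1 <- exp(-((-5):5)^2 / (2 * 1.5^2))
  g1 <- g1 / sum(g1)
  w2 <- outer(g1, g1)
  const <- ssim_constants()
  brute_ssim <- function(a, b) {
    H <- nrow(a); vals <- c()
    for (i in 1:(H - 10)) for (j in 1:(H - 10)) {
      wa <- a[i:(i + 10), j:(j + 10)]
      wb <- b[i:(i + 10), j:(j + 10)]
      mx <- sum(w2 * wa); my <- sum(w2 * wb)
      vx <- sum(w2 * wa^2) - mx^2
      vy <- sum(w2 * wb^2) - my^2
      cv <- sum(w2 * wa * wb) - mx * my
      vals <- c(vals, (2 * mx * my + const$c1) * (2 * cv + const$c2) /
                  ((mx^2 + my^2 + const$c1) * (vx + vy + const$c2)))
    }
    mean(vals)
  }
  pairs <- ssim_fixture_pairs(3L)
  for (p in pairs) {
    expect_equal(ssim(p$x, p$y, "standard_windowed"),
                 brute_ssim((p$x + 1) * 127.5, (p$y + 1) * 127.5),
                 tolerance = 1e-10)
  }
  # symmetry and boundedness
  expect_equal(ssim(pairs[[1]]$x, pairs[[1]]$y),
               ssim(pairs[[1]]$y, pairs[[1]]$x))
  expect_lte(ssim(pairs[[1]]$x, pairs[[1]]$y), 1)
})

test_that("metrics are invariant to image orientation conventions", {
  set.seed(4)
  a <- array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  b <- pmin(pmax(a + rnorm(length(a), sd = 0.1), -1), 1)
  ap <- aperm(a, c(2, 1, 3)); bp <- aperm(b, c(2, 1, 3))
  expect_equal(psnr(a, b), psnr(ap, bp))
  expect_equal(ssim(a, b), ssim(ap, bp), tolerance = 1e-12)
})

test_that("evaluation tables have one row per model and match their inputs", {
  m1 <- tiny_model(side = 16L, k = 4L, sr = 0.1, precision = "single",
                   seed = 60L)
  m2 <- tiny_model(side = 16L, k = 4L, sr = 0.05, precision = "single",
                   seed = 61L)
  imgs <- tiny_batch(16L, 3L, seed = 62L)
  tab <- evaluate_models(list(a = m1, b = m2), imgs,
                         recon_config(imax = 3L))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$sr, c(0.1, 0.05))
  expect_equal(tab$n, c(3L, 3L))
  direct <- batch_reconstruct(imgs, m1, recon_config(imax = 3L))$summary
  expect_equal(tab$psnr_mean[1], direct$psnr_mean)
})
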