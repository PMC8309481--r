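#' Reconstruction (latent optimisation) configuration
#'
#' After training, an image is reconstructed from its measurements `y` by
#' freezing the Sampler and Rebuilder and optimising the latent vector:
#' `loss(z) = || Sp(R(z)) - y ||_2^2`. The latent is initialised from the
#' Solver (`init = "solver"`, the deterministic mean of `Sv(y)`, a starting
#' point close to the optimum) or from a standard-normal draw
#' (`init = "random"`, the random-restart baseline), then updated for
#' `imax` iterations with Adam (a plain gradient-descent mode is
#' available).
#'
#' @param lr Latent learning rate (default 0.05).
#' @param imax Maximum iterations (default 100); `imax = 0` returns the
#'   initialisation, i.e. the plain forward pass when `init = "solver"`.
#' @param init `"solver"` or `"random"`.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed Seed for the random initialisation.
#' @param report_every Print the mean loss every this many iterations
#'   (0 = silent).
#' @return A `gencs_recon_config` list.
#' @export
recon_config <- function(lr = 0.05, imax = 100L,
                         init = c("solver", "random"),
                         optimizer = c("adam", "sgd"), seed = 0L,
                         report_every = 0L) {
  init <- match.arg(init)
  optimizer <- match.arg(optimizer)
  if (lr <= 0) stop_config("lr must be positive")
  if (imax < 0) stop_config("imax must be >= 0")
  structure(list(lr = lr, imax = as.integer(imax), init = init,
                 optimizer = optimizer, seed = as.integer(seed),
                 report_every = as.integer(report_every)),
            class = "gencs_recon_config")
}

rb_flat <- function(out) {
  if (is.array(out) && length(dim(out)) == 4L) flatten_images(out) else out
}

#' Measurement-consistency loss
#'
#' `loss(z) = || Sp(R(z)) - y ||_2^2`, the plain squared norm over
#' measurement entries (no averaging), evaluated with the Sampler and
#' Rebuilder in eval mode.
#'
#' @param model A `gencs_model` (trained or linear oracle).
#' @param z Latent vector or matrix (rows).
#' @param y Measurement vector or matrix (matching rows).
#' @return Scalar for a single latent, otherwise one value per row.
#' @export
recon_loss <- function(model, z, y) {
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1L)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  out <- rb_forward(model$rebuilder, z, train = FALSE)$out
  r <- tcrossprod(rb_flat(out), model$sampler$phi) - y
  v <- rowSums(r^2)
  if (single) v[[1L]] else v
}

# batched latent optimisation; one independent problem per row of y
recon_optimize <- function(y, model, config) {
  phi <- model$sampler$phi
  k <- model$config$k
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  if (ncol(y) != nrow(phi))
    stop_config("measurement length %d does not match m = %d",
                ncol(y), nrow(phi))
  N <- nrow(y)
  z <- if (config$init == "solver") {
    sv_forward(model$solver, y, train = FALSE)$mu
  } else {
    set.seed(config$seed)
    matrix(rnorm(N * k), N, k)
  }
  losses <- matrix(NA_real_, config$imax + 1L, N)
  st <- adam_init(z)
  fw <- NULL
  for (it in 0:config$imax) {
    fw <- rb_forward(model$rebuilder, z, train = FALSE)
    r <- tcrossprod(rb_flat(fw$out), phi) - y
    losses[it + 1L, ] <- rowSums(r^2)
    if (!all(is.finite(losses[it + 1L, ])))
      stop_config("non-finite reconstruction loss at iteration %d", it)
    if (config$report_every > 0L && it %% config$report_every == 0L) {
      message(sprintf("iter %4d  mean loss %.6g", it,
                      mean(losses[it + 1L, ])))
    }
    if (it == config$imax) break
    dflat <- 2 * (r %*% phi)
    dout <- if (is.array(fw$out) && length(dim(fw$out)) == 4L) {
      unflatten_images(dflat, dim(fw$out)[1], dim(fw$out)[3])
    } else dflat
    dz <- rb_backward_z(model$rebuilder, fw$caches, dout)
    if (config$optimizer == "adam") {
      up <- adam_update(z, dz, st, config$lr, beta1 = 0.9, beta2 = 0.999)
      z <- up$params
      st <- up$state
    } else {
      z <- z - config$lr * dz
    }
  }
  list(z = z, x_hat = fw$out, losses = losses)
}

#' Reconstruct one image from its measurements
#'
#' Runs the latent-optimisation reconstruction; all model parameters stay
#' untouched. The returned trace records the loss before the first update
#' (iteration 0), so the quality of the initialisation is measurable; with
#' `imax = 0` and `init = "solver"` the result is exactly the eval-mode
#' forward pass `R(Sv(y))`.
#'
#' @param y Measurement vector (length m).
#' @param model A trained `gencs_model` or a [linear_model()] oracle.
#' @param config A [recon_config()].
#' @return A `gencs_recon` list: `x_hat` (image array, or ambient vector
#'   for linear models), `z` (final latent), `loss` (length `imax + 1`),
#'   `init_loss`, `final_loss`.
#' @export
reconstruct <- function(y, model, config = recon_config()) {
  r <- recon_optimize(matrix(y, nrow = 1L), model, config)
  x_hat <- if (is.array(r$x_hat) && length(dim(r$x_hat)) == 4L) {
    array(r$x_hat[, , , 1L], dim = dim(r$x_hat)[1:3])
  } else as.vector(r$x_hat)
  structure(list(x_hat = x_hat, z = as.vector(r$z),
                 loss = as.vector(r$losses[, 1L]),
                 init_loss = r$losses[1L, 1L],
                 final_loss = r$losses[nrow(r$losses), 1L]),
            class = "gencs_recon")
}

#' @export
print.gencs_recon <- function(x, ...) {
  cat(sprintf("<gencs_recon> %d iterations, loss %.4g -> %.4g\n",
              length(x$loss) - 1L, x$init_loss, x$final_loss))
  invisible(x)
}

#' Reconstruct a test set and summarise image quality
#'
#' Measures each test image (through the model's own Sampler, or a
#' supplied external measurement matrix), reconstructs all images by
#' batched latent optimisation, and reports mean PSNR/SSIM against the
#' ground truth.
#'
#' @param images Test batch array (`side x side x channels x n`).
#' @param model A trained `gencs_model`.
#' @param config A [recon_config()].
#' @param matrix Optional external measurement matrix (e.g. a
#'   [gaussian_matrix()]) used instead of the model's Sampler for the
#'   measuring step; reconstruction then also uses it for the consistency
#'   loss.
#' @return List with `x_hat` (batch array), `losses`
#'   (`(imax+1) x n` trace matrix), `z` (final latents), `per_image`
#'   (data frame of psnr/ssim/final loss) and `summary` (one row: mean
#'   PSNR, mean SSIM, n).
#' @export
batch_reconstruct <- function(images, model, config = recon_config(),
                              matrix = NULL) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4]
  if (n < 1L) stop_config("empty test set")
  mdl <- model
  if (!is.null(matrix)) mdl$sampler$phi <- phi_of(matrix)
  y <- measure(mdl, images)
  r <- recon_optimize(y, mdl, config)
  per <- data.frame(
    image = seq_len(n),
    psnr = vapply(seq_len(n), function(i)
      psnr(images[, , , i], r$x_hat[, , , i]), 0),
    ssim = vapply(seq_len(n), function(i)
      ssim(images[, , , i], r$x_hat[, , , i],
           variant = if (dim(images)[1] >= 11L) "standard_windowed"
                     else "standard_global"), 0),
    init_loss = r$losses[1L, ],
    final_loss = r$losses[nrow(r$losses), ])
  list(x_hat = r$x_hat, losses = r$losses, z = r$z, per_image = per,
       summary = data.frame(psnr_mean = mean(per$psnr),
                            ssim_mean = mean(per$ssim),
                            n = n))
}
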