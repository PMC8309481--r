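#' SSIM stabilising constants
#'
#' @param L Dynamic range of the pixel values (255; metrics are computed
#'   on the 8-bit scale).
#' @param c1,c2 Stabilisers; default `(0.01 L)^2` and `(0.03 L)^2`.
#' @return List with `c1`, `c2`.
#' @export
ssim_constants <- function(L = 255, c1 = (0.01 * L)^2, c2 = (0.03 * L)^2) {
  if (c1 <= 0 || c2 <= 0) stop_config("c1 and c2 must be positive")
  list(c1 = c1, c2 = c2)
}

to_255 <- function(x) (x + 1) * 127.5

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(255^2 / MSE)` with the mean squared error taken over
#' all pixels and channels jointly. Inputs are model-scale images in
#' \[-1, 1\] and are mapped to the 8-bit \[0, 255\] scale first; identical
#' images return `Inf`.
#'
#' @param x,x_hat Image arrays of identical shape.
#' @return PSNR in dB.
#' @export
psnr <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)) || length(x) != length(x_hat))
    stop_config("shape mismatch in psnr")
  mse <- mean((to_255(x) - to_255(x_hat))^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

gauss_kernel1d <- function(win = 11L, sigma = 1.5) {
  r <- (win - 1L) %/% 2L
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g / sum(g)
}

# (H - win + 1) x H banded matrix performing a valid 1-D convolution
valid_conv_band <- function(H, g) {
  win <- length(g)
  out <- matrix(0, H - win + 1L, H)
  for (j in seq_len(win)) {
    idx <- seq_len(H - win + 1L)
    out[cbind(idx, idx + j - 1L)] <- g[j]
  }
  out
}

ssim_windowed_channel <- function(x, y, const, win = 11L, sigma = 1.5) {
  g <- gauss_kernel1d(win, sigma)
  Tr <- valid_conv_band(nrow(x), g)
  Tc <- valid_conv_band(ncol(x), g)
  mu_x <- Tr %*% x %*% t(Tc)
  mu_y <- Tr %*% y %*% t(Tc)
  exx <- Tr %*% (x * x) %*% t(Tc)
  eyy <- Tr %*% (y * y) %*% t(Tc)
  exy <- Tr %*% (x * y) %*% t(Tc)
  vx <- exx - mu_x^2
  vy <- eyy - mu_y^2
  cxy <- exy - mu_x * mu_y
  smap <- ((2 * mu_x * mu_y + const$c1) * (2 * cxy + const$c2)) /
    ((mu_x^2 + mu_y^2 + const$c1) * (vx + vy + const$c2))
  mean(smap)
}

#' Structural similarity index
#'
#' Three variants are provided:
#' \itemize{
#' \item `"standard_windowed"` (default, used for reporting): the standard
#'   SSIM with an 11x11 Gaussian window (sigma 1.5), weighted sample
#'   moments over every fully interior window, SSIM map averaged; colour
#'   images average the per-channel values.
#' \item `"standard_global"`: the standard formula
#'   `(2 mu_x mu_y + c1)(2 cov + c2) / ((mu_x^2 + mu_y^2 + c1)
#'   (var_x + var_y + c2))` over global image moments (all channels
#'   jointly).
#' \item `"as_printed"`: identical to `standard_global` but with the
#'   luminance numerator `(mu_x mu_y + c1)` — some sources print the
#'   formula without the factor 2; retained for fidelity and labelled
#'   separately because it does not equal 1 for identical images.
#' }
#' Inputs are model-scale images in \[-1, 1\], mapped to \[0, 255\] before
#' the moments are taken.
#'
#' @param x,x_hat Image arrays of identical shape (matrix or
#'   `side x side x channels`).
#' @param variant One of `"standard_windowed"`, `"standard_global"`,
#'   `"as_printed"`.
#' @param constants A [ssim_constants()] list.
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(x, x_hat, variant = c("standard_windowed",
                                       "standard_global", "as_printed"),
                 constants = ssim_constants()) {
  variant <- match.arg(variant)
  if (!identical(dim(x), dim(x_hat)))
    stop_config("shape mismatch in ssim")
  a <- to_255(x)
  b <- to_255(x_hat)
  if (variant == "standard_windowed") {
    if (is.matrix(a)) {
      a <- array(a, dim = c(dim(a), 1L))
      b <- array(b, dim = c(dim(b), 1L))
    }
    if (dim(a)[1] < 11L || dim(a)[2] < 11L)
      stop_config("windowed ssim needs images of at least 11 x 11")
    vals <- vapply(seq_len(dim(a)[3]), function(ci)
      ssim_windowed_channel(a[, , ci], b[, , ci], constants), 0)
    return(mean(vals))
  }
  mu_x <- mean(a); mu_y <- mean(b)
  vx <- mean((a - mu_x)^2); vy <- mean((b - mu_y)^2)
  cxy <- mean((a - mu_x) * (b - mu_y))
  lum <- if (variant == "standard_global") 2 * mu_x * mu_y + constants$c1
         else mu_x * mu_y + constants$c1
  lum * (2 * cxy + constants$c2) /
    ((mu_x^2 + mu_y^2 + constants$c1) * (vx + vy + constants$c2))
}

#' Evaluate trained models on a shared test set
#'
#' Runs [batch_reconstruct()] for every model and collects mean PSNR and
#' SSIM into a table with one row per (method, sampling rate).
#'
#' @param models Named list of trained `gencs_model`s; names become the
#'   `method` column.
#' @param images Shared test batch array.
#' @param config A [recon_config()].
#' @param file Optional CSV path to write the table to.
#' @return Data frame with columns `method`, `sr`, `psnr_mean`,
#'   `ssim_mean`, `n`.
#' @export
evaluate_models <- function(models, images, config = recon_config(),
                            file = NULL) {
  if (length(models) < 1L) stop_config("no models supplied")
  rows <- lapply(names(models), function(nm) {
    mdl <- models[[nm]]
    s <- batch_reconstruct(images, mdl, config)$summary
    cbind(data.frame(method = nm, sr = mdl$config$sr), s)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
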