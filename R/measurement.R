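#' Number of measurements at a given sampling rate
#'
#' The sampling rate `sr = m/n` is the ratio of the measurement count to the
#' ambient (flattened image) dimension. The measurement count is
#' `max(1, round(sr * n))` with ties rounded half up, so the realised ratio
#' matches `sr` as closely as possible.
#'
#' @param sr Sampling rate in (0, 1].
#' @param n Ambient dimension (flattened image length).
#' @return Integer measurement count `m`, `1 <= m <= n`.
#' @examples
#' measurement_count(0.1, 12288) # 1229
#' @export
measurement_count <- function(sr, n) {
  if (!is.numeric(sr) || length(sr) != 1L || sr <= 0 || sr > 1)
    stop_config("sr must lie in (0, 1], got %s", format(sr))
  m <- as.integer(min(n, max(1, floor(sr * n + 0.5))))
  m
}

#' Gaussian random measurement matrix
#'
#' Draws an `m x n` matrix with i.i.d. standard-normal entries, the baseline
#' measurement operator of classical compressed sensing (no row
#' normalisation is applied).
#'
#' @param m Number of measurements (rows).
#' @param n Ambient dimension (columns).
#' @param seed Integer seed; the same seed yields the identical matrix.
#' @return A `gencs_matrix` object: a list with `phi` (the m x n matrix),
#'   `kind = "gaussian"`, `m` and `n`.
#' @export
gaussian_matrix <- function(m, n, seed = 0L) {
  if (m < 1 || m > n) stop_config("need 1 <= m <= n, got m=%d n=%d", m, n)
  set.seed(seed)
  phi <- matrix(rnorm(m * n), m, n)
  new_measurement_matrix(phi, "gaussian")
}

new_measurement_matrix <- function(phi, kind) {
  structure(list(phi = phi, kind = kind, m = nrow(phi), n = ncol(phi)),
            class = "gencs_matrix")
}

#' @export
print.gencs_matrix <- function(x, ...) {
  cat(sprintf("<gencs_matrix> %s, %d x %d (sr = %.4f)\n",
              x$kind, x$m, x$n, x$m / x$n))
  invisible(x)
}

phi_of <- function(matrix) {
  if (inherits(matrix, "gencs_matrix")) matrix$phi
  else if (inherits(matrix, "gencs_model")) matrix$sampler$phi
  else if (is.matrix(matrix)) matrix
  else stop_config("not a measurement matrix")
}

#' Measure images through a linear Sampler
#'
#' Applies the measurement operator `y = Phi x` to one image or a batch.
#' The Sampler is a bias-free, activation-free linear projection; its
#' weights are the measurement matrix.
#'
#' @param matrix A `gencs_matrix`, a plain m x n matrix, or a `gencs_model`
#'   (whose Sampler is used).
#' @param x An image array (`side x side x channels`, values in \[-1, 1\]),
#'   a batch array with a fourth dimension, or an already-flattened numeric
#'   matrix with one image per row.
#' @return A numeric matrix of measurements, one row per image, `m` columns.
#' @export
measure <- function(matrix, x) {
  phi <- phi_of(matrix)
  xm <- if (is.array(x) && length(dim(x)) >= 3L) flatten_images(x)
        else if (is.null(dim(x))) matrix(x, nrow = 1L)
        else x
  if (ncol(xm) != ncol(phi))
    stop_config("flattened image length %d does not match n = %d",
                ncol(xm), ncol(phi))
  tcrossprod(xm, phi)
}

#' Empirical set-restricted eigenvalue estimate
#'
#' Estimates the smallest squared-norm contraction of a measurement matrix
#' over differences of images from a set:
#' `gamma_hat = min over pairs of ||Phi(x1 - x2)||^2 / ||x1 - x2||^2`.
#' This is the one-parameter empirical proxy for the set-restricted
#' eigenvalue condition (the additive constant `delta` is fixed at 0); it
#' also serves as a restricted-isometry diagnostic. Certified verification
#' is not attempted.
#'
#' @param matrix Measurement matrix (as in [measure()]).
#' @param images Batch array (`side x side x channels x n`) or matrix of
#'   flattened images (rows), at least two distinct images.
#' @param n_pairs Optional number of pairs to subsample (seeded); default
#'   uses all distinct pairs.
#' @param seed Seed for pair subsampling.
#' @return A list with `gamma_hat`, `delta` (always 0) and `n_pairs`.
#' @export
estimate_srec <- function(matrix, images, n_pairs = NULL, seed = 0L) {
  phi <- phi_of(matrix)
  xm <- if (is.array(images) && length(dim(images)) >= 3L)
    flatten_images(images) else images
  n_img <- nrow(xm)
  if (n_img < 2L) stop_config("need at least two images")
  pairs <- t(utils::combn(n_img, 2L))
  if (!is.null(n_pairs) && n_pairs < nrow(pairs)) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE]
  }
  diffs <- xm[pairs[, 1], , drop = FALSE] - xm[pairs[, 2], , drop = FALSE]
  den <- rowSums(diffs^2)
  keep <- den > 0
  if (!any(keep)) stop_config("all images identical; ratio undefined")
  num <- rowSums(tcrossprod(diffs[keep, , drop = FALSE], phi)^2)
  list(gamma_hat = min(num / den[keep]), delta = 0,
       n_pairs = sum(keep))
}

#' Export a measurement matrix as flat binary plus JSON sidecar
#'
#' @param matrix A `gencs_matrix` or model.
#' @param path Output path without extension; writes `<path>.bin`
#'   (little-endian doubles, column-major) and `<path>.json`.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(matrix, path, seed = NULL) {
  phi <- phi_of(matrix)
  kind <- if (inherits(matrix, "gencs_matrix")) matrix$kind else "learned"
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.vector(phi), con, size = 8L, endian = "little")
  close(con)
  meta <- list(m = nrow(phi), n = ncol(phi), kind = kind,
               flatten_order = "row-major (height, width, channel)",
               storage = "column-major float64 little-endian",
               seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a measurement matrix written by [export_matrix()]
#' @param path Path without extension.
#' @return A `gencs_matrix`.
#' @export
import_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  con <- file(paste0(path, ".bin"), "rb")
  v <- readBin(con, "double", n = meta$m * meta$n, size = 8L,
               endian = "little")
  close(con)
  new_measurement_matrix(matrix(v, meta$m, meta$n), meta$kind)
}
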