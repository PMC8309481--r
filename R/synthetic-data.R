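#' Configuration for a synthetic structured-image dataset
#'
#' The generators emulate the statistical character of task-driven image
#' acquisition: many images of one scene class with strong structural
#' similarity and a low-dimensional family of variations. Two kinds are
#' provided: `"rosette"` (a dark textured soil background with a centred,
#' multi-lobed green rosette, in the spirit of top-view plant phenotyping
#' imagery) and `"facelike"` (a skin-tone oval with two eyes and a mouth).
#' No photorealism is attempted.
#'
#' @param kind `"rosette"` or `"facelike"`.
#' @param side Image side in pixels; must be a power of two, at least 8
#'   (required by the 4-pixel-seed, stride-2 decoder geometry). Default 64.
#' @param channels Number of colour channels (default 3).
#' @param n_train,n_test Split sizes, each at least 1.
#' @param seed Integer seed; the same seed and config give a byte-identical
#'   dataset.
#' @param variation Named list of jitter parameters overriding the
#'   defaults: `center_off` (max centre offset, unit coords), `radius`
#'   (length-2 range of the rosette radius as a fraction of the image
#'   half-width times two, default `c(0.4, 0.8)`, i.e. 20--40% of the
#'   side), `lobes` (integer range, default `4:8`), `hue` (relative hue
#'   jitter, default 0.1).
#' @return A `gencs_synth_config` list.
#' @export
synth_config <- function(kind = c("rosette", "facelike"), side = 64L,
                         channels = 3L, n_train = 100L, n_test = 20L,
                         seed = 0L, variation = list()) {
  kind <- match.arg(kind)
  if (side < 8L || !is_power_of_two(side))
    stop_config("side must be a power of two >= 8, got %d", side)
  if (n_train < 1L || n_test < 1L)
    stop_config("n_train and n_test must be >= 1")
  var_def <- list(center_off = 0.15, radius = c(0.4, 0.8), lobes = 4:8,
                  hue = 0.1, lobe_depth = c(0.25, 0.45))
  var_def[names(variation)] <- variation
  structure(list(kind = kind, side = as.integer(side),
                 channels = as.integer(channels),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed), variation = var_def),
            class = "gencs_synth_config")
}

# 2x supersampled pixel-centre grid in [-1, 1]
render_grid <- function(side) {
  s <- 2L * side
  u <- (seq_len(s) - 0.5) / s * 2 - 1
  list(xx = matrix(u, s, s), yy = matrix(u, s, s, byrow = TRUE), s = s)
}

box_downsample2 <- function(m) {
  s <- nrow(m)
  o <- seq(1L, s, 2L)
  (m[o, o] + m[o + 1L, o] + m[o, o + 1L] + m[o + 1L, o + 1L]) / 4
}

render_rosette <- function(g, v) {
  cx <- runif(1, -v$center_off, v$center_off)
  cy <- runif(1, -v$center_off, v$center_off)
  r0 <- runif(1, v$radius[1], v$radius[2])
  lobes <- if (length(v$lobes) == 1L) v$lobes else sample(v$lobes, 1L)
  phase <- runif(1, 0, 2 * pi)
  depth <- runif(1, v$lobe_depth[1], v$lobe_depth[2])
  hue <- runif(1, -v$hue, v$hue)
  bg_j <- rnorm(3, sd = 0.03)
  tex <- list(f = runif(2, 2, 6), a = runif(1, 0, 2 * pi),
              p = runif(2, 0, 2 * pi), amp = runif(1, 0.02, 0.06))

  dx <- g$xx - cx; dy <- g$yy - cy
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  edge <- r0 * (0.62 + depth * cos(lobes * th + phase))
  leaf <- r <= edge
  core <- r <= 0.15 * r0
  shade <- 1 - 0.45 * pmin(r / pmax(edge, 1e-9), 1)

  u <- g$xx * cos(tex$a) + g$yy * sin(tex$a)
  w <- -g$xx * sin(tex$a) + g$yy * cos(tex$a)
  t1 <- tex$amp * (sin(tex$f[1] * pi * u + tex$p[1]) +
                   sin(tex$f[2] * pi * w + tex$p[2]))

  base <- c(-0.72, -0.70, -0.80) + bg_j
  leaf_col <- c(-0.45 + 0.3 * hue, 0.35 * (1 + hue), -0.45 - 0.2 * hue)
  core_col <- c(0.05, 0.15, -0.35)
  chans <- lapply(1:3, function(ci) {
    ch <- base[ci] + t1
    ch[leaf] <- (leaf_col[ci] + 0.65) * shade[leaf] - 0.65
    ch[core] <- core_col[ci]
    box_downsample2(ch)
  })
  chans
}

render_facelike <- function(g, v) {
  cx <- runif(1, -v$center_off, v$center_off)
  cy <- runif(1, -v$center_off, v$center_off)
  ax <- runif(1, 0.45, 0.60)
  ay <- runif(1, 0.60, 0.80)
  hue <- runif(1, -v$hue, v$hue)
  bg_j <- rnorm(3, sd = 0.05)
  eye_y <- cy - runif(1, 0.15, 0.28) * ay
  eye_dx <- runif(1, 0.35, 0.5) * ax
  eye_r <- runif(1, 0.06, 0.10)
  mouth_y <- cy + runif(1, 0.35, 0.5) * ay
  mouth_w <- runif(1, 0.18, 0.30)
  mouth_h <- runif(1, 0.05, 0.09)

  face <- ((g$xx - cx) / ax)^2 + ((g$yy - cy) / ay)^2 <= 1
  eyeL <- ((g$xx - (cx - eye_dx)) / eye_r)^2 +
          ((g$yy - eye_y) / (0.7 * eye_r))^2 <= 1
  eyeR <- ((g$xx - (cx + eye_dx)) / eye_r)^2 +
          ((g$yy - eye_y) / (0.7 * eye_r))^2 <= 1
  mouth <- ((g$xx - cx) / mouth_w)^2 + ((g$yy - mouth_y) / mouth_h)^2 <= 1

  grad <- 0.15 * g$yy
  base <- c(-0.35, -0.30, -0.15) + bg_j
  skin <- c(0.55 + 0.2 * hue, 0.15 + 0.1 * hue, -0.05 - 0.1 * hue)
  chans <- lapply(1:3, function(ci) {
    ch <- base[ci] + grad
    ch[face] <- skin[ci]
    ch[mouth & face] <- c(0.45, -0.35, -0.30)[ci]
    ch[(eyeL | eyeR) & face] <- -0.8
    box_downsample2(ch)
  })
  chans
}

#' Generate a seeded synthetic image dataset
#'
#' Draws `n_train + n_test` images from the configured low-dimensional scene
#' family; all randomness comes from `config$seed`, so identical calls
#' return bit-identical arrays. Values lie in \[-1, 1\].
#'
#' @param config A [synth_config()].
#' @return A `gencs_dataset`: list with `train` and `test` batch arrays of
#'   shape `side x side x channels x n` and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "gencs_synth_config"))
  set.seed(config$seed)
  g <- render_grid(config$side)
  n_all <- config$n_train + config$n_test
  render <- switch(config$kind, rosette = render_rosette,
                   facelike = render_facelike)
  imgs <- array(0, dim = c(config$side, config$side, config$channels, n_all))
  for (i in seq_len(n_all)) {
    chans <- render(g, config$variation)
    for (ci in seq_len(config$channels)) {
      imgs[, , ci, i] <- clamp(chans[[min(ci, 3L)]], -1, 1)
    }
  }
  structure(list(train = imgs[, , , seq_len(config$n_train), drop = FALSE],
                 test = imgs[, , , config$n_train + seq_len(config$n_test),
                             drop = FALSE],
                 config = config),
            class = "gencs_dataset")
}

#' @export
print.gencs_dataset <- function(x, ...) {
  cat(sprintf("<gencs_dataset> %s, side %d, %d train / %d test\n",
              x$config$kind, x$config$side, dim(x$train)[4], dim(x$test)[4]))
  invisible(x)
}

#' Mean pairwise Pearson correlation of a batch of images
#'
#' A scalar summary of within-set structural regularity: task-specific image
#' sets score far higher than white noise.
#'
#' @param images Batch array or matrix of flattened images.
#' @param max_images Cap on the number of images used (first `max_images`).
#' @return Mean of the upper-triangular pairwise correlation matrix.
#' @export
mean_pairwise_correlation <- function(images, max_images = 500L) {
  xm <- if (is.array(images) && length(dim(images)) >= 3L)
    flatten_images(images) else images
  if (nrow(xm) > max_images) xm <- xm[seq_len(max_images), , drop = FALSE]
  cm <- cor(t(xm))
  mean(cm[upper.tri(cm)])
}

#' Analytically solvable linear-decoder world
#'
#' Builds a verification oracle for latent-space reconstruction: a known
#' linear "generator" `A` (n x k, orthonormal columns), a Gaussian
#' measurement matrix `Phi`, latent truths `z*`, signals `x = A z*` (plus
#' optional Gaussian pixel noise) and exact measurements `y = Phi x`. When
#' `Phi A` has full column rank the least-squares latent solution is unique
#' and recoverable in closed form, so iterative reconstruction can be
#' checked against the normal-equations answer.
#'
#' @param n Ambient dimension.
#' @param k Latent dimension.
#' @param m Number of measurements; requires `k <= m <= n`.
#' @param n_samples Number of (z*, x, y) triples.
#' @param noise_sd Standard deviation of optional pixel noise (default 0).
#' @param seed Integer seed.
#' @param clip Clip noisy signals to \[-1, 1\] (only applied when
#'   `noise_sd > 0`).
#' @return A `gencs_linear_world` list with `A`, `phi` (a `gencs_matrix`),
#'   `z_star` (n_samples x k), `x` (n_samples x n), `y` (n_samples x m),
#'   `cond` (condition number of `Phi A`), `noise_sd` and `seed`.
#' @export
make_linear_world <- function(n, k, m, n_samples = 1L, noise_sd = 0,
                              seed = 0L, clip = FALSE) {
  if (k > m) stop_config(
    "k = %d > m = %d: least-squares latent recovery underdetermined", k, m)
  if (m > n) stop_config("need m <= n")
  set.seed(seed)
  A <- qr.Q(qr(matrix(rnorm(n * k), n, k)))
  phi <- matrix(rnorm(m * n), m, n)
  z_star <- matrix(rnorm(n_samples * k), n_samples, k)
  x <- tcrossprod(z_star, A)
  if (noise_sd > 0) {
    x <- x + matrix(rnorm(length(x), sd = noise_sd), nrow(x))
    if (clip) x <- clamp(x, -1, 1)
  }
  y <- tcrossprod(x, phi)
  pa <- phi %*% A
  structure(list(A = A, phi = new_measurement_matrix(phi, "gaussian"),
                 z_star = z_star, x = x, y = y,
                 cond = kappa(pa, exact = TRUE), noise_sd = noise_sd,
                 seed = seed),
            class = "gencs_linear_world")
}

#' Closed-form latent recovery in a linear world
#'
#' Solves the normal equations of the least-squares problem
#' `argmin_z || Phi A z - y ||^2` directly; the independent oracle against
#' which iterative reconstruction is validated.
#'
#' @param world A [make_linear_world()] object.
#' @param y Measurement matrix (rows); defaults to `world$y`.
#' @return Matrix of latent solutions, one row per measurement row.
#' @export
linear_world_solve <- function(world, y = world$y) {
  M <- world$phi$phi %*% world$A
  t(solve(crossprod(M), t(y %*% M)))
}

#' Wrap a linear world as a model usable by [reconstruct()]
#'
#' The Rebuilder is the linear map `A`, the Sampler is `Phi`, and the Solver
#' is the closed-form least-squares map (with unit variance), so the full
#' reconstruction machinery can run against an analytically known answer.
#'
#' @param world A [make_linear_world()] object.
#' @return A `gencs_model` with linear components.
#' @export
linear_model <- function(world) {
  M <- world$phi$phi %*% world$A
  pinv <- solve(crossprod(M), t(M))
  structure(list(
    sampler = list(phi = world$phi$phi, kind = "gaussian"),
    solver = structure(list(pinv = pinv, k = ncol(world$A)),
                       class = "linear_solver"),
    rebuilder = structure(list(A = world$A), class = "linear_rebuilder"),
    discriminator = NULL,
    config = list(side = NA_integer_, channels = NA_integer_,
                  k = ncol(world$A), n = nrow(world$A),
                  m = nrow(world$phi$phi))),
    class = "gencs_model")
}

#' Write a dataset as PNG files plus a JSON manifest
#'
#' @param dataset A `gencs_dataset`.
#' @param dir Output directory (created); images land in `train/` and
#'   `test/` subdirectories, 8-bit RGB, with the \[-1, 1\] values mapped to
#'   \[0, 1\].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gencs_dataset"))
  for (split in c("train", "test")) {
    d <- file.path(dir, split)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    imgs <- dataset[[split]]
    for (i in seq_len(dim(imgs)[4])) {
      png::writePNG(clamp((imgs[, , , i] + 1) / 2, 0, 1),
                    file.path(d, sprintf("img_%05d.png", i)))
    }
  }
  cfg <- dataset$config
  cfg$variation$lobes <- as.integer(cfg$variation$lobes)
  manifest <- list(config = unclass(cfg),
                   n_train = dim(dataset$train)[4],
                   n_test = dim(dataset$test)[4],
                   value_range = c(-1, 1), format = "png-8bit")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Dataset directory containing `manifest.json`.
#' @return A `gencs_dataset` (pixel values quantised to 8 bits).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  config <- synth_config(cfg$kind, cfg$side, cfg$channels, cfg$n_train,
                         cfg$n_test, cfg$seed,
                         variation = as.list(cfg$variation))
  read_split <- function(split) {
    files <- sort(list.files(file.path(dir, split), pattern = "\\.png$",
                             full.names = TRUE))
    imgs <- array(0, dim = c(cfg$side, cfg$side, cfg$channels,
                             length(files)))
    for (i in seq_along(files)) {
      v <- png::readPNG(files[i])
      if (length(dim(v)) == 2L) v <- array(v, dim = c(dim(v), 1L))
      imgs[, , , i] <- v[, , seq_len(cfg$channels)] * 2 - 1
    }
    imgs
  }
  structure(list(train = read_split("train"), test = read_split("test"),
                 config = config),
            class = "gencs_dataset")
}
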