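#' Model geometry and architecture configuration
#'
#' Defines the joint geometry of the four learnable parts. The Rebuilder
#' projects the k-dimensional latent vector to a `4 x 4` seed feature map
#' and upsamples through stride-2, kernel-5 transposed convolutions to the
#' configured side; the number of stages is `log2(side) - 2`, so the side
#' must be a power of two of at least 8. At the reference geometry
#' (`side = 64`, `width_base = 64`) the seed is `4 x 4 x 512` and the
#' channel schedule is 512-256-128-64-channels. The Solver is a fully
#' connected network with hidden widths 1024, 512 and 256 (ReLU + batch
#' normalisation) and a linear output of width `2k` holding the latent mean
#' and log-variance. The Discriminator mirrors the DCGAN critic: stride-2
#' convolutions with leaky-ReLU (slope 0.2) doubling channels each stage
#' from `width_base`, then a linear head to one logit.
#'
#' @param side Image side (power of two, >= 8). Default 64.
#' @param channels Image channels. Default 3.
#' @param k Latent dimension. Default 100.
#' @param sr Sampling rate in (0, 1]; the measurement count is
#'   `measurement_count(sr, side^2 * channels)`.
#' @param width_base Base channel width of Rebuilder/Discriminator
#'   (default 64, the reference geometry; smaller values give desk-scale
#'   models with the same design).
#' @param matrix_kind `"learned"` (Sampler weights trained jointly) or
#'   `"gaussian"` (fixed i.i.d. N(0,1) matrix, frozen during training).
#' @param tanh_hidden Use the hyperbolic tangent on all Rebuilder layers
#'   (the default); `FALSE` switches hidden layers to ReLU with a tanh
#'   output, the conventional DCGAN-generator variant.
#' @param solver_hidden Hidden widths of the Solver (default
#'   `c(1024, 512, 256)`).
#' @param precision `"single"` (default; convolution kernels run in single
#'   precision, the customary training precision) or `"double"` (used by
#'   gradient checks).
#' @param feature_layer Index of the Discriminator layer whose activation
#'   feeds the feature-matching loss; `NULL` selects the last convolutional
#'   feature map.
#' @param seed Seed for weight initialisation (N(0, 0.02) weights, zero
#'   biases) and the Gaussian matrix draw.
#' @return A `gencs_model_config` list (also records `n` and `m`).
#' @export
model_config <- function(side = 64L, channels = 3L, k = 100L, sr = 0.1,
                         width_base = 64L,
                         matrix_kind = c("learned", "gaussian"),
                         tanh_hidden = TRUE,
                         solver_hidden = c(1024L, 512L, 256L),
                         precision = c("single", "double"),
                         feature_layer = NULL, seed = 0L) {
  matrix_kind <- match.arg(matrix_kind)
  precision <- match.arg(precision)
  if (side < 8L || !is_power_of_two(side))
    stop_config("side must be a power of two >= 8, got %d", side)
  n <- as.integer(side)^2 * as.integer(channels)
  m <- measurement_count(sr, n)
  stages <- as.integer(log2(side) - 2)
  structure(list(side = as.integer(side), channels = as.integer(channels),
                 k = as.integer(k), sr = sr, n = n, m = m,
                 stages = stages, width_base = as.integer(width_base),
                 matrix_kind = matrix_kind, tanh_hidden = tanh_hidden,
                 solver_hidden = as.integer(solver_hidden),
                 precision = precision, feature_layer = feature_layer,
                 seed = as.integer(seed),
                 flatten_order = "row-major (height, width, channel)"),
            class = "gencs_model_config")
}

build_solver <- function(cfg) {
  single <- identical(cfg$precision, "single")
  widths <- c(cfg$m, cfg$solver_hidden)
  layers <- list()
  for (i in seq_along(cfg$solver_hidden)) {
    layers <- c(layers, list(layer_dense(widths[i], widths[i + 1L]),
                             layer_bn1d(widths[i + 1L]),
                             layer_act("relu")))
  }
  layers <- c(layers, list(
    layer_dense(widths[length(widths)], 2L * cfg$k)))
  structure(list(layers = layers, k = cfg$k, m = cfg$m),
            class = "net_solver")
}

build_rebuilder <- function(cfg) {
  single <- identical(cfg$precision, "single")
  c0 <- cfg$width_base * 2L^(cfg$stages - 1L)
  hid <- if (cfg$tanh_hidden) "tanh" else "relu"
  layers <- list(layer_dense(cfg$k, 4L * 4L * c0),
                 layer_act(hid),
                 layer_reshape_img(4L, 4L, c0))
  cin <- c0
  for (i in seq_len(cfg$stages)) {
    cout <- if (i < cfg$stages) cin %/% 2L else cfg$channels
    layers <- c(layers, list(layer_tconv(cin, cout, single = single),
                             layer_act(if (i < cfg$stages) hid else "tanh")))
    cin <- cout
  }
  structure(list(layers = layers, side = cfg$side, channels = cfg$channels,
                 k = cfg$k),
            class = "net_rebuilder")
}

build_discriminator <- function(cfg) {
  single <- identical(cfg$precision, "single")
  layers <- list()
  cin <- cfg$channels
  for (i in seq_len(cfg$stages)) {
    cout <- cfg$width_base * 2L^(i - 1L)
    layers <- c(layers, list(layer_conv(cin, cout, single = single),
                             layer_act("lrelu")))
    cin <- cout
  }
  flat_d <- 4L * 4L * cin
  layers <- c(layers, list(layer_flatten(), layer_dense(flat_d, 1L),
                           layer_act("sigmoid")))
  feature_layer <- cfg$feature_layer %||% (2L * cfg$stages)
  structure(list(layers = layers, feature_layer = feature_layer),
            class = "net_discriminator")
}

#' Initialise a full model
#'
#' Builds the Sampler (learned linear projection or frozen Gaussian
#' matrix), Solver, Rebuilder and Discriminator with seeded N(0, 0.02)
#' weight initialisation and zero biases.
#'
#' @param config A [model_config()].
#' @return A `gencs_model` list with components `sampler` (`$phi`,
#'   `$kind`), `solver`, `rebuilder`, `discriminator` and `config`.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "gencs_model_config"))
  set.seed(config$seed)
  phi <- if (config$matrix_kind == "gaussian") {
    matrix(rnorm(config$m * config$n), config$m, config$n)
  } else {
    matrix(rnorm(config$m * config$n, sd = 0.02), config$m, config$n)
  }
  structure(list(sampler = list(phi = phi, kind = config$matrix_kind),
                 solver = build_solver(config),
                 rebuilder = build_rebuilder(config),
                 discriminator = build_discriminator(config),
                 config = config),
            class = "gencs_model")
}

#' @export
print.gencs_model <- function(x, ...) {
  cfg <- x$config
  if (inherits(x$rebuilder, "linear_rebuilder")) {
    cat(sprintf("<gencs_model> linear oracle, n=%d k=%d m=%d\n",
                cfg$n, cfg$k, cfg$m))
  } else {
    np <- n_params(x)
    cat(sprintf(
      "<gencs_model> side=%d k=%d sr=%.3f (m=%d) matrix=%s, %s params\n",
      cfg$side, cfg$k, cfg$sr, cfg$m, x$sampler$kind,
      format(np$total, big.mark = ",")))
  }
  invisible(x)
}

#' Parameter counts per component
#' @param model A `gencs_model`.
#' @return List with counts for `sampler`, `solver`, `rebuilder`,
#'   `discriminator` and `total`.
#' @export
n_params <- function(model) {
  out <- list(sampler = length(model$sampler$phi),
              solver = n_params_net(model$solver),
              rebuilder = n_params_net(model$rebuilder),
              discriminator = n_params_net(model$discriminator))
  out$total <- sum(unlist(out))
  out
}

# the designated feature-layer activation, flattened to one row per image;
# the feature layer is a (leaky-)ReLU whose cache holds its input
disc_feature <- function(d, caches) {
  fl <- d$feature_layer
  lay <- d$layers[[fl]]
  xin <- caches[[fl]]$x
  feat <- if (identical(lay$type, "act") && lay$kind == "lrelu") {
    lrelu_cpp(xin, lay$alpha)
  } else if (identical(lay$type, "act") && lay$kind == "relu") {
    xin * (xin > 0)
  } else {
    stop("feature_layer must index an activation layer")
  }
  if (!is.null(dim(xin))) dim(feat) <- dim(xin)
  if (length(dim(feat)) == 4L) {
    dd <- dim(feat)
    t(matrix(feat, prod(dd[1:3]), dd[4]))
  } else feat
}

# ---- component forward passes (S3 over net vs linear-oracle components) ----

sv_forward <- function(solver, y, train = FALSE) UseMethod("sv_forward")

#' @export
sv_forward.net_solver <- function(solver, y, train = FALSE) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  if (ncol(y) != solver$m)
    stop_config("measurement length %d does not match m = %d",
                ncol(y), solver$m)
  r <- net_forward(solver, y, train = train)
  k <- solver$k
  list(mu = r$out[, seq_len(k), drop = FALSE],
       logvar = r$out[, k + seq_len(k), drop = FALSE],
       caches = r$caches, solver = r$net)
}

#' @export
sv_forward.linear_solver <- function(solver, y, train = FALSE) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  mu <- y %*% t(solver$pinv)
  list(mu = mu, logvar = mu * 0, caches = NULL, solver = solver)
}

rb_forward <- function(rebuilder, z, train = FALSE) UseMethod("rb_forward")

#' @export
rb_forward.net_rebuilder <- function(rebuilder, z, train = FALSE) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != rebuilder$k)
    stop_config("latent length %d does not match k = %d",
                ncol(z), rebuilder$k)
  r <- net_forward(rebuilder, z, train = train)
  list(out = r$out, caches = r$caches, rebuilder = r$net)
}

#' @export
rb_forward.linear_rebuilder <- function(rebuilder, z, train = FALSE) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  list(out = tcrossprod(z, rebuilder$A), caches = NULL,
       rebuilder = rebuilder)
}

# gradient of a scalar loss w.r.t. z given the gradient w.r.t. the output
rb_backward_z <- function(rebuilder, caches, dout) UseMethod("rb_backward_z")

#' @export
rb_backward_z.net_rebuilder <- function(rebuilder, caches, dout) {
  net_backward(rebuilder, caches, dout)$dx
}

#' @export
rb_backward_z.linear_rebuilder <- function(rebuilder, caches, dout) {
  dout %*% rebuilder$A
}

#' Solver forward pass
#'
#' Maps measurements to the latent Gaussian distribution
#' `(mu, logvar)`; the standard deviation is `exp(logvar / 2)`, so it is
#' positive by construction. Deterministic in eval mode (frozen batch-norm
#' statistics).
#'
#' @param model A `gencs_model` (or a solver component).
#' @param y Measurement vector or matrix (one row per image).
#' @param train Use batch statistics and update running ones.
#' @return List with `mu` and `logvar`, each `n x k`.
#' @export
solver_forward <- function(model, y, train = FALSE) {
  solver <- if (inherits(model, "gencs_model")) model$solver else model
  r <- sv_forward(solver, y, train = train)
  list(mu = r$mu, logvar = r$logvar)
}

#' Reparameterised latent sampling
#'
#' Draws `z = mu + exp(logvar/2) * eps` with `eps ~ N(0, I)`; written this
#' way so gradients flow to `mu` and `logvar` through the sample.
#'
#' @param dist List with `mu` and `logvar` (vectors or n x k matrices).
#' @param seed Optional seed for the draw.
#' @param eps Optional externally supplied standard-normal noise of the
#'   same shape (overrides `seed`); used for deterministic replay.
#' @return Latent vector/matrix of the same shape as `mu`.
#' @export
sample_latent <- function(dist, seed = NULL, eps = NULL) {
  mu <- dist$mu
  lv <- dist$logvar
  if (is.null(eps)) {
    if (!is.null(seed)) set.seed(seed)
    eps <- rnorm(length(mu))
    if (!is.null(dim(mu))) dim(eps) <- dim(mu)
  }
  mu + exp(lv / 2) * eps
}

#' Rebuilder forward pass
#'
#' Maps latent vectors to images. Output values lie strictly inside
#' (-1, 1) (final hyperbolic tangent).
#'
#' @param model A `gencs_model` (or a rebuilder component).
#' @param z Latent vector or `n x k` matrix.
#' @return Image batch array `side x side x channels x n` (a flattened
#'   `n x ambient` matrix for linear-oracle models).
#' @export
rebuild <- function(model, z) {
  rb <- if (inherits(model, "gencs_model")) model$rebuilder else model
  rb_forward(rb, z, train = FALSE)$out
}

#' Discriminator forward pass
#'
#' @param model A `gencs_model` (or a discriminator component).
#' @param x Image array or batch array.
#' @return List with `prob` (vector in (0,1)) and `features` (matrix, the
#'   flattened designated feature-layer activation per image).
#' @export
discriminate <- function(model, x) {
  d <- if (inherits(model, "gencs_model")) model$discriminator else model
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  r <- net_forward(d, x, train = FALSE)
  list(prob = as.vector(r$out), features = disc_feature(d, r$caches))
}

#' Full sensing-and-rebuilding forward pass
#'
#' The eval-mode composition `x_hat = R(Sv(Sp(x)))` using the latent mean
#' (no sampling): measure, solve for the latent distribution, rebuild from
#' its mean.
#'
#' @param model A `gencs_model`.
#' @param x Image array or batch.
#' @return Image batch array of the same shape as the input batch.
#' @export
pipeline_forward <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  y <- measure(model, x)
  dist <- solver_forward(model, y, train = FALSE)
  rebuild(model, dist$mu)
}
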