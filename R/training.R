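#' Loss configuration
#'
#' The three training losses:
#' \itemize{
#' \item Discriminator: `L_D = -log D(x) - log(1 - D(x_n))`, the binary
#'   cross entropy with the real image labelled 1 and the noise-generated
#'   image `x_n` labelled 0.
#' \item Rebuilder: `L_R = ||x_z - x||_p^p + ||D(x_z) - D(x)||_2^2
#'   - log D(x_n)`, where `x_z` is rebuilt from the encoded latent sample
#'   and the middle term compares either the designated Discriminator
#'   feature maps (default, the learned-similarity convention) or the
#'   scalar probabilities.
#' \item Encoder (Sampler + Solver): `L_E = ||x_z - x||_p^p + ||z||_2^2
#'   + L_l(mu, sigma) + ||D(x_z) - D(x)||_2^2` with the latent loss
#'   `L_l = -sum_i 0.5 (1 + log sigma_i^2 - sigma_i^2 - mu_i^2)`, the KL
#'   divergence from N(mu, sigma^2) to N(0, 1).
#' }
#' All image terms are summed over pixels and averaged over the batch
#' (`per_pixel = TRUE` switches to per-pixel averaging). Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` before logarithms.
#'
#' @param p Reconstruction norm order, 1 (default, the recommended variant)
#'   or 2.
#' @param feature_match `"feature_layer"` (default) or `"scalar_output"`.
#' @param weights Named non-negative weights for the terms `recon`,
#'   `feature`, `adv`, `znorm`, `latent`; all default to 1 (as the losses
#'   are written).
#' @param per_pixel Average image terms over pixels instead of summing.
#' @return A `gencs_loss_config` list.
#' @export
loss_config <- function(p = 1, feature_match = c("feature_layer",
                                                 "scalar_output"),
                        weights = list(), per_pixel = FALSE) {
  if (!p %in% c(1, 2)) stop_config("p must be 1 or 2")
  feature_match <- match.arg(feature_match)
  w <- list(recon = 1, feature = 1, adv = 1, znorm = 1, latent = 1)
  w[names(weights)] <- weights
  if (any(unlist(w) < 0)) stop_config("loss weights must be non-negative")
  structure(list(p = p, feature_match = feature_match, weights = w,
                 per_pixel = per_pixel),
            class = "gencs_loss_config")
}

#' Training schedule configuration
#'
#' @param batch_size Images per step (default 32).
#' @param lr Adam learning rate (default 0.001).
#' @param epochs Number of passes over the training set (default 30, a
#'   desk-scale setting; the reference geometry uses 100).
#' @param seed Seed controlling shuffling and all latent/noise draws.
#' @param beta1,beta2 Adam moment decays (DCGAN convention 0.5 / 0.999).
#' @return A `gencs_train_config` list.
#' @export
train_config <- function(batch_size = 32L, lr = 0.001, epochs = 30L,
                         seed = 0L, beta1 = 0.5, beta2 = 0.999) {
  if (batch_size < 1L || lr <= 0) stop_config("need batch_size >= 1, lr > 0")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2),
            class = "gencs_train_config")
}

#' Discriminator binary cross-entropy loss
#'
#' `-log(d_real) - log(1 - d_fake)` with natural logarithms; inputs are
#' probabilities in \[0, 1\] (clamped away from 0/1 before the logs).
#' Vector inputs return the mean.
#'
#' @param d_real,d_fake Discriminator probabilities for real images and
#'   noise-generated images.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  if (any(d_real < 0 | d_real > 1) || any(d_fake < 0 | d_fake > 1))
    stop_config("probabilities must lie in [0, 1]")
  pr <- clamp(d_real, PROB_EPS, 1 - PROB_EPS)
  pf <- clamp(d_fake, PROB_EPS, 1 - PROB_EPS)
  mean(-log(pr) - log(1 - pf))
}

#' Latent (KL) loss
#'
#' `L_l(mu, sigma) = -sum_i 0.5 (1 + log sigma_i^2 - sigma_i^2 - mu_i^2)`,
#' the KL divergence from the diagonal Gaussian N(mu, sigma^2) to the
#' standard normal; non-negative, zero exactly at mu = 0, sigma = 1.
#' Matrix inputs (one row per sample) return the batch mean of per-sample
#' sums.
#'
#' @param mu Mean vector or matrix.
#' @param logvar Log-variance vector or matrix (`sigma^2 = exp(logvar)`).
#' @return Scalar loss.
#' @export
latent_loss <- function(mu, logvar) {
  check_finite(mu, "mu"); check_finite(logvar, "logvar")
  per <- -0.5 * (1 + logvar - exp(logvar) - mu^2)
  if (is.matrix(mu)) mean(rowSums(per)) else sum(per)
}

recon_term <- function(x, x_z, p, per_pixel = FALSE) {
  d <- abs(x_z - x)
  v <- if (p == 1) d else d^2
  n_batch <- batch_size_of(x)
  s <- sum(v) / n_batch
  if (per_pixel) s / (length(x) / n_batch) else s
}

feature_term <- function(disc_outputs, cfg) {
  if (cfg$feature_match == "scalar_output") {
    mean((disc_outputs$d_xz - disc_outputs$d_x)^2)
  } else {
    mean(rowSums((disc_outputs$f_xz - disc_outputs$f_x)^2))
  }
}

#' Rebuilder loss
#'
#' See [loss_config()] for the formula. `disc_outputs` carries the
#' Discriminator responses: `d_x`, `d_xz`, `d_xn` (probabilities) and
#' `f_x`, `f_xz` (feature matrices, required for the default
#' feature-matching variant).
#'
#' @param x,x_z,x_n Ground truth, latent-rebuilt and noise-rebuilt images
#'   (same shape).
#' @param disc_outputs Named list of Discriminator responses.
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @export
rebuilder_loss <- function(x, x_z, x_n, disc_outputs,
                           config = loss_config()) {
  if (!identical(dim(x), dim(x_z))) stop_config("shape mismatch x vs x_z")
  w <- config$weights
  w$recon * recon_term(x, x_z, config$p, config$per_pixel) +
    w$feature * feature_term(disc_outputs, config) +
    w$adv * mean(-log(clamp(disc_outputs$d_xn, PROB_EPS, 1 - PROB_EPS)))
}

#' Encoder (Sampler + Solver) loss
#'
#' See [loss_config()] for the formula.
#'
#' @param x,x_z Ground truth and latent-rebuilt images.
#' @param z Sampled latent (vector or matrix).
#' @param mu,logvar Latent distribution parameters.
#' @param disc_outputs Named list of Discriminator responses (as in
#'   [rebuilder_loss()]).
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @export
encoder_loss <- function(x, x_z, z, mu, logvar, disc_outputs,
                         config = loss_config()) {
  if (!identical(dim(x), dim(x_z))) stop_config("shape mismatch x vs x_z")
  w <- config$weights
  zn <- if (is.matrix(z)) mean(rowSums(z^2)) else sum(z^2)
  w$recon * recon_term(x, x_z, config$p, config$per_pixel) +
    w$znorm * zn +
    w$latent * latent_loss(mu, logvar) +
    w$feature * feature_term(disc_outputs, config)
}

# One full forward pass plus (optionally) all gradients, evaluated at the
# step-start parameters. Returns losses, per-term values, parameter
# gradients for the Discriminator, Rebuilder and Encoder (Solver + Phi),
# and the solver with updated batch-norm running statistics.
train_forward_backward <- function(model, x, loss_cfg, eps_z, eps_n,
                                   want_grads = TRUE, train = TRUE) {
  cfg <- model$config
  w <- loss_cfg$weights
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[4]
  xflat <- flatten_images(x)
  phi <- model$sampler$phi
  y <- tcrossprod(xflat, phi)

  sv <- sv_forward(model$solver, y, train = train)
  mu <- sv$mu; logvar <- sv$logvar
  sig <- exp(logvar / 2)
  z <- mu + sig * eps_z

  zz <- rbind(z, eps_n)
  rb <- rb_forward(model$rebuilder, zz, train = train)
  idx_z <- seq_len(N); idx_n <- N + seq_len(N)
  x_z <- rb$out[, , , idx_z, drop = FALSE]
  x_n <- rb$out[, , , idx_n, drop = FALSE]

  xs <- array(c(x, rb$out), dim = c(dim(x)[1:3], 3L * N))
  d <- model$discriminator
  dr <- net_forward(d, xs, train = train)
  probs <- as.vector(dr$out)
  p_x <- probs[seq_len(N)]
  p_xz <- probs[N + seq_len(N)]
  p_xn <- probs[2L * N + seq_len(N)]
  feats <- disc_feature(d, dr$caches)
  f_x <- feats[seq_len(N), , drop = FALSE]
  f_xz <- feats[N + seq_len(N), , drop = FALSE]

  disc_outputs <- list(d_x = p_x, d_xz = p_xz, d_xn = p_xn,
                       f_x = f_x, f_xz = f_xz)
  terms <- list(
    recon = recon_term(x, x_z, loss_cfg$p, loss_cfg$per_pixel),
    feature = feature_term(disc_outputs, loss_cfg),
    adv = mean(-log(clamp(p_xn, PROB_EPS, 1 - PROB_EPS))),
    znorm = mean(rowSums(z^2)),
    latent = latent_loss(mu, logvar))
  losses <- list(
    L_D = discriminator_loss(p_x, p_xn),
    L_R = w$recon * terms$recon + w$feature * terms$feature +
      w$adv * terms$adv,
    L_E = w$recon * terms$recon + w$znorm * terms$znorm +
      w$latent * terms$latent + w$feature * terms$feature)
  if (!all(is.finite(unlist(losses)))) {
    stop_config("non-finite training loss (L_D=%g, L_R=%g, L_E=%g)",
                losses$L_D, losses$L_R, losses$L_E)
  }
  out <- list(losses = losses, terms = terms, solver = sv$solver,
              disc_outputs = disc_outputs)
  if (!want_grads) return(out)

  pix_scale <- if (loss_cfg$per_pixel) length(x) else N
  # --- Discriminator update gradients (real vs noise-generated; the
  #     latent-rebuilt slice gets a zero gradient) ---
  pr <- clamp(p_x, PROB_EPS, 1 - PROB_EPS)
  pf <- clamp(p_xn, PROB_EPS, 1 - PROB_EPS)
  dout_rf <- matrix(0, 3L * N, 1L)
  dout_rf[seq_len(N), 1L] <- -1 / (N * pr)
  dout_rf[2L * N + seq_len(N), 1L] <- 1 / (N * (1 - pf))
  grads_D <- net_backward(d, dr$caches, dout_rf,
                          need_dx_input = FALSE)$grads

  # --- gradients flowing back into the generated images ---
  dout_gen <- matrix(0, 3L * N, 1L)
  dout_gen[2L * N + seq_len(N), 1L] <- w$adv * (-1 / (N * pf))
  extra <- NULL
  if (loss_cfg$feature_match == "feature_layer") {
    dfeat <- w$feature * 2 * (f_xz - f_x) / N
    fl_cache <- dr$caches[[d$feature_layer]]$x
    fd <- dim(fl_cache)
    dfeat_arr <- array(0, dim = fd)
    dfeat_arr[, , , N + seq_len(N)] <-
      array(t(dfeat), dim = c(fd[1:3], N))
    extra <- list(index = d$feature_layer, grad = dfeat_arr)
  } else {
    dout_gen[N + seq_len(N), 1L] <- w$feature * 2 * (p_xz - p_x) / N
  }
  dimgs <- net_backward(d, dr$caches, dout_gen, extra = extra)$dx

  # --- Rebuilder gradients: x_z branch (recon + feature), x_n branch (adv)
  drecon <- if (loss_cfg$p == 1) sign(x_z - x) else 2 * (x_z - x)
  drecon <- w$recon * drecon / pix_scale
  dout_rb <- array(0, dim = dim(rb$out))
  dout_rb[, , , idx_z] <- drecon + dimgs[, , , N + seq_len(N), drop = FALSE]
  dout_rb[, , , idx_n] <- dimgs[, , , 2L * N + seq_len(N), drop = FALSE]
  rbk <- net_backward(model$rebuilder, rb$caches, dout_rb)
  grads_R <- rbk$grads

  # --- Encoder gradients through z = mu + sigma * eps ---
  dz <- rbk$dx[idx_z, , drop = FALSE] + w$znorm * 2 * z / N
  dmu <- dz + w$latent * mu / N
  dlogvar <- dz * 0.5 * sig * eps_z +
    w$latent * (-0.5 * (1 - exp(logvar))) / N
  sres <- net_backward(model$solver, sv$caches, cbind(dmu, dlogvar),
                       need_dx_input = TRUE)
  grads_E <- list(solver = sres$grads)
  if (model$sampler$kind == "learned") {
    grads_E$phi <- crossprod(sres$dx, xflat)
  }
  out$grads <- list(D = grads_D, R = grads_R, E = grads_E)
  out
}

#' Evaluate the three training losses on a batch
#'
#' Pure (no parameters are updated); the latent and noise draws can be
#' supplied explicitly, which makes the loss a deterministic function of
#' the parameters — this is what finite-difference gradient checks use.
#'
#' @param model A `gencs_model`.
#' @param x Image batch.
#' @param loss_cfg A [loss_config()].
#' @param eps_z Standard-normal reparameterisation noise (n x k).
#' @param eps_n Standard-normal noise latents (n x k).
#' @param train Evaluate with batch statistics (training mode), the mode
#'   used during optimisation.
#' @return List with `losses` (`L_D`, `L_R`, `L_E`) and per-`terms` values.
#' @export
training_losses <- function(model, x, loss_cfg = loss_config(),
                            eps_z = NULL, eps_n = NULL, train = TRUE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[4]
  k <- model$config$k
  if (is.null(eps_z)) eps_z <- matrix(rnorm(N * k), N, k)
  if (is.null(eps_n)) eps_n <- matrix(rnorm(N * k), N, k)
  r <- train_forward_backward(model, x, loss_cfg, eps_z, eps_n,
                              want_grads = FALSE, train = train)
  list(losses = r$losses, terms = r$terms)
}

train_opt_init <- function(model) {
  eparams <- list(solver = net_params(model$solver))
  if (model$sampler$kind == "learned") eparams$phi <- model$sampler$phi
  list(D = adam_init(net_params(model$discriminator)),
       R = adam_init(net_params(model$rebuilder)),
       E = adam_init(eparams))
}

#' One training step on a batch
#'
#' Runs the forward pass, computes all three losses and their gradients at
#' the step-start parameters, then applies one Adam step each in the order
#' Discriminator, Rebuilder, Encoder (Sampler + Solver jointly). When the
#' model uses a Gaussian measurement matrix, the matrix is frozen and
#' excluded from the Encoder update.
#'
#' @param model A `gencs_model`.
#' @param x Image batch array.
#' @param opt Optimiser state from a previous step, or `NULL` to
#'   initialise.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param eps_z,eps_n Optional explicit noise draws (default: drawn from
#'   the current RNG stream).
#' @return List with the updated `model`, `opt` state and a `record` of
#'   loss values and term breakdown.
#' @export
train_step <- function(model, x, opt = NULL, loss_cfg = loss_config(),
                       train_cfg = train_config(), eps_z = NULL,
                       eps_n = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[4]
  k <- model$config$k
  if (is.null(eps_z)) eps_z <- matrix(rnorm(N * k), N, k)
  if (is.null(eps_n)) eps_n <- matrix(rnorm(N * k), N, k)
  if (is.null(opt)) opt <- train_opt_init(model)

  r <- train_forward_backward(model, x, loss_cfg, eps_z, eps_n)
  model$solver <- r$solver      # batch-norm running statistics

  up <- adam_update(net_params(model$discriminator), r$grads$D, opt$D,
                    train_cfg$lr, train_cfg$beta1, train_cfg$beta2)
  model$discriminator <- net_set_params(model$discriminator, up$params)
  opt$D <- up$state

  up <- adam_update(net_params(model$rebuilder), r$grads$R, opt$R,
                    train_cfg$lr, train_cfg$beta1, train_cfg$beta2)
  model$rebuilder <- net_set_params(model$rebuilder, up$params)
  opt$R <- up$state

  eparams <- list(solver = net_params(model$solver))
  if (model$sampler$kind == "learned") eparams$phi <- model$sampler$phi
  up <- adam_update(eparams, r$grads$E, opt$E, train_cfg$lr,
                    train_cfg$beta1, train_cfg$beta2)
  model$solver <- net_set_params(model$solver, up$params$solver)
  if (model$sampler$kind == "learned") model$sampler$phi <- up$params$phi
  opt$E <- up$state

  list(model = model, opt = opt,
       record = c(r$losses, r$terms))
}

#' Train a full model
#'
#' Seeded epochs of shuffled batches, each processed by [train_step()].
#' With identical seeds and configuration the final model is bit-identical
#' across runs (single-threaded deterministic arithmetic).
#'
#' @param images Training images: a batch array or a `gencs_dataset` (its
#'   `train` split is used).
#' @param model A `gencs_model` from [init_model()], or a
#'   [model_config()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param checkpoint_dir Optional directory; a checkpoint is written after
#'   every epoch and the loss history alongside as CSV.
#' @param verbose Print one line per epoch.
#' @return List with the trained `model` and a `history` data frame (one
#'   row per step: epoch, step, losses and term breakdown).
#' @export
train_model <- function(images, model, loss_cfg = loss_config(),
                        train_cfg = train_config(), checkpoint_dir = NULL,
                        verbose = FALSE) {
  if (inherits(images, "gencs_dataset")) images <- images$train
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  n_img <- dim(images)[4]
  if (n_img < 1L) stop_config("empty training set")
  if (inherits(model, "gencs_model_config")) model <- init_model(model)

  set.seed(train_cfg$seed)
  opt <- train_opt_init(model)
  steps_per_epoch <- ceiling(n_img / train_cfg$batch_size)
  history <- vector("list", train_cfg$epochs * steps_per_epoch)
  si <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    perm <- sample.int(n_img)
    for (b in seq_len(steps_per_epoch)) {
      idx <- perm[((b - 1L) * train_cfg$batch_size + 1L):
                  min(b * train_cfg$batch_size, n_img)]
      st <- train_step(model, images[, , , idx, drop = FALSE], opt,
                       loss_cfg, train_cfg)
      model <- st$model
      opt <- st$opt
      si <- si + 1L
      history[[si]] <- c(list(epoch = epoch, step = si), st$record)
    }
    if (verbose) {
      h <- history[[si]]
      message(sprintf("epoch %3d  L_D %.4f  L_R %.2f  L_E %.2f",
                      epoch, h$L_D, h$L_R, h$L_E))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(model,
                      file.path(checkpoint_dir,
                                sprintf("epoch_%03d.rds", epoch)))
    }
  }
  history <- do.call(rbind, lapply(history, function(h)
    as.data.frame(h)))
  if (!is.null(checkpoint_dir)) {
    utils::write.csv(history, file.path(checkpoint_dir, "history.csv"),
                     row.names = FALSE)
  }
  list(model = model, history = history)
}
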