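# image loading, checkpoints and the end-to-end experiment driver

# (to x from) matrix of pixel-overlap weights realising area interpolation
area_resize_matrix <- function(from, to) {
  W <- matrix(0, to, from)
  scale <- from / to
  for (i in seq_len(to)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- ceiling(hi)
    for (j in j0:min(j1, from)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov / scale
    }
  }
  W
}

#' Load PNG images as model-scale arrays
#'
#' Decodes 8-bit PNGs, centre-crops to square, resizes to the configured
#' side with area interpolation (anti-aliasing on downscale) and maps
#' pixel values to \[-1, 1\] via `v / 127.5 - 1` (0 maps to -1, 255 to 1).
#'
#' @param path A PNG file or a directory of PNGs (searched
#'   non-recursively, sorted by name).
#' @param side Target side in pixels (default 64).
#' @param channels Required channel count (default 3); greyscale inputs
#'   are an error when 3 channels are required.
#' @return Batch array `side x side x channels x n`.
#' @export
load_images <- function(path, side = 64L, channels = 3L) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  } else path
  if (length(files) == 0L) stop_config("no PNG files at %s", path)
  out <- array(0, dim = c(side, side, channels, length(files)))
  for (i in seq_along(files)) {
    v <- png::readPNG(files[i])
    if (length(dim(v)) == 2L) {
      if (channels == 3L)
        stop_config("greyscale image %s where 3 channels required",
                    files[i])
      v <- array(v, dim = c(dim(v), 1L))
    }
    if (dim(v)[3] > channels) v <- v[, , seq_len(channels), drop = FALSE]
    h <- dim(v)[1]; w <- dim(v)[2]
    s <- min(h, w)
    r0 <- (h - s) %/% 2L
    c0 <- (w - s) %/% 2L
    v <- v[r0 + seq_len(s), c0 + seq_len(s), , drop = FALSE]
    A <- area_resize_matrix(s, side)
    for (ci in seq_len(channels)) {
      out[, , ci, i] <- A %*% v[, , ci] %*% t(A) * 2 - 1
    }
  }
  out
}

#' Save a model checkpoint
#'
#' One archive holding all four parameter sets plus the model
#' configuration (geometry, sampling rate, flatten order, seed).
#'
#' @param model A `gencs_model`.
#' @param path Output file path (RDS archive).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gencs_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path Checkpoint path.
#' @return A `gencs_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gencs_model")) stop_config("not a model checkpoint")
  model
}

#' End-to-end experiment configuration
#'
#' @param kind Synthetic dataset kind (`"rosette"` or `"facelike"`).
#' @param side Image side (power of two >= 8).
#' @param k Latent dimension.
#' @param n_train,n_test Dataset split sizes.
#' @param sr_list Sampling rates to train at.
#' @param matrix_kinds Sampler variants to train (`"learned"`,
#'   `"gaussian"`).
#' @param width_base Network base width (see [model_config()]).
#' @param loss A [loss_config()].
#' @param train A [train_config()].
#' @param recon A [recon_config()].
#' @param seed Global seed; per-model seeds are derived from it.
#' @param write_data Also write the generated dataset as PNGs.
#' @return A `gencs_experiment_config` list.
#' @export
experiment_config <- function(kind = "rosette", side = 32L, k = 16L,
                              n_train = 500L, n_test = 50L,
                              sr_list = c(0.02, 0.05),
                              matrix_kinds = c("learned", "gaussian"),
                              width_base = 32L,
                              loss = loss_config(),
                              train = train_config(),
                              recon = recon_config(),
                              seed = 0L, write_data = FALSE) {
  structure(list(kind = kind, side = as.integer(side), k = as.integer(k),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 sr_list = sr_list, matrix_kinds = matrix_kinds,
                 width_base = as.integer(width_base), loss = loss,
                 train = train, recon = recon, seed = as.integer(seed),
                 write_data = write_data),
            class = "gencs_experiment_config")
}

#' Run a full experiment: data, training grid, reconstruction, metrics
#'
#' Generates the dataset, trains one model per (sampling rate, matrix
#' kind), reconstructs the shared test set with each, and writes
#' checkpoints, loss histories, per-image metrics and the summary table
#' under `out_dir`. The resolved configuration is written first, so the
#' whole run is reproducible from `out_dir/config.rds` plus the seeds.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory.
#' @param verbose Print progress.
#' @return List with the `metrics` table and the named list of trained
#'   `models`.
#' @export
run_experiment <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "gencs_experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(config, file.path(out_dir, "config.rds"))
  jsonlite::write_json(
    list(kind = config$kind, side = config$side, k = config$k,
         n_train = config$n_train, n_test = config$n_test,
         sr_list = config$sr_list, matrix_kinds = config$matrix_kinds,
         width_base = config$width_base, seed = config$seed,
         p = config$loss$p, epochs = config$train$epochs,
         batch_size = config$train$batch_size, lr = config$train$lr,
         recon_lr = config$recon$lr, imax = config$recon$imax),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)

  sc <- synth_config(config$kind, config$side, 3L, config$n_train,
                     config$n_test, seed = config$seed)
  ds <- generate_dataset(sc)
  if (config$write_data) write_dataset(ds, file.path(out_dir, "data"))

  models <- list()
  i <- 0L
  for (sr in config$sr_list) {
    for (mk in config$matrix_kinds) {
      i <- i + 1L
      nm <- sprintf("%s_sr%g", mk, sr)
      if (verbose) message("training ", nm)
      mcfg <- model_config(side = config$side, k = config$k, sr = sr,
                           width_base = config$width_base,
                           matrix_kind = mk,
                           seed = config$seed + 1000L * i)
      tcfg <- config$train
      tcfg$seed <- config$seed + 1000L * i + 1L
      fit <- train_model(ds$train, init_model(mcfg), config$loss, tcfg,
                         verbose = FALSE)
      save_checkpoint(fit$model,
                      file.path(out_dir, paste0(nm, ".rds")))
      utils::write.csv(fit$history,
                       file.path(out_dir, paste0(nm, "_history.csv")),
                       row.names = FALSE)
      models[[nm]] <- fit$model
    }
  }
  metrics <- evaluate_models(models, ds$test, config$recon,
                             file = file.path(out_dir, "metrics.csv"))
  if (verbose) {
    message("metrics written to ", file.path(out_dir, "metrics.csv"))
    print(metrics)
  }
  list(metrics = metrics, models = models)
}
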