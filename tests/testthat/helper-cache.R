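# Desk-scale replication study shared across test files: 500 rosette images
# at side 32, latent dimension 16, sampling rates 0.02 and 0.05, three
# replicate seeds for the learned-matrix and Gaussian-matrix variants.
# Trained once on first access and cached for the session.

.gencs_cache <- new.env(parent = emptyenv())

ablation_study <- function() {
  if (!is.null(.gencs_cache$ablation)) return(.gencs_cache$ablation)
  ds <- generate_dataset(synth_config("rosette", side = 32L,
                                      n_train = 500L, n_test = 50L,
                                      seed = 101L))
  grid <- expand.grid(replicate = 1:3, kind = c("learned", "gaussian"),
                      sr = c(0.02, 0.05), stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  histories <- vector("list", nrow(grid))
  keep_model <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    mcfg <- model_config(side = 32L, k = 16L, sr = g$sr,
                         width_base = 32L, matrix_kind = g$kind,
                         seed = 200L + 10L * g$replicate)
    tcfg <- train_config(epochs = 10L, seed = 300L + 10L * g$replicate)
    fit <- train_model(ds$train, init_model(mcfg), loss_config(p = 1),
                       tcfg)
    br <- batch_reconstruct(ds$test, fit$model, recon_config(imax = 100L))
    rows[[i]] <- cbind(g, psnr = br$summary$psnr_mean,
                       ssim = br$summary$ssim_mean)
    histories[[i]] <- fit$history
    if (is.null(keep_model) && g$kind == "learned" && g$sr == 0.05) {
      keep_model <- fit$model
    }
  }
  .gencs_cache$ablation <- list(results = do.call(rbind, rows),
                                histories = histories, model = keep_model,
                                test = ds$test, grid = grid)
  .gencs_cache$ablation
}
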