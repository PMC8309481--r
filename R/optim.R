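# Adam optimiser over arbitrarily nested parameter lists.
# The update is fused into a single tree traversal; with ~10^6 parameters
# spread over many leaves this matters on a single core.

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_leaf <- function(p, g, m, v, c1, c2, lr, beta1, beta2, eps) {
  adam_leaf_cpp(p, g, m, v, c1, c2, lr, beta1, beta2, eps)
}

adam_tree <- function(p, g, m, v, c1, c2, lr, beta1, beta2, eps) {
  if (is.list(p)) {
    rm_ <- p; rmm <- m; rmv <- v
    for (i in seq_along(p)) {
      r <- adam_tree(p[[i]], g[[i]], m[[i]], v[[i]], c1, c2, lr, beta1,
                     beta2, eps)
      rm_[[i]] <- r$p; rmm[[i]] <- r$m; rmv[[i]] <- r$v
    }
    list(p = rm_, m = rmm, v = rmv)
  } else {
    adam_leaf(p, g, m, v, c1, c2, lr, beta1, beta2, eps)
  }
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  r <- adam_tree(params, grads, state$m, state$v, c1, c2, lr, beta1,
                 beta2, eps)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}
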