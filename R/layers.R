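# Minimal layer engine with explicit forward/backward passes.
#
# A network is a list of layers; each layer is a list carrying its type,
# its parameters (named arrays under $params) and fixed hyperparameters.
# Dense layers operate on N x features matrices; convolutional layers on
# (H, W, C, N) arrays. Batch-normalisation running statistics live in the
# layer and are returned updated from a training-mode forward pass.

layer_dense <- function(n_in, n_out, init_sd = 0.02) {
  list(type = "dense",
       params = list(W = matrix(rnorm(n_in * n_out, sd = init_sd), n_in, n_out),
                     b = numeric(n_out)))
}

layer_bn1d <- function(d, momentum = 0.9, eps = 1e-5) {
  list(type = "bn1d",
       params = list(gamma = rep(1, d), beta = numeric(d)),
       running_mean = numeric(d), running_var = rep(1, d),
       momentum = momentum, eps = eps)
}

layer_act <- function(kind, alpha = 0.2) {
  list(type = "act", kind = kind, alpha = alpha, params = list())
}

layer_reshape_img <- function(h, w, c) {
  list(type = "reshape_img", h = h, w = w, c = c, params = list())
}

layer_flatten <- function() list(type = "flatten", params = list())

layer_conv <- function(c_in, c_out, k = 5L, stride = 2L, pad = 2L,
                       single = TRUE, init_sd = 0.02) {
  list(type = "conv", stride = stride, pad = pad, single = single,
       params = list(W = array(rnorm(k * k * c_in * c_out, sd = init_sd),
                               dim = c(k, k, c_in, c_out)),
                     b = numeric(c_out)))
}

layer_tconv <- function(c_in, c_out, k = 5L, stride = 2L, pad = 2L,
                        opad = 1L, single = TRUE, init_sd = 0.02) {
  list(type = "tconv", stride = stride, pad = pad, opad = opad,
       single = single,
       params = list(W = array(rnorm(k * k * c_out * c_in, sd = init_sd),
                               dim = c(k, k, c_out, c_in)),
                     b = numeric(c_out)))
}

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    dense = {
      out <- x %*% layer$params$W
      out <- sweep(out, 2L, layer$params$b, "+")
      list(out = out, cache = list(x = x), layer = layer)
    },
    bn1d = {
      eps <- layer$eps
      if (train) {
        mu <- colMeans(x)
        xc <- sweep(x, 2L, mu)
        v <- colMeans(xc^2)
        xhat <- sweep(xc, 2L, sqrt(v + eps), "/")
        m <- layer$momentum
        layer$running_mean <- m * layer$running_mean + (1 - m) * mu
        layer$running_var <- m * layer$running_var + (1 - m) * v
      } else {
        mu <- layer$running_mean
        v <- layer$running_var
        xc <- sweep(x, 2L, mu)
        xhat <- sweep(xc, 2L, sqrt(v + eps), "/")
      }
      out <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L,
                   layer$params$beta, "+")
      list(out = out,
           cache = list(xhat = xhat, var = v, train = train),
           layer = layer)
    },
    act = {
      out <- switch(layer$kind,
        relu = x * (x > 0),
        lrelu = lrelu_cpp(x, layer$alpha),
        tanh = tanh(x),
        sigmoid = 1 / (1 + exp(-x)))
      if (!is.null(dim(x))) dim(out) <- dim(x)
      cache <- if (layer$kind %in% c("relu", "lrelu")) list(x = x)
               else list(out = out)
      list(out = out, cache = cache, layer = layer)
    },
    reshape_img = {
      n <- nrow(x)
      out <- array(t(x), dim = c(layer$h, layer$w, layer$c, n))
      list(out = out, cache = list(n = n), layer = layer)
    },
    flatten = {
      d <- dim(x)
      out <- t(matrix(x, prod(d[1:3]), d[4]))
      list(out = out, cache = list(d = d), layer = layer)
    },
    conv = {
      r <- conv_fwd_cache_cpp(x, layer$params$W, layer$params$b,
                              layer$stride, layer$pad, layer$single)
      list(out = r$out, cache = list(cols = r$cols, xdim = r$xdim),
           layer = layer)
    },
    tconv = {
      out <- tconv_fwd_cpp(x, layer$params$W, layer$params$b,
                           layer$stride, layer$pad, layer$opad, layer$single)
      list(out = out, cache = list(x = x), layer = layer)
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, cache, dout, need_dx = TRUE) {
  switch(layer$type,
    dense = {
      grads <- list(W = crossprod(cache$x, dout), b = colSums(dout))
      dx <- if (need_dx) tcrossprod(dout, layer$params$W) else NULL
      list(dx = dx, grads = grads)
    },
    bn1d = {
      xhat <- cache$xhat
      n <- nrow(xhat)
      dgamma <- colSums(dout * xhat)
      dbeta <- colSums(dout)
      dx <- NULL
      if (need_dx) {
        if (cache$train) {
          dxhat <- sweep(dout, 2L, layer$params$gamma, "*")
          inv_sd <- 1 / sqrt(cache$var + layer$eps)
          t1 <- sweep(dxhat, 2L, colMeans(dxhat))
          t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
          dx <- sweep(t1 - t2, 2L, inv_sd, "*")
        } else {
          dx <- sweep(sweep(dout, 2L, layer$params$gamma, "*"), 2L,
                      sqrt(layer$running_var + layer$eps), "/")
        }
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      dx <- switch(layer$kind,
        relu = dout * (cache$x > 0),
        lrelu = lrelu_bwd_cpp(cache$x, dout, layer$alpha),
        tanh = dout * (1 - cache$out^2),
        sigmoid = dout * cache$out * (1 - cache$out))
      list(dx = dx, grads = list())
    },
    reshape_img = {
      d <- dim(dout)
      list(dx = t(matrix(dout, prod(d[1:3]), d[4])), grads = list())
    },
    flatten = {
      list(dx = array(t(dout), dim = cache$d), grads = list())
    },
    conv = {
      r <- conv_bwd_cache_cpp(cache$cols, cache$xdim, layer$params$W, dout,
                              layer$stride, layer$pad, need_dx,
                              layer$single)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    },
    tconv = {
      r <- tconv_bwd_cpp(cache$x, layer$params$W, dout, layer$stride,
                         layer$pad, need_dx, layer$single)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    },
    stop("unknown layer type"))
}

# Forward through a whole network. Returns the output, per-layer caches and
# the (possibly updated, for batch norm) network.
net_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x, train = train)
    x <- r$out
    caches[[i]] <- r$cache
    net$layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, net = net)
}

# Backward through a whole network. `extra` optionally injects an additional
# gradient at the output of layer `extra$index` (used for feature matching).
# Returns dx at the input and parameter gradients in the same nested shape
# as net_params().
net_backward <- function(net, caches, dout, extra = NULL,
                         need_dx_input = TRUE) {
  L <- length(net$layers)
  grads <- vector("list", L)
  for (i in rev(seq_len(L))) {
    if (!is.null(extra) && extra$index == i) {
      dout <- dout + extra$grad
    }
    need_dx <- i > 1L || need_dx_input
    r <- layer_backward(net$layers[[i]], caches[[i]], dout, need_dx = need_dx)
    grads[[i]] <- r$grads
    dout <- r$dx
  }
  list(dx = dout, grads = grads)
}

net_params <- function(net) lapply(net$layers, function(l) l$params)

net_set_params <- function(net, params) {
  for (i in seq_along(net$layers)) net$layers[[i]]$params <- params[[i]]
  net
}

n_params_net <- function(net) {
  sum(unlist(lapply(net_params(net), function(p) sum(vapply(p, length, 1L)))))
}
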