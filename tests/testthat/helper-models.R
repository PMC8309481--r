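# shared builders for tiny models and seeded fixtures

tiny_model <- function(side = 8L, k = 3L, sr = 0.05, width_base = 8L,
                       precision = "double", matrix_kind = "learned",
                       seed = 2L) {
  init_model(model_config(side = side, channels = 3L, k = k, sr = sr,
                          width_base = width_base, precision = precision,
                          matrix_kind = matrix_kind, seed = seed))
}

tiny_batch <- function(side = 8L, n = 4L, seed = 3L) {
  set.seed(seed)
  array(runif(side * side * 3L * n, -1, 1), c(side, side, 3L, n))
}

# seeded image pairs used for metric oracles (the same recipe generated the
# frozen reference values)
ssim_fixture_pairs <- function(n_pairs = 50L, side = 16L, seed = 100L) {
  set.seed(seed)
  lapply(seq_len(n_pairs), function(i) {
    x <- matrix(runif(side * side, -1, 1), side, side)
    sdv <- 0.05 + 0.4 * runif(1)
    y <- pmin(pmax(x + matrix(rnorm(side * side, sd = sdv), side, side),
                   -1), 1)
    list(x = x, y = y)
  })
}

# naive direct convolution, the independent oracle for the GEMM kernels
naive_conv <- function(x, W, b, stride = 2L, pad = 2L) {
  d <- dim(x); k <- dim(W)[1]; Co <- dim(W)[4]
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  out <- array(0, c(Ho, Wo, Co, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(Co))
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      s <- b[co]
      for (ci in seq_len(d[3])) for (i in seq_len(k)) for (j in seq_len(k)) {
        h <- (ho - 1L) * stride - pad + i
        w <- (wo - 1L) * stride - pad + j
        if (h >= 1 && h <= d[1] && w >= 1 && w <= d[2])
          s <- s + x[h, w, ci, n] * W[i, j, ci, co]
      }
      out[ho, wo, co, n] <- s
    }
  out
}

# central finite difference of f at x[idx], step h
central_fd <- function(f, x, idx, h = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}
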