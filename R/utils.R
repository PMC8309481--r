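#' @useDynLib gencs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif cor sd
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

is_power_of_two <- function(x) {
  x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

#' Flatten images to measurement-ready row vectors
#'
#' Images are flattened in row-major order over (height, width, channel),
#' i.e. channel fastest, then column, then row. The order is fixed so that a
#' learned measurement matrix stays portable across save/load; checkpoints
#' record it.
#'
#' @param x An image array of shape `side x side x channels` or a batch of
#'   shape `side x side x channels x n`.
#' @return A numeric matrix with one row per image and `side^2 * channels`
#'   columns.
#' @export
flatten_images <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  d <- dim(x)
  n <- prod(d[1:3])
  t(matrix(aperm(x, c(3L, 2L, 1L, 4L)), nrow = n, ncol = d[4]))
}

#' Restore flattened row vectors to image arrays
#'
#' Inverse of [flatten_images()].
#'
#' @param m Matrix with one flattened image per row (or a single vector).
#' @param side Image side in pixels.
#' @param channels Number of channels.
#' @return Array of shape `side x side x channels x nrow(m)`.
#' @export
unflatten_images <- function(m, side, channels) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  n <- nrow(m)
  a <- array(t(m), dim = c(channels, side, side, n))
  aperm(a, c(3L, 2L, 1L, 4L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# probabilities are clamped before logs for numerical safety
PROB_EPS <- 1e-7

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_config("non-finite values in %s", what)
  invisible(x)
}

# last-dimension subset of a batch array (images or matrices); keeps dims
batch_subset <- function(x, idx) {
  d <- dim(x)
  if (is.null(d)) return(x[idx])
  if (length(d) == 2L) return(x[idx, , drop = FALSE])
  if (length(d) == 4L) return(x[, , , idx, drop = FALSE])
  stop("unsupported batch array")
}

batch_size_of <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(1L)          # a single flattened image
  switch(as.character(length(d)),
         "2" = d[1],                  # rows of flattened images
         "3" = 1L,                    # one H x W x C image
         "4" = d[4],                  # image batch
         stop("unsupported batch array"))
}

# map a function over every numeric leaf of two parallel nested lists
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map(f, a[[nm]])
    out
  } else {
    f(a)
  }
}
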