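abort_persbo <- function(message, class) {
  abort(message, class = c(paste0("persbo_", class), "persbo_error"))
}

warn_persbo <- function(message, class) {
  warn(message, class = c(paste0("persbo_", class), "persbo_warning"))
}

#' Derive a child seed from a master seed and a key
#'
#' Deterministic 32-bit mixing so that every randomized step of a protocol or
#' benchmark run draws from its own reproducible stream, keyed by iteration,
#' algorithm, repeat, etc.
#'
#' @param seed master integer seed.
#' @param ... integer key components.
#' @return an integer seed in `[1, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  key <- c(seed, ...)
  h <- 0
  for (k in key) h <- (h * 69069 + as.numeric(k) + 1) %% 2147483562
  as.integer(h) + 1L
}

# squared Euclidean distances between rows of A and rows of B
sqdist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_persbo(sprintf("`%s` must be a single finite number.", name), "invalid_input")
  }
  if (positive && x <= 0) {
    abort_persbo(sprintf("`%s` must be > 0.", name), "invalid_input")
  }
  invisible(x)
}
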