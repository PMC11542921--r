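# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stop_param("`%s` must be > 0", name)
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_param("`%s` must be an integer", name)
  }
  invisible(x)
}

as_image <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "visual_target")) return(x$pixels)
  stop_param("expected a pixel matrix or visual_target")
}

# Window operator for separable local statistics: a (n - w + 1) x n matrix
# whose i-th row holds the 1-D kernel at offset i ("valid" windows only).
window_operator <- function(n, kernel) {
  w <- length(kernel)
  if (w > n) stop_param("window (%d) larger than image dimension (%d)", w, n)
  m <- n - w + 1L
  op <- matrix(0, m, n)
  for (i in seq_len(m)) op[i, i:(i + w - 1L)] <- kernel
  op
}

gaussian_kernel_1d <- function(width, sigma) {
  half <- (width - 1) / 2
  k <- exp(-((seq_len(width) - 1 - half)^2) / (2 * sigma^2))
  k / sum(k)
}

# Squared Euclidean norm of a matrix or vector.
sq_norm <- function(x) sum(x * x)

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer whatever the user passes for the master seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
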