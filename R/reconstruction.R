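# Linear reconstruction and the bias-variance expected-error objective.
#
# A sequence of stimuli c_1..c_T evokes independent Bernoulli responses
# r_i ~ Bernoulli(p_{c_i}); the brain is modeled as linearly reconstructing
# the stimulus from the summed spike counts, s_hat = A (r_1 + ... + r_T). The
# expected squared error decomposes exactly into a bias term on the expected
# reconstruction and a sum of per-element variances:
#   E ||s - A sum r_i||^2 = ||s - A sum p_{c_i}||^2 + sum_i v_{c_i},
#   v_c = sum_n ||a_n||^2 p_{n,c} (1 - p_{n,c}).

#' Linear reconstruction of a stimulus from a spike-count response
#'
#' @param filters A `recon_filter`.
#' @param response Numeric vector of spike counts, one per cell.
#' @return Pixel matrix `A %*% response` reshaped to the filter grid.
#' @export
reconstruct <- function(filters, response) {
  if (length(response) != ncol(filters$A)) {
    stop_param("response length %d != number of cells %d",
               length(response), ncol(filters$A))
  }
  matrix(as.numeric(filters$A %*% response),
         filters$grid_shape[1], filters$grid_shape[2])
}

#' Relative mean squared error between target and reconstruction
#'
#' Squared error normalized by the squared norm of the target:
#' `||s - s_hat||^2 / ||s||^2`.
#'
#' @param target,reconstruction Pixel matrices (or `visual_target`s) of equal
#'   shape.
#' @return Non-negative scalar.
#' @export
relative_mse <- function(target, reconstruction) {
  s <- as_image(target); r <- as_image(reconstruction)
  if (!all(dim(s) == dim(r))) stop_param("target and reconstruction shapes differ")
  denom <- sq_norm(s)
  if (denom == 0) stop_param("relative MSE undefined for an all-zero target")
  sq_norm(s - r) / denom
}

#' Reconstruction variance contributed by one dictionary element
#'
#' `v_c = sum_n ||a_n||^2 p_{n,c} (1 - p_{n,c})`, the total pixel variance of
#' the reconstruction when the element's Bernoulli response is sampled once.
#'
#' @param filters A `recon_filter`.
#' @param p_c Activation-probability vector over cells (values in \[0, 1\]).
#' @return Non-negative scalar; exactly 0 when every probability is 0 or 1.
#' @export
element_variance <- function(filters, p_c) {
  if (length(p_c) != ncol(filters$A)) stop_param("probability vector length mismatch")
  if (any(p_c < 0 | p_c > 1)) stop_param("probabilities must be in [0, 1]")
  sum(filters$col_sq_norms * p_c * (1 - p_c))
}

#' Expected squared reconstruction error of a stimulation sequence
#'
#' Evaluates the exact bias-variance decomposition for a sequence of
#' activation-probability vectors under per-step response independence.
#'
#' @param target Pixel matrix or `visual_target`.
#' @param filters A `recon_filter`.
#' @param probability_sequence Matrix (cells x steps), list of probability
#'   vectors, or NULL/zero-column for an empty sequence.
#' @return An `error_report`: list with `bias`, `variance`, `expected_error`
#'   (= bias + variance) and `relative_expected_error` (divided by
#'   `||target||^2`).
#' @export
expected_error <- function(target, filters, probability_sequence) {
  s <- as_image(target)
  n_cells <- ncol(filters$A)
  if (is.list(probability_sequence)) {
    probability_sequence <-
      if (length(probability_sequence) == 0) matrix(0, n_cells, 0)
      else do.call(cbind, probability_sequence)
  }
  if (is.null(probability_sequence)) probability_sequence <- matrix(0, n_cells, 0)
  P <- as.matrix(probability_sequence)
  if (nrow(P) != n_cells) stop_param("probability vectors have wrong length")
  if (any(P < 0 | P > 1)) stop_param("probabilities must be in [0, 1]")
  cum_p <- if (ncol(P) > 0) rowSums(P) else numeric(n_cells)
  bias <- sq_norm(s - reconstruct(filters, cum_p))
  variance <- sum(filters$col_sq_norms * P * (1 - P))
  structure(
    list(bias = bias, variance = variance, expected_error = bias + variance,
         relative_expected_error = (bias + variance) / sq_norm(s)),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> expected %.4g (bias %.4g + variance %.4g), relative %.4g\n",
              x$expected_error, x$bias, x$variance, x$relative_expected_error))
  invisible(x)
}

#' Fractional performance gap between two error levels
#'
#' `(err_hi - err_lo) / err_hi`: the fraction of error that the better method
#' removes. Used consistently for the greedy-vs-relaxed and
#' dictionary-vs-perfect-control comparisons.
#'
#' @param err_hi,err_lo Errors with `err_hi >= err_lo >= 0` expected (the
#'   value is still computed if the ordering is violated, and is then
#'   negative).
#' @return Scalar gap (1 = the better method removes all error).
#' @export
fractional_gap <- function(err_hi, err_lo) (err_hi - err_lo) / err_hi
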