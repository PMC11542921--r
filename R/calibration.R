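# Activation-curve calibration analysis: sigmoid fits in log-amplitude,
# threshold extraction, and the bi-electrode exclusion-radius summary.

#' Fit a sigmoidal activation curve to stimulation scan data
#'
#' Maximum-likelihood logistic regression of spike probability on
#' log-amplitude (the calibration grid is logarithmic, so the sigmoid lives in
#' log-current). The activation threshold is the amplitude at which the fitted
#' curve crosses probability 0.5; its variance is obtained from the observed
#' information via the delta method.
#'
#' @param amplitudes Current amplitudes (µA), at least 4 levels.
#' @param trial_counts Trials per amplitude.
#' @param success_counts Evoked-spike counts per amplitude (real-valued counts
#'   are accepted, so noiseless probability data can be fit exactly).
#' @return An `activation_curve`: amplitude grid, observed probabilities,
#'   fitted coefficients (intercept, slope on log-amplitude), `threshold_uA`,
#'   `threshold_var`, `fitted_p`, and `identifiable` (FALSE when responses are
#'   all-zero or all-max, in which case the threshold is NA).
#' @export
fit_sigmoid_activation <- function(amplitudes, trial_counts, success_counts) {
  if (length(amplitudes) < 4) stop_param("need at least 4 amplitude levels")
  if (length(trial_counts) != length(amplitudes) ||
      length(success_counts) != length(amplitudes)) {
    stop_param("amplitudes, trial_counts and success_counts must align")
  }
  if (any(success_counts < 0) || any(trial_counts < 0) ||
      any(success_counts > trial_counts)) {
    stop_param("counts must satisfy 0 <= successes <= trials")
  }
  obs_p <- ifelse(trial_counts > 0, success_counts / trial_counts, NA)
  curve <- list(amplitudes = amplitudes, trial_counts = trial_counts,
                success_counts = success_counts, probabilities = obs_p)
  tot_s <- sum(success_counts); tot_n <- sum(trial_counts)
  if (tot_s == 0 || tot_s == tot_n) {
    curve$identifiable <- FALSE
    curve$threshold_uA <- NA_real_
    curve$threshold_var <- NA_real_
    class(curve) <- "activation_curve"
    return(curve)
  }
  la <- log(amplitudes)
  fit <- suppressWarnings(
    stats::glm(cbind(success_counts, trial_counts - success_counts) ~ la,
               family = stats::binomial())
  )
  co <- stats::coef(fit)
  curve$coefficients <- co
  curve$fitted_p <- stats::plogis(co[1] + co[2] * la)
  if (!is.finite(co[2]) || co[2] <= 0) {
    curve$identifiable <- FALSE
    curve$threshold_uA <- NA_real_
    curve$threshold_var <- NA_real_
  } else {
    lt <- unname(-co[1] / co[2])
    vc <- stats::vcov(fit)
    grad <- c(-1 / co[2], co[1] / co[2]^2)
    var_lt <- as.numeric(t(grad) %*% vc %*% grad)
    curve$identifiable <- TRUE
    curve$threshold_uA <- exp(lt)
    # delta method: Var(exp(lt)) ~= exp(lt)^2 Var(lt)
    curve$threshold_var <- exp(lt)^2 * var_lt
  }
  class(curve) <- "activation_curve"
  curve
}

#' @export
print.activation_curve <- function(x, ...) {
  if (isTRUE(x$identifiable)) {
    cat(sprintf("<activation_curve> threshold %.3g uA (SD %.2g), %d levels\n",
                x$threshold_uA, sqrt(x$threshold_var), length(x$amplitudes)))
  } else {
    cat("<activation_curve> non-identifiable (no threshold)\n")
  }
  invisible(x)
}

#' Fractional change in activation threshold between two curves
#'
#' `|t_paired - t_single| / t_single`: the interaction measure for
#' bi-electrode stimulation, scale-invariant in current units.
#'
#' @param single_curve,paired_curve `activation_curve`s (single-electrode and
#'   paired-electrode).
#' @return Scalar, or NA with a warning if either threshold is undefined.
#' @export
fractional_threshold_change <- function(single_curve, paired_curve) {
  if (!isTRUE(single_curve$identifiable) || !isTRUE(paired_curve$identifiable)) {
    warning("undefined threshold; returning NA")
    return(NA_real_)
  }
  abs(paired_curve$threshold_uA - single_curve$threshold_uA) /
    single_curve$threshold_uA
}

#' Distance-binned summary of bi-electrode threshold interactions
#'
#' Bins electrode pairs by separation and computes, per bin, the
#' inverse-variance weighted mean fractional threshold change and a bootstrap
#' standard error (pairs are resampled within bins).
#'
#' @param pair_results Data frame with columns `distance_um`, `frac_change`
#'   and `threshold_var` (single-electrode threshold variance used for the
#'   weights).
#' @param distance_bins Bin edges in µm (default 8 bins to 400 µm).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for resampling.
#' @return Data frame: bin_lo, bin_hi, n_pairs, weighted_mean, boot_se.
#'   Empty bins are omitted with a message.
#' @export
exclusion_radius_summary <- function(pair_results,
                                     distance_bins = seq(0, 400, by = 50),
                                     n_boot = 1000L, seed = 1L) {
  need <- c("distance_um", "frac_change", "threshold_var")
  if (!all(need %in% names(pair_results))) {
    stop_param("pair_results must have columns %s", paste(need, collapse = ", "))
  }
  ok <- stats::complete.cases(pair_results[, need])
  pr <- pair_results[ok, ]
  bin <- cut(pr$distance_um, distance_bins, include.lowest = TRUE)
  set.seed(derive_seed(seed, 6L))
  rows <- lapply(seq_along(levels(bin)), function(b) {
    idx <- which(as.integer(bin) == b)
    if (length(idx) == 0) {
      message(sprintf("bin %s empty; omitted", levels(bin)[b]))
      return(NULL)
    }
    wts <- 1 / pmax(pr$threshold_var[idx], .Machine$double.eps)
    wm <- sum(wts * pr$frac_change[idx]) / sum(wts)
    boots <- vapply(seq_len(n_boot), function(r) {
      j <- idx[sample.int(length(idx), length(idx), replace = TRUE)]
      wj <- 1 / pmax(pr$threshold_var[j], .Machine$double.eps)
      sum(wj * pr$frac_change[j]) / sum(wj)
    }, 0)
    data.frame(bin_lo = distance_bins[b], bin_hi = distance_bins[b + 1],
               n_pairs = length(idx), weighted_mean = wm,
               boot_se = stats::sd(boots))
  })
  do.call(rbind, rows)
}

#' Simulate a single-electrode (or bi-electrode) activation scan
#'
#' Draws binomial spike counts from a ground-truth logistic activation curve,
#' emulating the calibration protocol (default: 40 log-spaced levels over
#' 0.1-4 µA, 27 trials each). A threshold shift factor emulates the effect of
#' a simultaneously stimulating secondary electrode.
#'
#' @param threshold_uA True activation threshold.
#' @param slope True sigmoid slope in log-amplitude.
#' @param n_trials Trials per level (default 27).
#' @param amplitudes Amplitude grid (default 40 log-spaced in 0.1-4).
#' @param shift_factor Multiplies the threshold (1 = no interaction).
#' @param seed Integer seed.
#' @return Data frame: amplitude_uA, n_trials, n_spikes.
#' @export
simulate_activation_scan <- function(threshold_uA, slope = 10, n_trials = 27L,
                                     amplitudes = NULL, shift_factor = 1,
                                     seed = 1L) {
  if (is.null(amplitudes)) {
    amplitudes <- exp(seq(log(0.1), log(4), length.out = 40))
  }
  set.seed(derive_seed(seed, 7L))
  p <- stats::plogis(slope * (log(amplitudes) - log(threshold_uA * shift_factor)))
  data.frame(amplitude_uA = amplitudes, n_trials = n_trials,
             n_spikes = stats::rbinom(length(p), n_trials, p))
}
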