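# Stimulation dictionary: single-electrode stimuli at logarithmically spaced
# current amplitudes, with per-cell activation probabilities following a
# sigmoid in log-amplitude whose threshold grows with soma-electrode distance.

#' Generate a calibrated-like single-electrode stimulation dictionary
#'
#' Every (electrode, amplitude) pair is a candidate dictionary element. The
#' activation probability of cell `n` for current `a` on an electrode at
#' distance `d` from its soma is `plogis(slope * (log(a) - log(t)))` with
#' threshold `t = t0_n * exp(d / lambda_d)`; `t0_n` carries mild log-normal
#' cell-to-cell heterogeneity. Probabilities below 0.005 are truncated to zero
#' (they are unmeasurable at calibration trial counts). Elements are retained
#' only if they activate at least one cell with probability >= 0.01; a random
#' fraction of high-amplitude elements is flagged as axon-bundle activation
#' and excluded (high-current stimuli predominantly recruit axon bundles on
#' real arrays, so the default removes most of the top amplitude tertile). A single null element (all-zero probabilities, element_id 0)
#' is appended so the encoder can always choose not to stimulate.
#'
#' `selectivity` in (0, 1] sets the spatial decay length
#' `lambda_d = 40 + 120 * (1 - selectivity)` µm: smaller values give more
#' non-selective elements that co-activate two or more cells, as seen with
#' axonal stimulation in calibrated interfaces.
#'
#' @param array An `electrode_array`.
#' @param population A `cell_population` (as from [make_retina()]).
#' @param filters The matching `recon_filter` (used for variance penalties).
#' @param n_amplitudes Number of current levels (default 40).
#' @param amp_range_uA Amplitude range in µA, logarithmically spaced
#'   (default 0.1–4).
#' @param selectivity Spatial selectivity control in (0, 1], see Details.
#' @param axon_fraction Fraction of elements flagged as axon-bundle activation
#'   (drawn from the high-amplitude tertile) and excluded.
#' @param seed Integer seed.
#' @param threshold_base_uA Median activation threshold at zero
#'   soma-electrode distance (µA).
#' @param threshold_sd_log Log-normal SD of cell-to-cell threshold
#'   heterogeneity.
#' @param slope Sigmoid slope in log-amplitude units.
#' @param retention_p Minimum per-cell activation probability for an element
#'   to be retained (default 0.01).
#' @param axon_contact_prob Probability that a (cell, electrode) pair is
#'   coupled through the cell's axon of passage: such pairs activate at a
#'   near-somatic threshold regardless of soma distance. Off (0) by default;
#'   enabling it *adds* access paths, enlarging the retained dictionary.
#' @return A `stim_dictionary`: sparse matrix `D` (cells x retained elements,
#'   null element last), variance vector `v` (`v_c = sum_n ||a_n||^2 *
#'   p_{n,c} (1 - p_{n,c})`), `elements` data frame aligned with the columns
#'   of `D`, full `meta` table for all raw elements (with `axon_bundle` and
#'   `retained` flags), and `electrode_xy`.
#' @export
make_dictionary <- function(array, population, filters,
                            n_amplitudes = 40L, amp_range_uA = c(0.1, 4),
                            selectivity = 0.25, axon_fraction = 0.25,
                            seed = 1L, threshold_base_uA = 2.1,
                            threshold_sd_log = 0.5, slope = 6,
                            retention_p = 0.01, axon_contact_prob = 0) {
  if (!inherits(array, "electrode_array")) stop_param("`array` must be an electrode_array")
  if (!inherits(filters, "recon_filter")) stop_param("`filters` must be a recon_filter")
  n_cells <- nrow(population)
  if (ncol(filters$A) != n_cells) {
    stop_param("population (%d cells) does not match filters (%d columns)",
               n_cells, ncol(filters$A))
  }
  check_scalar(n_amplitudes, "n_amplitudes", positive = TRUE, integerish = TRUE)
  if (selectivity <= 0 || selectivity > 1) stop_param("`selectivity` must be in (0, 1]")

  set.seed(derive_seed(seed, 3L))
  lambda_d <- 40 + 120 * (1 - selectivity)
  amps <- exp(seq(log(amp_range_uA[1]), log(amp_range_uA[2]),
                  length.out = n_amplitudes))
  n_elec <- nrow(array$positions)
  n_raw <- n_elec * n_amplitudes
  meta <- data.frame(
    element_id = seq_len(n_raw),
    electrode_id = rep(seq_len(n_elec), each = n_amplitudes),
    amplitude_uA = rep(amps, n_elec),
    stringsAsFactors = FALSE
  )

  # Axon-bundle emulation: flag a random subset of high-amplitude elements.
  high <- which(meta$amplitude_uA >= amps[ceiling(2 * n_amplitudes / 3)])
  n_flag <- min(length(high), round(axon_fraction * n_raw))
  meta$axon_bundle <- FALSE
  if (n_flag > 0) meta$axon_bundle[sample(high, n_flag)] <- TRUE

  p_trip <- NULL
  max_p <- numeric(n_raw)
  if (n_cells > 0) {
    t0 <- threshold_base_uA * exp(stats::rnorm(n_cells, 0, threshold_sd_log))
    soma <- cbind(population$soma_x_um, population$soma_y_um)
    dmat <- sqrt(outer(soma[, 1], array$positions[, 1], "-")^2 +
                 outer(soma[, 2], array$positions[, 2], "-")^2)
    thr <- t0 * exp(dmat / lambda_d)          # cells x electrodes
    if (axon_contact_prob > 0) {
      # axon-of-passage couplings: distant pairs with near-somatic thresholds
      contact <- matrix(stats::runif(length(thr)) < axon_contact_prob,
                        nrow(thr), ncol(thr))
      thr_ax <- t0 * exp(40 / lambda_d)
      thr[contact] <- pmin(thr[contact], rep(thr_ax, ncol(thr))[row(thr)[contact]])
    }
    # Only pairs whose threshold can yield p >= 0.005 within the amplitude
    # range contribute nonzero probabilities.
    reach <- which(thr <= amp_range_uA[2] * exp(-stats::qlogis(0.005) / slope),
                   arr.ind = TRUE)
    if (nrow(reach) > 0) {
      cell_i <- rep(reach[, 1], each = n_amplitudes)
      elec_i <- rep(reach[, 2], each = n_amplitudes)
      amp_i <- rep(seq_len(n_amplitudes), nrow(reach))
      p <- stats::plogis(slope * (log(amps[amp_i]) -
                                  log(thr[reach])[rep(seq_len(nrow(reach)),
                                                      each = n_amplitudes)]))
      keep <- p >= 0.005
      el_col <- (elec_i - 1L) * n_amplitudes + amp_i
      p_trip <- cbind(cell = cell_i[keep], el = el_col[keep], p = p[keep])
      mp <- tapply(p_trip[, 3], p_trip[, 2], max)
      max_p[as.integer(names(mp))] <- mp
    }
  }
  meta$max_p <- max_p
  meta$retained <- max_p >= retention_p & !meta$axon_bundle

  kept <- which(meta$retained)
  if (!is.null(p_trip)) {
    col_of <- match(p_trip[, 2], kept)
    ok <- !is.na(col_of)
    D <- Matrix::sparseMatrix(i = p_trip[ok, 1], j = col_of[ok],
                              x = p_trip[ok, 3],
                              dims = c(n_cells, length(kept) + 1L))
  } else {
    D <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n_cells, length(kept) + 1L))
  }
  elements <- data.frame(
    element_id = c(meta$element_id[kept], 0L),
    electrode_id = c(meta$electrode_id[kept], NA_integer_),
    amplitude_uA = c(meta$amplitude_uA[kept], NA_real_),
    is_null = c(rep(FALSE, length(kept)), TRUE),
    stringsAsFactors = FALSE
  )
  a2 <- filters$col_sq_norms
  v <- as.numeric(Matrix::colSums(D * (1 - D) * a2))
  structure(
    list(D = D, v = v, elements = elements, meta = meta,
         electrode_xy = array$positions, n_cells = n_cells,
         params = list(n_amplitudes = n_amplitudes, amp_range_uA = amp_range_uA,
                       selectivity = selectivity, lambda_d_um = lambda_d,
                       axon_fraction = axon_fraction, seed = seed,
                       threshold_base_uA = threshold_base_uA,
                       threshold_sd_log = threshold_sd_log, slope = slope,
                       retention_p = retention_p,
                       axon_contact_prob = axon_contact_prob)),
    class = "stim_dictionary"
  )
}

#' @export
print.stim_dictionary <- function(x, ...) {
  n_multi <- sum(Matrix::colSums(x$D >= 0.5) >= 2)
  cat(sprintf(paste0("<stim_dictionary> %d retained elements (+1 null), ",
                     "%d cells, %d co-activate >=2 cells at p>=0.5\n"),
              ncol(x$D) - 1L, x$n_cells, n_multi))
  invisible(x)
}

#' Number of elements (columns of D, including the null element)
#' @param dictionary A `stim_dictionary`.
#' @export
n_elements <- function(dictionary) ncol(dictionary$D)

#' Sample Bernoulli spike responses for one dictionary element
#'
#' Each trial draws an independent 0/1 spike for every cell with the element's
#' calibrated activation probabilities.
#'
#' @param dictionary A `stim_dictionary`.
#' @param element_id Element id (0 for the null element).
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed.
#' @return Integer matrix, trials x cells.
#' @export
sample_responses <- function(dictionary, element_id, n_trials, seed = 1L) {
  check_scalar(n_trials, "n_trials", positive = TRUE, integerish = TRUE)
  col <- match(element_id, dictionary$elements$element_id)
  if (is.na(col)) stop_param("unknown element_id: %s", element_id)
  p <- as.numeric(dictionary$D[, col])
  set.seed(derive_seed(seed, 4L))
  matrix(stats::rbinom(n_trials * length(p), 1L, rep(p, each = n_trials)),
         n_trials, length(p))
}

#' Restrict a dictionary to a subset of electrodes
#'
#' Keeps all retained elements on the given electrodes plus the null element;
#' used for hardware-subsampling analyses.
#'
#' @param dictionary A `stim_dictionary`.
#' @param electrode_ids Electrode ids to keep.
#' @return A `stim_dictionary` with the restricted element set.
#' @export
restrict_dictionary <- function(dictionary, electrode_ids) {
  keep <- dictionary$elements$is_null |
    dictionary$elements$electrode_id %in% electrode_ids
  if (sum(keep) <= 1L) stop_param("restriction removes every stimulating element")
  out <- dictionary
  out$D <- dictionary$D[, keep, drop = FALSE]
  out$v <- dictionary$v[keep]
  out$elements <- dictionary$elements[keep, , drop = FALSE]
  rownames(out$elements) <- NULL
  out
}
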