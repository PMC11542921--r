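# Performance bounds and the static pixel-wise baseline.
#
# relaxed_joint: minimize ||s - A D w||^2 + v'w over w >= 0 (continuous
# relaxation of the integer element-usage program) -- a lower bound on any
# ordered stimulation sequence's expected error, hence on greedy dithering.
# perfect_control: minimize ||s - A r||^2 over r >= 0 -- the error floor if
# every cell's spike count could be set independently.

#' Relaxed joint optimization lower bound
#'
#' Solves the convex program `min_{w >= 0} ||s - A D w||^2 + v'w` by
#' coordinate descent with an active-set strategy (full sweeps locate
#' violators of the KKT conditions, inner sweeps refine the support). The
#' linear variance penalty rules out a plain non-negative least-squares
#' reformulation, so the solver is exact for the stated objective.
#'
#' @param target Pixel matrix or `visual_target`.
#' @param filters A `recon_filter`.
#' @param dictionary A `stim_dictionary`.
#' @param tol Relative objective-change convergence tolerance (default 1e-8).
#' @param kkt_tol KKT residual tolerance at return (default 1e-5, scaled).
#' @param max_sweeps Full-sweep cap; exceeding it raises a diagnostic error.
#' @param cache Optional [element_cache()].
#' @return List with `w` (usage vector over dictionary columns), `objective`
#'   (`||s - ADw||^2 + v'w`), `bias`, `variance_term`,
#'   `relative_expected_error` (objective / ||s||^2), `relative_mse_expected`
#'   (bias-only / ||s||^2), `kkt_residual`, `sweeps`.
#' @export
relaxed_joint <- function(target, filters, dictionary, tol = 1e-8,
                          kkt_tol = 1e-5, max_sweeps = 10000L, cache = NULL) {
  if (ncol(dictionary$D) < 1) stop_param("dictionary has no elements")
  if (is.null(cache)) cache <- element_cache(filters, dictionary)
  s <- as.numeric(as_image(target))
  m <- ncol(cache$Q)
  b <- as.numeric(Matrix::crossprod(cache$Q, s))
  qq <- cache$qq
  v <- cache$v
  g_idx <- cache$g_idx; g_val <- cache$g_val
  c0 <- sq_norm(s)

  w <- numeric(m)
  g <- numeric(m)                       # g = G w
  obj <- c0
  act <- which(qq > 0)                  # null / zero columns never help
  objective <- function() c0 - 2 * sum(b * w) + sum(w * g) + sum(v * w)

  sweep_set <- function(set) {
    for (j in set) {
      num <- b[j] - v[j] / 2 - (g[j] - qq[j] * w[j])
      wj <- max(0, num / qq[j])
      dlt <- wj - w[j]
      if (dlt != 0) {
        idx <- g_idx[[j]]
        g[idx] <<- g[idx] + g_val[[j]] * dlt
        w[j] <<- wj
      }
    }
  }

  kkt_scale <- max(1, if (length(act)) max(abs(2 * b[act] - v[act])) else 1)
  kkt_res <- function() {
    grad <- 2 * (g - b) + v
    r <- 0
    if (length(act)) r <- max(r, max(-grad[act]))
    if (any(w > 0)) r <- max(r, max(abs(grad[w > 0])))
    r / kkt_scale
  }

  sweeps <- 0L
  res <- Inf
  repeat {
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps) {
      stop_param("relaxed_joint did not converge: KKT residual %.3g after %d sweeps",
                 res, sweeps - 1L)
    }
    sweep_set(act)
    # refine on the current support until stalled
    repeat {
      prev <- objective()
      sweep_set(which(w > 0))
      cur <- objective()
      if (prev - cur <= tol * max(1, abs(cur))) break
    }
    new <- objective()
    res <- kkt_res()
    if (res <= kkt_tol && obj - new <= tol * max(1, abs(new))) {
      obj <- new
      break
    }
    obj <- new
  }
  # exact recomputation (guards against incremental drift in g)
  bias <- sq_norm(s - as.numeric(cache$Q %*% w))
  obj <- bias + sum(v * w)
  g <- as.numeric(Matrix::crossprod(cache$Q, cache$Q %*% w))
  res <- kkt_res()
  list(w = w, objective = obj, bias = bias, variance_term = sum(v * w),
       relative_expected_error = obj / c0, relative_mse_expected = bias / c0,
       kkt_residual = res, sweeps = sweeps)
}

#' Perfect-control lower bound
#'
#' Non-negative least squares `min_{r >= 0} ||s - A r||^2`: the reconstruction
#' error if the interface could set every cell's spike count directly. Solved
#' with the Lawson-Hanson algorithm.
#'
#' @param target Pixel matrix or `visual_target`.
#' @param filters A `recon_filter` with at least one cell.
#' @return List with `r` (relaxed spike-count vector), `objective`
#'   (`||s - Ar||^2`) and `relative_mse`.
#' @export
perfect_control <- function(target, filters) {
  if (ncol(filters$A) == 0) stop_param("filters contain no cells")
  s <- as.numeric(as_image(target))
  fit <- pracma::lsqnonneg(as.matrix(filters$A), s)
  r <- as.numeric(fit$x)
  obj <- sq_norm(s - as.numeric(filters$A %*% r))
  list(r = r, objective = obj, relative_mse = obj / sq_norm(s))
}

# ---- Static pixel-wise baseline ------------------------------------------

# Mean target intensity in a square window (side window_um) centered on each
# electrode; pixels whose centers fall in the window contribute equally.
electrode_window_pixels <- function(filters, array, window_um = 130) {
  half <- window_um / 2
  lapply(seq_len(nrow(array$positions)), function(e) {
    ex <- array$positions[e, 1]; ey <- array$positions[e, 2]
    cols <- which(abs(filters$pixel_x - ex) <= half)
    rows <- which(abs(filters$pixel_y - ey) <= half)
    as.integer(outer(rows, (cols - 1L) * filters$grid_shape[1], "+"))
  })
}

sigmoid_current <- function(s, par) par[1] + par[2] / (1 + exp(par[3] * s + par[4]))

# Snap a requested current to the element with the nearest retained amplitude
# on the electrode (log scale, matching the logarithmic calibration grid).
snap_element <- function(current, elec_elems) {
  if (current <= 0 || nrow(elec_elems) == 0) return(NA_integer_)
  elec_elems$column[which.min(abs(log(elec_elems$amplitude_uA) - log(current)))]
}

# Expected-reconstruction contribution of one electrode across targets.
elec_apply_par <- function(e, par, by_elec, intens, Q, dictionary, n_t, n_max) {
  n_rep <- max(0L, min(n_max, round(par[5])))
  img <- matrix(0, nrow(Q), n_t); vr <- numeric(n_t)
  if (n_rep > 0) {
    for (k in seq_len(n_t)) {
      colq <- snap_element(sigmoid_current(intens[e, k], par), by_elec[[e]])
      if (!is.na(colq)) {
        img[, k] <- n_rep * as.numeric(Q[, colq])
        vr[k] <- n_rep * dictionary$v[colq]
      }
    }
  }
  list(img = img, vr = vr)
}

#' Fit the static pixel-wise mapping baseline
#'
#' Approximates existing implants: each electrode's current is a scaled
#' sigmoid `i = a + b / (1 + exp(c s + d))` of the mean target intensity in a
#' window around the electrode, delivered `n` times. All five parameters are
#' fit per electrode by derivative-free (Nelder-Mead) minimization of the
#' expected reconstruction error over the training targets, cycling over
#' electrodes (block coordinate descent) since the bias term couples them.
#' Electrodes with no retained element are excluded (`n = 0`).
#'
#' @param training_targets List of targets.
#' @param filters A `recon_filter`.
#' @param dictionary A `stim_dictionary`.
#' @param array The `electrode_array`.
#' @param window_um Intensity-sampling window size (default 130 µm).
#' @param passes Block-coordinate passes over electrodes (default 2).
#' @param maxit Nelder-Mead iterations per electrode per pass (default 60).
#' @param n_max Largest allowed repeat count per electrode (default 20).
#' @param init Optional `pixelwise_mapping` (or parameter matrix with columns
#'   a, b, c, d, n) to start the block descent from; the returned training
#'   error never exceeds the initial mapping's.
#' @return A `pixelwise_mapping`: per-electrode parameter table and achieved
#'   `training_error` (mean relative expected error).
#' @export
fit_pixelwise_mapping <- function(training_targets, filters, dictionary, array,
                                  window_um = 130, passes = 2L, maxit = 60L,
                                  n_max = 20L, init = NULL) {
  if (length(training_targets) < 1) stop_param("need at least one training target")
  n_elec <- nrow(array$positions)
  win <- electrode_window_pixels(filters, array, window_um)
  Q <- filters$A %*% dictionary$D
  el <- dictionary$elements
  by_elec <- lapply(seq_len(n_elec), function(e) {
    idx <- which(!el$is_null & el$electrode_id == e)
    data.frame(column = idx, amplitude_uA = el$amplitude_uA[idx])
  })
  s_mats <- lapply(training_targets, as_image)
  s_norms <- vapply(s_mats, sq_norm, 0)
  n_t <- length(s_mats)
  S <- vapply(s_mats, as.numeric, numeric(nrow(Q)))
  S <- matrix(S, nrow(Q), n_t)
  # mean window intensity per (electrode, target)
  intens <- vapply(s_mats, function(sm) {
    sv <- as.numeric(sm)
    vapply(win, function(px) if (length(px)) mean(sv[px]) else 0, 0)
  }, numeric(n_elec))
  intens <- matrix(intens, n_elec)

  contrib <- vector("list", n_elec)
  par_tab <- matrix(rep(c(0.5, 3, -4, 0, 0), each = n_elec), n_elec)
  colnames(par_tab) <- c("a", "b", "c", "d", "n")
  if (!is.null(init)) {
    pm <- if (inherits(init, "pixelwise_mapping"))
      as.matrix(init$parameters[, c("a", "b", "c", "d", "n")]) else as.matrix(init)
    if (!all(dim(pm) == dim(par_tab))) stop_param("init has wrong dimensions")
    par_tab[] <- pm
  }
  active <- which(vapply(by_elec, nrow, 0L) > 0)
  par_tab[setdiff(seq_len(n_elec), active), "n"] <- 0

  elec_apply <- function(e, par) elec_apply_par(e, par, by_elec, intens, Q,
                                                dictionary, n_t, n_max)

  total_img <- matrix(0, nrow(Q), n_t)
  total_var <- numeric(n_t)
  for (e in seq_len(n_elec)) {
    contrib[[e]] <- if (e %in% active)
      elec_apply_par(e, par_tab[e, ], by_elec, intens, Q, dictionary, n_t, n_max)
    else list(img = matrix(0, nrow(Q), n_t), vr = numeric(n_t))
    total_img <- total_img + contrib[[e]]$img
    total_var <- total_var + contrib[[e]]$vr
  }
  err_of <- function(img, vr) mean((colSums((S - img)^2) + vr) / s_norms)

  amp_lo <- vapply(by_elec[active], function(b) min(b$amplitude_uA), 0)
  amp_hi <- vapply(by_elec[active], function(b) max(b$amplitude_uA), 0)
  for (pass in seq_len(passes)) {
    for (ii in seq_along(active)) {
      e <- active[ii]
      base_img <- total_img - contrib[[e]]$img
      base_var <- total_var - contrib[[e]]$vr
      fobj <- function(par) {
        res <- elec_apply(e, par)
        err_of(base_img + res$img, base_var + res$vr)
      }
      # candidate starts: current parameters, and intensity-to-current maps of
      # either polarity spanning this electrode's calibrated amplitudes
      cands <- list(par_tab[e, ],
                    c(amp_lo[ii], amp_hi[ii] - amp_lo[ii], -6, 0, 2),
                    c(amp_lo[ii], amp_hi[ii] - amp_lo[ii], 6, 0, 2))
      best_par <- c(par_tab[e, 1:4], 0)   # n = 0: no stimulation
      best_val <- err_of(base_img, base_var)
      for (p0 in cands) {
        fit <- stats::optim(p0, fobj, method = "Nelder-Mead",
                            control = list(maxit = maxit))
        if (fit$value < best_val) { best_val <- fit$value; best_par <- fit$par }
      }
      par_tab[e, ] <- best_par
      res <- elec_apply(e, best_par)
      contrib[[e]] <- res
      total_img <- base_img + res$img
      total_var <- base_var + res$vr
    }
  }
  structure(
    list(parameters = data.frame(electrode_id = seq_len(n_elec), par_tab),
         window_um = window_um, n_max = n_max,
         training_error = err_of(total_img, total_var)),
    class = "pixelwise_mapping"
  )
}

#' Apply a fitted pixel-wise mapping to a target
#'
#' Computes each electrode's current from its sigmoid, snaps it to the nearest
#' retained amplitude (log scale) and emits that element `n` times; repeats
#' are interleaved round-robin across electrodes, consistent with
#' temporally-dithered delivery.
#'
#' @param target Pixel matrix or `visual_target`.
#' @param mapping A `pixelwise_mapping`.
#' @param dictionary A `stim_dictionary`.
#' @param filters A `recon_filter`.
#' @param array The `electrode_array`.
#' @return List with `steps` (delivery order data frame), `columns` (chosen
#'   dictionary columns with repeats) and `error` (an `error_report`).
#' @export
apply_pixelwise <- function(target, mapping, dictionary, filters, array) {
  sm <- as_image(target)
  sv <- as.numeric(sm)
  win <- electrode_window_pixels(filters, array, mapping$window_um)
  el <- dictionary$elements
  pt <- mapping$parameters
  cols <- integer(0); reps <- integer(0)
  for (e in seq_len(nrow(pt))) {
    n_rep <- max(0L, min(mapping$n_max, round(pt$n[e])))
    if (n_rep == 0) next
    idx <- which(!el$is_null & el$electrode_id == e)
    if (length(idx) == 0) next
    s_e <- if (length(win[[e]])) mean(sv[win[[e]]]) else 0
    cur <- sigmoid_current(s_e, as.numeric(pt[e, c("a", "b", "c", "d")]))
    colq <- snap_element(cur, data.frame(column = idx,
                                         amplitude_uA = el$amplitude_uA[idx]))
    if (!is.na(colq)) { cols <- c(cols, colq); reps <- c(reps, n_rep) }
  }
  # round-robin interleave of repeats across electrodes
  order_cols <- integer(0)
  if (length(cols) > 0) {
    for (k in seq_len(max(reps))) {
      order_cols <- c(order_cols, cols[reps >= k])
    }
  }
  P <- dictionary$D[, order_cols, drop = FALSE]
  err <- expected_error(sm, filters, as.matrix(P))
  steps <- data.frame(
    step = seq_along(order_cols),
    element_id = el$element_id[order_cols],
    electrode_id = el$electrode_id[order_cols],
    amplitude_uA = el$amplitude_uA[order_cols]
  )
  list(steps = steps, columns = order_cols, error = err)
}
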