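# Shared fixtures, built once per test run and memoized.

.fixture_store <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_store[[key]])) .fixture_store[[key]] <- builder()
  .fixture_store[[key]]
}

# Tiny fixture: 2 x 4 electrodes, 3 ON + 3 OFF cells, 6 amplitude levels.
tiny_fixture <- function() {
  memo("tiny", function() {
    ret <- make_retina(2, 4, 60, n_on = 3, n_off = 3, rf_radius_um = 40,
                       seed = 4, mosaic_exclusion = 0.4)
    ret$dictionary <- make_dictionary(ret$array, ret$cells, ret$filters,
                                      n_amplitudes = 6, seed = 4)
    ret
  })
}

# Small study fixture: 4 x 8 electrodes, 12 + 12 cells (fast enough for
# module tests that need realistic structure).
small_fixture <- function() {
  memo("small", function() {
    fx <- synthetic_fixture(seed = 11, rows = 4L, cols = 8L,
                            n_on = 12L, n_off = 12L)
    fx
  })
}

# The full acceptance-scale fixture (8 x 16, 50 + 50 cells).
study_fixture <- function() {
  memo("study", function() synthetic_fixture(seed = 101L))
}

# Hand-built dictionary for controlled algebraic cases: D given explicitly.
manual_dictionary <- function(D, filters, electrode_ids = NULL,
                              amplitudes = NULL, electrode_xy = NULL) {
  m <- ncol(D)
  D <- cbind(D, 0)  # append null element
  D <- methods::as(methods::as(Matrix::Matrix(D, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  a2 <- filters$col_sq_norms
  v <- as.numeric(Matrix::colSums(D * (1 - D) * a2))
  structure(
    list(D = D, v = v,
         elements = data.frame(
           element_id = c(seq_len(m), 0L),
           electrode_id = c(electrode_ids %||% seq_len(m), NA),
           amplitude_uA = c(amplitudes %||% rep(1, m), NA),
           is_null = c(rep(FALSE, m), TRUE)),
         meta = NULL,
         electrode_xy = electrode_xy %||%
           cbind(x = seq_len(m) * 1000, y = rep(0, m)),
         n_cells = nrow(D), params = list()),
    class = "stim_dictionary"
  )
}

# Minimal hand-built filter object from an explicit A matrix.
manual_filters <- function(A, grid_shape, pixel_pitch_um = 44) {
  A <- methods::as(Matrix::Matrix(A, sparse = TRUE), "CsparseMatrix")
  structure(
    list(A = A, grid_shape = as.integer(grid_shape),
         pixel_pitch_um = pixel_pitch_um,
         pixel_x = (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * pixel_pitch_um,
         pixel_y = ((grid_shape[1] + 1) / 2 - seq_len(grid_shape[1])) * pixel_pitch_um,
         col_sq_norms = Matrix::colSums(A^2)),
    class = "recon_filter"
  )
}

# Independent projected-gradient solver for min ||s - Mw||^2 + v'w, w >= 0;
# deliberately naive (used only as a cross-check oracle).
pg_solve <- function(M, s, v, iters = 20000, w0 = NULL) {
  M <- as.matrix(M)
  L <- 2 * norm(M, "2")^2
  w <- w0 %||% numeric(ncol(M))
  for (i in seq_len(iters)) {
    g <- 2 * as.numeric(crossprod(M, M %*% w - s)) + v
    w_new <- pmax(w - g / L, 0)
    if (sqrt(sum((w_new - w)^2)) < 1e-12) { w <- w_new; break }
    w <- w_new
  }
  obj <- sum((s - M %*% w)^2) + sum(v * w)
  list(w = w, objective = obj)
}

# Brute-force refractory mask: replay a history of chosen probability
# vectors against the masking rule, step by step.
brute_mask <- function(D, history_cols, theta, window, null_col) {
  n_cells <- nrow(D)
  t_now <- length(history_cols) + 1L
  last_hit <- rep(-Inf, n_cells)
  for (t in seq_along(history_cols)) {
    col <- history_cols[t]
    if (!is.na(col)) {
      hit <- which(as.numeric(D[, col]) > theta)
      last_hit[hit] <- t
    }
  }
  mask <- vapply(seq_len(ncol(D)), function(c) {
    cells <- which(as.numeric(D[, c]) > theta)
    all(t_now - last_hit[cells] > window)
  }, NA)
  mask[null_col] <- TRUE
  mask
}

# Direct per-window SSIM evaluation (loop oracle, Gaussian weights).
ssim_loop <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                      L = 2) {
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  k1d <- exp(-((seq_len(window) - 1 - (window - 1) / 2)^2) / (2 * sigma^2))
  k1d <- k1d / sum(k1d)
  wmat <- outer(k1d, k1d)
  nr <- nrow(a) - window + 1L; nc <- ncol(a) - window + 1L
  vals <- numeric(nr * nc); idx <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    wa <- a[i:(i + window - 1L), j:(j + window - 1L)]
    wb <- b[i:(i + window - 1L), j:(j + window - 1L)]
    ux <- sum(wmat * wa); uy <- sum(wmat * wb)
    sxx <- sum(wmat * wa^2) - ux^2
    syy <- sum(wmat * wb^2) - uy^2
    sxy <- sum(wmat * wa * wb) - ux * uy
    idx <- idx + 1L
    vals[idx] <- ((2 * ux * uy + C1) * (2 * sxy + C2)) /
      ((ux^2 + uy^2 + C1) * (sxx + syy + C2))
  }
  mean(vals)
}
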