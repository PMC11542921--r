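# Synthetic retina fixtures: electrode lattice, ON/OFF mosaics with signed
# Gaussian reconstruction filters, and checkerboard targets. These emulate the
# calibration products of a lab-prototype epiretinal interface so that every
# downstream analysis runs without recorded data.

#' Construct an electrode array on an isosceles triangular lattice
#'
#' Electrodes sit on a triangular lattice with `pitch_um` spacing: within a row
#' electrodes are `pitch_um` apart, rows are `pitch_um * sqrt(3)/2` apart and
#' every other row is shifted by half a pitch, so every interior electrode's
#' nearest neighbour is exactly `pitch_um` away. The array is centered at the
#' origin and coordinates are in micrometers.
#'
#' @param rows,cols Lattice dimensions (default 16 x 32, i.e. 512 electrodes).
#' @param pitch_um Electrode spacing in micrometers (default 60).
#' @return An object of class `electrode_array`: list with `positions`
#'   (n x 2 matrix, columns `x`, `y`, µm), `rows`, `cols`, `pitch_um`.
#' @export
make_electrode_array <- function(rows = 16L, cols = 32L, pitch_um = 60) {
  check_scalar(rows, "rows", positive = TRUE, integerish = TRUE)
  check_scalar(cols, "cols", positive = TRUE, integerish = TRUE)
  check_scalar(pitch_um, "pitch_um", positive = TRUE)
  row_step <- pitch_um * sqrt(3) / 2
  xy <- do.call(rbind, lapply(seq_len(rows), function(r) {
    x <- (seq_len(cols) - 1) * pitch_um + ifelse(r %% 2 == 0, pitch_um / 2, 0)
    cbind(x = x, y = (r - 1) * row_step)
  }))
  xy[, 1] <- xy[, 1] - mean(range(xy[, 1]))
  xy[, 2] <- xy[, 2] - mean(range(xy[, 2]))
  structure(
    list(positions = xy, rows = as.integer(rows), cols = as.integer(cols),
         pitch_um = pitch_um),
    class = "electrode_array"
  )
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %d x %d triangular lattice, %g um pitch\n",
              x$rows, x$cols, x$pitch_um))
  invisible(x)
}

# Jittered hexagonal mosaic of n points covering [xr] x [yr]; returns the n
# lattice sites nearest the region center, each perturbed within a disk whose
# radius is a fixed fraction of the lattice spacing, so same-type receptive
# field centers keep a guaranteed minimum separation.
mosaic_points <- function(n, xr, yr, jitter_frac = 0.12) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  area <- diff(xr) * diff(yr)
  spacing <- sqrt(2 * area / (sqrt(3) * n))
  phase <- stats::runif(2, 0, spacing)
  xs <- seq(xr[1] - spacing, xr[2] + spacing, by = spacing)
  ys <- seq(yr[1] - spacing, yr[2] + spacing, by = spacing * sqrt(3) / 2)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    cbind(xs + ifelse(i %% 2 == 0, spacing / 2, 0) + phase[1], ys[i] + phase[2])
  }))
  ctr <- c(mean(xr), mean(yr))
  d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
  pts <- pts[order(d2)[seq_len(n)], , drop = FALSE]
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- jitter_frac * spacing * sqrt(stats::runif(n))
  pts + cbind(rad * cos(ang), rad * sin(ang))
}

#' Generate a synthetic retina: electrode array, ON/OFF mosaics and filters
#'
#' Builds the three calibration products needed by the encoder: the electrode
#' lattice, a population of ON and OFF cells whose receptive-field (RF)
#' centers form independent mosaics, and the linear reconstruction filter
#' matrix `A` (pixels x cells). Each cell's filter is a signed 2-D Gaussian
#' (positive for ON, negative for OFF) truncated at three standard deviations,
#' a stand-in for denoised, scaled receptive fields.
#'
#' The pixel grid defaults to the array footprint plus a 3-sigma RF margin at
#' `pixel_pitch_um` resolution, but can be fixed with `grid_shape` (rows,
#' cols), in which case cells still tile the array footprint at the grid
#' center.
#'
#' @param rows,cols,pitch_um Electrode lattice, see [make_electrode_array()].
#' @param n_on,n_off Number of ON and OFF cells.
#' @param rf_radius_um Gaussian RF radius (sigma) in micrometers, or NULL to
#'   scale it with mosaic density (0.45 x the expected same-type spacing, so
#'   RF diameters approximately tile the mosaic, as parasol cells do).
#' @param gain Peak filter amplitude in stimulus-intensity units per spike.
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param pixel_pitch_um Pixel size in micrometers (default 44).
#' @param grid_shape Optional c(rows, cols) pixel grid override.
#' @param mosaic_exclusion Minimum same-type center separation, as a fraction
#'   of the RF diameter (`2 * rf_radius_um`); generation fails if the
#'   requested density cannot honor it.
#' @param soma_jitter_um SD of the offset between RF center and soma
#'   (electrical activation happens at the soma, reconstruction at the RF).
#' @return List with elements `array` (`electrode_array`), `cells`
#'   (`cell_population`: data frame of cell_id, type, x_um, y_um, soma_x_um,
#'   soma_y_um, rf_radius_um, gain) and `filters` (`recon_filter`: sparse `A`,
#'   `grid_shape`, `pixel_pitch_um`, pixel center coordinates).
#' @export
make_retina <- function(rows = 16L, cols = 32L, pitch_um = 60,
                        n_on = 0L, n_off = 0L, rf_radius_um = 60,
                        gain = 0.5, seed = 1L, pixel_pitch_um = 44,
                        grid_shape = NULL, mosaic_exclusion = 0.7,
                        soma_jitter_um = 30) {
  check_scalar(n_on, "n_on", integerish = TRUE)
  check_scalar(n_off, "n_off", integerish = TRUE)
  if (n_on < 0 || n_off < 0) stop_param("n_on and n_off must be >= 0")
  check_scalar(pixel_pitch_um, "pixel_pitch_um", positive = TRUE)
  array <- make_electrode_array(rows, cols, pitch_um)
  if (is.null(rf_radius_um)) {
    ar <- apply(array$positions, 2, function(z) diff(range(z)))
    spacing <- sqrt(2 * prod(ar) / (sqrt(3) * max(1, max(n_on, n_off))))
    rf_radius_um <- 0.45 * spacing
  }
  check_scalar(rf_radius_um, "rf_radius_um", positive = TRUE)

  set.seed(derive_seed(seed, 1L))
  margin <- 3 * rf_radius_um
  xr <- range(array$positions[, 1]) + c(-margin, margin)
  yr <- range(array$positions[, 2]) + c(-margin, margin)
  if (is.null(grid_shape)) {
    grid_shape <- c(ceiling(diff(yr) / pixel_pitch_um),
                    ceiling(diff(xr) / pixel_pitch_um))
  }
  grid_shape <- as.integer(grid_shape)
  # Pixel centers; row 1 is the top of the image (largest y).
  px_x <- (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * pixel_pitch_um
  px_y <- ((grid_shape[1] + 1) / 2 - seq_len(grid_shape[1])) * pixel_pitch_um

  place <- function(n) mosaic_points(n, range(array$positions[, 1]),
                                     range(array$positions[, 2]))
  on_xy <- place(n_on)
  off_xy <- place(n_off)
  centers <- rbind(on_xy, off_xy)
  n_cells <- n_on + n_off
  types <- rep(c("ON", "OFF"), c(n_on, n_off))

  min_sep <- mosaic_exclusion * 2 * rf_radius_um
  for (ty in c("ON", "OFF")) {
    pts <- centers[types == ty, , drop = FALSE]
    if (nrow(pts) > 1) {
      if (min(stats::dist(pts)) <= min_sep) {
        stop_param(paste0("cannot place %d %s cells with center separation > ",
                          "%.0f um; reduce the cell count or the exclusion ",
                          "fraction"), nrow(pts), ty, min_sep)
      }
    }
  }

  cells <- data.frame(
    cell_id = seq_len(n_cells),
    type = types,
    x_um = centers[, 1], y_um = centers[, 2],
    soma_x_um = centers[, 1] + stats::rnorm(n_cells, 0, soma_jitter_um),
    soma_y_um = centers[, 2] + stats::rnorm(n_cells, 0, soma_jitter_um),
    rf_radius_um = rep(rf_radius_um, n_cells),
    gain = rep(gain, n_cells),
    stringsAsFactors = FALSE
  )
  class(cells) <- c("cell_population", "data.frame")

  n_px <- prod(grid_shape)
  trip <- vector("list", max(n_cells, 1L))
  if (n_cells > 0) {
    grid_x <- matrix(px_x, grid_shape[1], grid_shape[2], byrow = TRUE)
    grid_y <- matrix(px_y, grid_shape[1], grid_shape[2])
    for (i in seq_len(n_cells)) {
      d2 <- (grid_x - centers[i, 1])^2 + (grid_y - centers[i, 2])^2
      keep <- which(d2 <= (3 * rf_radius_um)^2)
      sgn <- if (types[i] == "ON") 1 else -1
      trip[[i]] <- cbind(keep, i,
                         sgn * gain * exp(-d2[keep] / (2 * rf_radius_um^2)))
    }
    trip <- do.call(rbind, trip)
    A <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                              dims = c(n_px, n_cells))
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n_px, 0L))
  }
  filters <- structure(
    list(A = A, grid_shape = grid_shape, pixel_pitch_um = pixel_pitch_um,
         pixel_x = px_x, pixel_y = px_y,
         col_sq_norms = Matrix::colSums(A^2)),
    class = "recon_filter"
  )
  list(array = array, cells = cells, filters = filters)
}

#' @export
print.recon_filter <- function(x, ...) {
  cat(sprintf("<recon_filter> %d x %d pixel grid (%g um), %d cells\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_pitch_um, ncol(x$A)))
  invisible(x)
}

#' Random black/white checkerboard targets
#'
#' Each target is an equiprobable random -1/+1 checkerboard on the given
#' grid: with `block_px = 1` every pixel is i.i.d.; with larger `block_px`
#' the independent unit is a square checker of that many display pixels.
#'
#' @param n_targets Number of targets (>= 1).
#' @param grid_shape c(rows, cols) pixel grid.
#' @param seed Integer seed.
#' @param block_px Checker square side in display pixels (default 1 gives
#'   i.i.d. pixels; larger values emulate the coarse checkerboards used in
#'   closed-loop validation protocols, where checker squares span several
#'   display pixels and are comparable to receptive-field diameters).
#' @return List of `visual_target` objects (fields `pixels`, `grid_shape`).
#' @export
make_checkerboard_targets <- function(n_targets, grid_shape, seed = 1L,
                                      block_px = 1L) {
  check_scalar(n_targets, "n_targets", positive = TRUE, integerish = TRUE)
  check_scalar(block_px, "block_px", positive = TRUE, integerish = TRUE)
  set.seed(derive_seed(seed, 2L))
  nb <- ceiling(grid_shape / block_px)
  lapply(seq_len(n_targets), function(i) {
    blk <- matrix(sample(c(-1, 1), prod(nb), replace = TRUE), nb[1], nb[2])
    px <- blk[rep(seq_len(nb[1]), each = block_px)[seq_len(grid_shape[1])],
              rep(seq_len(nb[2]), each = block_px)[seq_len(grid_shape[2])],
              drop = FALSE]
    structure(list(pixels = px, grid_shape = as.integer(grid_shape)),
              class = "visual_target")
  })
}

#' @export
print.visual_target <- function(x, ...) {
  cat(sprintf("<visual_target> %d x %d, range [%g, %g]\n",
              x$grid_shape[1], x$grid_shape[2], min(x$pixels), max(x$pixels)))
  invisible(x)
}
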