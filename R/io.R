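# Serialization: HDF5 for fixtures (arrays), CSV for tabular outputs, PNG for
# images, YAML for configuration, JSON for summaries.

FIXTURE_SCHEMA_VERSION <- "1"

#' Save a retina fixture to HDF5 (with optional CSV sidecar)
#'
#' Writes datasets /A, /D, /v, /electrode_xy, /cell_meta, /element_meta plus
#' shape/pitch metadata and a schema version attribute. `A` and `D` are
#' stored dense; the loader restores sparse form.
#'
#' @param fixture List with `array`, `cells`, `filters`, `dictionary` (as from
#'   [synthetic_fixture()]).
#' @param path Output .h5 path (overwritten).
#' @param sidecar_csv Optional path for an element-metadata CSV (columns
#'   element_id, electrode_id, amplitude_uA, axon_bundle, retained).
#' @return `path`, invisibly.
#' @export
save_fixture <- function(fixture, path, sidecar_csv = NULL) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  f <- fixture$filters; d <- fixture$dictionary
  rhdf5::h5write(as.matrix(f$A), path, "A")
  rhdf5::h5write(as.matrix(d$D), path, "D")
  rhdf5::h5write(d$v, path, "v")
  rhdf5::h5write(fixture$array$positions, path, "electrode_xy")
  cells <- as.data.frame(fixture$cells)
  rhdf5::h5write(cells, path, "cell_meta")
  el <- d$elements
  el$is_null <- as.integer(el$is_null)
  rhdf5::h5write(el, path, "element_meta")
  meta <- d$meta
  meta$axon_bundle <- as.integer(meta$axon_bundle)
  meta$retained <- as.integer(meta$retained)
  rhdf5::h5write(meta, path, "raw_element_meta")
  rhdf5::h5write(c(f$grid_shape, f$pixel_pitch_um), path, "grid_info")
  rhdf5::h5write(c(fixture$array$rows, fixture$array$cols,
                   fixture$array$pitch_um), path, "array_info")
  rhdf5::h5write(FIXTURE_SCHEMA_VERSION, path, "schema_version")
  if (!is.null(sidecar_csv)) {
    utils::write.csv(d$meta[, c("element_id", "electrode_id", "amplitude_uA",
                                "axon_bundle", "retained")],
                     sidecar_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Load a fixture saved by [save_fixture()]
#'
#' @param path .h5 path.
#' @return Fixture list (`array`, `cells`, `filters`, `dictionary`); arrays
#'   are bit-identical to what was saved.
#' @export
load_fixture <- function(path) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  names_have <- tryCatch(rhdf5::h5ls(path, recursive = FALSE)$name,
                         error = function(e) stop_param(
                           "not a readable fixture file: %s", path))
  need <- c("A", "D", "v", "electrode_xy", "cell_meta", "element_meta",
            "grid_info", "array_info", "schema_version")
  if (!all(need %in% names_have)) {
    stop_param("fixture file %s is missing datasets: %s", path,
               paste(setdiff(need, names_have), collapse = ", "))
  }
  ver <- as.character(rhdf5::h5read(path, "schema_version"))
  if (!identical(ver, FIXTURE_SCHEMA_VERSION)) {
    stop_param("fixture schema version %s != supported version %s",
               ver, FIXTURE_SCHEMA_VERSION)
  }
  ai <- rhdf5::h5read(path, "array_info")
  array <- make_electrode_array(ai[1], ai[2], ai[3])
  array$positions <- rhdf5::h5read(path, "electrode_xy")
  colnames(array$positions) <- c("x", "y")
  drop_dims <- function(df) { df[] <- lapply(df, as.vector); df }
  cells <- drop_dims(as.data.frame(rhdf5::h5read(path, "cell_meta")))
  class(cells) <- c("cell_population", "data.frame")
  gi <- rhdf5::h5read(path, "grid_info")
  grid_shape <- as.integer(gi[1:2]); pitch <- gi[3]
  A <- methods::as(Matrix::Matrix(rhdf5::h5read(path, "A")), "CsparseMatrix")
  filters <- structure(
    list(A = A, grid_shape = grid_shape, pixel_pitch_um = pitch,
         pixel_x = (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * pitch,
         pixel_y = ((grid_shape[1] + 1) / 2 - seq_len(grid_shape[1])) * pitch,
         col_sq_norms = Matrix::colSums(A^2)),
    class = "recon_filter"
  )
  elements <- drop_dims(as.data.frame(rhdf5::h5read(path, "element_meta")))
  elements$is_null <- as.logical(elements$is_null)
  meta <- drop_dims(as.data.frame(rhdf5::h5read(path, "raw_element_meta")))
  meta$axon_bundle <- as.logical(meta$axon_bundle)
  meta$retained <- as.logical(meta$retained)
  dictionary <- structure(
    list(D = methods::as(Matrix::Matrix(rhdf5::h5read(path, "D")),
                         "CsparseMatrix"),
         v = as.numeric(rhdf5::h5read(path, "v")),
         elements = elements, meta = meta,
         electrode_xy = array$positions, n_cells = nrow(cells),
         params = list()),
    class = "stim_dictionary"
  )
  list(array = array, cells = cells, filters = filters,
       dictionary = dictionary)
}

#' Write a stimulation sequence to CSV
#' @param sequence A `stim_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence_csv <- function(sequence, path) {
  utils::write.csv(sequence$steps, path, row.names = FALSE)
  invisible(path)
}

#' Export an image matrix as 8-bit grayscale PNG
#'
#' Intensities are mapped linearly from \[lo, hi\] (defaults: the image range)
#' to \[0, 255\]; the mapping is returned so the scale is recoverable.
#'
#' @param image Pixel matrix.
#' @param path Output path.
#' @param lo,hi Intensity bounds mapped to black/white.
#' @return List with `path`, `lo`, `hi`, invisibly.
#' @export
write_image_png <- function(image, path, lo = NULL, hi = NULL) {
  img <- as_image(image)
  img[is.na(img)] <- 0
  lo <- lo %||% min(img); hi <- hi %||% max(img)
  rng <- if (hi > lo) hi - lo else 1
  png::writePNG((img - lo) / rng, path)
  invisible(list(path = path, lo = lo, hi = hi))
}
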