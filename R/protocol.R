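# Study-protocol orchestration: the standard synthetic fixture, the
# checkerboard encoding protocol (greedy + bounds + baseline on a target
# batch), and a YAML-configured multi-stage runner.

#' Standard synthetic study fixture
#'
#' One call builds the fixture used throughout the analyses: a triangular
#' electrode subarray, ON/OFF mosaics with density-scaled Gaussian filters
#' (see [make_retina()]) and the default calibrated-like dictionary. The
#' defaults give an 8 x 16 subarray with ~50 + 50 cells; pass `rows = 16,
#' cols = 32, n_on = 350, n_off = 350` for a full-array fixture.
#'
#' @param seed Integer seed.
#' @param rows,cols Electrode lattice (default 8 x 16).
#' @param n_on,n_off Cell counts (default 50 + 50).
#' @param grid_shape Optional pixel-grid override (e.g. c(40, 80) for
#'   dynamic-scene runs).
#' @param ... Further arguments to [make_retina()].
#' @return List with `array`, `cells`, `filters`, `dictionary`.
#' @export
synthetic_fixture <- function(seed = 1L, rows = 8L, cols = 16L,
                              n_on = 50L, n_off = 50L, grid_shape = NULL,
                              ...) {
  ret <- make_retina(rows, cols, 60, n_on = n_on, n_off = n_off,
                     rf_radius_um = NULL, seed = seed,
                     grid_shape = grid_shape, ...)
  ret$dictionary <- make_dictionary(ret$array, ret$cells, ret$filters,
                                    seed = seed)
  ret
}

#' Checkerboard targets for the bounds protocol
#'
#' The study's target batch: random checkerboards with 6-pixel (264 µm)
#' checkers. Closed-loop validation protocols use coarse checkers (352 µm,
#' i.e. several receptive-field diameters); 6 display pixels is the closest
#' scaling that still leaves a non-degenerate target ensemble on the
#' subarray's pixel grid.
#'
#' @param fixture A fixture (for the pixel grid).
#' @param n_targets Number of targets (default 20).
#' @param seed Integer seed.
#' @param block_px Checker size (default 6).
#' @return List of `visual_target`s.
#' @export
protocol_targets <- function(fixture, n_targets = 20L, seed = 1L,
                             block_px = 6L) {
  make_checkerboard_targets(n_targets, fixture$filters$grid_shape,
                            seed = seed, block_px = block_px)
}

#' Held-out targets guaranteed distinct from a reference set
#'
#' Draws targets with [protocol_targets()] and drops any that duplicate a
#' member of `exclude` (coarse checkers have a finite ensemble, so collisions
#' between independently seeded batches are possible).
#'
#' @param fixture,n_targets,seed,block_px As in [protocol_targets()].
#' @param exclude List of targets the result must be disjoint from.
#' @return List of `n_targets` distinct targets.
#' @export
disjoint_targets <- function(fixture, n_targets, seed, exclude,
                             block_px = 6L) {
  pool <- protocol_targets(fixture, 3L * n_targets, seed = seed,
                           block_px = block_px)
  keys <- vapply(exclude, function(t) paste(t$pixels, collapse = ""), "")
  keep <- list()
  for (tg in pool) {
    k <- paste(tg$pixels, collapse = "")
    if (!(k %in% keys)) {
      keep[[length(keep) + 1L]] <- tg
      keys <- c(keys, k)   # also dedup within the drawn pool
    }
    if (length(keep) == n_targets) break
  }
  if (length(keep) < n_targets) stop_param("target ensemble too small")
  keep
}

#' Run the checkerboard encoding protocol: greedy + bounds per target
#'
#' For every target, runs greedy temporal dithering (up to `T_max` steps with
#' refractory masking), the relaxed-joint lower bound and perfect control,
#' and tabulates errors and fractional gaps.
#'
#' @param fixture A fixture from [synthetic_fixture()].
#' @param targets List of targets (default: [protocol_targets()] with the
#'   fixture's seed).
#' @param T_max,theta,window Greedy parameters (defaults 10000, 0.1, 100).
#' @param seed Seed used when `targets` is NULL.
#' @return Data frame with one row per target: err_greedy, err_relaxed,
#'   err_perfect (relative expected errors), gap_greedy
#'   (= (greedy - relaxed)/greedy) and gap_dictionary
#'   (= (relaxed - perfect)/relaxed), n_steps.
#' @export
encode_protocol <- function(fixture, targets = NULL, T_max = 10000L,
                            theta = 0.1, window = 100L, seed = 1L) {
  targets <- targets %||% protocol_targets(fixture, seed = seed)
  cache <- element_cache(fixture$filters, fixture$dictionary)
  rows <- lapply(seq_along(targets), function(i) {
    tg <- targets[[i]]
    sg <- run_greedy(tg, fixture$filters, fixture$dictionary, T_max = T_max,
                     theta = theta, window = window, cache = cache)
    rj <- relaxed_joint(tg, fixture$filters, fixture$dictionary, cache = cache)
    pc <- perfect_control(tg, fixture$filters)
    data.frame(
      target_id = i,
      err_greedy = sg$error$relative_expected_error,
      err_relaxed = rj$relative_expected_error,
      err_perfect = pc$relative_mse,
      gap_greedy = fractional_gap(sg$error$expected_error, rj$objective),
      gap_dictionary = fractional_gap(rj$objective, pc$objective),
      n_steps = sg$n_steps
    )
  })
  do.call(rbind, rows)
}

#' Run a configured multi-stage protocol
#'
#' Executes the configured stages in order and writes per-stage CSV outputs
#' plus a JSON summary recording the package version, seeds and a config
#' hash, so every report is regenerable from its inputs. Stages:
#' `generate` (fixture -> HDF5), `encode` (greedy per target),
#' `bounds` (adds relaxed + perfect), `baseline` (pixel-wise mapping),
#' `subsample` (electrode-fraction curve), `dynamic` (fixational-benefit
#' runs), `perceptual` (budget sweep).
#'
#' @param config A YAML path or config list. Recognized top-level fields:
#'   `seed`, `out_dir`, `stages` (character vector), `fixture` (arguments to
#'   [synthetic_fixture()]), `targets` (`n`, `block_px`), `encode`
#'   (`T_max`, `theta`, `window`), `subsample` (`fractions`), `dynamic`
#'   (`scene_shape`, `n_fixations`, `choices_per_frame`, `n_reps`),
#'   `perceptual` (`lambdas`, `metric`).
#' @return List of stage results (also written under `out_dir`), invisibly.
#' @export
run_protocol <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_param("config must be a list or a YAML path")
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "."
  stages <- config$stages %||% "generate"
  known <- c("generate", "encode", "bounds", "baseline", "subsample",
             "dynamic", "perceptual")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_param("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fx_args <- config$fixture %||% list()
  fx_args$seed <- fx_args$seed %||% seed
  fixture <- do.call(synthetic_fixture, fx_args)
  results <- list()
  summary <- list(
    package_version = as.character(utils::packageVersion("stimdither")),
    seed = seed,
    config_hash = sum(utf8ToInt(paste(
      deparse(config[setdiff(names(config), "out_dir")]), collapse = ""))),
    stages = stages
  )

  if ("generate" %in% stages) {
    p <- file.path(out_dir, "fixture.h5")
    save_fixture(fixture, p, sidecar_csv = file.path(out_dir, "elements.csv"))
    results$generate <- p
  }

  tg_cfg <- config$targets %||% list()
  targets <- protocol_targets(fixture, n_targets = tg_cfg$n %||% 20L,
                              seed = tg_cfg$seed %||% seed,
                              block_px = tg_cfg$block_px %||% 3L)
  enc <- config$encode %||% list()

  if (any(c("encode", "bounds") %in% stages)) {
    tab <- encode_protocol(fixture, targets, T_max = enc$T_max %||% 10000L,
                           theta = enc$theta %||% 0.1,
                           window = enc$window %||% 100L)
    utils::write.csv(tab, file.path(out_dir, "bounds.csv"), row.names = FALSE)
    results$bounds <- tab
    summary$median_gap_greedy <- stats::median(tab$gap_greedy)
    summary$median_gap_dictionary <- stats::median(tab$gap_dictionary)
    summary$median_err_greedy <- stats::median(tab$err_greedy)
  }

  if ("baseline" %in% stages) {
    half <- seq_len(ceiling(length(targets) / 2))
    map <- fit_pixelwise_mapping(targets[half], fixture$filters,
                                 fixture$dictionary, fixture$array)
    errs <- vapply(targets[-half], function(tg)
      apply_pixelwise(tg, map, fixture$dictionary, fixture$filters,
                      fixture$array)$error$relative_expected_error, 0)
    results$baseline <- list(mapping = map, eval_errors = errs)
    summary$median_err_pixelwise <- stats::median(errs)
  }

  if ("subsample" %in% stages) {
    ss_cfg <- config$subsample %||% list()
    tr <- protocol_targets(fixture, n_targets = tg_cfg$n %||% 20L,
                           seed = derive_seed(seed, 20L))
    sc <- subsampling_curve(fixture$filters, fixture$dictionary, tr, targets,
                            fractions = ss_cfg$fractions %||% seq(0.1, 1, 0.1),
                            T_max = enc$T_max %||% 10000L)
    utils::write.csv(sc$curve, file.path(out_dir, "subsample.csv"),
                     row.names = FALSE)
    results$subsample <- sc
  }

  if ("dynamic" %in% stages) {
    dy <- config$dynamic %||% list()
    scene <- make_natural_scene(dy$scene_shape %||% (2 * fixture$filters$grid_shape),
                                seed = derive_seed(seed, 30L))
    fb <- fixational_benefit(scene, fixture$filters, fixture$cells,
                             fixture$dictionary,
                             n_reps = dy$n_reps %||% 5L, seed = seed,
                             n_fixations = dy$n_fixations %||% 100L,
                             choices_per_frame = dy$choices_per_frame %||% 12L)
    utils::write.csv(fb$per_rep, file.path(out_dir, "dynamic.csv"),
                     row.names = FALSE)
    results$dynamic <- fb
    summary$fixational_saccade_ratio <- fb$ratio
  }

  if ("perceptual" %in% stages) {
    pc_cfg <- config$perceptual %||% list()
    scene <- make_natural_scene(pc_cfg$scene_shape %||%
                                  (2 * fixture$filters$grid_shape),
                                seed = derive_seed(seed, 40L))
    sw <- budget_sweep(scene, fixture$filters, fixture$dictionary,
                       lambdas = pc_cfg$lambdas %||% c(0, 1e-4, 1e-3, 1e-2),
                       metric = pc_cfg$metric %||% "mse")
    utils::write.csv(sw, file.path(out_dir, "perceptual.csv"),
                     row.names = FALSE)
    results$perceptual <- sw
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
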