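# Gaze simulation, dynamic stimuli, spatiotemporal greedy and scene assembly.

test_that("natural scenes are normalized, in range and reproducible", {
  sc <- make_natural_scene(c(30, 40), seed = 3)
  expect_equal(dim(sc), c(30L, 40L))
  expect_true(all(abs(sc) <= 1))
  expect_equal(sd(sc), 0.45, tolerance = 0.05)
  expect_identical(sc, make_natural_scene(c(30, 40), seed = 3))
})

test_that("zero interval spread and no jitter give periodic static gaze", {
  sc <- make_natural_scene(c(30, 40), seed = 3)
  gz <- generate_gaze(sc, c(10, 12), n_fixations = 5, mean_ms = 300,
                      sd_ms = 0, jitter_sd_px = 0, seed = 1)
  expect_true(all(gz$fixations$n_frames == 36))  # 300 ms at 120 Hz
  # positions constant within each fixation
  for (i in 1:5) {
    fr <- gz$frames[gz$frames$fixation_id == i, ]
    expect_equal(unique(fr$row), gz$fixations$row[i])
    expect_equal(unique(fr$col), gz$fixations$col[i])
  }
})

test_that("Brownian jitter increments have the configured SD", {
  sc <- matrix(0, 200, 200)
  gz <- generate_gaze(sc, c(20, 20), n_fixations = 1, mean_ms = 90000,
                      sd_ms = 0, jitter_sd_px = 3, seed = 2)
  fr <- gz$frames[gz$frames$fixation_id == 1, ]
  inc <- c(diff(fr$row), diff(fr$col))
  n <- length(inc)
  se <- 3 / sqrt(2 * (n - 1))     # SE of a sample SD estimate
  expect_lt(abs(sd(inc) - 3), 3 * se)
})

test_that("flat scenes give uniform fixation sampling", {
  sc <- matrix(0.2, 24, 24)
  gz <- generate_gaze(sc, c(16, 16), n_fixations = 10000, mean_ms = 10,
                      sd_ms = 0, jitter_sd_px = 0, seed = 4)
  # 9 x 9 valid top-left corners; chi-square goodness of fit to uniform
  cnt <- table(factor(paste(gz$fixations$row, gz$fixations$col),
                      levels = as.vector(outer(1:9, 1:9, paste))))
  chi <- chisq.test(as.numeric(cnt))
  expect_gt(chi$p.value, 0.001)
})

test_that("dynamic stimulus crops follow the eye and the scene", {
  sc <- make_natural_scene(c(30, 40), seed = 5)
  gz <- generate_gaze(sc, c(10, 12), n_fixations = 2, sd_ms = 0,
                      jitter_sd_px = 0, seed = 6)
  frames <- dynamic_stimulus(sc, gz)
  i1 <- which(gz$frames$fixation_id == 1)
  expect_true(all(vapply(frames[i1], identical, NA, frames[[i1[1]]])))
  r <- gz$fixations$row[1]; c <- gz$fixations$col[1]
  expect_equal(frames[[1]], sc[r:(r + 9), c:(c + 11)])
  # translation equivariance: shifting the eye by one pixel shifts the crop
  gz$frames$row[1] <- gz$frames$row[1] + 1
  f2 <- dynamic_stimulus(sc, gz)
  expect_equal(f2[[1]], sc[(r + 1):(r + 10), c:(c + 11)])
})

test_that("spatiotemporal filters are causal, peak-normalized and signed", {
  fx <- tiny_fixture()
  stf <- make_st_filter(fx$filters, fx$cells)
  expect_equal(max(stf$kernel), 1)
  expect_true(all(diff(stf$kernel) < 0))  # causal decay
  expect_equal(stf$polarity, ifelse(fx$cells$type == "ON", 1, -1))
  expect_error(make_st_filter(fx$filters, fx$cells, kernel = numeric(0)),
               "kernel")
  expect_error(make_st_filter(fx$filters, fx$cells, kernel = c(-1, 1)),
               "kernel")
})

test_that("empty frame streams give empty sequences", {
  fx <- tiny_fixture()
  stf <- make_st_filter(fx$filters, fx$cells)
  out <- dynamic_greedy(list(), stf, fx$dictionary, choices_per_frame = 3)
  expect_equal(nrow(out$steps), 0L)
  expect_length(out$recon, 0L)
})

test_that("an impulse kernel reduces dynamic greedy to static greedy", {
  fx <- tiny_fixture()
  stf <- make_st_filter(fx$filters, fx$cells, kernel = 1)
  set.seed(21)
  gs <- fx$filters$grid_shape
  frames <- lapply(1:3, function(i)
    matrix(sample(c(-1, 1), prod(gs), TRUE), gs[1], gs[2]))
  dg <- dynamic_greedy(frames, stf, fx$dictionary, choices_per_frame = 8,
                       theta = 0.1, window = 0L)
  for (f in 1:3) {
    st <- run_greedy(frames[[f]], fx$filters, fx$dictionary, T_max = 8,
                     theta = 0.1, window = 0L)
    expect_equal(dg$steps$element_id[dg$steps$frame == f],
                 st$steps$element_id)
    expect_equal(as.numeric(dg$recon[[f]]),
                 as.numeric(fx$filters$A %*% st$cum_expected),
                 tolerance = 1e-12)
  }
})

test_that("dynamic choices match the exhaustive windowed objective", {
  fx <- tiny_fixture()
  stf <- make_st_filter(fx$filters, fx$cells, kernel = c(1, 0.5))
  set.seed(22)
  gs <- fx$filters$grid_shape
  frames <- lapply(1:2, function(i)
    matrix(runif(prod(gs), -1, 1), gs[1], gs[2]))
  dg <- dynamic_greedy(frames, stf, fx$dictionary, choices_per_frame = 3,
                       theta = 1.01, window = 0L)
  Q <- as.matrix(fx$filters$A %*% fx$dictionary$D)
  Tm <- sapply(frames, as.numeric)
  Rm <- 0 * Tm
  kk <- stf$kernel
  picks <- integer(0)
  for (f in 1:2) for (sl in 1:3) {
    Kf <- min(2, 2 - f + 1); kf <- kk[1:Kf]; kap <- sum(kf^2)
    dvals <- vapply(seq_len(ncol(Q)), function(c) {
      d <- kap * fx$dictionary$v[c]
      for (j in 1:Kf) {
        E <- Tm[, f + j - 1] - Rm[, f + j - 1]
        d <- d + sum((E - kf[j] * Q[, c])^2) - sum(E^2)
      }
      d
    }, 0)
    best <- which.min(dvals)
    if (dvals[best] < 0) {
      for (j in 1:Kf) Rm[, f + j - 1] <- Rm[, f + j - 1] + kf[j] * Q[, best]
      picks <- c(picks, fx$dictionary$elements$element_id[best])
    }
  }
  expect_equal(dg$steps$element_id, picks)
})

test_that("scene assembly averages correctly and conserves coverage", {
  # hand-built gaze: two fixations, one frame each
  mk_gaze <- function(rows, cols, patch, scene) {
    structure(list(
      fixations = data.frame(fixation_id = seq_along(rows), row = rows,
                             col = cols, onset_ms = 0,
                             duration_ms = 1, n_frames = 1L),
      frames = data.frame(frame = seq_along(rows), t_ms = 0, row = rows,
                          col = cols, fixation_id = seq_along(rows)),
      patch_shape = patch, scene_shape = scene, frame_rate = 120,
      jitter_sd_px = 0, n_clamped = 0L), class = "gaze_trace")
  }
  # single fixation: assembled patch equals the reconstruction, rest NA
  gz <- mk_gaze(2, 3, c(2, 2), c(6, 8))
  rec <- list(matrix(1:4, 2, 2))
  asm <- assemble_scene(rec, gz, c(6, 8))
  expect_equal(asm$image[2:3, 3:4], rec[[1]])
  expect_equal(sum(asm$coverage), 4L)
  expect_true(all(is.na(asm$image[asm$coverage == 0])))
  # two disjoint fixations: no mixing
  gz2 <- mk_gaze(c(1, 5), c(1, 5), c(2, 2), c(6, 8))
  rec2 <- list(matrix(0, 2, 2), matrix(1, 2, 2))
  asm2 <- assemble_scene(rec2, gz2, c(6, 8))
  expect_equal(asm2$image[1:2, 1:2], matrix(0, 2, 2))
  expect_equal(asm2$image[5:6, 5:6], matrix(1, 2, 2))
  # half-overlapping constant patches of 0 and 1 average to 0.5
  gz3 <- mk_gaze(c(1, 1), c(1, 2), c(2, 2), c(6, 8))
  rec3 <- list(matrix(0, 2, 2), matrix(1, 2, 2))
  asm3 <- assemble_scene(rec3, gz3, c(6, 8))
  expect_equal(asm3$image[1:2, 2], c(0.5, 0.5))
  # coverage conservation with a support mask
  sup <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  asm4 <- assemble_scene(rec3, gz3, c(6, 8), support = sup)
  expect_equal(sum(asm4$coverage), 2L * sum(sup))
})

test_that("fixational jitter lowers the final assembled error", {
  # the benefit requires the viewing geometry of the dynamic protocol: a
  # patch much larger than the filter support, so jitter expands the scene
  # area each fixation reconstructs
  fx <- memo("study40", function() synthetic_fixture(seed = 101L,
                                                     grid_shape = c(40, 80)))
  scene <- make_natural_scene(c(80, 160), seed = 7)
  cache <- element_cache(fx$filters, fx$dictionary)
  errs <- vapply(1:2, function(r) {
    wj <- encode_scene(scene, fx$filters, fx$cells, fx$dictionary,
                       n_fixations = 40, choices_per_frame = 12,
                       jitter_sd_px = 3, seed = r, cache = cache)
    wo <- encode_scene(scene, fx$filters, fx$cells, fx$dictionary,
                       n_fixations = 40, choices_per_frame = 12,
                       jitter_sd_px = 0, seed = r, cache = cache)
    c(wj$trace$err_full[40], wo$trace$err_full[40])
  }, numeric(2))
  expect_lt(median(errs[1, ]), median(errs[2, ]))
})
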