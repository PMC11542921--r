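# Fixture generator: electrode lattice geometry, mosaics, filters,
# dictionaries and targets.

test_that("electrode lattice has the stated geometry", {
  arr <- make_electrode_array()
  expect_equal(nrow(arr$positions), 512L)
  arr <- make_electrode_array(8, 16, 60)
  # nearest-neighbor distance of interior electrodes equals the pitch
  d <- as.matrix(dist(arr$positions))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  interior <- which(arr$positions[, 1] > min(arr$positions[, 1]) + 60 &
                    arr$positions[, 1] < max(arr$positions[, 1]) - 60 &
                    arr$positions[, 2] > min(arr$positions[, 2]) + 60 &
                    arr$positions[, 2] < max(arr$positions[, 2]) - 60)
  expect_true(length(interior) > 0)
  expect_equal(unname(nn[interior]), rep(60, length(interior)),
               tolerance = 1e-9)
  expect_equal(nrow(unique(arr$positions)), nrow(arr$positions))
})

test_that("empty populations give empty filters but a full array", {
  ret <- make_retina(16, 32, 60, n_on = 0, n_off = 0, rf_radius_um = 60,
                     seed = 1)
  expect_equal(nrow(ret$array$positions), 512L)
  expect_equal(nrow(ret$cells), 0L)
  expect_equal(ncol(ret$filters$A), 0L)
})

test_that("ON columns have positive means, OFF columns negative", {
  ret <- make_retina(8, 16, 60, n_on = 25, n_off = 25, rf_radius_um = 60,
                     seed = 1)
  mu <- Matrix::colMeans(ret$filters$A)
  expect_true(all(mu[ret$cells$type == "ON"] > 0))
  expect_true(all(mu[ret$cells$type == "OFF"] < 0))
  # filters vanish outside 3 sigma of the RF center
  i <- 7L
  px <- expand.grid(y = ret$filters$pixel_y, x = ret$filters$pixel_x)
  d <- sqrt((px$x - ret$cells$x_um[i])^2 + (px$y - ret$cells$y_um[i])^2)
  col <- as.numeric(ret$filters$A[, i])
  expect_true(all(col[d > 3 * 60] == 0))
  expect_true(all(col[d < 60] != 0))
})

test_that("same-type mosaics respect the exclusion separation", {
  fx <- study_fixture()
  rf <- fx$cells$rf_radius_um[1]
  for (ty in c("ON", "OFF")) {
    pts <- fx$cells[fx$cells$type == ty, c("x_um", "y_um")]
    expect_gt(min(dist(pts)), 0.7 * 2 * rf)
  }
  # requesting an impossible density fails loudly
  expect_error(make_retina(2, 2, 60, n_on = 50, n_off = 0, rf_radius_um = 60),
               "cannot place")
})

test_that("fixture generation is seed-deterministic", {
  a <- make_retina(4, 8, 60, n_on = 10, n_off = 10, rf_radius_um = 45, seed = 3)
  b <- make_retina(4, 8, 60, n_on = 10, n_off = 10, rf_radius_um = 45, seed = 3)
  expect_identical(a$cells, b$cells)
  expect_identical(as.matrix(a$filters$A), as.matrix(b$filters$A))
  c <- make_retina(4, 8, 60, n_on = 10, n_off = 10, rf_radius_um = 45, seed = 5)
  expect_false(identical(a$cells$x_um, c$cells$x_um))
  d1 <- make_dictionary(a$array, a$cells, a$filters, seed = 3)
  d2 <- make_dictionary(b$array, b$cells, b$filters, seed = 3)
  expect_identical(as.matrix(d1$D), as.matrix(d2$D))
  expect_identical(d1$elements, d2$elements)
})

test_that("dictionary honors retention, axon-exclusion and null-element rules", {
  fx <- small_fixture()
  d <- fx$dictionary
  nn <- !d$elements$is_null
  # every retained non-null element activates >= 1 cell with p >= 0.01
  expect_true(all(apply(as.matrix(d$D[, nn, drop = FALSE]), 2, max) >= 0.01))
  # exhaustive scan of the raw metadata against the retention rule
  expect_equal(d$meta$retained, d$meta$max_p >= 0.01 & !d$meta$axon_bundle)
  # axon-flagged elements never appear among the columns of D
  expect_length(intersect(d$elements$element_id,
                          d$meta$element_id[d$meta$axon_bundle]), 0)
  # exactly one null element, all-zero probabilities, zero variance
  expect_equal(sum(d$elements$is_null), 1L)
  null_col <- which(d$elements$is_null)
  expect_true(all(d$D[, null_col] == 0))
  expect_equal(d$v[null_col], 0)
  # variance vector matches the per-element definition
  vv <- apply(as.matrix(d$D), 2, function(p) element_variance(fx$filters, p))
  expect_equal(d$v, vv, tolerance = 1e-12)
  expect_true(all(d$v >= 0))
})

test_that("activation probability is non-decreasing in amplitude", {
  fx <- small_fixture()
  d <- fx$dictionary
  el <- d$elements[!d$elements$is_null, ]
  for (e in unique(el$electrode_id)) {
    cols <- which(!d$elements$is_null & d$elements$electrode_id == e)
    cols <- cols[order(d$elements$amplitude_uA[cols])]
    if (length(cols) < 2) next
    P <- as.matrix(d$D[, cols, drop = FALSE])
    expect_true(all(diff(t(P)) >= -1e-12))
  }
})

test_that("defaults on a full 512-electrode array give 1000-5000 elements", {
  ret <- make_retina(16, 32, 60, n_on = 350, n_off = 350, rf_radius_um = NULL,
                     seed = 7)
  d <- make_dictionary(ret$array, ret$cells, ret$filters, seed = 7)
  n_ret <- sum(d$meta$retained)
  expect_gte(n_ret, 1000L)
  expect_lte(n_ret, 5000L)
  # a substantial fraction of elements co-activate two or more cells
  nn <- !d$elements$is_null
  frac_multi <- mean(Matrix::colSums(d$D[, nn, drop = FALSE] >= 0.5) >= 2)
  expect_gt(frac_multi, 0.15)
})

test_that("dictionary edge cases behave", {
  ret <- make_retina(2, 4, 60, n_on = 0, n_off = 0, rf_radius_um = 40, seed = 1)
  d <- make_dictionary(ret$array, ret$cells, ret$filters, n_amplitudes = 6,
                       seed = 1)
  expect_equal(ncol(d$D), 1L)  # only the null element
  expect_true(d$elements$is_null[1])
  # mismatched population/filters is a consistency error
  fx <- tiny_fixture()
  expect_error(make_dictionary(fx$array, fx$cells[1:2, ], fx$filters),
               "does not match")
})

test_that("checkerboard targets are +/-1, unbiased and reproducible", {
  tg <- make_checkerboard_targets(1, c(2, 2), seed = 1)[[1]]
  expect_true(all(tg$pixels %in% c(-1, 1)))
  tgs <- make_checkerboard_targets(20, c(40, 80), seed = 2)
  px <- unlist(lapply(tgs, function(t) t$pixels))
  se <- 1 / sqrt(length(px))
  expect_lt(abs(mean(px)), 3 * se)
  expect_equal(length(unique(vapply(tgs, function(t) paste(t$pixels[1:32],
    collapse = ""), ""))), 20L)
  again <- make_checkerboard_targets(20, c(40, 80), seed = 2)
  expect_identical(tgs, again)
  # block checkers are constant on block_px squares
  tb <- make_checkerboard_targets(1, c(9, 9), seed = 3, block_px = 3)[[1]]
  expect_true(all(tb$pixels[1:3, 1:3] == tb$pixels[1, 1]))
})

test_that("sampled responses are Bernoulli with the calibrated rates", {
  fx <- small_fixture()
  d <- fx$dictionary
  # null element: all zeros
  z <- sample_responses(d, 0L, 50, seed = 1)
  expect_true(all(z == 0))
  expect_equal(dim(z), c(50L, d$n_cells))
  # unknown element errors
  expect_error(sample_responses(d, 999999L, 5), "unknown element")
  # empirical rates converge to p within 3 binomial SEs
  nn_cols <- which(!d$elements$is_null)
  col <- nn_cols[which.max(Matrix::colSums(d$D[, nn_cols, drop = FALSE] > 0.2))]
  p <- as.numeric(d$D[, col])
  r <- sample_responses(d, d$elements$element_id[col], 10000, seed = 2)
  expect_true(all(r %in% c(0L, 1L)))
  emp <- colMeans(r)
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(emp - p) <= 3 * se + 1e-12))
})
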