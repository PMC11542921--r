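# Perceptual-metric extension: SSIM (standard reference parameterization,
# Gaussian-weighted 11x11 windows over the valid region) with an analytic
# gradient, and joint optimization of per-patch element usages under MSE or
# SSIM with an L1 stimulation-budget penalty.

ssim_ops <- function(dims, window, sigma) {
  k <- gaussian_kernel_1d(window, sigma)
  list(Kr = window_operator(dims[1], k), Kc = window_operator(dims[2], k))
}

ssim_stats <- function(x, y, ops, C1, C2) {
  Kr <- ops$Kr; Kc <- ops$Kc
  ux <- Kr %*% x %*% t(Kc); uy <- Kr %*% y %*% t(Kc)
  sxx <- Kr %*% (x * x) %*% t(Kc) - ux^2
  syy <- Kr %*% (y * y) %*% t(Kc) - uy^2
  sxy <- Kr %*% (x * y) %*% t(Kc) - ux * uy
  A1 <- 2 * ux * uy + C1; A2 <- 2 * sxy + C2
  B1 <- ux^2 + uy^2 + C1; B2 <- sxx + syy + C2
  list(ux = ux, uy = uy, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       S = (A1 * A2) / (B1 * B2))
}

#' Structural similarity (SSIM) between two images
#'
#' Mean local SSIM over Gaussian-weighted sliding windows (valid windows
#' only): `S = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#' ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))` with
#' `C1 = (k1 L)^2`, `C2 = (k2 L)^2`.
#'
#' @param image_a,image_b Pixel matrices of equal shape.
#' @param window Window side (default 11).
#' @param sigma Gaussian window SD (default 1.5).
#' @param k1,k2 Stability constants (defaults 0.01, 0.03).
#' @param dynamic_range Intensity range L (default 2 for \[-1, 1\] images).
#' @return Scalar in \[-1, 1\]; 1 for identical images.
#' @export
ssim <- function(image_a, image_b, window = 11L, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03, dynamic_range = 2) {
  a <- as_image(image_a); b <- as_image(image_b)
  if (!all(dim(a) == dim(b))) stop_param("images must have equal shape")
  if (dynamic_range <= 0) stop_param("dynamic_range must be > 0")
  if (window > min(dim(a))) stop_param("window larger than image")
  C1 <- (k1 * dynamic_range)^2; C2 <- (k2 * dynamic_range)^2
  st <- ssim_stats(a, b, ssim_ops(dim(a), window, sigma), C1, C2)
  mean(st$S)
}

# Gradient of mean local SSIM with respect to the second image.
ssim_grad <- function(x, y, ops, C1, C2) {
  st <- ssim_stats(x, y, ops, C1, C2)
  denom <- st$B1 * st$B2
  F1 <- 2 * (st$ux * st$A2 - st$uy * st$S * st$B2) / denom
  F2 <- -st$S / st$B2
  F3 <- 2 * st$A1 / denom
  Kr <- ops$Kr; Kc <- ops$Kc
  back <- function(M) t(Kr) %*% M %*% Kc
  N <- length(st$S)
  g <- back(F1) + 2 * y * back(F2) - 2 * back(F2 * st$uy) +
    x * back(F3) - back(F3 * st$ux)
  list(value = mean(st$S), grad = g / N)
}

# Patch placement grid: top-left corners with roughly patch/2 stride,
# always including the far edge.
patch_grid <- function(scene_shape, patch_shape, stride = NULL) {
  stride <- stride %||% pmax(1L, floor(patch_shape / 2))
  pos1 <- unique(c(seq(1L, scene_shape[1] - patch_shape[1] + 1L, by = stride[1]),
                   scene_shape[1] - patch_shape[1] + 1L))
  pos2 <- unique(c(seq(1L, scene_shape[2] - patch_shape[2] + 1L, by = stride[2]),
                   scene_shape[2] - patch_shape[2] + 1L))
  expand.grid(row = pos1, col = pos2)
}

#' Jointly optimize per-patch stimulation usage under MSE or SSIM
#'
#' Covers the scene with patches at all (discretized) fixation locations and
#' minimizes `d(s, G({A D w_i})) + lambda * sum_i ||w_i||_1` over non-negative
#' usage vectors `w_i`, where `G` assembles the scene by averaging patch
#' reconstructions over their footprints (uniform fixation distribution) and
#' `d` is relative MSE or `1 - SSIM` (expected responses only; the variance
#' term does not enter this formulation). Solved by proximal projected
#' gradient descent with backtracking; the non-negativity constraint and the
#' L1 penalty are handled exactly by the prox (shifted soft-thresholding).
#'
#' Assembly and the error are evaluated with uncovered pixels reconstructing
#' to 0; footprints are the filter support, so a dense enough patch grid
#' covers (nearly) the whole scene.
#'
#' @param scene Scene pixel matrix.
#' @param filters A `recon_filter` (its grid is the patch shape).
#' @param dictionary A `stim_dictionary`.
#' @param metric "mse" or "ssim".
#' @param lambda_ L1 budget penalty (>= 0).
#' @param stride Patch grid stride (default half the patch).
#' @param max_iter Iteration cap (default 300).
#' @param tol Relative objective-change tolerance (default 1e-7).
#' @param step0 Initial step size (default from a power-iteration Lipschitz
#'   estimate of the MSE term).
#' @param cache Optional [element_cache()].
#' @return A `patch_usage_set`: `W` (elements x patches), `assembled` scene,
#'   `metric_value` (relative MSE or SSIM of the assembly), `objective`,
#'   `total_usage`, `lambda`, `converged`, `iterations`, `grad_norm`,
#'   `patches`.
#' @export
joint_patch_optimize <- function(scene, filters, dictionary,
                                 metric = c("mse", "ssim"), lambda_ = 0,
                                 stride = NULL, max_iter = 300L, tol = 1e-7,
                                 step0 = NULL, cache = NULL) {
  metric <- match.arg(metric)
  if (lambda_ < 0) stop_param("lambda_ must be >= 0")
  if (is.null(cache)) cache <- element_cache(filters, dictionary)
  Q <- cache$Q
  m <- ncol(Q)
  ps <- filters$grid_shape
  locs <- patch_grid(dim(scene), ps, stride)
  P <- nrow(locs)
  sup <- filter_support(filters)
  sup_idx <- which(as.numeric(sup) > 0)

  # scene linear indices of each patch's supported pixels + coverage
  nr <- nrow(scene)
  cnt <- matrix(0L, nrow(scene), ncol(scene))
  scene_idx <- vector("list", P)
  for (i in seq_len(P)) {
    ri <- locs$row[i] + (sup_idx - 1L) %% ps[1]
    ci <- locs$col[i] + (sup_idx - 1L) %/% ps[1]
    scene_idx[[i]] <- (ci - 1L) * nr + ri
    cnt[scene_idx[[i]]] <- cnt[scene_idx[[i]]] + 1L
  }
  cov <- cnt > 0
  Qs <- Q[sup_idx, , drop = FALSE]

  assemble <- function(W) {
    g <- matrix(0, nrow(scene), ncol(scene))
    PX <- as.matrix(Qs %*% W)
    for (i in seq_len(P)) g[scene_idx[[i]]] <- g[scene_idx[[i]]] + PX[, i]
    g / pmax(cnt, 1L)
  }
  adjoint <- function(gr) {
    # gradient wrt W of sum(gr * assemble(W))
    GP <- vapply(seq_len(P), function(i)
      gr[scene_idx[[i]]] / cnt[scene_idx[[i]]], numeric(length(sup_idx)))
    as.matrix(Matrix::crossprod(Qs, matrix(GP, length(sup_idx), P)))
  }

  s2cov <- sq_norm(scene[cov])
  if (metric == "ssim") {
    ops <- ssim_ops(dim(scene), 11L, 1.5)
    C1 <- (0.01 * 2)^2; C2 <- (0.03 * 2)^2
  }
  smooth_fg <- function(W) {
    g <- assemble(W)
    if (metric == "mse") {
      resid <- (scene - g) * cov
      list(value = sq_norm(resid) / s2cov, grad_g = -2 * resid / s2cov)
    } else {
      sg <- ssim_grad(scene, g, ops, C1, C2)
      list(value = 1 - sg$value, grad_g = -sg$grad)
    }
  }

  if (is.null(step0)) {
    # power iteration on the assemble/adjoint pair for a Lipschitz estimate
    set.seed(1L)
    Wp <- matrix(stats::rnorm(m * P), m, P)
    for (it in 1:15) {
      Wp <- adjoint(assemble(Wp) * cov)
      nw <- sqrt(sq_norm(Wp))
      if (nw == 0) break
      Wp <- Wp / nw
    }
    op_norm2 <- sq_norm(assemble(Wp) * cov)
    L <- 2 * max(op_norm2, 1e-12) / if (metric == "mse") s2cov else 1
    step0 <- 1 / L
  }

  W <- matrix(0, m, P)
  fg <- smooth_fg(W)
  obj <- fg$value + lambda_ * sum(W)
  step <- step0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gradW <- adjoint(fg$grad_g)
    repeat {
      W_new <- pmax(W - step * (gradW + lambda_), 0)
      fg_new <- smooth_fg(W_new)
      obj_new <- fg_new$value + lambda_ * sum(W_new)
      if (obj_new <= obj + 1e-12 || step < 1e-12 * step0) break
      step <- step / 2
    }
    moved <- sqrt(sq_norm(W_new - W))
    improved <- obj - obj_new
    W <- W_new; fg <- fg_new
    if (improved >= 0) obj <- obj_new
    if (moved == 0 || improved <= tol * max(1, abs(obj))) {
      converged <- TRUE
      break
    }
    step <- min(step * 1.5, step0 * 100)
  }
  gradW <- adjoint(fg$grad_g)
  if (!converged) {
    warning(sprintf("joint_patch_optimize: iteration cap reached (grad norm %.3g)",
                    sqrt(sq_norm(gradW))))
  }
  g <- assemble(W)
  structure(
    list(W = W, lambda = lambda_, metric = metric, assembled = g,
         covered = cov,
         metric_value = if (metric == "mse") sq_norm((scene - g) * cov) / s2cov
                        else ssim(scene, g * cov),
         objective = obj, total_usage = sum(W), converged = converged,
         iterations = iter, grad_norm = sqrt(sq_norm(gradW)),
         patches = locs),
    class = "patch_usage_set"
  )
}

#' @export
print.patch_usage_set <- function(x, ...) {
  cat(sprintf(paste0("<patch_usage_set> %s, lambda %.3g: %d patches, total ",
                     "usage %.1f, metric %.4f\n"),
              x$metric, x$lambda, ncol(x$W), x$total_usage, x$metric_value))
  invisible(x)
}

#' Sweep the stimulation-budget penalty
#'
#' Solves [joint_patch_optimize()] over a lambda grid and tabulates the
#' budget/quality trade-off; along the sweep the total usage is non-
#' increasing in lambda.
#'
#' @param scene,filters,dictionary,metric,... As in [joint_patch_optimize()].
#' @param lambdas Penalty grid (increasing).
#' @return Data frame: lambda, metric_value, total_usage, converged.
#' @export
budget_sweep <- function(scene, filters, dictionary, lambdas,
                         metric = "mse", ...) {
  cache <- element_cache(filters, dictionary)
  rows <- lapply(lambdas, function(l) {
    r <- joint_patch_optimize(scene, filters, dictionary, metric = metric,
                              lambda_ = l, cache = cache, ...)
    data.frame(lambda = l, metric_value = r$metric_value,
               total_usage = r$total_usage, converged = r$converged)
  })
  do.call(rbind, rows)
}
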