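# Greedy temporal dithering: per-step selection of the dictionary element that
# most decreases the expected reconstruction error, under refractory masking
# and optional exclusion-radius spatial multiplexing.
#
# The run loop is incremental: with Q = A D (pixels x elements), the objective
# change of element c given residual r = s - A P is -2 q_c.r + ||q_c||^2 + v_c,
# and choosing c* updates the score vector q.r by the c* column of the Gram
# matrix G = Q'Q. This is algebraically identical to direct evaluation (the
# exhaustive-argmin oracle in the tests guards it) and makes each step
# O(elements + filter overlap of the chosen element).

#' Precompute per-element reconstruction quantities for a fixture
#'
#' Caches `Q = A D`, its column norms, the Gram matrix `Q'Q` and index
#' structures shared by every greedy run on the same filters + dictionary.
#' Passing the cache to [run_greedy()] amortizes the setup across targets.
#'
#' @param filters A `recon_filter`.
#' @param dictionary A `stim_dictionary`.
#' @return An `element_cache` object.
#' @export
element_cache <- function(filters, dictionary) {
  Q <- filters$A %*% dictionary$D
  G <- methods::as(Matrix::crossprod(Q), "CsparseMatrix")
  G <- methods::as(G, "generalMatrix")
  m <- ncol(Q)
  gp <- G@p
  g_idx <- lapply(seq_len(m), function(j)
    if (gp[j + 1] > gp[j]) G@i[(gp[j] + 1):gp[j + 1]] + 1L else integer(0))
  g_val <- lapply(seq_len(m), function(j)
    if (gp[j + 1] > gp[j]) G@x[(gp[j] + 1):gp[j + 1]] else numeric(0))
  structure(
    list(Q = Q, qq = as.numeric(Matrix::colSums(Q^2)), v = dictionary$v,
         g_idx = g_idx, g_val = g_val,
         elements = dictionary$elements,
         null_col = which(dictionary$elements$is_null),
         n_cells = dictionary$n_cells),
    class = "element_cache"
  )
}

#' Initialize a refractory state
#'
#' Tracks, for every cell, the last step at which it was "targeted" (the
#' chosen element had activation probability above `theta` for it). Elements
#' that would re-target such a cell within `window` subsequent steps are
#' masked out.
#'
#' @param n_cells Number of cells.
#' @param theta Probability threshold (default 0.1).
#' @param window Masking window in steps (default 100).
#' @return A `refractory_state`.
#' @export
refractory_state <- function(n_cells, theta = 0.1, window = 100L) {
  structure(
    list(theta = theta, window = as.integer(window), step = 0L,
         last_hit = rep(-Inf, n_cells)),
    class = "refractory_state"
  )
}

#' Elapsed steps since each cell was last targeted
#' @param state A `refractory_state`.
#' @return Numeric vector (Inf for never-targeted cells) relative to the
#'   upcoming step.
#' @export
steps_since_targeted <- function(state) state$step + 1 - state$last_hit

#' Record one executed step in a refractory state
#'
#' @param state A `refractory_state`.
#' @param p_chosen Probability vector of the chosen element, or a matrix
#'   (cells x picks) for a multiplexed step; may be NULL for an idle step.
#' @return The updated state.
#' @export
refractory_record <- function(state, p_chosen = NULL) {
  state$step <- state$step + 1L
  if (!is.null(p_chosen)) {
    P <- as.matrix(p_chosen)
    hit <- which(apply(P > state$theta, 1, any))
    state$last_hit[hit] <- state$step
  }
  state
}

#' Valid-element mask under refractory constraints
#'
#' An element is valid for the upcoming step iff every cell it activates with
#' probability above `theta` was not targeted within the last `window` steps.
#' The null element is always valid.
#'
#' @param dictionary A `stim_dictionary`.
#' @param state A `refractory_state`.
#' @return Logical vector over the columns of `D`.
#' @export
valid_mask <- function(dictionary, state) {
  since <- steps_since_targeted(state)
  hot <- which(since <= state$window)
  mask <- rep(TRUE, ncol(dictionary$D))
  if (length(hot) > 0) {
    nhit <- Matrix::colSums(dictionary$D[hot, , drop = FALSE] > state$theta)
    mask <- nhit == 0
  }
  mask[dictionary$elements$is_null] <- TRUE
  mask
}

#' One greedy selection step (definitional form)
#'
#' Evaluates `||s - A(P + p_c)||^2 + v_c` for every valid element `c` and
#' returns the minimizer; ties are broken toward the lowest element id (the
#' null element has id 0). This direct evaluation defines the per-step
#' objective; [run_greedy()] computes the same argmin incrementally.
#'
#' @param target Pixel matrix or `visual_target`.
#' @param filters A `recon_filter`.
#' @param cumulative_expected_response Vector of cumulative expected spike
#'   counts `P = sum of p_{c_i}` so far.
#' @param dictionary A `stim_dictionary`.
#' @param mask Logical validity vector over elements (must include the null
#'   element).
#' @return List with `element_id`, `objective` (the minimized value) and
#'   `column` (index into the dictionary columns).
#' @export
greedy_step <- function(target, filters, cumulative_expected_response,
                        dictionary, mask = NULL) {
  s <- as.numeric(as_image(target))
  if (is.null(mask)) mask <- rep(TRUE, ncol(dictionary$D))
  if (!any(mask & dictionary$elements$is_null)) {
    stop_param("mask must include the null element")
  }
  resid <- s - as.numeric(filters$A %*% cumulative_expected_response)
  Q <- filters$A %*% dictionary$D
  obj <- sq_norm(resid) - 2 * as.numeric(Matrix::crossprod(Q, resid)) +
    as.numeric(Matrix::colSums(Q^2)) + dictionary$v
  obj[!mask] <- Inf
  best <- which(obj <= min(obj) + 0)
  if (length(best) > 1) best <- best[which.min(dictionary$elements$element_id[best])]
  list(element_id = dictionary$elements$element_id[best],
       objective = obj[best], column = best)
}

#' Run greedy temporal dithering on a target
#'
#' Iterates greedy selection for up to `T_max` steps. After each executed step
#' the refractory state is advanced: cells targeted with probability above
#' `theta` block, for `window` steps, every element that would re-target them.
#' When `exclusion_radius_um > 0` and `max_per_step > 1`, several elements are
#' picked greedily within one time step (spatial multiplexing); after each
#' pick, elements on electrodes within the exclusion radius of any picked
#' electrode are disabled for the remainder of the step.
#'
#' A step on which the null element wins under masking is recorded as an idle
#' step (stimulation pauses while refractory windows expire). The run stops
#' early only when the null element would also win against the unmasked
#' dictionary, i.e. no retained element can decrease the objective any more.
#'
#' @param target Pixel matrix or `visual_target`.
#' @param filters A `recon_filter`.
#' @param dictionary A `stim_dictionary`.
#' @param T_max Maximum number of time steps (0 gives an empty sequence).
#' @param theta,window Refractory parameters (defaults 0.1 and 100).
#' @param exclusion_radius_um Spatial exclusion radius in µm; 0 disables
#'   multiplexing.
#' @param max_per_step Maximum picks per time step (1 disables multiplexing).
#' @param sample If TRUE, Bernoulli responses are drawn for every pick.
#' @param seed Seed for response sampling (selection itself is deterministic).
#' @param cache Optional [element_cache()] to reuse across targets.
#' @return A `stim_sequence`: `steps` data frame (step, slot, element_id,
#'   electrode_id, amplitude_uA, objective), expected-`trace` per executed
#'   step, `cum_expected` response vector, `error` report, idle/executed step
#'   counts, and (if sampled) `sampled_counts` + `sampled_relative_mse`.
#' @export
run_greedy <- function(target, filters, dictionary, T_max = 10000L,
                       theta = 0.1, window = 100L, exclusion_radius_um = 0,
                       max_per_step = 1L, sample = FALSE, seed = 1L,
                       cache = NULL) {
  if (T_max < 0) stop_param("T_max must be >= 0")
  if (exclusion_radius_um < 0) stop_param("exclusion_radius_um must be >= 0")
  if (length(which(dictionary$elements$is_null)) != 1L) {
    stop_param("dictionary must contain exactly one null element")
  }
  if (is.null(cache)) cache <- element_cache(filters, dictionary)
  s <- as.numeric(as_image(target))
  m <- ncol(cache$Q)
  null_col <- cache$null_col
  multiplex <- exclusion_radius_um > 0 && max_per_step > 1

  # cell -> elements with p > theta, element -> targeted cells
  Dt <- methods::as(dictionary$D, "TsparseMatrix")
  selp <- Dt@x > theta
  cell_elems <- split(Dt@j[selp] + 1L, factor(Dt@i[selp] + 1L,
                                              levels = seq_len(cache$n_cells)))
  elem_cells <- split(Dt@i[selp] + 1L, factor(Dt@j[selp] + 1L,
                                              levels = seq_len(m)))

  elec_of <- dictionary$elements$electrode_id
  if (multiplex) {
    exy <- dictionary$electrode_xy
    edist <- as.matrix(stats::dist(exy))
    elems_by_elec <- split(seq_len(m)[!is.na(elec_of)],
                           factor(elec_of[!is.na(elec_of)],
                                  levels = seq_len(nrow(exy))))
  }

  # Cached sparse columns of D for cheap per-pick expected-response updates.
  dp <- dictionary$D@p
  d_idx <- lapply(seq_len(m), function(j)
    if (dp[j + 1] > dp[j]) dictionary$D@i[(dp[j] + 1):dp[j + 1]] + 1L else integer(0))
  d_val <- lapply(seq_len(m), function(j)
    if (dp[j + 1] > dp[j]) dictionary$D@x[(dp[j] + 1):dp[j + 1]] else numeric(0))

  scores <- as.numeric(Matrix::crossprod(cache$Q, s))
  bias <- sq_norm(s)
  cumvar <- 0
  blocked_until <- rep(-1, m)
  last_hit <- rep(-Inf, cache$n_cells)
  cum_expected <- numeric(cache$n_cells)
  max_rec <- max(1L, T_max * max(1L, if (multiplex) max_per_step else 1L))
  trace <- numeric(max(1L, T_max)); n_trace <- 0L
  rec_step <- integer(max_rec); rec_slot <- integer(max_rec)
  rec_col <- integer(max_rec); rec_obj <- numeric(max_rec); n_rec <- 0L
  n_idle <- 0L
  stopped_early <- FALSE
  eid <- dictionary$elements$element_id

  t <- 0L
  while (t < T_max) {
    t <- t + 1L
    step_disabled <- NULL
    picked_cols <- integer(0)
    for (slot in seq_len(if (multiplex) max_per_step else 1L)) {
      delta <- -2 * scores + cache$qq + cache$v
      masked <- delta
      masked[blocked_until >= t] <- Inf
      if (!is.null(step_disabled)) masked[step_disabled] <- Inf
      masked[null_col] <- 0
      best <- which.min(masked)
      mval <- masked[best]
      if (mval >= 0 || best == null_col) {
        # Null wins among valid elements.
        if (slot == 1L) {
          delta[null_col] <- 0
          if (min(delta) >= -1e-12) {
            stopped_early <- TRUE
            t <- t - 1L
          } else {
            n_idle <- n_idle + 1L
            n_trace <- n_trace + 1L
            trace[n_trace] <- bias + cumvar
          }
        }
        break
      }
      ties <- which(masked <= mval)
      if (length(ties) > 1) best <- ties[which.min(eid[ties])]
      # Accept pick
      bias <- bias - 2 * scores[best] + cache$qq[best]
      cumvar <- cumvar + cache$v[best]
      idx <- cache$g_idx[[best]]
      scores[idx] <- scores[idx] - cache$g_val[[best]]
      di <- d_idx[[best]]
      cum_expected[di] <- cum_expected[di] + d_val[[best]]
      picked_cols <- c(picked_cols, best)
      n_rec <- n_rec + 1L
      rec_step[n_rec] <- t; rec_slot[n_rec] <- slot
      rec_col[n_rec] <- best; rec_obj[n_rec] <- bias + cumvar
      if (multiplex) {
        near <- which(edist[elec_of[best], ] <= exclusion_radius_um)
        step_disabled <- unique(c(step_disabled,
                                  unlist(elems_by_elec[near], use.names = FALSE)))
      }
    }
    if (stopped_early) break
    if (length(picked_cols) > 0) {
      hit <- unique(unlist(elem_cells[picked_cols], use.names = FALSE))
      if (length(hit) > 0) {
        last_hit[hit] <- t
        bu <- t + window
        for (n in hit) {
          els <- cell_elems[[n]]
          blocked_until[els] <- pmax(blocked_until[els], bu)
        }
      }
      n_trace <- n_trace + 1L
      trace[n_trace] <- bias + cumvar
    }
  }

  trace <- trace[seq_len(n_trace)]
  rec_col <- rec_col[seq_len(n_rec)]
  steps <- data.frame(
    step = rec_step[seq_len(n_rec)], slot = rec_slot[seq_len(n_rec)],
    element_id = eid[rec_col],
    electrode_id = dictionary$elements$electrode_id[rec_col],
    amplitude_uA = dictionary$elements$amplitude_uA[rec_col],
    objective = rec_obj[seq_len(n_rec)]
  )
  err <- list(bias = bias, variance = cumvar, expected_error = bias + cumvar,
              relative_expected_error = (bias + cumvar) / sq_norm(s))
  class(err) <- "error_report"
  out <- list(
    steps = steps, trace = trace, cum_expected = cum_expected, error = err,
    n_steps = t, n_idle = n_idle, n_picks = length(rec_col),
    stopped_early = stopped_early,
    params = list(T_max = T_max, theta = theta, window = window,
                  exclusion_radius_um = exclusion_radius_um,
                  max_per_step = max_per_step, seed = seed)
  )
  if (sample) {
    set.seed(derive_seed(seed, 5L))
    counts <- numeric(cache$n_cells)
    for (col in rec_col) {
      p <- as.numeric(dictionary$D[, col])
      counts <- counts + stats::rbinom(length(p), 1L, p)
    }
    out$sampled_counts <- counts
    out$sampled_relative_mse <- relative_mse(s_matrix(target, filters),
                                             reconstruct(filters, counts))
  }
  structure(out, class = "stim_sequence")
}

s_matrix <- function(target, filters) {
  s <- as_image(target)
  matrix(as.numeric(s), filters$grid_shape[1], filters$grid_shape[2])
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf(paste0("<stim_sequence> %d picks in %d steps (%d idle)%s; ",
                     "relative expected error %.4f\n"),
              x$n_picks, x$n_steps, x$n_idle,
              if (x$stopped_early) ", early stop" else "",
              x$error$relative_expected_error))
  invisible(x)
}
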