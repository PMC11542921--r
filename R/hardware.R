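# Hardware-oriented analyses: which electrodes the encoder actually uses, and
# how much performance survives when the dictionary is restricted to the most
# frequently used subset (implant power/memory savings).

#' Per-electrode stimulation frequency of one or more sequences
#'
#' @param sequences A `stim_sequence` or list of them.
#' @param n_electrodes Total electrode count (inferred from the sequences'
#'   largest electrode id if omitted).
#' @return Data frame: electrode_id, count, frequency (counts normalized to
#'   sum to 1 over all electrodes; all-zero when no picks were made).
#' @export
electrode_usage <- function(sequences, n_electrodes = NULL) {
  if (inherits(sequences, "stim_sequence")) sequences <- list(sequences)
  if (length(sequences) < 1) stop_param("need at least one sequence")
  elec <- unlist(lapply(sequences, function(s) s$steps$electrode_id))
  elec <- elec[!is.na(elec)]
  if (is.null(n_electrodes)) n_electrodes <- max(elec, 1L)
  counts <- tabulate(elec, nbins = n_electrodes)
  total <- sum(counts)
  data.frame(electrode_id = seq_len(n_electrodes), count = counts,
             frequency = if (total > 0) counts / total else rep(0, n_electrodes))
}

#' Reconstruction error as a function of dictionary electrode fraction
#'
#' Ranks electrodes by their greedy stimulation frequency on the training
#' targets, then, for each fraction, restricts the dictionary to the
#' top-ranked electrodes (plus the null element) and re-runs greedy dithering
#' and the relaxed-joint lower bound on the held-out evaluation targets.
#' Training and evaluation target sets must be disjoint.
#'
#' @param filters A `recon_filter`.
#' @param dictionary A `stim_dictionary`.
#' @param train_targets,eval_targets Lists of targets (disjoint).
#' @param fractions Electrode fractions in (0, 1] (default 0.1..1.0).
#' @param T_max,theta,window Greedy parameters passed to [run_greedy()].
#' @param relaxed Also compute the relaxed-joint lower bound per fraction
#'   (default TRUE).
#' @return List with `curve` (data frame: fraction, n_electrodes,
#'   err_greedy, err_relaxed — mean relative expected errors over evaluation
#'   targets) and `ranking` (electrode ids, most used first).
#' @export
subsampling_curve <- function(filters, dictionary, train_targets, eval_targets,
                              fractions = seq(0.1, 1, by = 0.1),
                              T_max = 10000L, theta = 0.1, window = 100L,
                              relaxed = TRUE) {
  if (any(fractions <= 0 | fractions > 1)) stop_param("fractions must be in (0, 1]")
  same <- any(vapply(train_targets, function(a) any(vapply(
    eval_targets, function(b) identical(as_image(a), as_image(b)), NA)), NA))
  if (isTRUE(same)) stop_param("train and eval target sets must be disjoint")

  cache_full <- element_cache(filters, dictionary)
  train_runs <- lapply(train_targets, function(tg)
    run_greedy(tg, filters, dictionary, T_max = T_max, theta = theta,
               window = window, cache = cache_full))
  usage <- electrode_usage(train_runs,
                           n_electrodes = max(dictionary$elements$electrode_id,
                                              na.rm = TRUE))
  ranking <- usage$electrode_id[order(-usage$count, usage$electrode_id)]
  used <- sum(usage$count > 0)

  rows <- lapply(sort(fractions), function(f) {
    n_keep <- max(1L, round(f * length(ranking)))
    sub <- restrict_dictionary(dictionary, ranking[seq_len(n_keep)])
    cache <- element_cache(filters, sub)
    errs_g <- vapply(eval_targets, function(tg)
      run_greedy(tg, filters, sub, T_max = T_max, theta = theta,
                 window = window, cache = cache)$error$relative_expected_error, 0)
    errs_r <- if (relaxed) vapply(eval_targets, function(tg)
      relaxed_joint(tg, filters, sub, cache = cache)$relative_expected_error, 0)
      else rep(NA_real_, length(eval_targets))
    data.frame(fraction = f, n_electrodes = n_keep,
               err_greedy = mean(errs_g), err_relaxed = mean(errs_r))
  })
  list(curve = do.call(rbind, rows), ranking = ranking, n_used_train = used)
}
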