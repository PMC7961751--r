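#' Iterated 75/25 hold-out scoring of one-class HMMs
#'
#' The evaluation scheme behind the intra-subject experiments: at each
#' iteration a seeded random split puts `floor(train_fraction * |S+|)`
#' positive samples (at least 2) into training; a fresh HMM is fitted on the
#' training positives only, then the held-out positives (truth `TRUE`) and
#' every negative sample (truth `FALSE`) are scored by their sequence
#' log-likelihood under that model. Scores from all iterations are pooled
#' into one table; since every window has the same length the
#' log-likelihoods share a common scale. Per-iteration RNG substreams are
#' derived deterministically from `(seed, iteration)`, so runs are
#' bit-reproducible.
#'
#' @param s_plus,s_minus Samples tibbles (see
#'   [extract_positive_samples()]) with the positive-criterion and
#'   negative-criterion samples.
#' @param n_iterations Number of hold-out iterations (study default 12500).
#' @param train_fraction Fraction of `s_plus` used for training
#'   (default 0.75).
#' @param n_states Hidden states of each fitted HMM (default 3).
#' @param seed Master seed.
#' @param channels Optional channel subset to project onto first.
#' @param max_iter,tol EM stopping rule passed to [hmm_fit()].
#' @return A tibble of scored samples: `iteration`, `sample_ref`, `score`,
#'   `truth`.
#' @export
run_iterated <- function(s_plus, s_minus, n_iterations = 12500,
                         train_fraction = 0.75, n_states = 3, seed = 1,
                         channels = NULL, max_iter = 100, tol = 1e-4) {
  if (!is.null(channels)) {
    s_plus <- project_channels(s_plus, channels)
    s_minus <- project_channels(s_minus, channels)
  }
  pos <- s_plus$signal
  neg <- s_minus$signal
  n_pos <- length(pos)
  if (n_pos < 4) {
    abort(sprintf(
      "Insufficient positive samples for subject %s: %d (need at least 4).",
      s_plus$subject_id[1] %||% "?", n_pos))
  }
  n_train <- max(2L, floor(train_fraction * n_pos))
  if (n_train >= n_pos) n_train <- n_pos - 1L
  neg_refs <- paste0("neg_", seq_along(neg))

  out <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    it_seed <- iter_seed(seed, it)
    train_idx <- with_seed(it_seed, sample.int(n_pos, n_train))
    test_idx <- setdiff(seq_len(n_pos), train_idx)
    model <- hmm_fit(pos[train_idx], n_states = n_states, seed = it_seed,
                     max_iter = max_iter, tol = tol)
    scores_pos <- vapply(pos[test_idx], function(m) hmm_loglik(model, m),
                         numeric(1))
    scores_neg <- vapply(neg, function(m) hmm_loglik(model, m), numeric(1))
    out[[it]] <- tibble::tibble(
      iteration = it,
      sample_ref = c(paste0("pos_", test_idx), neg_refs),
      score = c(scores_pos, scores_neg),
      truth = c(rep(TRUE, length(test_idx)), rep(FALSE, length(neg)))
    )
  }
  dplyr::bind_rows(out)
}

# deterministic 32-bit substream seed from (seed, iteration)
iter_seed <- function(seed, iteration) {
  as.integer((as.numeric(seed) * 48271 + iteration * 9973) %% 2147483647L)
}

split_by_class <- function(samples, subject) {
  subj <- samples[samples$subject_id == subject, , drop = FALSE]
  if (nrow(subj) == 0) abort(sprintf("Unknown subject: %s", subject))
  list(pos = subj[subj$klass == "concentrated", , drop = FALSE],
       neg = subj[subj$klass == "non_concentrated", , drop = FALSE])
}

#' Experiment 1: intra-subject concentration detection
#'
#' Criterion: is the window labelled as concentrated? `S+` holds all of the
#' subject's concentrated windows, `S-` all their non-concentrated windows.
#' An HMM is repeatedly trained on 75% of `S+` and held-out positives plus
#' all negatives are scored; the pooled scores form one ROC.
#'
#' @param samples Samples tibble covering the whole cohort.
#' @param subject Subject id.
#' @inheritParams run_iterated
#' @return A `conc_roc`.
#' @export
experiment_intra_detection <- function(samples, subject, n_iterations = 12500,
                                       n_states = 3, seed = 1,
                                       train_fraction = 0.75, channels = NULL,
                                       max_iter = 100, tol = 1e-4) {
  sp <- split_by_class(samples, subject)
  if (nrow(sp$neg) == 0) {
    abort(sprintf("Subject %s has no non-concentrated samples.", subject))
  }
  scored <- run_iterated(sp$pos, sp$neg, n_iterations = n_iterations,
                         train_fraction = train_fraction, n_states = n_states,
                         seed = seed, channels = channels,
                         max_iter = max_iter, tol = tol)
  pooled_roc(scored)
}

#' Experiment 2: subject identification from concentrated windows
#'
#' Criterion: does the concentrated window belong to the target subject?
#' `S+` holds the target's concentrated windows; `S-` holds the concentrated
#' windows of every other subject. Same iterated scheme as experiment 1.
#'
#' @inheritParams experiment_intra_detection
#' @return A `conc_roc`.
#' @export
experiment_subject_id <- function(samples, subject, n_iterations = 12500,
                                  n_states = 3, seed = 1,
                                  train_fraction = 0.75, channels = NULL,
                                  max_iter = 100, tol = 1e-4) {
  if (length(unique(samples$subject_id)) < 2) {
    abort("Subject identification needs at least 2 subjects.")
  }
  pos <- samples[samples$subject_id == subject &
                   samples$klass == "concentrated", , drop = FALSE]
  neg <- samples[samples$subject_id != subject &
                   samples$klass == "concentrated", , drop = FALSE]
  if (nrow(pos) == 0) abort(sprintf("Unknown subject: %s", subject))
  scored <- run_iterated(pos, neg, n_iterations = n_iterations,
                         train_fraction = train_fraction, n_states = n_states,
                         seed = seed, channels = channels,
                         max_iter = max_iter, tol = tol)
  pooled_roc(scored)
}

#' Experiment 3: inter-subject concentration detection
#'
#' Tests whether a model built without the target subject's data can detect
#' their concentration. In the default direction (`"train_others"`) a single
#' HMM is fitted on the pooled concentrated windows of all other subjects
#' and scores the target's concentrated (truth `TRUE`) and non-concentrated
#' (truth `FALSE`) windows. The alternative direction (`"train_target"`)
#' trains on all of the target's concentrated windows and scores every other
#' subject's windows. Either way there is a single fit, no iteration loop.
#'
#' @inheritParams experiment_intra_detection
#' @param direction `"train_others"` (default) or `"train_target"`.
#' @return A `conc_roc`.
#' @export
experiment_inter_subject <- function(samples, subject, n_states = 3,
                                     seed = 1, channels = NULL,
                                     direction = c("train_others",
                                                   "train_target"),
                                     max_iter = 100, tol = 1e-4) {
  direction <- match.arg(direction)
  if (length(unique(samples$subject_id)) < 2) {
    abort("Inter-subject evaluation needs at least 2 subjects.")
  }
  if (!subject %in% samples$subject_id) {
    abort(sprintf("Unknown subject: %s", subject))
  }
  if (!is.null(channels)) samples <- project_channels(samples, channels)
  if (direction == "train_others") {
    train <- samples[samples$subject_id != subject &
                       samples$klass == "concentrated", , drop = FALSE]
    test <- samples[samples$subject_id == subject, , drop = FALSE]
  } else {
    train <- samples[samples$subject_id == subject &
                       samples$klass == "concentrated", , drop = FALSE]
    test <- samples[samples$subject_id != subject, , drop = FALSE]
  }
  model <- hmm_fit(train$signal, n_states = n_states, seed = seed,
                   max_iter = max_iter, tol = tol)
  scored <- tibble::tibble(
    iteration = 0L,
    sample_ref = paste0(test$klass, "_", seq_len(nrow(test))),
    score = vapply(test$signal, function(m) hmm_loglik(model, m), numeric(1)),
    truth = test$klass == "concentrated"
  )
  pooled_roc(scored)
}

#' Sensor-fusion sweep over channel subsets
#'
#' Runs the chosen intra-subject experiment for every nonempty subset of the
#' available channels (all `2^M - 1 = 15` of them with the full four-signal
#' set), per subject, by projecting the samples onto each subset. Subsets
#' are enumerated deterministically by size then canonical channel order.
#' The inter-subject experiment is excluded from the sweep by design.
#'
#' @inheritParams experiment_intra_detection
#' @param experiment `"intra_detection"` or `"subject_id"`.
#' @param channels Channels to sweep (default all four).
#' @return A long tibble: `subset_id`, `size`, `label`, `subject_id`,
#'   `auc`, `eer`.
#' @export
fusion_sweep <- function(samples, experiment = c("intra_detection",
                                                 "subject_id"),
                         channels = .channels, n_iterations = 12500,
                         n_states = 3, seed = 1, train_fraction = 0.75,
                         max_iter = 100, tol = 1e-4) {
  experiment <- tryCatch(match.arg(experiment), error = function(e) {
    abort("The fusion sweep supports only the intra-subject experiments (intra_detection, subject_id).")
  })
  subsets <- channel_subsets(channels)
  subjects <- unique(samples$subject_id)
  fn <- switch(experiment,
               intra_detection = experiment_intra_detection,
               subject_id = experiment_subject_id)
  rows <- list()
  for (i in seq_len(nrow(subsets))) {
    for (subj in subjects) {
      roc <- fn(samples, subj, n_iterations = n_iterations,
                n_states = n_states, seed = seed + subsets$subset_id[i],
                train_fraction = train_fraction,
                channels = subsets$channels[[i]],
                max_iter = max_iter, tol = tol)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subset_id = subsets$subset_id[i], size = subsets$size[i],
        label = subsets$label[i], subject_id = subj,
        auc = roc$auc, eer = roc$eer
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Tabulate per-subject experiment results
#'
#' Lays out experiment results the way the study reports them: one row per
#' subject with AUC and EER columns plus an `Average` row
#' (`report_experiments()`), and for the fusion sweep one row per channel
#' subset with four indicator columns, per-subject AUC/EER and averages
#' (`report_fusion()`). Values are rounded to 2 decimals; pass the result of
#' these functions to [readr::write_csv()] (or use [pipeline_run()]) to get
#' the CSV files, with full-precision companions written alongside.
#'
#' @param results A tibble with columns `subject_id`, `auc`, `eer` (and
#'   `experiment` if several are stacked).
#' @param digits Rounding for the display table (default 2; `NULL` keeps
#'   full precision).
#' @return A tibble in the report layout.
#' @export
report_experiments <- function(results, digits = 2) {
  if (nrow(results) == 0) abort("No results to report.")
  grp <- if ("experiment" %in% names(results)) c("experiment") else character()
  avg <- dplyr::summarise(
    dplyr::group_by(results, dplyr::across(dplyr::all_of(grp))),
    subject_id = "Average", auc = mean(.data$auc), eer = mean(.data$eer),
    .groups = "drop"
  )
  out <- dplyr::bind_rows(
    results[, c(grp, "subject_id", "auc", "eer")], avg)
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, auc = round(.data$auc, digits),
                         eer = round(.data$eer, digits))
  }
  out
}

#' @rdname report_experiments
#' @param sweep A long fusion-sweep tibble from [fusion_sweep()].
#' @export
report_fusion <- function(sweep, digits = 2) {
  if (nrow(sweep) == 0) abort("No results to report.")
  present <- .channels[.channels %in% unlist(strsplit(sweep$label, "+",
                                                      fixed = TRUE))]
  wide <- tidyr::pivot_wider(
    sweep, id_cols = c("subset_id", "size", "label"),
    names_from = "subject_id", values_from = c("auc", "eer"),
    names_glue = "{.value}_{subject_id}"
  )
  for (ch in rev(present)) {
    wide <- dplyr::mutate(
      wide,
      !!tolower(ch) := as.integer(purrr::map_lgl(
        strsplit(.data$label, "+", fixed = TRUE), ~ ch %in% .x)),
      .after = "label"
    )
  }
  avg <- dplyr::summarise(dplyr::group_by(sweep, .data$subset_id),
                          auc_avg = mean(.data$auc), eer_avg = mean(.data$eer),
                          .groups = "drop")
  out <- dplyr::arrange(dplyr::left_join(wide, avg, by = "subset_id"),
                        .data$subset_id)
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::starts_with(c("auc", "eer")), ~ round(.x, digits)))
  }
  out
}
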