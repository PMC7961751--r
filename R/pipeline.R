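#' Read a directory of session recordings and labels
#'
#' Expects the layout written by [write_cohort()] /
#' [pipeline_simulate()]: paired `<stem>_recording.csv` and
#' `<stem>_labels.csv` files.
#'
#' @param dir Directory with session CSVs.
#' @return A sessions tibble (`subject_id`, `session_id`, `recording`,
#'   `events`) usable by [extract_cohort_samples()].
#' @export
read_cohort <- function(dir) {
  rec_files <- sort(list.files(dir, pattern = "_recording\\.csv$",
                               full.names = TRUE))
  if (length(rec_files) == 0) {
    abort(sprintf("No *_recording.csv files found in %s", dir))
  }
  rows <- lapply(rec_files, function(rf) {
    lf <- sub("_recording\\.csv$", "_labels.csv", rf)
    if (!file.exists(lf)) abort(sprintf("Missing label file: %s", lf))
    rec <- read_recording(rf)
    tibble::tibble(subject_id = rec_subject(rec),
                   session_id = attr(rec, "session_id"),
                   recording = list(rec), events = list(read_labels(lf)))
  })
  dplyr::bind_rows(rows)
}

#' Simulate a cohort and write it to disk
#'
#' Thin orchestration over [simulate_cohort()] and [write_cohort()].
#'
#' @param out_dir Output directory.
#' @param spec A [cohort_spec()].
#' @return The manifest path, invisibly.
#' @export
pipeline_simulate <- function(out_dir, spec = cohort_spec()) {
  cohort <- simulate_cohort(spec)
  write_cohort(cohort, out_dir)
}

write_report_pair <- function(tbl, out_dir, stem, digits = 2) {
  rounded <- dplyr::mutate(tbl, dplyr::across(dplyr::where(is.numeric),
                                              ~ round(.x, digits)))
  readr::write_csv(rounded, file.path(out_dir, paste0(stem, ".csv")))
  readr::write_csv(tbl, file.path(out_dir, paste0(stem, "_full.csv")))
  invisible(NULL)
}

#' Run the detection experiments end to end
#'
#' Filters artifacts, extracts samples, runs the chosen experiment for every
#' subject and writes the per-subject AUC/EER table (2-decimal CSV plus a
#' full-precision companion), the pooled ROC points per subject, and a JSON
#' run manifest with the configuration and seeds.
#'
#' @param input Either a directory of session CSVs (see [read_cohort()]),
#'   a `conc_cohort`, or a sessions tibble.
#' @param out_dir Output directory for result files.
#' @param experiment One of `"intra_detection"`, `"subject_id"`,
#'   `"inter_subject"`.
#' @param n_iterations Hold-out iterations (default 12500; ignored by the
#'   inter-subject experiment, which uses a single fit).
#' @param n_states,seed,train_fraction,channels Passed to the experiment.
#' @param direction Inter-subject direction (see
#'   [experiment_inter_subject()]).
#' @return The per-subject results tibble, invisibly.
#' @export
pipeline_run <- function(input, out_dir,
                         experiment = c("intra_detection", "subject_id",
                                        "inter_subject"),
                         n_iterations = 12500, n_states = 3, seed = 1,
                         train_fraction = 0.75, channels = NULL,
                         direction = "train_others") {
  experiment <- match.arg(experiment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- gather_samples(input)
  log_sample_counts(samples)
  subjects <- sort(unique(samples$subject_id))
  rows <- list()
  for (subj in subjects) {
    roc <- switch(
      experiment,
      intra_detection = experiment_intra_detection(
        samples, subj, n_iterations = n_iterations, n_states = n_states,
        seed = seed, train_fraction = train_fraction, channels = channels),
      subject_id = experiment_subject_id(
        samples, subj, n_iterations = n_iterations, n_states = n_states,
        seed = seed, train_fraction = train_fraction, channels = channels),
      inter_subject = experiment_inter_subject(
        samples, subj, n_states = n_states, seed = seed,
        channels = channels, direction = direction)
    )
    readr::write_csv(roc$points,
                     file.path(out_dir, sprintf("roc_%s_%s.csv",
                                                experiment, subj)))
    rows[[length(rows) + 1L]] <- dplyr::mutate(glance(roc),
                                               subject_id = subj,
                                               .before = 1)
  }
  results <- dplyr::bind_rows(rows)
  write_report_pair(report_experiments(results, digits = NULL), out_dir,
                    paste0("results_", experiment))
  write_manifest(out_dir, list(
    experiment = experiment, n_iterations = n_iterations,
    n_states = n_states, seed = seed, train_fraction = train_fraction,
    channels = channels %||% .channels, direction = direction,
    subjects = subjects,
    n_samples = nrow(samples)
  ))
  invisible(results)
}

#' Run the sensor-fusion sweep end to end
#'
#' @inheritParams pipeline_run
#' @param experiment `"intra_detection"` or `"subject_id"`.
#' @param channels Channels to sweep (default all four).
#' @return The wide fusion report tibble, invisibly.
#' @export
pipeline_sweep <- function(input, out_dir,
                           experiment = c("intra_detection", "subject_id"),
                           channels = .channels, n_iterations = 12500,
                           n_states = 3, seed = 1, train_fraction = 0.75) {
  experiment <- match.arg(experiment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- gather_samples(input)
  log_sample_counts(samples)
  sweep <- fusion_sweep(samples, experiment = experiment,
                        channels = channels, n_iterations = n_iterations,
                        n_states = n_states, seed = seed,
                        train_fraction = train_fraction)
  wide <- report_fusion(sweep, digits = NULL)
  write_report_pair(wide, out_dir, paste0("fusion_", experiment))
  write_manifest(out_dir, list(
    experiment = experiment, n_iterations = n_iterations,
    n_states = n_states, seed = seed, train_fraction = train_fraction,
    channels = channels, n_subsets = length(unique(sweep$subset_id))
  ))
  invisible(wide)
}

gather_samples <- function(input) {
  if (is.character(input)) {
    extract_cohort_samples(read_cohort(input))
  } else if (inherits(input, "conc_cohort") ||
             (is.data.frame(input) && "recording" %in% names(input))) {
    extract_cohort_samples(input)
  } else if (is.data.frame(input) && "signal" %in% names(input)) {
    input
  } else {
    abort("`input` must be a directory, a cohort, sessions or samples.")
  }
}

log_sample_counts <- function(samples) {
  counts <- dplyr::count(samples, .data$subject_id, .data$klass)
  msg <- paste(sprintf("%s/%s: %d", counts$subject_id, counts$klass,
                       counts$n), collapse = ", ")
  message("sample counts: ", msg)
}

write_manifest <- function(out_dir, config) {
  manifest <- list(
    package = "concdetect",
    version = as.character(utils::packageVersion("concdetect")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(NULL)
}
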