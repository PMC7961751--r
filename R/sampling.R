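#' Extract concentrated (positive) sample windows
#'
#' Concentration is assumed on a 6 s frame around each expert-labelled peak:
#' the window spans the 3 s before and after the peak. The peak time is
#' snapped to the nearest frame and the window is half-open in frame space,
#' `[t - 3, t + 3)`, so a window holds exactly
#' `round(2 * half_window_s * rate)` frames per channel — the 4 x 60 matrix
#' at the defaults. Windows that fall outside the recording or touch an
#' invalidated artifact span are skipped (and reported via the
#' `n_skipped` attribute).
#'
#' @param rec An artifact-filtered `conc_recording`.
#' @param events Label events (tibble with `time_s`, `state`); only
#'   `"concentration"` events are used.
#' @param half_window_s Half window length in seconds (default 3).
#' @return A samples tibble: `subject_id`, `session_id`, `klass`,
#'   `origin_time_s`, `channels` (list), `signal` (list of channels x frames
#'   matrices).
#' @export
extract_positive_samples <- function(rec, events, half_window_s = 3) {
  rate <- rec_rate(rec)
  half <- round(half_window_s * rate)
  n <- nrow(rec)
  mat <- recording_matrix(rec)
  events <- events[events$state == "concentration", , drop = FALSE]
  out <- list()
  skipped <- 0L
  for (t in sort(events$time_s)) {
    p <- round(t * rate)                   # 0-based frame of the peak
    first <- p - half + 1L                 # 1-based window start
    last <- p + half                       # 1-based window end (inclusive)
    if (first < 1 || last > n || window_has_invalid(mat, first, last)) {
      skipped <- skipped + 1L
      next
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      subject_id = rec_subject(rec),
      session_id = attr(rec, "session_id"),
      klass = "concentrated",
      origin_time_s = t,
      channels = list(rec_channels(rec)),
      signal = list(mat[, first:last, drop = FALSE])
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) res <- empty_samples()
  attr(res, "n_skipped") <- skipped
  res
}

empty_samples <- function() {
  tibble::tibble(subject_id = character(), session_id = character(),
                 klass = character(), origin_time_s = double(),
                 channels = list(), signal = list())
}

recording_matrix <- function(rec) {
  m <- t(as.matrix(tibble::as_tibble(rec)[, .channel_cols[rec_channels(rec)]]))
  rownames(m) <- rec_channels(rec)
  m
}

window_has_invalid <- function(mat, first, last) {
  anyNA(mat[, first:last, drop = FALSE])
}

#' Extract non-concentrated (negative) sample windows
#'
#' Negative slots are chosen greedily left-to-right over the eligible part
#' of the recording: the first `discard_head_s` seconds are discarded, every
#' point of a slot must be at least `peak_gap_s` from every concentration
#' peak, the slot must lie fully inside the recording with no invalidated
#' frames, and consecutive selected slots are separated by at least
#' `slot_gap_s`. Greedy left-to-right packing attains the maximum feasible
#' slot count for this one-dimensional packing problem.
#'
#' @inheritParams extract_positive_samples
#' @param slot_s Slot length in seconds (default 6).
#' @param peak_gap_s Minimum distance from any peak (default 120).
#' @param slot_gap_s Minimum gap between consecutive slots (default 6).
#' @param discard_head_s Leading seconds excluded from slots (default 1).
#' @return A samples tibble (see [extract_positive_samples()]) with
#'   `klass = "non_concentrated"`; `origin_time_s` is the slot start.
#' @export
extract_negative_samples <- function(rec, events, slot_s = 6,
                                     peak_gap_s = 120, slot_gap_s = 6,
                                     discard_head_s = 1) {
  rate <- rec_rate(rec)
  n <- nrow(rec)
  slot_frames <- round(slot_s * rate)
  gap_frames <- round(slot_gap_s * rate)
  mat <- recording_matrix(rec)
  peaks <- sort(events$time_s[events$state == "concentration"])
  starts <- negative_slot_starts(
    n_frames = n, rate = rate, peaks = peaks, valid = !colSums_na(mat),
    slot_frames = slot_frames, gap_frames = gap_frames,
    peak_gap_s = peak_gap_s, discard_head_s = discard_head_s
  )
  if (length(starts) == 0) return(empty_samples())
  dplyr::bind_rows(lapply(starts, function(f) tibble::tibble(
    subject_id = rec_subject(rec),
    session_id = attr(rec, "session_id"),
    klass = "non_concentrated",
    origin_time_s = (f - 1) / rate,
    channels = list(rec_channels(rec)),
    signal = list(mat[, f:(f + slot_frames - 1L), drop = FALSE])
  )))
}

colSums_na <- function(mat) colSums(is.na(mat)) > 0

# greedy left-to-right packing over 1-based start frames
negative_slot_starts <- function(n_frames, rate, peaks, valid,
                                 slot_frames, gap_frames,
                                 peak_gap_s, discard_head_s) {
  first_start <- floor(discard_head_s * rate + 1e-9) + 1L
  feasible <- slot_feasible_mask(n_frames, rate, peaks, valid, slot_frames,
                                 peak_gap_s, first_start)
  starts <- integer()
  f <- first_start
  while (f <= n_frames - slot_frames + 1L) {
    if (feasible[f]) {
      starts <- c(starts, f)
      f <- f + slot_frames + gap_frames
    } else {
      f <- f + 1L
    }
  }
  starts
}

# feasibility of a slot starting at each 1-based frame (ignoring slot gaps)
slot_feasible_mask <- function(n_frames, rate, peaks, valid, slot_frames,
                               peak_gap_s, first_start) {
  feasible <- logical(n_frames)
  last_start <- n_frames - slot_frames + 1L
  if (last_start < first_start) return(feasible)
  ok_valid <- if (all(valid)) {
    rep(TRUE, last_start)
  } else {
    csum <- cumsum(!valid)
    bad_in_slot <- csum[seq_len(last_start) + slot_frames - 1L] -
      c(0, csum)[seq_len(last_start)]
    bad_in_slot == 0
  }
  for (f in first_start:last_start) {
    if (!ok_valid[f]) next
    a <- (f - 1) / rate
    b <- a + slot_frames / rate
    ok <- all(peaks <= a - peak_gap_s | peaks >= b + peak_gap_s)
    feasible[f] <- ok
  }
  feasible
}

#' Restrict samples to a channel subset
#'
#' Keeps only the requested signal rows of every sample matrix, in the order
#' given, leaving class and origin untouched. This is the projection used by
#' the sensor-fusion sweep.
#'
#' @param samples A samples tibble.
#' @param subset Ordered character vector of channel codes.
#' @return The projected samples tibble.
#' @export
project_channels <- function(samples, subset) {
  if (length(subset) == 0) abort("`subset` must name at least one channel.")
  dplyr::mutate(
    samples,
    signal = purrr::map2(.data$signal, .data$channels, function(m, ch) {
      bad <- setdiff(subset, ch)
      if (length(bad) > 0) {
        abort(sprintf("Unknown channel(s): %s", paste(bad, collapse = ", ")))
      }
      m[match(subset, ch), , drop = FALSE]
    }),
    channels = purrr::map(.data$channels, function(ch) subset)
  )
}

#' Serialise samples to a directory of CSV matrices
#'
#' Writes one CSV per sample (frames in columns, channels in rows) plus a
#' `manifest.csv` with columns
#' `subject_id,session_id,klass,origin_time_s,channels,path`.
#'
#' @param samples A samples tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    paths[i] <- sprintf("sample_%04d.csv", i)
    m <- samples$signal[[i]]
    df <- tibble::as_tibble(as.data.frame(t(m)))
    names(df) <- samples$channels[[i]]
    readr::write_csv(df, file.path(dir, paths[i]))
  }
  manifest <- dplyr::mutate(
    dplyr::select(samples, -"signal"),
    channels = vapply(.data$channels, paste, character(1), collapse = "+"),
    path = paths
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' @rdname write_samples
#' @export
read_samples <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  sig <- vector("list", nrow(manifest))
  chans <- strsplit(manifest$channels, "+", fixed = TRUE)
  for (i in seq_len(nrow(manifest))) {
    df <- readr::read_csv(file.path(dir, manifest$path[i]),
                          show_col_types = FALSE, progress = FALSE)
    m <- t(as.matrix(df[, chans[[i]], drop = FALSE]))
    rownames(m) <- chans[[i]]
    sig[[i]] <- m
  }
  dplyr::mutate(dplyr::select(manifest, -"path"),
                channels = chans, signal = sig)
}
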