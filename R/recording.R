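#' Build a multichannel physiological recording
#'
#' A recording is a tibble with a `time_s` column and one column per channel
#' (`hr_bpm`, `br_bcpm`, `sc_us`, `st_c`), carrying the subject/session
#' identity and sampling rate as attributes. Frame `k` (1-based) corresponds
#' to time `start_time_s + (k - 1) / rate_hz`; all windows downstream are
#' half-open in frame space, which makes a 6 s window exactly 60 frames at
#' the 10 Hz capture rate.
#'
#' @param data Data frame with `time_s` and the channel columns.
#' @param subject_id,session_id Identifiers.
#' @param rate_hz Sampling rate in Hz (default 10).
#' @param channels Channel codes present (default: inferred from columns).
#' @return A `conc_recording` tibble.
#' @export
new_recording <- function(data, subject_id = "s1", session_id = "sess1",
                          rate_hz = 10, channels = NULL) {
  data <- tibble::as_tibble(data)
  if (!"time_s" %in% names(data)) abort("Recording needs a `time_s` column.")
  present <- .channels[.channel_cols %in% names(data)]
  if (is.null(channels)) channels <- present
  check_channels(channels)
  missing <- setdiff(.channel_cols[channels], names(data))
  if (length(missing) > 0) {
    abort(sprintf("Recording is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 1) abort("Recording must contain at least one frame.")
  if (!is.numeric(rate_hz) || rate_hz <= 0) abort("`rate_hz` must be positive.")
  data <- data[, c("time_s", unname(.channel_cols[channels]))]
  structure(
    data,
    class = c("conc_recording", class(tibble::tibble())),
    subject_id = subject_id,
    session_id = session_id,
    rate_hz = rate_hz,
    channels = channels,
    invalid_spans = empty_spans()
  )
}

empty_spans <- function() {
  tibble::tibble(channel = character(), start_frame = integer(),
                 end_frame = integer())
}

#' @export
print.conc_recording <- function(x, ...) {
  cat(sprintf("<recording> subject=%s session=%s rate=%g Hz frames=%d (%.1f s)\n",
              attr(x, "subject_id"), attr(x, "session_id"),
              attr(x, "rate_hz"), nrow(x), nrow(x) / attr(x, "rate_hz")))
  NextMethod()
}

#' Recording metadata accessors
#'
#' @param rec A `conc_recording`.
#' @return `rec_rate()` the sampling rate in Hz, `rec_subject()` the subject
#'   id, `rec_channels()` the channel codes, `rec_duration()` the length in
#'   seconds, `rec_invalid_spans()` the artifact spans flagged by
#'   [filter_artifacts()].
#' @export
rec_rate <- function(rec) attr(rec, "rate_hz")

#' @rdname rec_rate
#' @export
rec_subject <- function(rec) attr(rec, "subject_id")

#' @rdname rec_rate
#' @export
rec_channels <- function(rec) attr(rec, "channels")

#' @rdname rec_rate
#' @export
rec_duration <- function(rec) nrow(rec) / attr(rec, "rate_hz")

#' @rdname rec_rate
#' @export
rec_invalid_spans <- function(rec) {
  sp <- attr(rec, "invalid_spans")
  if (is.null(sp)) empty_spans() else sp
}

#' Read a recording from its CSV dialect
#'
#' The canonical on-disk format is a UTF-8 CSV with header
#' `time_s,hr_bpm,br_bcpm,sc_us,st_c`, one row per 10 Hz frame, and optional
#' leading comment lines `# key=value` carrying metadata (`subject`,
#' `session`, `rate_hz`). When no `rate_hz` metadata is present the rate is
#' inferred from the median step of the time column (relative jitter up to
#' 1e-3 is tolerated).
#'
#' @param path Path to the CSV file.
#' @param channels Channels the file must provide (default all four).
#' @return A `conc_recording`.
#' @export
read_recording <- function(path, channels = .channels) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  check_channels(channels)
  meta <- read_hash_metadata(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) abort(sprintf("Recording file is empty: %s", path))
  need <- c("time_s", unname(.channel_cols[channels]))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Recording file %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  tm <- df$time_s
  if (nrow(df) > 1 && any(diff(tm) <= 0)) {
    abort(sprintf("Non-monotone time column in %s", path))
  }
  if (!is.null(meta$rate_hz)) {
    rate <- as.numeric(meta$rate_hz)
  } else if (nrow(df) > 1) {
    steps <- diff(tm)
    step <- stats::median(steps)
    if (max(abs(steps - step)) > 1e-3 * step) {
      abort(sprintf("Irregular sampling in %s: cannot infer rate", path))
    }
    rate <- 1 / step
  } else {
    rate <- 10
  }
  new_recording(df,
                subject_id = meta$subject %||% "unknown",
                session_id = meta$session %||% "unknown",
                rate_hz = rate, channels = channels)
}

read_hash_metadata <- function(path) {
  lines <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    lines <- c(lines, ln)
  }
  kv <- list()
  for (ln in lines) {
    body <- trimws(sub("^#", "", ln))
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      kv[[key]] <- val
    }
  }
  kv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to the CSV dialect read by [read_recording()]
#'
#' @param rec A `conc_recording`.
#' @param path Output path.
#' @param digits Significant digits for the signal values (default 10, which
#'   round-trips the synthetic signals to float precision).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 10) {
  header <- c(
    sprintf("# subject=%s", rec_subject(rec)),
    sprintf("# session=%s", attr(rec, "session_id")),
    sprintf("# rate_hz=%s", format(rec_rate(rec), digits = 15))
  )
  df <- tibble::as_tibble(rec)
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::everything(), ~ formatC(.x, digits = digits, format = "g")
  ))
  writeLines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read expert label events
#'
#' Label files are CSVs with header `time_s,state,source`; each row marks the
#' instant an expert (or the synthetic generator) placed a concentration
#' peak. Events are returned sorted by time.
#'
#' @param path Path to the label CSV.
#' @return A tibble with columns `time_s`, `state`, `source`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(
                          time_s = readr::col_double(),
                          state = readr::col_character(),
                          source = readr::col_character()
                        ))
  validate_labels(df)
}

validate_labels <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("time_s", "state", "source")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Label table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) return(df[need])
  if (any(df$time_s < 0)) abort("Label events must have non-negative time_s.")
  known_states <- c("concentration")
  bad <- setdiff(unique(df$state), known_states)
  if (length(bad) > 0) {
    abort(sprintf("Unknown label state(s): %s", paste(bad, collapse = ", ")))
  }
  bad_src <- setdiff(unique(df$source), c("expert", "synthetic"))
  if (length(bad_src) > 0) {
    abort(sprintf("Unknown label source(s): %s", paste(bad_src, collapse = ", ")))
  }
  dplyr::arrange(df[need], .data$time_s)
}

#' @rdname read_labels
#' @param labels Label tibble as returned by [read_labels()].
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels, path)
  invisible(path)
}

#' Per-channel validity ranges for artifact filtering
#'
#' Defaults encode the two artifact classes flagged in the study protocol:
#' non-physical skin conductance readings (sensor-skin contact loss shows up
#' as values at or below zero) and implausibly high heart rate. Breath rate
#' and skin temperature are unconstrained by default. The numeric bounds are
#' configurable; they are implementation defaults, not measured constants.
#'
#' @param sc_min Exclusive lower bound for skin conductance (default 0).
#' @param hr_range Inclusive heart-rate validity range in BPM
#'   (default `c(25, 240)`).
#' @param br_range,st_range Optional validity ranges for breath rate and
#'   skin temperature (`NULL` = unconstrained).
#' @return A named list of `c(lower, upper)` ranges, one per constrained
#'   channel, with attribute `sc_exclusive_lower`.
#' @export
artifact_rules <- function(sc_min = 0, hr_range = c(25, 240),
                           br_range = NULL, st_range = NULL) {
  rules <- list(HR = hr_range, SC = c(sc_min, Inf),
                BR = br_range, ST = st_range)
  rules <- rules[!vapply(rules, is.null, logical(1))]
  structure(rules, sc_exclusive_lower = TRUE)
}

#' Filter sensor artifacts from a recording
#'
#' Frames violating the per-channel validity rules are handled by run length:
#' runs no longer than `max_gap_s` with valid frames on both sides are
#' linearly interpolated from the nearest valid neighbours; longer runs (and
#' runs touching the recording edge) are set to `NA` and recorded as invalid
#' spans, so that sample windows overlapping them can be rejected. Valid
#' frames pass through untouched and the frame count is preserved, which
#' makes the operation idempotent.
#'
#' @param rec A `conc_recording`.
#' @param rules Validity ranges from [artifact_rules()].
#' @param max_gap_s Longest gap (seconds) that is still interpolated
#'   (default 1).
#' @return The filtered `conc_recording`; its `artifact_report` attribute
#'   holds a tibble of per-channel interpolated/invalidated frame counts and
#'   [rec_invalid_spans()] returns the flagged spans.
#' @export
filter_artifacts <- function(rec, rules = artifact_rules(), max_gap_s = 1) {
  rate <- rec_rate(rec)
  max_gap <- floor(max_gap_s * rate + 1e-9)
  spans <- empty_spans()
  report <- tibble::tibble(channel = rec_channels(rec),
                           n_frames_interpolated = 0L,
                           n_frames_invalidated = 0L)
  for (ch in rec_channels(rec)) {
    col <- .channel_cols[[ch]]
    x <- rec[[col]]
    rng <- rules[[ch]]
    bad <- !is.finite(x)
    if (!is.null(rng)) {
      lo_excl <- ch == "SC" && isTRUE(attr(rules, "sc_exclusive_lower"))
      ok_lo <- if (lo_excl) x > rng[1] else x >= rng[1]
      bad <- bad | !(ok_lo & x <= rng[2])
    }
    if (!any(bad)) next
    if (all(bad)) {
      abort(sprintf("Channel %s is entirely invalid after artifact rules.", ch))
    }
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    n_interp <- 0L
    n_invalid <- 0L
    for (i in which(r$values)) {
      s <- starts[i]; e <- ends[i]
      interior <- s > 1 && e < length(x)
      if (interior && r$lengths[i] <= max_gap) {
        x[s:e] <- x[s - 1] + (x[e + 1] - x[s - 1]) * seq_len(e - s + 1) / (e - s + 2)
        n_interp <- n_interp + (e - s + 1L)
      } else {
        x[s:e] <- NA_real_
        n_invalid <- n_invalid + (e - s + 1L)
        spans <- dplyr::bind_rows(spans, tibble::tibble(
          channel = ch, start_frame = as.integer(s), end_frame = as.integer(e)))
      }
    }
    rec[[col]] <- x
    report$n_frames_interpolated[report$channel == ch] <- n_interp
    report$n_frames_invalidated[report$channel == ch] <- n_invalid
  }
  attr(rec, "invalid_spans") <- spans
  attr(rec, "artifact_report") <- report
  rec
}

#' @rdname filter_artifacts
#' @export
artifact_report <- function(rec) {
  rep <- attr(rec, "artifact_report")
  if (is.null(rep)) {
    tibble::tibble(channel = rec_channels(rec),
                   n_frames_interpolated = 0L, n_frames_invalidated = 0L)
  } else {
    rep
  }
}
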