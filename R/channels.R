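#' The four physiological channels
#'
#' The analysis works with four wearable-friendly signals sampled at 10 Hz:
#' heart rate (`HR`, beats per minute), breath rate (`BR`, breath cycles per
#' minute), skin conductance (`SC`, microsiemens) and skin temperature
#' (`ST`, degrees Celsius). `channel_info()` returns the registry mapping the
#' short channel codes to their CSV column names and units.
#'
#' @return A tibble with columns `channel`, `column`, `unit`.
#' @export
#' @examples
#' channel_info()
channel_info <- function() {
  tibble::tibble(
    channel = c("HR", "BR", "SC", "ST"),
    column  = c("hr_bpm", "br_bcpm", "sc_us", "st_c"),
    unit    = c("BPM", "BCPM", "uS", "degC")
  )
}

# canonical channel order used everywhere (fusion subsets, matrices, CSVs)
.channels <- c("HR", "BR", "SC", "ST")
.channel_cols <- c(HR = "hr_bpm", BR = "br_bcpm", SC = "sc_us", ST = "st_c")

check_channels <- function(channels, allowed = .channels, arg = "channels") {
  if (length(channels) == 0) {
    abort(sprintf("`%s` must name at least one channel.", arg))
  }
  bad <- setdiff(channels, allowed)
  if (length(bad) > 0) {
    abort(sprintf("Unknown channel(s) in `%s`: %s", arg,
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(channels)) {
    abort(sprintf("`%s` contains duplicated channels.", arg))
  }
  invisible(channels)
}

#' Enumerate nonempty channel subsets for the fusion sweep
#'
#' Lists all `2^M - 1` nonempty subsets of the given channels in a
#' deterministic order: by subset size, then by canonical channel order
#' (HR, BR, SC, ST). With all four channels this yields the 15 combinations
#' swept in the sensor-fusion experiments.
#'
#' @param channels Character vector of channel codes (default all four).
#' @return A tibble with one row per subset: `subset_id`, `size`,
#'   `label` (e.g. `"HR+ST"`), and a list-column `channels`.
#' @export
#' @examples
#' channel_subsets()            # 15 rows
#' channel_subsets(c("HR","ST"))  # 3 rows
channel_subsets <- function(channels = .channels) {
  check_channels(channels)
  channels <- .channels[.channels %in% channels]
  m <- length(channels)
  subsets <- unlist(
    lapply(seq_len(m), function(k) utils::combn(channels, k, simplify = FALSE)),
    recursive = FALSE
  )
  tibble::tibble(
    subset_id = seq_along(subsets),
    size = lengths(subsets),
    label = vapply(subsets, paste, character(1), collapse = "+"),
    channels = subsets
  )
}
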