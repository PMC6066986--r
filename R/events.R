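#' Write a run schedule as a BIDS-style events table
#'
#' Tab-separated, columns `onset` (s), `duration` (s), `trial_type`,
#' `music_track`; onsets are 0-based from the first non-dummy volume and
#' strictly increasing. Missing music tracks (neutral blocks) are written as
#' `n/a`. Output is byte-deterministic for a given schedule.
#'
#' @param schedule an `nfb_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "nfb_schedule"))
  b <- schedule$blocks
  lines <- c(
    "onset\tduration\ttrial_type\tmusic_track",
    sprintf("%.1f\t%.1f\t%s\t%s", b$onset_s, b$duration_s, b$condition,
            ifelse(is.na(b$music_track), "n/a", b$music_track))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an events table written by [write_events()]
#'
#' @param path events TSV path.
#' @return Data frame with columns `onset`, `duration`, `trial_type`,
#'   `music_track` (`NA` where the file holds `n/a`).
#' @export
read_events <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("numeric", "numeric",
                                          "character", "character"))
  tbl$music_track[tbl$music_track == "n/a"] <- NA_character_
  tbl
}

#' Rebuild an `nfb_schedule` from an events table
#'
#' Inverse of [write_events()] given the acquisition parameters that the
#' events file does not carry.
#'
#' @param events data frame as returned by [read_events()].
#' @inheritParams build_run_schedule
#' @return An `nfb_schedule`.
#' @export
schedule_from_events <- function(events, method = c("ROI", "SVM"),
                                 run_index = 1L, tr_s = 2, n_dummy = 5L) {
  method <- match.arg(method)
  stopifnot(all(diff(events$onset) > 0))
  total_s <- sum(events$duration)
  structure(list(
    blocks = data.frame(
      block = seq_len(nrow(events)),
      condition = events$trial_type,
      onset_s = events$onset,
      duration_s = events$duration,
      music_track = events$music_track,
      stringsAsFactors = FALSE
    ),
    tr_s = tr_s, n_dummy = as.integer(n_dummy),
    n_volumes = as.integer(total_s / tr_s),
    run_index = as.integer(run_index), method = method
  ), class = "nfb_schedule")
}
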