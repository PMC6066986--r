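#' Block-design scheduling for neurofeedback sessions
#'
#' A session comprises four runs (one training run followed by three
#' neurofeedback runs), each built from 16 blocks: 8 neutral blocks of 30 s
#' and 4 + 4 emotion blocks (tenderness, anguish) of 46 s, for 608 s = 304
#' volumes at TR = 2 s. The ROI method alternates the two emotions
#' (`N,E1,N,E2` repeated four times); the SVM method groups each emotion's
#' four blocks consecutively (`N,E1` four times, then `N,E2` four times).
#' Every emotion block is preceded by a neutral block, which the feedback
#' baselines require.
#'
#' @name schedule
NULL

.CONDITIONS <- c("neutral", "tenderness", "anguish")
.EMOTIONS <- c("tenderness", "anguish")
.BLOCK_DURATION <- c(neutral = 30, tenderness = 46, anguish = 46)

.other_emotion <- function(emotion) setdiff(.EMOTIONS, emotion)

#' Build one run's block schedule
#'
#' @param method `"ROI"` (emotions alternate) or `"SVM"` (each emotion's
#'   blocks are grouped consecutively).
#' @param start_emotion first emotion of the session, `"tenderness"` or
#'   `"anguish"`. The leading emotion alternates across runs 1--4 so block
#'   order is counterbalanced within the session.
#' @param run_index run number, 1 (training) to 4.
#' @param tr_s repetition time in seconds.
#' @param n_dummy leading dummy volumes discarded before the task starts;
#'   they are not counted in `n_volumes`.
#' @return An object of class `nfb_schedule`: a list with a `blocks` data
#'   frame (`block`, `condition`, `onset_s`, `duration_s`, `music_track`),
#'   plus `tr_s`, `n_dummy`, `n_volumes`, `run_index`, `method`.
#' @examples
#' sched <- build_run_schedule("ROI", "tenderness", 1)
#' sched$n_volumes  # 304
#' @export
build_run_schedule <- function(method = c("ROI", "SVM"),
                               start_emotion = c("tenderness", "anguish"),
                               run_index = 1L, tr_s = 2, n_dummy = 5L) {
  method <- match.arg(method)
  start_emotion <- match.arg(start_emotion)
  stopifnot(tr_s > 0, run_index %in% 1:4, n_dummy >= 0)

  # counterbalance: the leading emotion alternates over runs 1-4
  e1 <- if (run_index %% 2 == 1) start_emotion else .other_emotion(start_emotion)
  e2 <- .other_emotion(e1)

  conditions <- if (method == "ROI") {
    rep(c("neutral", e1, "neutral", e2), 4)
  } else {
    c(rep(c("neutral", e1), 4), rep(c("neutral", e2), 4))
  }
  durations <- unname(.BLOCK_DURATION[conditions])
  onsets <- cumsum(c(0, durations[-length(durations)]))

  total_s <- sum(durations)
  if (total_s %% tr_s != 0) {
    stop("block durations (", total_s, " s) are not a whole number of TRs")
  }

  structure(list(
    blocks = data.frame(
      block = seq_along(conditions),
      condition = conditions,
      onset_s = onsets,
      duration_s = durations,
      music_track = NA_character_,
      stringsAsFactors = FALSE
    ),
    tr_s = tr_s,
    n_dummy = as.integer(n_dummy),
    n_volumes = as.integer(total_s / tr_s),
    run_index = as.integer(run_index),
    method = method
  ), class = "nfb_schedule")
}

#' Build a full four-run session design
#'
#' Run 1 is the training run; runs 2--4 deliver feedback. All runs share the
#' method and TR; the leading emotion alternates across runs.
#'
#' @inheritParams build_run_schedule
#' @param track_pool named list with `tenderness` and `anguish` character
#'   vectors of music-track identifiers (at least 4 each); passed to
#'   [assign_music()].
#' @return An object of class `nfb_design`: list with `method`,
#'   `start_emotion`, `tr_s`, `n_dummy` and `runs` (list of 4
#'   `nfb_schedule`).
#' @export
build_session_design <- function(method = c("ROI", "SVM"),
                                 start_emotion = c("tenderness", "anguish"),
                                 tr_s = 2, n_dummy = 5L,
                                 track_pool = default_track_pool()) {
  method <- match.arg(method)
  start_emotion <- match.arg(start_emotion)
  runs <- lapply(1:4, function(r) {
    assign_music(build_run_schedule(method, start_emotion, r, tr_s, n_dummy),
                 track_pool)
  })
  structure(list(
    method = method, start_emotion = start_emotion,
    tr_s = tr_s, n_dummy = as.integer(n_dummy), runs = runs
  ), class = "nfb_design")
}

#' Default music-track pool
#'
#' Four excerpt identifiers per emotion, matching the four emotion blocks of
#' each run; neutral blocks carry no music.
#' @return Named list of character vectors.
#' @export
default_track_pool <- function() {
  list(
    tenderness = sprintf("tenderness_%02d", 1:4),
    anguish = sprintf("anguish_%02d", 1:4)
  )
}

#' Assign music tracks to the emotion blocks of a run
#'
#' Each of the four blocks of an emotion receives a distinct track from the
#' pool, in block order; neutral blocks receive none.
#'
#' @param schedule an `nfb_schedule`.
#' @param track_pool named list with at least 4 track ids per emotion.
#' @return The schedule with `music_track` filled in for emotion blocks.
#' @export
assign_music <- function(schedule, track_pool = default_track_pool()) {
  stopifnot(inherits(schedule, "nfb_schedule"))
  for (emo in .EMOTIONS) {
    pool <- track_pool[[emo]]
    idx <- which(schedule$blocks$condition == emo)
    if (length(pool) < length(idx)) {
      stop("track pool for '", emo, "' has ", length(pool),
           " tracks; need at least ", length(idx))
    }
    schedule$blocks$music_track[idx] <- pool[seq_along(idx)]
  }
  schedule
}

#' Label each volume of a run with its block condition
#'
#' Volume `i` (1-based, counted from the first non-dummy volume) is labeled
#' with the condition of the block containing time `(i - 1 - shift) * tr_s`.
#' The shift aligns labels with the delayed hemodynamic response; the first
#' `shift_volumes` volumes fall before the shifted run start and are labeled
#' `"discard"`.
#'
#' @param schedule an `nfb_schedule`.
#' @param shift_volumes hemodynamic label shift in volumes (0--5); default 2
#'   volumes = 4 s at TR 2 s, the conventional BOLD lag.
#' @return Character vector of length `n_volumes` with values in
#'   `c("discard", "neutral", "tenderness", "anguish")`.
#' @export
label_volumes <- function(schedule, shift_volumes = 2L) {
  stopifnot(inherits(schedule, "nfb_schedule"),
            shift_volumes >= 0, shift_volumes <= 5)
  n <- schedule$n_volumes
  tr <- schedule$tr_s
  ends <- schedule$blocks$onset_s + schedule$blocks$duration_s
  labels <- character(n)
  for (i in seq_len(n)) {
    t <- (i - 1 - shift_volumes) * tr
    if (t < 0) {
      labels[i] <- "discard"
    } else {
      labels[i] <- schedule$blocks$condition[which(t < ends)[1]]
    }
  }
  labels
}

#' Per-volume block index, under the same shift convention as labels
#' @noRd
.block_of_volume <- function(schedule, shift_volumes = 2L) {
  n <- schedule$n_volumes
  tr <- schedule$tr_s
  ends <- schedule$blocks$onset_s + schedule$blocks$duration_s
  vapply(seq_len(n), function(i) {
    t <- (i - 1 - shift_volumes) * tr
    if (t < 0) NA_integer_ else which(t < ends)[1]
  }, integer(1))
}

#' @export
print.nfb_schedule <- function(x, ...) {
  cat(sprintf("<nfb_schedule> %s run %d: %d blocks, %d volumes @ TR %g s (+%d dummy)\n",
              x$method, x$run_index, nrow(x$blocks), x$n_volumes, x$tr_s,
              x$n_dummy))
  cat(paste(substr(x$blocks$condition, 1, 1), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.nfb_design <- function(x, ...) {
  cat(sprintf("<nfb_design> %s session starting with %s: 4 runs, %d volumes total\n",
              x$method, x$start_emotion,
              sum(vapply(x$runs, function(r) r$n_volumes, integer(1)))))
  invisible(x)
}
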