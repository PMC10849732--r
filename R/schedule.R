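#' Stimulus schedules for tilt-in-place imaging
#'
#' A `tilt_schedule` describes the timed sequence of pitch-tilt stimulus
#' segments delivered during one 65-second imaging epoch, together with the
#' imaging frame rate. Two schedules are supported:
#'
#' \describe{
#'   \item{tonic}{horizontal baseline (5 s at 0 degrees), nose-down tilt
#'     (15 s at -19), horizontal (15 s), nose-up tilt (15 s at +19),
#'     horizontal (15 s). Responses are read out in the first second of each
#'     restoration to horizontal.}
#'   \item{impulse}{horizontal baseline (20 s), a 10-ms impulse (4 ms eccentric
#'     rotation, 2 ms hold, 4 ms restoration), horizontal (30 s), a second
#'     10-ms impulse, horizontal (15 s).}
#' }
#'
#' @param frame_rate imaging rate in frames per second (default 3).
#' @return an object of class `tilt_schedule`: a list with `type`, `segments`
#'   (data.frame of `label`, `duration_s`, `angle_deg`), `frame_rate`, and
#'   `n_frames = round(total duration * frame_rate)`.
#' @examples
#' sch <- tonic_schedule()
#' sch$n_frames   # 195 frames at 3 frames/s over 65 s
#' @export
tonic_schedule <- function(frame_rate = 3) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  segments <- data.frame(
    label      = c("baseline", "nose_down_tilt", "horizontal",
                   "nose_up_tilt", "horizontal"),
    duration_s = c(5, 15, 15, 15, 15),
    angle_deg  = c(0, -19, 0, 19, 0),
    stringsAsFactors = FALSE
  )
  new_tilt_schedule("tonic", segments, frame_rate)
}

#' @rdname tonic_schedule
#' @export
impulse_schedule <- function(frame_rate = 3) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  segments <- data.frame(
    label      = c("baseline", "impulse", "horizontal", "impulse",
                   "horizontal"),
    duration_s = c(20, 0.01, 30, 0.01, 15 - 0.02),
    angle_deg  = c(0, NA, 0, NA, 0),
    stringsAsFactors = FALSE
  )
  new_tilt_schedule("impulse", segments, frame_rate)
}

new_tilt_schedule <- function(type, segments, frame_rate) {
  total <- sum(segments$duration_s)
  stopifnot(abs(total - 65) < 1e-6)
  structure(
    list(type = type, segments = segments, frame_rate = frame_rate,
         n_frames = as.integer(round(total * frame_rate))),
    class = "tilt_schedule"
  )
}

#' @export
print.tilt_schedule <- function(x, ...) {
  cat(sprintf("<tilt_schedule: %s, %g frames/s, %d frames over %g s>\n",
              x$type, x$frame_rate, x$n_frames, sum(x$segments$duration_s)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

# Cumulative start time (s) of each segment.
segment_onsets <- function(schedule) {
  c(0, cumsum(schedule$segments$duration_s))[seq_len(nrow(schedule$segments))]
}

# 1-based frame index of the first frame at or after time t (seconds).
frame_at <- function(t, frame_rate) as.integer(floor(t * frame_rate)) + 1L

# Frame indices covering [t0, t0 + 1 s): the response window is the first
# second of restoration, i.e. ceil(frame_rate) frames from the onset frame.
response_window_frames <- function(t0, frame_rate, n_frames) {
  start <- frame_at(t0, frame_rate)
  idx <- seq.int(start, length.out = as.integer(ceiling(frame_rate)))
  idx[idx <= n_frames]
}

# Named list of analysis windows (frame indices) for a schedule.
#
# tonic:   baseline_down = initial 5-s baseline; response_down = first 1 s of
#          the horizontal segment after the nose-down tilt; baseline_up = last
#          3 s of that same horizontal segment; response_up = first 1 s of the
#          final horizontal segment.
# impulse: baseline = the 20-s pre-impulse window; response_1/response_2 =
#          first 1 s after each impulse.
schedule_windows <- function(schedule) {
  fr <- schedule$frame_rate
  nf <- schedule$n_frames
  on <- segment_onsets(schedule)
  if (schedule$type == "tonic") {
    # segments: 1 baseline, 2 nose-down, 3 horizontal, 4 nose-up, 5 horizontal
    base_down <- seq.int(1L, frame_at(on[2], fr) - 1L)
    resp_down <- response_window_frames(on[3], fr, nf)
    horiz_end <- on[4]                      # end of post-nose-down horizontal
    base_up <- seq.int(frame_at(horiz_end - 3, fr), frame_at(horiz_end, fr) - 1L)
    resp_up <- response_window_frames(on[5], fr, nf)
    list(baseline_down = base_down, response_down = resp_down,
         baseline_up = base_up, response_up = resp_up)
  } else {
    baseline <- seq.int(1L, frame_at(on[2], fr) - 1L)
    resp1 <- response_window_frames(on[3], fr, nf)
    resp2 <- response_window_frames(on[5], fr, nf)
    list(baseline = baseline, response_1 = resp1, response_2 = resp2)
  }
}
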