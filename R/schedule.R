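#' Frame schedules
#'
#' A frame schedule records the start and end (seconds post-injection) of
#' every reconstructed time frame of a dynamic PET acquisition.  Frames must
#' be non-overlapping and ordered; gaps are permitted.
#'
#' @param frame_start,frame_end numeric vectors of frame boundaries in
#'   seconds; equal length, `frame_end > frame_start`, starts strictly
#'   increasing, `frame_start[i+1] >= frame_end[i]`.
#' @param label short text label for the schedule.
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `frame_start`, `frame_end` (seconds) and attributes `label`.
#' @examples
#' sched <- frame_schedule(c(0, 30, 60), c(30, 60, 120), "demo")
#' frame_mid_min(sched)
#' @export
frame_schedule <- function(frame_start, frame_end, label = "custom") {
  frame_start <- as.numeric(frame_start)
  frame_end <- as.numeric(frame_end)
  if (length(frame_start) != length(frame_end) || length(frame_start) == 0L)
    stop_petsime("frame_start and frame_end must be non-empty and equal length",
                 "petsime_invalid_schedule")
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end)))
    stop_petsime("frame boundaries must be finite", "petsime_invalid_schedule")
  if (any(frame_start < 0))
    stop_petsime("frame_start must be >= 0", "petsime_invalid_schedule")
  if (any(frame_end <= frame_start))
    stop_petsime("each frame_end must exceed its frame_start",
                 "petsime_invalid_schedule")
  if (length(frame_start) > 1L) {
    if (any(diff(frame_start) <= 0))
      stop_petsime("frame starts must be strictly increasing",
                   "petsime_invalid_schedule")
    if (any(frame_start[-1L] < frame_end[-length(frame_end)] - 1e-9))
      stop_petsime("frames must not overlap", "petsime_invalid_schedule")
  }
  structure(data.frame(frame_start = frame_start, frame_end = frame_end),
            label = label, class = c("frame_schedule", "data.frame"))
}

#' @rdname frame_schedule
#' @param x a `frame_schedule`.
#' @export
n_frames <- function(x) nrow(x)

#' @rdname frame_schedule
#' @export
frame_dur_min <- function(x) (x$frame_end - x$frame_start) / 60

#' @rdname frame_schedule
#' @export
frame_mid_min <- function(x) (x$frame_start + x$frame_end) / 120

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule '%s'> %d frames, %.0f-%.0f s (%.1f min total)\n",
              attr(x, "label"), nrow(x), x$frame_start[1],
              x$frame_end[nrow(x)], x$frame_end[nrow(x)] / 60))
  invisible(x)
}

#' Scanner frame-schedule presets
#'
#' Returns one of the frame schedules used for dynamic `[18F]`FEPPA imaging:
#' the HRRT schedules (120-min scans: 33 frames; 180-min scans: 44 frames;
#' `5 x 30, 1 x 45, 2 x 60, 1 x 90, 1 x 120, 1 x 210 s` followed by 22 or 33
#' five-minute frames, the variable-length background frame excluded) and
#' the PET/MR (mMR) 90-min schedule of 52 frames (`1 x 20, 12 x 5, 8 x 15,
#' 4 x 30, 5 x 60, 10 x 120, 11 x 300, 1 x 279 s`, 5399 s in total).
#'
#' @param preset one of `"hrrt_120"`, `"hrrt_180"`, `"mmr_90"`.
#' @return a [frame_schedule()].
#' @examples
#' n_frames(make_frame_schedule("mmr_90"))
#' @export
make_frame_schedule <- function(preset) {
  durs <- switch(preset,
    hrrt_120 = c(rep(30, 5), 45, rep(60, 2), 90, 120, 210, rep(300, 22)),
    hrrt_180 = c(rep(30, 5), 45, rep(60, 2), 90, 120, 210, rep(300, 33)),
    mmr_90   = c(20, rep(5, 12), rep(15, 8), rep(30, 4), rep(60, 5),
                 rep(120, 10), rep(300, 11), 279),
    stop_petsime(sprintf("unknown frame-schedule preset '%s'", preset),
                 "petsime_invalid_schedule")
  )
  ends <- cumsum(durs)
  frame_schedule(c(0, ends[-length(ends)]), ends, label = preset)
}
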