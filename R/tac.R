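#' Regional time-activity curve
#'
#' Frame-averaged, decay-corrected activity concentration of one brain
#' region, bound to its frame schedule.  Negative values are allowed (noisy
#' frames may undershoot zero).
#'
#' @param region region name.
#' @param schedule a [frame_schedule()].
#' @param activity numeric, kBq/ml, one value per frame.
#' @return an object of class `tac`.
#' @export
tac <- function(region, schedule, activity) {
  stopifnot(inherits(schedule, "frame_schedule"))
  activity <- as.numeric(activity)
  if (length(activity) != n_frames(schedule))
    stop_petsime(sprintf("region '%s': %d activity values for %d frames",
                         region, length(activity), n_frames(schedule)),
                 "petsime_invalid_tac")
  if (any(!is.finite(activity)))
    stop_petsime(sprintf("region '%s': non-finite activity", region),
                 "petsime_invalid_tac")
  structure(list(region = region, schedule = schedule, activity = activity),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac '%s'> %d frames on '%s', peak %.2f kBq/ml\n",
              x$region, n_frames(x$schedule), attr(x$schedule, "label"),
              max(x$activity)))
  invisible(x)
}

#' Truncate a TAC to a shorter scan duration
#'
#' Keeps the frames lying wholly inside the window, i.e. those with
#' `frame_end <= duration` (partially acquired frames are dropped).
#'
#' @param x a [tac()].
#' @param duration_min scan duration to keep, minutes.
#' @return a `tac` on the truncated schedule.
#' @examples
#' sched <- make_frame_schedule("hrrt_120")
#' t0 <- tac("frontal", sched, rep(1, n_frames(sched)))
#' n_frames(truncate_tac(t0, 90)$schedule)  # 26
#' @export
truncate_tac <- function(x, duration_min) {
  stopifnot(inherits(x, "tac"))
  if (duration_min <= 0)
    stop_petsime("duration must be positive", "petsime_invalid_parameter")
  keep <- x$schedule$frame_end <= duration_min * 60 + 1e-9
  if (!any(keep))
    stop_petsime("no frames remain after truncation", "petsime_empty_tac")
  if (all(keep)) {
    if (duration_min * 60 > max(x$schedule$frame_end) + 1e-9)
      warning("requested duration exceeds the scan; returning it unchanged")
    return(x)
  }
  sched <- frame_schedule(x$schedule$frame_start[keep],
                          x$schedule$frame_end[keep],
                          label = sprintf("%s_trunc%g", attr(x$schedule, "label"),
                                          duration_min))
  tac(x$region, sched, x$activity[keep])
}
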