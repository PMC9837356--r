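# Internal evaluation grid shared by model_tac and all fitting routines.
#
# The model curve is computed on a uniform grid (default 1 s) with the
# plasma-parent input interpolated piecewise-linearly; frame values are
# trapezoidal time-averages between frame boundaries, which must therefore
# lie on the grid.

build_model_grid <- function(input, schedule, grid_dt_s = 1) {
  stopifnot(inherits(input, "input_function"),
            inherits(schedule, "frame_schedule"))
  t_end_s <- max(schedule$frame_end)
  if (max(input$time_min) * 60 < t_end_s - 1e-6)
    stop_petsime("frame schedule extends beyond the input-function support",
                 "petsime_coverage_error")
  bounds <- c(schedule$frame_start, schedule$frame_end)
  idx <- bounds / grid_dt_s
  if (any(abs(idx - round(idx)) > 1e-6))
    stop_petsime("frame boundaries must be multiples of the model grid step; use a finer grid_dt_s",
                 "petsime_invalid_parameter")
  t_min <- seq(0, t_end_s, by = grid_dt_s) / 60
  cp <- if (is.null(input$plasma_parent)) NULL else
    input_at(input, "plasma_parent", t_min)
  wb <- input_at(input, "whole_blood", t_min)
  ia <- as.integer(round(schedule$frame_start / grid_dt_s)) + 1L
  ib <- as.integer(round(schedule$frame_end / grid_dt_s)) + 1L
  # frame-averaged whole blood (trapezoid, matching the tissue average)
  dtm <- grid_dt_s / 60
  cum <- c(0, cumsum((wb[-1] + wb[-length(wb)]) / 2 * dtm))
  wb_fr <- (cum[ib] - cum[ia]) / ((ib - ia) * dtm)
  list(t_min = t_min, dt_min = dtm, cp = cp, wb = wb, wb_fr = wb_fr,
       ia = ia, ib = ib, schedule = schedule)
}

grid_tcm_frames <- function(grid, K1, k2, k3, k4, vB) {
  cpp_tcm_frames(K1, k2, k3, k4, vB, grid$cp, grid$dt_min,
                 grid$ia, grid$ib, grid$wb_fr)
}

#' Model a regional TAC with the 2TCM
#'
#' Predicts the PET signal
#' `C(t) = (1 - vB) (Cp_parent (x) IRF)(t) + vB Cwb(t)` for the given rate
#' constants and input function, reported per frame either as the time
#' average over the frame (default; what scanners report) or as the value
#' at the frame midpoint.
#'
#' @param rates a [rate_constants()].
#' @param input an [input_function()] whose grid spans the schedule and
#'   carries a plasma-parent curve.
#' @param schedule a [frame_schedule()].
#' @param region region name given to the returned TAC.
#' @param mode `"frame_average"` or `"midpoint"`.
#' @param grid_dt_s internal convolution grid step, seconds.
#' @return a noiseless [tac()].
#' @examples
#' inp <- synth_input(t_max_min = 95)
#' sched <- make_frame_schedule("mmr_90")
#' mt <- model_tac(rate_constants(0.235, 0.1, 0.239, 0.047), inp, sched)
#' @export
model_tac <- function(rates, input, schedule, region = "model",
                      mode = c("frame_average", "midpoint"), grid_dt_s = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(rates, "rate_constants"))
  grid <- build_model_grid(input, schedule, grid_dt_s)
  if (is.null(grid$cp))
    stop_petsime("input function has no plasma-parent curve; apply metabolite_correct() first",
                 "petsime_invalid_input")
  if (mode == "frame_average") {
    vals <- grid_tcm_frames(grid, rates$K1, rates$k2, rates$k3, rates$k4,
                            rates$vB)
  } else {
    conv1 <- tissue_curve(grid, rates)
    mid <- frame_mid_min(schedule)
    tis <- approx(grid$t_min, conv1, xout = mid)$y
    wbm <- approx(grid$t_min, grid$wb, xout = mid)$y
    vals <- (1 - rates$vB) * tis + rates$vB * wbm
  }
  tac(region, schedule, vals)
}

# tissue curve (IRF convolved with plasma parent) on the model grid
tissue_curve <- function(grid, rates) {
  irf <- biexp_irf(rates)
  if (irf$degenerate) {
    # split the coincident roots by a relatively tiny amount
    eps <- irf$theta1 * 1e-7
    r2 <- rate_constants(rates$K1, rates$k2, rates$k3, rates$k4 + eps,
                         rates$vB)
    irf <- biexp_irf(r2)
  }
  irf$phi1 * cpp_exp_conv(grid$cp, grid$dt_min, irf$theta1) +
    irf$phi2 * cpp_exp_conv(grid$cp, grid$dt_min, irf$theta2)
}
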