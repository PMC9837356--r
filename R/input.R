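#' Input function container
#'
#' Whole-blood and metabolite-corrected plasma-parent activity on a fine,
#' uniform, strictly increasing time grid starting at (or before) injection.
#'
#' @param time_min uniform time grid, minutes.
#' @param whole_blood whole-blood activity, kBq/ml.
#' @param plasma_parent metabolite-corrected plasma-parent activity, kBq/ml;
#'   may be `NULL` for a raw whole-blood curve awaiting metabolite
#'   correction.
#' @param provenance one of `"AIF"`, `"IDIF"`, `"synthetic"`.
#' @return an object of class `input_function`.
#' @export
input_function <- function(time_min, whole_blood, plasma_parent = NULL,
                           provenance = c("AIF", "IDIF", "synthetic")) {
  provenance <- match.arg(provenance)
  time_min <- as.numeric(time_min)
  whole_blood <- as.numeric(whole_blood)
  if (length(time_min) < 2L || any(diff(time_min) <= 0))
    stop_petsime("time grid must be strictly increasing with >= 2 points",
                 "petsime_invalid_input")
  dt <- diff(time_min)
  if (max(dt) - min(dt) > 1e-6 * max(dt))
    stop_petsime("time grid must be uniform", "petsime_invalid_input")
  if (length(whole_blood) != length(time_min))
    stop_petsime("whole_blood length must match the time grid",
                 "petsime_invalid_input")
  if (!is.null(plasma_parent)) {
    plasma_parent <- as.numeric(plasma_parent)
    if (length(plasma_parent) != length(time_min))
      stop_petsime("plasma_parent length must match the time grid",
                   "petsime_invalid_input")
  }
  structure(list(time_min = time_min, whole_blood = whole_blood,
                 plasma_parent = plasma_parent, provenance = provenance),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "<input_function %s> %d points, 0-%.1f min, wb peak %.2f kBq/ml%s\n",
    x$provenance, length(x$time_min), max(x$time_min), max(x$whole_blood),
    if (is.null(x$plasma_parent)) " (no plasma-parent curve)" else ""))
  invisible(x)
}

# linear interpolation of an input curve at arbitrary minutes
input_at <- function(input, what, t_min) {
  y <- input[[what]]
  if (is.null(y))
    stop_petsime(sprintf("input function has no '%s' curve", what),
                 "petsime_invalid_input")
  if (min(t_min) < input$time_min[1] - 1e-9 ||
      max(t_min) > max(input$time_min) + 1e-9)
    stop_petsime("requested times fall outside the input-function support",
                 "petsime_coverage_error")
  approx(input$time_min, y, xout = t_min, rule = 1)$y
}

#' Synthetic tracer input function
#'
#' Builds a smooth whole-blood curve from a gamma-variate bolus peak joined
#' at the peak to a biexponential washout,
#' \deqn{C_{wb}(t) = A (t/t_p)^{\alpha} e^{\alpha (1 - t/t_p)}, t \le t_p}
#' \deqn{C_{wb}(t) = A [w e^{-\mu_1 (t - t_p)} + (1-w) e^{-\mu_2 (t - t_p)}], t > t_p}
#' so the curve peaks exactly at `peak_time_min` with value `peak_kbq_ml`.
#' The consistent plasma-parent curve is obtained by applying a synthetic
#' blood-to-plasma-ratio model and Hill parent-fraction model:
#' `Cp(t) = Cwb(t) / BPR(t) * f(t)`.
#'
#' @param peak_kbq_ml bolus peak amplitude (kBq/ml).
#' @param peak_time_min time of the whole-blood peak (min).
#' @param alpha gamma-variate shape of the rising edge.
#' @param w_fast,mu_fast,mu_slow washout mixture: fast fraction and the two
#'   decay rates (min^-1).
#' @param bpr synthetic blood-to-plasma-ratio model ([bpr_model()]).
#' @param hill synthetic parent-fraction model ([hill_model()]).
#' @param t_max_min grid end (min); must cover the frame schedule to be used.
#' @param grid_dt_s grid spacing in seconds (default 1 s).
#' @return an [input_function()] with provenance `"synthetic"`.
#' @examples
#' inp <- synth_input(t_max_min = 90)
#' max(inp$whole_blood)
#' @export
synth_input <- function(peak_kbq_ml = 40, peak_time_min = 1.0, alpha = 3,
                        w_fast = 0.75, mu_fast = 1.5, mu_slow = 0.01,
                        bpr = bpr_model(A1 = 0.35, A2 = 0.80,
                                        lam1 = 0.08, lam2 = 0),
                        hill = hill_model(a = 0.10, b = 1.5, c = 60),
                        t_max_min = 90, grid_dt_s = 1) {
  if (peak_time_min <= 0)
    stop_petsime("peak time must be positive", "petsime_invalid_parameter")
  if (peak_kbq_ml < 0 || w_fast < 0 || w_fast > 1 || mu_fast < 0 ||
      mu_slow < 0 || alpha <= 0)
    stop_petsime("invalid synthetic-input parameters",
                 "petsime_invalid_parameter")
  t <- seq(0, t_max_min, by = grid_dt_s / 60)
  wb <- numeric(length(t))
  up <- t <= peak_time_min
  wb[up] <- peak_kbq_ml * (t[up] / peak_time_min)^alpha *
    exp(alpha * (1 - t[up] / peak_time_min))
  td <- t[!up] - peak_time_min
  wb[!up] <- peak_kbq_ml * (w_fast * exp(-mu_fast * td) +
                            (1 - w_fast) * exp(-mu_slow * td))
  cp <- wb / bpr_value(bpr, t) * hill_value(hill, t)
  out <- input_function(t, wb, cp, provenance = "synthetic")
  attr(out, "params") <- list(peak_kbq_ml = peak_kbq_ml,
                              peak_time_min = peak_time_min, alpha = alpha,
                              w_fast = w_fast, mu_fast = mu_fast,
                              mu_slow = mu_slow, bpr = unclass(bpr),
                              hill = unclass(hill), t_max_min = t_max_min,
                              grid_dt_s = grid_dt_s)
  out
}
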