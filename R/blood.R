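#' Serial blood samples
#'
#' @param time_min minutes post-injection, `>= 0`.
#' @param whole_blood,plasma activity, kBq/ml, `>= 0`.
#' @param parent_fraction fraction of plasma activity from unmetabolized
#'   tracer, in `[0, 1]`; `NA` where not measured.
#' @param site `"arterial"` or `"venous"` (recycled).
#' @return a data frame of class `blood_samples`.
#' @export
blood_samples <- function(time_min, whole_blood, plasma,
                          parent_fraction = NA_real_, site = "venous") {
  df <- data.frame(time_min = as.numeric(time_min),
                   whole_blood = as.numeric(whole_blood),
                   plasma = as.numeric(plasma),
                   parent_fraction = as.numeric(parent_fraction),
                   site = as.character(site))
  if (any(df$time_min < 0) || any(df$whole_blood < 0, na.rm = TRUE) ||
      any(df$plasma < 0, na.rm = TRUE))
    stop_petsime("times and activities must be non-negative",
                 "petsime_invalid_sample")
  pf <- df$parent_fraction
  if (any(pf < 0 | pf > 1, na.rm = TRUE))
    stop_petsime("parent fractions must lie in [0, 1]",
                 "petsime_invalid_sample")
  if (!all(df$site %in% c("arterial", "venous")))
    stop_petsime("site must be 'arterial' or 'venous'",
                 "petsime_invalid_sample")
  class(df) <- c("blood_samples", "data.frame")
  df
}

# bounded least squares with a few fixed starts; returns best nlminb fit
multistart_nlminb <- function(objective, starts, lower, upper,
                              control = list(eval.max = 5000, iter.max = 5000,
                                             rel.tol = 1e-12)) {
  best <- NULL
  scale <- 1 / pmax(abs(starts[[1]]), 1e-3)
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(nlminb(st, objective, scale = scale, lower = lower,
                           upper = upper, control = control),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop_petsime("optimization failed from every start", "petsime_fit_failure")
  best
}

#' Biexponential blood-to-plasma ratio model
#'
#' `BPR(t) = A1 exp(-lam1 t) + A2 exp(-lam2 t)` with non-negative
#' amplitudes and `lam1 >= lam2 >= 0` (a plateau is the `lam -> 0` limit).
#'
#' @param A1,A2 amplitudes (unitless).
#' @param lam1,lam2 decay rates, min^-1.
#' @export
bpr_model <- function(A1, A2, lam1, lam2) {
  if (A1 < 0 || A2 < 0 || lam2 < 0 || lam1 < lam2)
    stop_petsime("require A1, A2 >= 0 and lam1 >= lam2 >= 0",
                 "petsime_invalid_parameter")
  structure(list(A1 = A1, A2 = A2, lam1 = lam1, lam2 = lam2),
            class = "bpr_model")
}

#' @rdname bpr_model
#' @param model a `bpr_model`.
#' @param t minutes.
#' @export
bpr_value <- function(model, t) {
  model$A1 * exp(-model$lam1 * t) + model$A2 * exp(-model$lam2 * t)
}

#' @export
print.bpr_model <- function(x, ...) {
  cat(sprintf("<bpr_model> %.4g exp(-%.4g t) + %.4g exp(-%.4g t)%s\n",
              x$A1, x$lam1, x$A2, x$lam2,
              if (!is.null(attr(x, "rss")))
                sprintf("  [RSS %.3g]", attr(x, "rss")) else ""))
  invisible(x)
}

#' Fit the blood-to-plasma ratio
#'
#' Least-squares biexponential fit to BPR points computed as
#' `whole_blood / plasma` from paired samples.
#'
#' @param samples a [blood_samples()] data frame with `>= 4` usable rows.
#' @return a [bpr_model()] with attributes `rss` and `data` (the fitted
#'   points).
#' @export
fit_bpr <- function(samples) {
  stopifnot(inherits(samples, "data.frame"))
  use <- is.finite(samples$whole_blood) & is.finite(samples$plasma)
  if (any(samples$plasma[use] == 0))
    stop_petsime("plasma activity of 0 in a sample: BPR undefined",
                 "petsime_invalid_sample")
  tt <- samples$time_min[use]
  y <- samples$whole_blood[use] / samples$plasma[use]
  if (length(y) < 4L)
    stop_petsime("need >= 4 samples with positive plasma to fit the BPR",
                 "petsime_insufficient_data")
  # par = (A1, A2, lam2, dlam) with lam1 = lam2 + dlam, all >= 0
  obj <- function(p) {
    r <- y - (p[1] * exp(-(p[3] + p[4]) * tt) + p[2] * exp(-p[3] * tt))
    sum(r * r)
  }
  spread <- max(y) - min(y)
  starts <- list(c(spread, min(y), 0, 0.1),
                 c(spread, min(y), 0, 0.5),
                 c(mean(y) / 2, mean(y) / 2, 0.005, 0.05))
  fit <- multistart_nlminb(obj, starts, lower = c(0, 0, 0, 0),
                           upper = c(10 * max(y), 10 * max(y), 5, 5))
  p <- fit$par
  out <- bpr_model(A1 = p[1], A2 = p[2], lam1 = p[3] + p[4], lam2 = p[3])
  attr(out, "rss") <- fit$objective
  attr(out, "data") <- data.frame(time_min = tt, bpr = y)
  out
}

#' Hill parent-fraction model
#'
#' `f(t) = 1 - ((1 - a) t^b) / (c + t^b)`: the fraction of plasma activity
#' from unmetabolized tracer, equal to 1 at injection and decreasing
#' monotonically to the plateau `a`.
#'
#' @param a plateau fraction in `[0, 1]`.
#' @param b Hill slope, `> 0`.
#' @param c scale, `> 0` (units min^b).
#' @export
hill_model <- function(a, b, c) {
  if (a < 0 || a > 1 || b <= 0 || c <= 0)
    stop_petsime("require a in [0,1], b > 0, c > 0",
                 "petsime_invalid_parameter")
  structure(list(a = a, b = b, c = c), class = "hill_model")
}

#' @rdname hill_model
#' @param model a `hill_model`.
#' @param t minutes.
#' @export
hill_value <- function(model, t) {
  tb <- ifelse(t > 0, t^model$b, 0)
  1 - ((1 - model$a) * tb) / (model$c + tb)
}

#' @export
print.hill_model <- function(x, ...) {
  cat(sprintf("<hill_model> plateau a = %.3g, slope b = %.3g, scale c = %.4g min^b\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Fit the Hill parent-fraction model
#'
#' @param samples a [blood_samples()] data frame with `>= 4` rows carrying a
#'   measured `parent_fraction`.
#' @return a [hill_model()] with attributes `rss` and `data`.
#' @export
fit_parent_fraction <- function(samples) {
  stopifnot(inherits(samples, "data.frame"))
  use <- is.finite(samples$parent_fraction)
  tt <- samples$time_min[use]
  y <- samples$parent_fraction[use]
  if (length(y) < 4L)
    stop_petsime("need >= 4 samples with a parent fraction to fit the Hill model",
                 "petsime_insufficient_data")
  if (any(y < 0 | y > 1))
    stop_petsime("parent fractions outside [0, 1]", "petsime_invalid_sample")
  obj <- function(p) {
    m <- hill_model(p[1], p[2], p[3])
    r <- y - hill_value(m, tt)
    sum(r * r)
  }
  tmed <- max(stats::median(tt), 1)
  starts <- list(c(min(y), 1.5, tmed^1.5),
                 c(min(y), 1.0, tmed),
                 c(min(y), 3.0, tmed^3))
  fit <- multistart_nlminb(obj, starts, lower = c(0, 1e-6, 1e-6),
                           upper = c(1, 10, 1e8))
  out <- hill_model(fit$par[1], fit$par[2], fit$par[3])
  attr(out, "rss") <- fit$objective
  attr(out, "data") <- data.frame(time_min = tt, parent_fraction = y)
  out
}

#' Metabolite-correct a whole-blood input function
#'
#' Builds the plasma-parent curve
#' `Cp(t) = Cwb(t) / BPR(t) * f(t)` on the curve's own grid.
#'
#' @param wb_curve an [input_function()] with a whole-blood curve.
#' @param bpr a [bpr_model()].
#' @param hill a [hill_model()].
#' @return the input function with `plasma_parent` populated.
#' @export
metabolite_correct <- function(wb_curve, bpr, hill) {
  stopifnot(inherits(wb_curve, "input_function"),
            inherits(bpr, "bpr_model"), inherits(hill, "hill_model"))
  b <- bpr_value(bpr, wb_curve$time_min)
  if (any(b <= 0))
    stop_petsime("BPR model is non-positive on the input grid",
                 "petsime_model_domain")
  wb_curve$plasma_parent <- wb_curve$whole_blood / b *
    hill_value(hill, wb_curve$time_min)
  wb_curve
}

#' Scale an IDIF to late venous samples
#'
#' Multiplies the image-derived input function by the scalar `s` minimizing
#' `sum_i (venous_i - s * idif(t_i))^2` over whole-blood venous samples at
#' the scaling times (default 45, 60 and 90 min), i.e.
#' `s = sum(v_i u_i) / sum(u_i^2)` with `u_i = idif(t_i)`.
#'
#' @param idif an [input_function()] covering the scaling times.
#' @param venous a [blood_samples()] data frame of venous samples.
#' @param times_min scaling times, minutes.
#' @return the scaled input function, with attribute `scale_factor`.
#' @export
scale_idif <- function(idif, venous, times_min = c(45, 60, 90)) {
  stopifnot(inherits(idif, "input_function"))
  v <- vapply(times_min, function(tm) {
    hit <- which(abs(venous$time_min - tm) < 1e-6 & venous$site == "venous")
    if (length(hit) == 0) NA_real_ else mean(venous$whole_blood[hit])
  }, numeric(1))
  if (any(is.na(v)))
    stop_petsime(sprintf("no venous sample at requested time(s) %s min",
                         paste(times_min[is.na(v)], collapse = ", ")),
                 "petsime_scaling_error")
  u <- input_at(idif, "whole_blood", times_min)
  if (sum(u^2) == 0)
    stop_petsime("IDIF is zero at every scaling time", "petsime_degenerate")
  s <- sum(v * u) / sum(u^2)
  idif$whole_blood <- s * idif$whole_blood
  if (!is.null(idif$plasma_parent))
    idif$plasma_parent <- s * idif$plasma_parent
  attr(idif, "scale_factor") <- s
  idif
}

#' Venous-versus-arterial agreement
#'
#' Ordinary least-squares regression of venous on arterial measurements
#' (venous as the response), with the Pearson r-squared and a two-sided
#' t-test of the regression slope against 1.
#'
#' @param venous,arterial paired measurements (e.g. BPRs or parent
#'   fractions), `>= 3` pairs.
#' @return a list of class `agreement_stats` with `slope`, `intercept`,
#'   `r_squared`, `p_slope_vs_one`, `n`.
#' @export
venous_arterial_agreement <- function(venous, arterial) {
  venous <- as.numeric(venous)
  arterial <- as.numeric(arterial)
  if (length(venous) != length(arterial) || length(venous) < 3L)
    stop_petsime("need >= 3 complete venous/arterial pairs",
                 "petsime_insufficient_data")
  if (stats::var(arterial) == 0)
    stop_petsime("arterial values have zero variance; regression is degenerate",
                 "petsime_degenerate")
  fit <- lm(venous ~ arterial)
  # an exact fit triggers summary.lm's perfect-fit warning; se = 0 there
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  df <- fit$df.residual
  p <- if (se < 1e-12) {
    if (abs(slope - 1) < 1e-8) 1 else 0
  } else 2 * pt(abs((slope - 1) / se), df, lower.tail = FALSE)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared, p_slope_vs_one = p,
                 n = length(venous), orientation = "venous ~ arterial"),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> venous = %.3f * arterial + %.3f, R^2 = %.3f, p(slope != 1) = %.3g (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$p_slope_vs_one, x$n))
  invisible(x)
}
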