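#' Two-tissue compartment rate constants
#'
#' @param K1 influx rate, ml cm^-3 min^-1.
#' @param k2,k3,k4 tissue rate constants, min^-1.
#' @param vB fractional blood volume in `[0, 1)`; default 0.05.
#' @return an object of class `rate_constants`.
#' @examples
#' rate_constants(K1 = 0.235, k2 = 0.1, k3 = 0.239, k4 = 0.047)
#' @export
rate_constants <- function(K1, k2, k3, k4, vB = 0.05) {
  K1 <- unname(K1); k2 <- unname(k2); k3 <- unname(k3); k4 <- unname(k4)
  vB <- unname(vB)
  v <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB)
  if (any(!is.finite(v)))
    stop_petsime("rate constants must be finite", "petsime_invalid_parameter")
  if (any(v[c("K1", "k2", "k3", "k4")] < 0))
    stop_petsime("rate constants must be non-negative",
                 "petsime_invalid_parameter")
  if (vB < 0 || vB >= 1)
    stop_petsime("vB must lie in [0, 1)", "petsime_invalid_parameter")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf(
    "<rate_constants> K1 = %.4g ml/cm3/min, k2 = %.4g, k3 = %.4g, k4 = %.4g min^-1, vB = %.3g\n",
    x$K1, x$k2, x$k3, x$k4, x$vB))
  invisible(x)
}

#' Biexponential impulse response of the 2TCM
#'
#' Closed-form impulse response `IRF(t) = phi1 exp(-theta1 t) +
#' phi2 exp(-theta2 t)` with
#' `theta_{1,2} = ((k2+k3+k4) +/- sqrt((k2+k3+k4)^2 - 4 k2 k4)) / 2`,
#' `phi1 = K1 (theta1 - k3 - k4) / (theta1 - theta2)` and
#' `phi2 = K1 (k3 + k4 - theta2) / (theta1 - theta2)`.  When the two decay
#' rates coincide (discriminant below tolerance) the degenerate form
#' `IRF(t) = K1 exp(-theta t) (1 + (k3 + k4 - theta) t)` is used.
#'
#' @param rates a [rate_constants()] with `k2 > 0` and `k2 + k3 + k4 > 0`.
#' @return an object of class `biexp_irf` with fields `phi1`, `phi2`,
#'   `theta1`, `theta2` and a `degenerate` flag.
#' @examples
#' irf <- biexp_irf(rate_constants(0.235, 0.1, 0.239, 0.047))
#' eval_irf(irf, c(0, 1, 10))
#' @export
biexp_irf <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (rates$k2 <= 0)
    stop_petsime("k2 must be positive", "petsime_invalid_parameter")
  s <- rates$k2 + rates$k3 + rates$k4
  disc <- s^2 - 4 * rates$k2 * rates$k4
  degenerate <- disc < (1e-12 * s^2)
  if (degenerate) {
    theta <- s / 2
    out <- list(phi1 = rates$K1, phi2 = rates$K1 * (rates$k3 + rates$k4 - theta),
                theta1 = theta, theta2 = theta, degenerate = TRUE)
  } else {
    sq <- sqrt(disc)
    theta1 <- (s + sq) / 2
    theta2 <- (s - sq) / 2
    out <- list(phi1 = rates$K1 * (theta1 - rates$k3 - rates$k4) / sq,
                phi2 = rates$K1 * (rates$k3 + rates$k4 - theta2) / sq,
                theta1 = theta1, theta2 = theta2, degenerate = FALSE)
  }
  structure(out, class = "biexp_irf")
}

#' @rdname biexp_irf
#' @param irf a `biexp_irf`.
#' @param t times in minutes.
#' @export
eval_irf <- function(irf, t) {
  stopifnot(inherits(irf, "biexp_irf"))
  if (irf$degenerate)
    exp(-irf$theta1 * t) * (irf$phi1 + irf$phi2 * t)
  else
    irf$phi1 * exp(-irf$theta1 * t) + irf$phi2 * exp(-irf$theta2 * t)
}

#' @export
print.biexp_irf <- function(x, ...) {
  cat(sprintf("<biexp_irf> phi = (%.4g, %.4g), theta = (%.4g, %.4g) min^-1%s\n",
              x$phi1, x$phi2, x$theta1, x$theta2,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Macro-parameters (distribution volumes) from 2TCM rates
#'
#' Computes `V_ND = K1/k2`, `V_T = V_ND (1 + k3/k4)`,
#' `V_S = V_T - V_ND` and `BP_ND = (V_T - V_ND)/V_ND`.
#'
#' @param rates a [rate_constants()] with `k2 > 0`; `k4` may be 0 only when
#'   `k3 = 0` (then `V_T = V_ND`).
#' @return an object of class `distribution_volumes` with fields `V_ND`,
#'   `V_T`, `V_S` (ml/cm^3) and `BP_ND` (unitless).
#' @examples
#' derive_dvs(rate_constants(0.235, 0.1, 0.2390, 0.0470))
#' @export
derive_dvs <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (rates$k2 <= 0)
    stop_petsime("k2 must be positive to derive V_ND",
                 "petsime_invalid_parameter")
  V_ND <- rates$K1 / rates$k2
  if (rates$k3 == 0) {
    V_T <- V_ND
  } else {
    if (rates$k4 <= 0)
      stop_petsime("V_T is unbounded: k4 = 0 with k3 > 0",
                   "petsime_unbounded_vt")
    V_T <- V_ND * (1 + rates$k3 / rates$k4)
  }
  structure(list(V_ND = V_ND, V_T = V_T, V_S = V_T - V_ND,
                 BP_ND = (V_T - V_ND) / V_ND),
            class = "distribution_volumes")
}

#' @export
print.distribution_volumes <- function(x, ...) {
  cat(sprintf(
    "<distribution_volumes> V_ND = %.3f, V_T = %.3f, V_S = %.3f ml/cm3, BP_ND = %.3f\n",
    x$V_ND, x$V_T, x$V_S, x$BP_ND))
  invisible(x)
}
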