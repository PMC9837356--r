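#' Optimizer options for kinetic fitting
#'
#' Controls shared by [fit_2tcm()], [sime_joint_fit()], [sime_grid_search()]
#' and [refit_fixed_vnd()].  The default bounds and starting values are
#' chosen for `[18F]`FEPPA-like kinetics: `k2, k3, k4` in
#' `[1e-6, 2] min^-1`, `V_ND` in `[0.1, 10] ml/cm^3`, start at `k2 = 0.1`,
#' `k3 = 0.05`, `k4 = 0.03`, `V_ND = 2.0`.  Fits use a bounded local
#' optimizer (`nlminb`) from `n_starts` starting points: the literature
#' start plus `n_starts - 1` multiplicative log-normal perturbations drawn
#' under fixed internal seeds, so results are reproducible irrespective of
#' the caller's RNG state.  Ties across starts are broken by lowest cost,
#' then lowest `V_ND`.
#'
#' @param n_starts number of starts (default 5).
#' @param perturb_sd SD of the log-normal start perturbations.
#' @param k_lower,k_upper bounds for `k2, k3, k4` (min^-1).
#' @param vnd_lower,vnd_upper bounds for `V_ND` (ml/cm^3).
#' @param start named numeric start (`k2`, `k3`, `k4`, `V_ND`).
#' @param rel_tol,x_tol,max_iter `nlminb` convergence controls.
#' @param grid_dt_s internal convolution grid step, seconds.
#' @param prescan number of coarse profile-scan candidates over `V_ND`
#'   used to seed an additional global start of [sime_joint_fit()]
#'   (0 or 1 disables the pre-scan).
#' @return a list of class `sime_options`.
#' @export
sime_options <- function(n_starts = 5, perturb_sd = 0.35,
                         k_lower = 1e-6, k_upper = 2,
                         vnd_lower = 0.1, vnd_upper = 10,
                         start = c(k2 = 0.1, k3 = 0.05, k4 = 0.03, V_ND = 2.0),
                         rel_tol = 1e-10, x_tol = 1e-8, max_iter = 5000,
                         grid_dt_s = 1, prescan = 12) {
  structure(list(n_starts = n_starts, perturb_sd = perturb_sd,
                 k_lower = k_lower, k_upper = k_upper,
                 vnd_lower = vnd_lower, vnd_upper = vnd_upper,
                 start = start, rel_tol = rel_tol, x_tol = x_tol,
                 max_iter = max_iter, grid_dt_s = grid_dt_s,
                 prescan = prescan),
            class = "sime_options")
}

nlminb_control <- function(options) {
  list(eval.max = options$max_iter * 4, iter.max = options$max_iter,
       rel.tol = options$rel_tol, x.tol = options$x_tol)
}

# starting points: the literature start plus fixed-seed log-normal
# multiplicative perturbations, clipped to the bounds
make_starts <- function(base, lower, upper, options) {
  starts <- list(base)
  if (options$n_starts > 1) {
    for (i in seq_len(options$n_starts - 1)) {
      fac <- with_local_seed(100 + i,
                             exp(rnorm(length(base), 0, options$perturb_sd)))
      starts[[i + 1]] <- pmin(pmax(base * fac, lower), upper)
    }
  }
  starts
}

# run nlminb from each start; keep the best (lowest cost, ties by a
# user-supplied key, e.g. V_ND).  A polish restart from the winning
# solution both tightens it and decides convergence: the fit is accepted
# as converged if any run reports success or the restart cannot improve
# the cost beyond round-off (nlminb's "false convergence" at a flat
# minimum of a noiseless problem).
run_starts <- function(objective, starts, lower, upper, options,
                       tie_key = function(p) 0, scale = NULL,
                       gradient = NULL) {
  if (is.null(scale)) scale <- 1 / pmax(abs(starts[[1]]), 1e-3)
  one <- function(st)
    tryCatch(nlminb(st, objective, gradient = gradient, scale = scale,
                    lower = lower, upper = upper,
                    control = nlminb_control(options)),
             error = function(e) NULL)
  fits <- Filter(function(f) !is.null(f) && is.finite(f$objective),
                 lapply(starts, one))
  if (length(fits) == 0)
    stop_petsime("all optimizer starts failed", "petsime_fit_failure")
  costs <- vapply(fits, `[[`, numeric(1), "objective")
  near <- which(costs <= min(costs) * (1 + 1e-10) + 1e-300)
  keys <- vapply(fits[near], function(f) tie_key(f$par), numeric(1))
  best <- fits[[near[which.min(keys)]]]
  polish <- one(best$par)
  if (!is.null(polish) && is.finite(polish$objective) &&
      polish$objective <= best$objective) {
    polish$iterations <- best$iterations + polish$iterations
    best <- polish
  }
  # converged if the returned cost was reached by a run that terminated
  # successfully (the polish restart itself may stop on a technicality)
  ok <- vapply(fits, function(f) f$convergence == 0 &&
                 f$objective <= best$objective * (1 + 1e-6) + 1e-12,
               logical(1))
  best$converged <- best$convergence == 0 || any(ok)
  best$par <- unname(best$par)
  best
}

# Amplitude normalization of the plasma-parent input used by every fit:
# the optimizer works with cp scaled to unit time-average over the scan,
# so starting values and bounds act on a canonical scale and the fitted
# kinetics are equivariant under rescaled (e.g. miscalibrated) inputs.
# Influx-bearing parameters (K1, V_ND) are converted back afterwards.
input_norm_factor <- function(grid) {
  sn <- mean(grid$cp)
  if (!is.finite(sn) || sn <= 0)
    stop_petsime("plasma-parent input is zero or negative on average",
                 "petsime_degenerate")
  sn
}

# objective/gradient pair sharing one evaluation cache (nlminb requests
# both at the same iterate)
make_obj_grad <- function(eval_fn) {
  last_p <- NULL
  last <- NULL
  fetch <- function(p) {
    if (is.null(last_p) || !identical(p, last_p)) {
      last <<- eval_fn(p)
      last_p <<- p
    }
    last
  }
  list(obj = function(p) fetch(p)$value,
       grad = function(p) fetch(p)$grad)
}

at_bounds_flag <- function(par, lower, upper, tol = 1e-6) {
  any(par - lower < tol * pmax(1, abs(lower)) + 1e-9 |
      upper - par < tol * pmax(1, abs(upper)))
}

resolve_weights <- function(weights, schedule) {
  if (is.character(weights)) {
    w <- switch(weights,
      frame_duration = {
        d <- frame_dur_min(schedule)
        d / sum(d)
      },
      uniform = rep(1 / n_frames(schedule), n_frames(schedule)),
      none = rep(1, n_frames(schedule)),
      stop_petsime(sprintf("unknown weights mode '%s'", weights),
                   "petsime_invalid_parameter"))
    attr(w, "mode") <- weights
    return(w)
  }
  w <- as.numeric(weights)
  if (length(w) != n_frames(schedule) || any(!is.finite(w)) || any(w < 0))
    stop_petsime("custom weights must be non-negative, one per frame",
                 "petsime_invalid_parameter")
  attr(w, "mode") <- "custom"
  w
}

new_fit_result <- function(rates, cost, converged, n_iter, at_bounds,
                           weights_mode, method) {
  structure(list(rates = rates, dvs = derive_dvs(rates), cost = cost,
                 converged = converged, n_iter = n_iter,
                 at_bounds = at_bounds, weights_mode = weights_mode,
                 method = method),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result %s> K1 = %.4g, k2 = %.4g, k3 = %.4g, k4 = %.4g | V_T = %.3f, BP_ND = %.3f | cost %.4g%s%s\n",
    x$method, x$rates$K1, x$rates$k2, x$rates$k3, x$rates$k4,
    x$dvs$V_T, x$dvs$BP_ND, x$cost,
    if (x$converged) "" else " [not converged]",
    if (x$at_bounds) " [at bounds]" else ""))
  invisible(x)
}

#' Weighted 2TCM fit of a single regional TAC
#'
#' Minimizes `sum_i w_i (TAC_i - model_i)^2` over `(K1, k2, k3, k4)` within
#' bounds, with the blood-volume fraction fixed (default 5%).  Default
#' weights are proportional to frame duration (normalized to sum 1).
#'
#' @param x a [tac()].
#' @param input an [input_function()] with a plasma-parent curve spanning
#'   the schedule.
#' @param weights `"frame_duration"` (default), `"uniform"`, `"none"`, or a
#'   numeric vector of non-negative per-frame weights.
#' @param vB fixed blood-volume fraction.
#' @param options a [sime_options()].
#' @return a `fit_result` with elements `rates`, `dvs`, `cost`,
#'   `converged`, `n_iter`, `at_bounds`.
#' @export
fit_2tcm <- function(x, input, weights = "frame_duration", vB = 0.05,
                     options = sime_options()) {
  stopifnot(inherits(x, "tac"))
  if (all(x$activity == 0))
    stop_petsime("all-zero TAC: nothing to fit", "petsime_degenerate")
  grid <- build_model_grid(input, x$schedule, options$grid_dt_s)
  if (is.null(grid$cp))
    stop_petsime("input function has no plasma-parent curve",
                 "petsime_invalid_input")
  w <- resolve_weights(weights, x$schedule)
  sn <- input_norm_factor(grid)
  cpn <- grid$cp / sn
  og <- make_obj_grad(function(p) {
    g <- cpp_tcm_wrss_grad(p[1], p[2], p[3], p[4], vB, cpn, grid$dt_min,
                           grid$ia, grid$ib, grid$wb_fr, x$activity, w)
    list(value = g[1], grad = g[2:5])
  })
  # K1 is fitted on the normalized-input scale, so its start and implied
  # bounds carry the normalization factor (physical bounds preserved)
  s0 <- options$start
  base <- c(s0[["k2"]] * s0[["V_ND"]] * sn, s0[["k2"]], s0[["k3"]],
            s0[["k4"]])
  lower <- c(options$k_lower * options$vnd_lower * sn,
             rep(options$k_lower, 3))
  upper <- c(options$k_upper * options$vnd_upper * sn,
             rep(options$k_upper, 3))
  starts <- make_starts(base, lower, upper, options)
  best <- run_starts(og$obj, starts, lower, upper, options,
                     tie_key = function(p) p[1] / p[2], gradient = og$grad)
  rates <- rate_constants(best$par[1] / sn, best$par[2], best$par[3],
                          best$par[4], vB)
  new_fit_result(rates, best$objective, best$converged,
                 best$iterations, at_bounds_flag(best$par, lower, upper),
                 attr(w, "mode"), "2tcm")
}

#' Refit a region with a fixed non-displaceable volume
#'
#' Fits `(k2, k3, k4)` with `K1 = k2 * V_ND` held to the supplied common
#' value, as done after a SIME fit to re-derive regional rate constants.
#'
#' @inheritParams fit_2tcm
#' @param V_ND fixed non-displaceable distribution volume, ml/cm^3.
#' @return a `fit_result`.
#' @export
refit_fixed_vnd <- function(x, input, V_ND, weights = "frame_duration",
                            vB = 0.05, options = sime_options()) {
  if (!is.numeric(V_ND) || length(V_ND) != 1L || !is.finite(V_ND) || V_ND <= 0)
    stop_petsime("V_ND must be a single positive number",
                 "petsime_invalid_parameter")
  stopifnot(inherits(x, "tac"))
  if (all(x$activity == 0))
    stop_petsime("all-zero TAC: nothing to fit", "petsime_degenerate")
  grid <- build_model_grid(input, x$schedule, options$grid_dt_s)
  w <- resolve_weights(weights, x$schedule)
  sn <- input_norm_factor(grid)
  cpn <- grid$cp / sn
  Vn <- V_ND * sn
  og <- make_obj_grad(function(p) {
    g <- cpp_tcm_wrss_grad(p[1] * Vn, p[1], p[2], p[3], vB, cpn,
                           grid$dt_min, grid$ia, grid$ib, grid$wb_fr,
                           x$activity, w)
    list(value = g[1], grad = c(g[3] + Vn * g[2], g[4], g[5]))
  })
  base <- options$start[c("k2", "k3", "k4")]
  lower <- rep(options$k_lower, 3)
  upper <- rep(options$k_upper, 3)
  starts <- make_starts(base, lower, upper, options)
  best <- run_starts(og$obj, starts, lower, upper, options,
                     gradient = og$grad)
  rates <- rate_constants(best$par[1] * V_ND, best$par[1], best$par[2],
                          best$par[3], vB)
  new_fit_result(rates, best$objective, best$converged,
                 best$iterations, at_bounds_flag(best$par, lower, upper),
                 attr(w, "mode"), "2tcm_fixed_vnd")
}
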