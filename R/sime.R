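# Shared validation/setup for the SIME fits: all TACs must sit on one
# schedule and one input-function grid.
sime_setup <- function(tacs, input, weights, options) {
  if (!is.list(tacs) || !all(vapply(tacs, inherits, logical(1), "tac")))
    stop_petsime("tacs must be a list of tac objects", "petsime_invalid_tac")
  R <- length(tacs)
  if (R < 1) stop_petsime("no TACs supplied", "petsime_invalid_tac")
  sched <- tacs[[1]]$schedule
  for (x in tacs[-1]) {
    if (n_frames(x$schedule) != n_frames(sched) ||
        any(abs(x$schedule$frame_start - sched$frame_start) > 1e-9) ||
        any(abs(x$schedule$frame_end - sched$frame_end) > 1e-9))
      stop_petsime("all TACs must share one frame schedule",
                   "petsime_invalid_tac")
  }
  if (R <= 3)
    warning(sprintf(
      "SIME with %d ROI(s): estimates are unreliable with 3 or fewer regions",
      R))
  grid <- build_model_grid(input, sched, options$grid_dt_s)
  if (is.null(grid$cp))
    stop_petsime("input function has no plasma-parent curve",
                 "petsime_invalid_input")
  w <- resolve_weights(weights, sched)
  nm <- vapply(tacs, `[[`, character(1), "region")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  sn <- input_norm_factor(grid)
  list(R = R, grid = grid, w = w, sched = sched, regions = nm,
       acts = lapply(tacs, `[[`, "activity"),
       sn = sn, cpn = grid$cp / sn)
}

# pooled SIME cost and analytic gradient for [V_ND, (k2,k3,k4) x R] on the
# amplitude-normalized input; K1_r = k2_r * V_ND, so dV picks up
# sum_r k2_r * dK1_r
sime_cost_fun <- function(setup, vB) {
  force(setup); force(vB)
  function(p) {
    V <- p[1]
    tot <- 0
    grad <- numeric(length(p))
    for (r in seq_len(setup$R)) {
      k <- p[(3 * r - 1):(3 * r + 1)]
      g <- cpp_tcm_wrss_grad(k[1] * V, k[1], k[2], k[3], vB,
                             setup$cpn, setup$grid$dt_min,
                             setup$grid$ia, setup$grid$ib,
                             setup$grid$wb_fr, setup$acts[[r]], setup$w)
      tot <- tot + g[1]
      grad[1] <- grad[1] + k[1] * g[2]
      grad[(3 * r - 1):(3 * r + 1)] <- c(g[3] + V * g[2], g[4], g[5])
    }
    list(value = tot, grad = grad)
  }
}

# Profile scan over candidate (physical) V_ND values: each region is
# fitted conditionally on the candidate, warm-starting from the previous
# candidate's solution.  Shared by the grid search and by the joint fit's
# global pre-scan.
sime_profile_scan <- function(setup, vB, grid, options, multi_first = TRUE) {
  lower <- rep(options$k_lower, 3)
  upper <- rep(options$k_upper, 3)
  base <- options$start[c("k2", "k3", "k4")]
  warm <- vector("list", setup$R)
  costs <- numeric(length(grid))
  kmats <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    Vn <- grid[g] * setup$sn
    km <- matrix(0, setup$R, 3)
    tot <- 0
    for (r in seq_len(setup$R)) {
      og <- make_obj_grad(function(p) {
        gr <- cpp_tcm_wrss_grad(p[1] * Vn, p[1], p[2], p[3], vB,
                                setup$cpn, setup$grid$dt_min,
                                setup$grid$ia, setup$grid$ib,
                                setup$grid$wb_fr, setup$acts[[r]], setup$w)
        list(value = gr[1], grad = c(gr[3] + Vn * gr[2], gr[4], gr[5]))
      })
      starts <- if (!is.null(warm[[r]])) list(warm[[r]], base)
                else if (multi_first && g == 1)
                  make_starts(base, lower, upper, options)
                else list(base)
      f <- run_starts(og$obj, starts, lower, upper, options,
                      gradient = og$grad)
      warm[[r]] <- f$par
      km[r, ] <- f$par
      tot <- tot + f$objective
    }
    costs[g] <- tot
    kmats[[g]] <- km
  }
  list(costs = costs, kmats = kmats, grid = grid)
}

build_sime_result <- function(setup, V, kmat, vB, converged, n_iter, method,
                              options, weights_mode, extra = list()) {
  per_region <- vector("list", setup$R)
  names(per_region) <- setup$regions
  total_cost <- 0
  n_at_bounds <- 0
  for (r in seq_len(setup$R)) {
    k <- kmat[r, ]
    cost_r <- cpp_tcm_wrss(k[1] * V, k[1], k[2], k[3], vB, setup$grid$cp,
                           setup$grid$dt_min, setup$grid$ia, setup$grid$ib,
                           setup$grid$wb_fr, setup$acts[[r]], setup$w)
    total_cost <- total_cost + cost_r
    ab <- at_bounds_flag(k, rep(options$k_lower, 3), rep(options$k_upper, 3))
    n_at_bounds <- n_at_bounds + ab
    rates <- rate_constants(k[1] * V, k[1], k[2], k[3], vB)
    per_region[[r]] <- new_fit_result(rates, cost_r, converged, n_iter, ab,
                                      weights_mode, method)
  }
  failed <- FALSE
  reason <- NULL
  if (!converged) {
    failed <- TRUE
    reason <- "no optimizer start converged"
  } else if (n_at_bounds > setup$R / 2) {
    failed <- TRUE
    reason <- sprintf("%d of %d regional fits at parameter bounds",
                      n_at_bounds, setup$R)
  }
  structure(c(list(V_ND_common = V, per_region = per_region,
                   total_cost = total_cost, converged = converged,
                   failed = failed, failure_reason = reason,
                   method = method, weights_mode = weights_mode,
                   n_regions = setup$R,
                   n_frames_fit = n_frames(setup$sched)),
              extra),
            class = "sime_result")
}

#' @export
print.sime_result <- function(x, ...) {
  cat(sprintf(
    "<sime_result %s> V_ND = %.3f ml/cm3 over %d ROIs, total cost %.4g%s\n",
    x$method, x$V_ND_common, x$n_regions, x$total_cost,
    if (x$failed) sprintf("  FAILED (%s)", x$failure_reason) else ""))
  df <- as.data.frame(x)
  print(df[, c("region", "K1", "k2", "k3", "k4", "V_T", "BP_ND")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.sime_result <- function(x, ...) {
  do.call(rbind, lapply(names(x$per_region), function(nm) {
    fr <- x$per_region[[nm]]
    data.frame(region = nm, K1 = fr$rates$K1, k2 = fr$rates$k2,
               k3 = fr$rates$k3, k4 = fr$rates$k4, V_ND = fr$dvs$V_ND,
               V_T = fr$dvs$V_T, V_S = fr$dvs$V_S, BP_ND = fr$dvs$BP_ND,
               cost = fr$cost, converged = fr$converged,
               at_bounds = fr$at_bounds)
  }))
}

#' SIME joint fit with a common non-displaceable volume
#'
#' Minimizes the pooled cost
#' `sum_regions sum_frames (TAC - model)^2` over per-region `(k2, k3, k4)`
#' plus a single `V_ND` shared by all regions, with `K1 = k2 * V_ND`.
#' The pooled cost is unweighted by default; per-frame weights may be
#' supplied.  Fewer than four regions triggers a warning (the estimate is
#' known to be unreliable with three or fewer) but the fit is attempted.
#'
#' @param tacs a list of [tac()] objects sharing one frame schedule.
#' @param input an [input_function()] with a plasma-parent curve.
#' @param weights `"none"` (default), `"frame_duration"`, `"uniform"`, or a
#'   numeric per-frame vector.
#' @param vB fixed blood-volume fraction.
#' @param options a [sime_options()].
#' @return a `sime_result`: `V_ND_common`, `per_region` fit results (whose
#'   `K1 = k2 * V_ND_common` by construction), `total_cost`, `converged`,
#'   and a `failed` flag with reason.
#' @export
sime_joint_fit <- function(tacs, input, weights = "none", vB = 0.05,
                           options = sime_options()) {
  setup <- sime_setup(tacs, input, weights, options)
  og <- make_obj_grad(sime_cost_fun(setup, vB))
  # V_ND is fitted on the normalized-input scale: start and bounds carry
  # the normalization factor so the physical bounds are preserved
  s0 <- options$start
  base <- c(s0[["V_ND"]] * setup$sn, rep(s0[c("k2", "k3", "k4")], setup$R))
  lower <- c(options$vnd_lower * setup$sn, rep(options$k_lower, 3 * setup$R))
  upper <- c(options$vnd_upper * setup$sn, rep(options$k_upper, 3 * setup$R))
  starts <- make_starts(base, lower, upper, options)
  if (options$prescan > 1) {
    # global pre-scan: coarse profile of the pooled cost over V_ND, its
    # argmin seeding an extra start (the cost valley can hold distant
    # local minima that the literature-based starts miss)
    cand <- exp(seq(log(max(options$vnd_lower, 0.25)),
                    log(options$vnd_upper), length.out = options$prescan))
    scan <- sime_profile_scan(setup, vB, cand, options, multi_first = FALSE)
    gbest <- which.min(scan$costs)
    starts <- c(starts, list(c(cand[gbest] * setup$sn,
                               as.vector(t(scan$kmats[[gbest]])))))
  }
  best <- run_starts(og$obj, starts, lower, upper, options,
                     tie_key = function(p) p[1], gradient = og$grad)
  kmat <- matrix(best$par[-1], nrow = setup$R, byrow = TRUE)
  build_sime_result(setup, best$par[1] / setup$sn, kmat, vB,
                    best$converged,
                    best$iterations, "sime_optimizer", options,
                    attr(setup$w, "mode"))
}

#' SIME by grid search over the common volume
#'
#' The grid-search variant: for each candidate `V_ND` on the grid, each
#' region is profile-fitted over `(k2, k3, k4)` with `K1 = k2 * V_ND`;
#' the candidate minimizing the pooled cost is returned.  Serves as an
#' independent cross-check of [sime_joint_fit()].  A minimum at a grid
#' endpoint raises a warning (the grid likely excludes the optimum).
#'
#' @inheritParams sime_joint_fit
#' @param grid increasing candidate `V_ND` values, ml/cm^3.
#' @return a `sime_result` with extra fields `grid` and `grid_cost`.
#' @export
sime_grid_search <- function(tacs, input, grid = seq(0.5, 6, by = 0.05),
                             weights = "none", vB = 0.05,
                             options = sime_options()) {
  grid <- as.numeric(grid)
  if (length(grid) == 0 || any(!is.finite(grid)) || any(grid <= 0) ||
      is.unsorted(grid, strictly = TRUE))
    stop_petsime("grid must be non-empty, positive and strictly increasing",
                 "petsime_invalid_parameter")
  setup <- sime_setup(tacs, input, weights, options)
  scan <- sime_profile_scan(setup, vB, grid, options, multi_first = TRUE)
  i <- which.min(scan$costs)
  if (length(grid) > 1 && (i == 1 || i == length(grid)))
    warning("grid-search minimum lies at a grid endpoint; the grid may exclude the optimum")
  build_sime_result(setup, grid[i], scan$kmats[[i]], vB, TRUE, NA_integer_,
                    "sime_grid", options, attr(setup$w, "mode"),
                    extra = list(grid = grid, grid_cost = scan$costs))
}

#' V_ND stability across ROI subsets
#'
#' Runs [sime_joint_fit()] on every `k`-region subset of the supplied TACs
#' and summarizes the spread of the common `V_ND` across subsets.  Per-fit
#' failures are recorded, not fatal.  `k <= 3` attaches a warning: with
#' three or fewer regions the common volume is not reliably identifiable.
#'
#' @inheritParams sime_joint_fit
#' @param k subset size, `3 <= k <= length(tacs)`.
#' @return a list of class `roi_subset_result`: `table` (one row per
#'   subset: regions, `V_ND`, `failed`), `mean_vnd`, `sd_vnd`, `results`.
#' @export
roi_subset_vnd <- function(tacs, input, k, weights = "none", vB = 0.05,
                           options = sime_options()) {
  R <- length(tacs)
  if (k < 3 || k > R)
    stop_petsime("subset size k must satisfy 3 <= k <= number of regions",
                 "petsime_invalid_parameter")
  if (k <= 3)
    warning("k = 3: SIME is known to fail with only three regions")
  combos <- combn(R, k, simplify = FALSE)
  results <- lapply(combos, function(idx) {
    tryCatch(suppressWarnings(
      sime_joint_fit(tacs[idx], input, weights, vB, options)),
      error = function(e) structure(list(failed = TRUE,
                                         failure_reason = conditionMessage(e),
                                         V_ND_common = NA_real_),
                                    class = "sime_result"))
  })
  regions <- vapply(tacs, `[[`, character(1), "region")
  tab <- data.frame(
    subset = vapply(combos, function(i) paste(regions[i], collapse = "+"),
                    character(1)),
    V_ND = vapply(results, `[[`, numeric(1), "V_ND_common"),
    failed = vapply(results, `[[`, logical(1), "failed"))
  ok <- !tab$failed & is.finite(tab$V_ND)
  structure(list(table = tab, mean_vnd = mean(tab$V_ND[ok]),
                 sd_vnd = sd(tab$V_ND[ok]), k = k, results = results),
            class = "roi_subset_result")
}

#' @export
print.roi_subset_result <- function(x, ...) {
  cat(sprintf(
    "<roi_subset_result> k = %d: %d subsets, V_ND = %.3f +/- %.3f ml/cm3 (%d failed)\n",
    x$k, nrow(x$table), x$mean_vnd, x$sd_vnd, sum(x$table$failed)))
  invisible(x)
}
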