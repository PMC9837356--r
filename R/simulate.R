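#' Per-frame noise profiles
#'
#' A noise profile gives, per frame, the relative standard deviation of
#' frame noise as a fraction of the TAC's mean activity.  The default
#' profile is flat 5% with 10% on frames shorter than 30 s (short frames
#' carry fewer counts); a profile measured from fit residuals can be built
#' with [residual_profile()].
#'
#' @param schedule a [frame_schedule()].
#' @param base relative SD applied to all frames.
#' @param short_frame relative SD applied to frames shorter than
#'   `short_threshold_s`.
#' @param short_threshold_s duration cutoff, seconds.
#' @return an object of class `noise_profile`: a numeric vector (one value
#'   per frame) with the schedule label attached.
#' @export
noise_profile <- function(schedule, base = 0.05, short_frame = 0.10,
                          short_threshold_s = 30) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (base < 0 || short_frame < 0)
    stop_petsime("noise levels must be non-negative",
                 "petsime_invalid_parameter")
  dur <- schedule$frame_end - schedule$frame_start
  p <- ifelse(dur < short_threshold_s, short_frame, base)
  structure(p, label = attr(schedule, "label"), class = "noise_profile")
}

#' @rdname noise_profile
#' @param level flat relative SD for every frame.
#' @export
flat_noise_profile <- function(schedule, level = 0.05) {
  noise_profile(schedule, base = level, short_frame = level)
}

#' Noise profile from fit residuals
#'
#' Builds the measured noise profile used to drive simulations: for each
#' region and frame, the absolute residual between a measured TAC and its
#' model fit is normalized by the TAC's mean activity, then averaged across
#' subjects.
#'
#' @param observed,fitted lists (one element per subject) of lists of
#'   [tac()] objects (one per region, same regions and schedule
#'   throughout); `fitted` holds the model curves.
#' @return a named list of `noise_profile` vectors, one per region.
#' @export
residual_profile <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) == 0)
    stop_petsime("observed and fitted must be non-empty lists of equal length",
                 "petsime_invalid_tac")
  regions <- vapply(observed[[1]], `[[`, character(1), "region")
  sched <- observed[[1]][[1]]$schedule
  out <- setNames(vector("list", length(regions)), regions)
  for (j in seq_along(regions)) {
    acc <- matrix(NA_real_, length(observed), n_frames(sched))
    for (s in seq_along(observed)) {
      obs <- observed[[s]][[j]]
      fit <- fitted[[s]][[j]]
      if (n_frames(obs$schedule) != n_frames(sched))
        stop_petsime("schedules are not aligned across subjects",
                     "petsime_invalid_tac")
      m <- mean(obs$activity)
      if (m == 0)
        stop_petsime(sprintf("region '%s': mean activity is zero", obs$region),
                     "petsime_degenerate")
      acc[s, ] <- abs(obs$activity - fit$activity) / m
    }
    out[[j]] <- structure(colMeans(acc), label = attr(sched, "label"),
                          class = "noise_profile")
  }
  out
}

#' Add frame-wise Gaussian noise to a theoretical TAC
#'
#' Each frame receives independent Gaussian noise with standard deviation
#' `profile[i] * mean(activity)` — scaled to the TAC's mean activity, not
#' the frame's own value.  Negative results are kept (decay-corrected PET
#' frames can undershoot zero).  The caller's RNG state is left untouched.
#'
#' @param x a noiseless [tac()].
#' @param profile a `noise_profile` (or numeric vector, one value per
#'   frame).
#' @param seed integer seed; the same seed reproduces the noise exactly.
#' @return a noisy [tac()].
#' @export
add_noise <- function(x, profile, seed) {
  stopifnot(inherits(x, "tac"))
  p <- as.numeric(profile)
  if (length(p) != n_frames(x$schedule))
    stop_petsime("noise profile length must match the schedule",
                 "petsime_invalid_parameter")
  if (any(p < 0))
    stop_petsime("noise profile must be non-negative",
                 "petsime_invalid_parameter")
  sds <- p * mean(x$activity)
  eps <- with_local_seed(seed, rnorm(length(p), 0, 1)) * sds
  tac(x$region, x$schedule, x$activity + eps)
}

#' FEPPA-like simulation truth table
#'
#' Six-region ground truth emulating reported `[18F]`FEPPA kinetics: a
#' common `V_ND = 2.35 ml/cm^3` and regional total volumes
#' `V_T = 14.30, 15.16, 11.69, 11.80, 15.10, 13.80 ml/cm^3` (frontal,
#' temporal, cerebellum, thalamus, insula, caudate).  Rate constants are
#' back-derived with `k2 = 0.1 min^-1` and `k4 = 0.047 min^-1` fixed and
#' `k3 = k4 (V_T/V_ND - 1)`, so `K1 = k2 V_ND = 0.235`.
#'
#' @param V_ND common non-displaceable volume, ml/cm^3.
#' @param k2,k4 fixed rate constants, min^-1.
#' @param vB blood-volume fraction attached to the rates.
#' @return a data frame with columns `region`, `K1`, `k2`, `k3`, `k4`,
#'   `V_ND`, `V_T`, `V_S`, `BP_ND`, plus attribute `rates` (a named list of
#'   [rate_constants()]).
#' @export
feppa_truth <- function(V_ND = 2.35, k2 = 0.1, k4 = 0.047, vB = 0.05) {
  region <- c("frontal", "temporal", "cerebellum", "thalamus", "insula",
              "caudate")
  V_T <- c(14.30, 15.16, 11.69, 11.80, 15.10, 13.80)
  k3 <- k4 * (V_T / V_ND - 1)
  rates <- setNames(lapply(k3, function(k3r)
    rate_constants(k2 * V_ND, k2, k3r, k4, vB)), region)
  df <- data.frame(region = region, K1 = k2 * V_ND, k2 = k2, k3 = k3,
                   k4 = k4, V_ND = V_ND, V_T = V_T, V_S = V_T - V_ND,
                   BP_ND = (V_T - V_ND) / V_ND)
  attr(df, "rates") <- rates
  df
}

#' Monte Carlo parameter-recovery analysis for SIME
#'
#' Generates `n_reps` noisy multi-region datasets from a known truth, runs
#' the SIME joint fit on each, and summarizes the recovered `V_ND`, `V_T`,
#' `V_S` and `BP_ND` distributions: mean, SD, coefficient of variation
#' (`100 * SD / mean`), 25th/75th percentiles and relative bias
#' (`100 * (mean - truth) / truth`).
#'
#' Per-replicate noise seeds are drawn once from the master `seed`, so the
#' whole experiment is reproducible and any single replicate can be re-run
#' in isolation from its recorded seed.
#'
#' @param truth a named list of [rate_constants()] (one per region, all
#'   sharing `K1/k2`), or a data frame from [feppa_truth()].
#' @param input an [input_function()] spanning the schedule.
#' @param schedule a [frame_schedule()].
#' @param profile a `noise_profile` (applied to every region) or a named
#'   list of profiles per region.
#' @param n_reps number of replicates, `>= 2`.
#' @param seed master seed.
#' @param weights,vB,options passed to [sime_joint_fit()].
#' @param max_fail_frac abort if more than this fraction of replicates
#'   fails.
#' @return an object of class `recovery_stats`: `stats` (one row per
#'   region x parameter), `draws` (per-replicate estimates), `rep_seeds`,
#'   `n_failed`.
#' @export
monte_carlo_recovery <- function(truth, input, schedule, profile, n_reps,
                                 seed, weights = "none", vB = 0.05,
                                 options = sime_options(),
                                 max_fail_frac = 0.2) {
  if (n_reps < 2)
    stop_petsime("n_reps must be >= 2", "petsime_invalid_parameter")
  rates <- if (is.data.frame(truth)) attr(truth, "rates") else truth
  if (is.null(names(rates)) ||
      !all(vapply(rates, inherits, logical(1), "rate_constants")))
    stop_petsime("truth must be a named list of rate_constants (or feppa_truth())",
                 "petsime_invalid_parameter")
  regions <- names(rates)
  profs <- if (is.list(profile) && !inherits(profile, "noise_profile")) {
    if (!all(regions %in% names(profile)))
      stop_petsime("per-region profile list must cover every region",
                   "petsime_invalid_parameter")
    profile[regions]
  } else setNames(rep(list(profile), length(regions)), regions)

  theo <- lapply(regions, function(r)
    model_tac(rates[[r]], input, schedule, region = r,
              grid_dt_s = options$grid_dt_s))
  names(theo) <- regions
  true_dvs <- lapply(rates, derive_dvs)

  rep_seeds <- with_local_seed(seed,
                               sample.int(.Machine$integer.max, n_reps))
  draws <- vector("list", n_reps)
  n_failed <- 0L
  for (i in seq_len(n_reps)) {
    noisy <- lapply(regions, function(r)
      add_noise(theo[[r]], profs[[r]], rep_seeds[i] %% 2147483647L))
    res <- tryCatch(suppressWarnings(
      sime_joint_fit(noisy, input, weights, vB, options)),
      error = function(e) NULL)
    if (is.null(res) || res$failed) {
      n_failed <- n_failed + 1L
      next
    }
    df <- as.data.frame(res)
    df$rep <- i
    draws[[i]] <- df
  }
  if (n_failed > max_fail_frac * n_reps)
    stop_petsime(sprintf(
      "systematic fit failure: %d of %d replicates failed", n_failed, n_reps),
      "petsime_analysis_error")
  draws <- do.call(rbind, draws)

  summarize <- function(est, tru) {
    m <- mean(est)
    data.frame(truth = tru, mean = m, sd = sd(est),
               cov_pct = if (m > 0) 100 * sd(est) / m else NA_real_,
               q25 = unname(quantile(est, 0.25)),
               q75 = unname(quantile(est, 0.75)),
               bias_pct = 100 * (m - tru) / tru)
  }
  rows <- list()
  for (r in regions) {
    sub <- draws[draws$region == r, ]
    td <- true_dvs[[r]]
    for (p in c("V_ND", "V_T", "V_S", "BP_ND")) {
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(region = r, parameter = p),
              summarize(sub[[p]], td[[p]]))
    }
  }
  structure(list(stats = do.call(rbind, rows), draws = draws,
                 rep_seeds = rep_seeds, n_reps = n_reps,
                 n_failed = n_failed, seed = seed),
            class = "recovery_stats")
}

#' @export
print.recovery_stats <- function(x, ...) {
  cat(sprintf("<recovery_stats> %d replicates (%d failed), master seed %s\n",
              as.integer(x$n_reps), x$n_failed, format(x$seed)))
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}
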