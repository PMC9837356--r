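# CSV dialects
#
#   TAC file:   frame_start_s, frame_end_s, <one activity column per region>
#   blood file: time_min, whole_blood_kBq_ml, plasma_kBq_ml,
#               parent_fraction (may be empty), site
#   input file: time_min, whole_blood_kBq_ml, plasma_parent_kBq_ml

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_petsime(sprintf("%s: missing column(s) %s", path,
                         paste(missing, collapse = ", ")),
                 "petsime_parse_error")
}

check_numeric <- function(df, cols, path, allow_na = character(0)) {
  for (cl in cols) {
    v <- df[[cl]]
    bad <- if (cl %in% allow_na) which(!is.na(v) & !is.finite(v))
           else which(!is.finite(v))
    if (length(bad))
      stop_petsime(sprintf("%s: non-numeric value in column '%s', row %d",
                           path, cl, bad[1]),
                   "petsime_parse_error")
  }
}

#' Read and write regional TACs
#'
#' The TAC CSV carries the frame schedule in its first two columns
#' (`frame_start_s`, `frame_end_s`) and one activity column (kBq/ml) per
#' region; the header row carries the region names.
#'
#' @param path CSV file path.
#' @return `read_tacs()`: a named list of [tac()] objects sharing one
#'   schedule.
#' @export
read_tacs <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  require_columns(df, c("frame_start_s", "frame_end_s"), path)
  regions <- setdiff(names(df), c("frame_start_s", "frame_end_s"))
  if (length(regions) == 0)
    stop_petsime(sprintf("%s: no region columns", path), "petsime_parse_error")
  check_numeric(df, c("frame_start_s", "frame_end_s", regions), path)
  if (is.unsorted(df$frame_start_s, strictly = TRUE))
    stop_petsime(sprintf("%s: frame starts are not strictly increasing", path),
                 "petsime_parse_error")
  sched <- tryCatch(
    frame_schedule(df$frame_start_s, df$frame_end_s,
                   label = tools::file_path_sans_ext(basename(path))),
    error = function(e)
      stop_petsime(sprintf("%s: %s", path, conditionMessage(e)),
                   "petsime_parse_error"))
  setNames(lapply(regions, function(r) tac(r, sched, df[[r]])), regions)
}

#' @rdname read_tacs
#' @param tacs a named list of [tac()] objects sharing one schedule.
#' @export
write_tacs <- function(tacs, path) {
  sched <- tacs[[1]]$schedule
  df <- data.frame(frame_start_s = sched$frame_start,
                   frame_end_s = sched$frame_end)
  for (x in tacs) df[[x$region]] <- x$activity
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write blood-sample tables
#'
#' @param path CSV file path.
#' @return `read_blood()`: a [blood_samples()] data frame.
#' @export
read_blood <- function(path) {
  df <- read.csv(path)
  require_columns(df, c("time_min", "whole_blood_kBq_ml", "plasma_kBq_ml",
                        "parent_fraction", "site"), path)
  check_numeric(df, c("time_min", "whole_blood_kBq_ml", "plasma_kBq_ml",
                      "parent_fraction"), path,
                allow_na = "parent_fraction")
  tryCatch(
    blood_samples(df$time_min, df$whole_blood_kBq_ml, df$plasma_kBq_ml,
                  df$parent_fraction, df$site),
    error = function(e)
      stop_petsime(sprintf("%s: %s", path, conditionMessage(e)),
                   "petsime_parse_error"))
}

#' @rdname read_blood
#' @param samples a [blood_samples()] data frame.
#' @export
write_blood <- function(samples, path) {
  df <- data.frame(time_min = samples$time_min,
                   whole_blood_kBq_ml = samples$whole_blood,
                   plasma_kBq_ml = samples$plasma,
                   parent_fraction = samples$parent_fraction,
                   site = samples$site)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write input functions
#'
#' @param path CSV file path.
#' @param provenance provenance tag for the curve read.
#' @return `read_input()`: an [input_function()].
#' @export
read_input <- function(path, provenance = "AIF") {
  df <- read.csv(path)
  require_columns(df, c("time_min", "whole_blood_kBq_ml"), path)
  has_pp <- "plasma_parent_kBq_ml" %in% names(df)
  check_numeric(df, c("time_min", "whole_blood_kBq_ml",
                      if (has_pp) "plasma_parent_kBq_ml"), path)
  if (is.unsorted(df$time_min, strictly = TRUE))
    stop_petsime(sprintf("%s: times are not strictly increasing", path),
                 "petsime_parse_error")
  tryCatch(
    input_function(df$time_min, df$whole_blood_kBq_ml,
                   if (has_pp) df$plasma_parent_kBq_ml,
                   provenance = provenance),
    error = function(e)
      stop_petsime(sprintf("%s: %s", path, conditionMessage(e)),
                   "petsime_parse_error"))
}

#' @rdname read_input
#' @param input an [input_function()].
#' @export
write_input <- function(input, path) {
  df <- data.frame(time_min = input$time_min,
                   whole_blood_kBq_ml = input$whole_blood)
  if (!is.null(input$plasma_parent))
    df$plasma_parent_kBq_ml <- input$plasma_parent
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Assembles and validates the configuration driving
#' [run_quantification()].  `read_run_config()` loads it from JSON; CLI
#' flags or function arguments may override individual fields.
#'
#' @param tac_csv path to the regional TAC file.
#' @param input_csv path to the input-function file (whole blood, with or
#'   without a plasma-parent column).
#' @param blood_csv optional path to the blood-sample table (required to
#'   metabolite-correct or scale the input).
#' @param provenance `"AIF"` or `"IDIF"`; IDIFs are scaled to late venous
#'   samples.
#' @param vB blood-volume fraction in `[0, 1)`.
#' @param scan_duration_min fit duration; TACs are truncated to it.
#' @param weights SIME weights mode.
#' @param scaling_times_min venous scaling times for IDIFs.
#' @param seed integer seed recorded in the run record.
#' @param out_dir output directory (created if needed); `NULL` for no file
#'   output.
#' @param options a [sime_options()].
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(tac_csv, input_csv, blood_csv = NULL,
                       provenance = c("AIF", "IDIF"), vB = 0.05,
                       scan_duration_min = NULL, weights = "none",
                       scaling_times_min = c(45, 60, 90), seed = 1,
                       out_dir = NULL, options = sime_options()) {
  provenance <- match.arg(provenance)
  if (vB < 0 || vB >= 1)
    stop_petsime("vB must lie in [0, 1)", "petsime_invalid_parameter")
  if (!is.null(scan_duration_min) && scan_duration_min <= 0)
    stop_petsime("scan_duration_min must be positive",
                 "petsime_invalid_parameter")
  for (p in c(tac_csv, input_csv, blood_csv))
    if (!file.exists(p))
      stop_petsime(sprintf("file not found: %s", p), "petsime_parse_error")
  structure(list(tac_csv = tac_csv, input_csv = input_csv,
                 blood_csv = blood_csv, provenance = provenance, vB = vB,
                 scan_duration_min = scan_duration_min, weights = weights,
                 scaling_times_min = scaling_times_min, seed = seed,
                 out_dir = out_dir, options = options),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON configuration file.
#' @param ... overrides for individual fields.
#' @export
read_run_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("tac_csv", "input_csv", "blood_csv", "provenance", "vB",
             "scan_duration_min", "weights", "scaling_times_min", "seed",
             "out_dir")
  unknown <- setdiff(names(raw), c(known, "options"))
  if (length(unknown))
    stop_petsime(sprintf("%s: unknown config field(s) %s", path,
                         paste(unknown, collapse = ", ")),
                 "petsime_parse_error")
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$options))
    args$options <- do.call(sime_options, raw$options)
  over <- list(...)
  args[names(over)] <- over
  # resolve relative paths against the config's directory
  for (f in c("tac_csv", "input_csv", "blood_csv"))
    if (!is.null(args[[f]]) && !file.exists(args[[f]]))
      args[[f]] <- file.path(dirname(path), args[[f]])
  do.call(run_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_petsime(sprintf("%s: %s", name, conditionMessage(e)),
                 "petsime_stage_error")
  })
}

#' Full quantification pipeline
#'
#' Chains the minimally invasive workflow: fit the blood-to-plasma ratio
#' and Hill parent fraction from blood samples, scale the IDIF to late
#' venous samples (IDIF provenance only), metabolite-correct the
#' whole-blood curve, truncate the TACs to the requested duration, run the
#' SIME joint fit, and refit each region with the common `V_ND` fixed.
#' Results are written as a per-region parameter CSV and a JSON run record
#' when `out_dir` is set.
#'
#' @param config a [run_config()].
#' @return a list of class `quant_report`: `sime`, `refits`, `table`,
#'   `input`, `bpr`, `hill`, `config`, `files`.
#' @export
run_quantification <- function(config) {
  stopifnot(inherits(config, "run_config"))
  message("reading inputs")
  tacs <- stage("read_tacs", read_tacs(config$tac_csv))
  input <- stage("read_input",
                 read_input(config$input_csv, config$provenance))
  blood <- if (!is.null(config$blood_csv))
    stage("read_blood", read_blood(config$blood_csv))

  bpr <- hill <- NULL
  if (config$provenance == "IDIF") {
    if (is.null(blood))
      stop_petsime("scale_idif: no venous samples (blood_csv missing)",
                   "petsime_stage_error")
    message("scaling IDIF to venous samples")
    input <- stage("scale_idif",
                   scale_idif(input, blood, config$scaling_times_min))
  }
  if (is.null(input$plasma_parent)) {
    if (is.null(blood))
      stop_petsime("metabolite_correct: no blood samples (blood_csv missing)",
                   "petsime_stage_error")
    message("fitting blood models and metabolite-correcting")
    bpr <- stage("fit_bpr", fit_bpr(blood))
    hill <- stage("fit_parent_fraction", fit_parent_fraction(blood))
    input <- stage("metabolite_correct", metabolite_correct(input, bpr, hill))
  }
  if (!is.null(config$scan_duration_min)) {
    message(sprintf("truncating TACs to %g min", config$scan_duration_min))
    tacs <- stage("truncate_tac",
                  lapply(tacs, truncate_tac, config$scan_duration_min))
  }
  message(sprintf("SIME joint fit over %d regions", length(tacs)))
  sime <- stage("sime_joint_fit",
                sime_joint_fit(tacs, input, config$weights, config$vB,
                               config$options))
  if (sime$failed)
    stop_petsime(sprintf("sime_joint_fit: %s", sime$failure_reason),
                 "petsime_fit_failure")
  message(sprintf("common V_ND = %.3f ml/cm3; refitting regions",
                  sime$V_ND_common))
  refits <- stage("refit_fixed_vnd",
                  lapply(tacs, refit_fixed_vnd, input = input,
                         V_ND = sime$V_ND_common, vB = config$vB,
                         options = config$options))
  tab <- as.data.frame(sime)

  files <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files$parameters <- file.path(config$out_dir, "sime_parameters.csv")
    write.csv(tab, files$parameters, row.names = FALSE)
    files$run_record <- file.path(config$out_dir, "run_record.json")
    rec <- list(config = unclass(config)[setdiff(names(config),
                                                 c("options"))],
                options = unclass(config$options),
                weights_mode = sime$weights_mode,
                V_ND_common = sime$V_ND_common,
                total_cost = sime$total_cost,
                idif_scale = attr(input, "scale_factor"),
                package_version = as.character(packageVersion("petsime")),
                r_version = R.version.string)
    jsonlite::write_json(rec, files$run_record, auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  }
  structure(list(sime = sime, refits = refits, table = tab, input = input,
                 bpr = bpr, hill = hill, config = config, files = files),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report>\n")
  print(x$sime)
  invisible(x)
}
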