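#' Run the command-line pipeline
#'
#' Programmatic entry point behind the `inst/cli/pdmsdose.R` script. The
#' first element of `args` selects a subcommand; the rest are `--flag value`
#' pairs:
#'
#' * `synth` — generate a synthetic membrane dataset
#'   (`--chemical --seed --noise-cv --replicates --out`);
#' * `fit` — fit every DMSO fraction in a series CSV and extrapolate to zero
#'   DMSO (`--series --out [--seed]`), writing a parameter table CSV and a
#'   JSON report;
#' * `simulate-membrane` — forward-model a membrane experiment
#'   (`--chemical --dmso --t-end-h --out`);
#' * `simulate-channel` — pulse/circadian channel run
#'   (`--chemical --geometry <preset or config file> --schedule
#'   pulse:c0,t_on,t_off | circadian:mean,amp,acrophase | constant:c0`
#'   `--flow-rate-ul-min --t-end-h --out [--quasi-steady]
#'   [--equilibrium-interface]`), writing the time-series CSV and a metrics
#'   JSON;
#' * `report` — summarize a metrics JSON (`--metrics`).
#'
#' Every output directory receives a `manifest.json` recording the package
#' version, the parsed configuration and the seed, sufficient to re-run the
#' job.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, an integer exit status: 0 success, 2 usage/config
#'   error, 3 validation error, 4 solver failure.
#' @export
run_pipeline <- function(args = character()) {
  status <- tryCatch({
    if (!length(args)) stop_usage("no subcommand given (synth | fit | simulate-membrane | simulate-channel | report)")
    cmd <- args[1]
    opts <- parse_flags(args[-1])
    switch(cmd,
      "synth" = cmd_synth(opts),
      "fit" = cmd_fit(opts),
      "simulate-membrane" = cmd_sim_membrane(opts),
      "simulate-channel" = cmd_sim_channel(opts),
      "report" = cmd_report(opts),
      stop_usage("unknown subcommand: ", cmd))
    0L
  },
  pdmsdose_usage_error = function(e) { message("usage error: ", conditionMessage(e)); 2L },
  pdmsdose_validation_error = function(e) { message("validation error: ", conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 4L })
  invisible(status)
}

stop_usage <- function(...) {
  stop(structure(class = c("pdmsdose_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
stop_validation <- function(...) {
  stop(structure(class = c("pdmsdose_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_usage("expected a --flag, got: ", a)
    key <- substring(a, 3)
    if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE   # bare switch
      i <- i + 1L
    }
  }
  opts
}

opt_num <- function(opts, key, default = NULL) {
  v <- opts[[key]]
  if (is.null(v)) {
    if (is.null(default)) stop_usage("missing required flag --", key)
    return(default)
  }
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop_usage("--", key, " must be numeric, got: ", v)
  x
}

opt_chr <- function(opts, key, default = NULL) {
  v <- opts[[key]]
  if (is.null(v)) {
    if (is.null(default)) stop_usage("missing required flag --", key)
    return(default)
  }
  as.character(v)
}

resolve_chemical <- function(opts) {
  if (!is.null(opts[["params-file"]])) {
    path <- opts[["params-file"]]
    if (!file.exists(path)) stop_usage("params file not found: ", path)
    return(read_chemical_config(path))
  }
  name <- opt_chr(opts, "chemical")
  if (!name %in% list_chemicals()) {
    stop_usage("unknown bundled chemical '", name, "'; bundled names: ",
               paste(list_chemicals(), collapse = ", "))
  }
  chemical(name)
}

resolve_device <- function(opts) {
  geom <- opt_chr(opts, "geometry", "bioreactor")
  q <- opt_num(opts, "flow-rate-ul-min", 0)
  if (geom %in% c("bioreactor", "regehr")) {
    device_preset(geom, flow_rate_ul_min = q)
  } else {
    if (!file.exists(geom)) stop_usage("geometry file not found: ", geom)
    dev <- read_device_config(geom)
    dev$flow_rate_ul_min <- q
    dev
  }
}

resolve_schedule <- function(opts) {
  spec <- opt_chr(opts, "schedule", "constant:1")
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  nums <- if (length(parts) > 1) as.numeric(strsplit(parts[2], ",")[[1]]) else numeric()
  if (any(is.na(nums))) stop_usage("malformed schedule spec: ", spec)
  switch(parts[1],
    constant = schedule_constant(nums[1] %||% 1),
    pulse = schedule_pulse(nums[1], nums[2] %||% 0, nums[3] %||% 1),
    circadian = circadian_schedule(mean = nums[1], amplitude = nums[2],
                                   acrophase = nums[3] %||% 0,
                                   period = nums[4] %||% 24),
    stop_usage("unknown schedule variant: ", parts[1]))
}

out_dir <- function(opts) {
  d <- opt_chr(opts, "out")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_manifest <- function(dir, cmd, config, seed = NA) {
  jsonlite::write_json(
    list(tool = "pdmsdose",
         version = as.character(utils::packageVersion("pdmsdose")),
         subcommand = cmd, config = config, seed = seed),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE, na = "null")
}

cmd_synth <- function(opts) {
  params <- resolve_chemical(opts)
  seed <- as.integer(opt_num(opts, "seed", 1))
  noise_cv <- opt_num(opts, "noise-cv", 0.05)
  replicates <- as.integer(opt_num(opts, "replicates", 3))
  dir <- out_dir(opts)
  dat <- generate_membrane_dataset(params, noise_cv = noise_cv,
                                   replicates = replicates, seed = seed)
  write_series_csv(dat, file.path(dir, "series.csv"))
  write_manifest(dir, "synth", c(attr(dat, "manifest"),
                                 list(chemical = params$name)), seed)
  message("wrote ", file.path(dir, "series.csv"))
}

cmd_fit <- function(opts) {
  path <- opt_chr(opts, "series")
  if (!file.exists(path)) stop_usage("series file not found: ", path)
  series <- tryCatch(read_series_csv(path),
                     error = function(e) stop_validation(conditionMessage(e)))
  if (!"fraction_dmso" %in% names(series)) series$fraction_dmso <- 0
  dir <- out_dir(opts)
  assembly <- membrane_assembly()
  fractions <- sort(unique(series$fraction_dmso))
  fit_ctrl <- fit_control(n_starts = as.integer(opt_num(opts, "starts", 1)))
  fits <- lapply(fractions, function(f) {
    asm <- assembly
    asm$composition <- solution_composition(f)
    fit_membrane_experiment(series[series$fraction_dmso == f, ], asm,
                            control = fit_ctrl)
  })
  tab <- do.call(rbind, lapply(seq_along(fractions), function(i) {
    est <- fits[[i]]$estimates
    data.frame(fraction_dmso = fractions[i],
               log_kps = est$estimate[1], log_kps_se = est$se[1],
               log_dp = est$estimate[2], log_dp_se = est$se[2],
               log_h = if (fits[[i]]$h_is_lower_bound)
                 fits[[i]]$h_lower_bound else est$estimate[3],
               h_is_lower_bound = fits[[i]]$h_is_lower_bound,
               log_ds_eff = est$estimate[4], log_ds_eff_se = est$se[4],
               ssr = fits[[i]]$ssr)
  }))
  utils::write.csv(tab, file.path(dir, "parameters.csv"), row.names = FALSE)
  report <- list(parameter_table = tab)
  if (length(fractions) >= 2L) {
    pts <- data.frame(fraction = tab$fraction_dmso, log_kps = tab$log_kps,
                      se = tab$log_kps_se)
    if (any(!is.finite(pts$se)) || any(pts$se <= 0)) pts$se <- NULL
    ex <- extrapolate_partition(pts)
    report$extrapolation <- list(log_kpw = ex$log_kpw, se_log_kpw = ex$se_log_kpw,
                                 log_kpd = ex$log_kpd, se_log_kpd = ex$se_log_kpd)
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null", force = TRUE)
  write_manifest(dir, "fit", list(series = path), opts[["seed"]] %||% NA)
  message("wrote ", file.path(dir, "parameters.csv"))
}

cmd_sim_membrane <- function(opts) {
  params <- resolve_chemical(opts)
  dmso <- opt_num(opts, "dmso", 0)
  t_end <- opt_num(opts, "t-end-h", 24)
  dir <- out_dir(opts)
  asm <- membrane_assembly(dmso_fraction = dmso)
  st <- simulate_membrane(asm, params,
                          sample_times = unique(sort(c(seq(0, t_end, length.out = 49L)))))
  out <- st$series
  out$fraction_dmso <- dmso
  out$replicate <- 1L
  write_series_csv(out, file.path(dir, "series.csv"))
  write_manifest(dir, "simulate-membrane",
                 list(chemical = params$name, dmso = dmso, t_end_h = t_end))
  message("wrote ", file.path(dir, "series.csv"))
}

cmd_sim_channel <- function(opts) {
  params <- resolve_chemical(opts)
  device <- resolve_device(opts)
  schedule <- resolve_schedule(opts)
  t_end <- opt_num(opts, "t-end-h", 4)
  mesh <- as.integer(opt_num(opts, "mesh", 45))
  ctrl <- channel_control(nx = mesh,
                          quasi_steady = isTRUE(opts[["quasi-steady"]]),
                          equilibrium_interface = isTRUE(opts[["equilibrium-interface"]]),
                          dt_h = opt_num(opts, "dt-h", 0.002))
  dir <- out_dir(opts)
  res <- simulate_channel(device, params, schedule, t_end, ctrl)
  utils::write.csv(
    res$series[, c("time_h", "avg_channel_conc", "outlet_conc",
                   "delivered_mass", "delivered_mass_avg")],
    file.path(dir, "timeseries.csv"), row.names = FALSE)
  metrics <- dose_metrics(res)
  write_metrics_json(metrics, file.path(dir, "metrics.json"))
  write_manifest(dir, "simulate-channel",
                 list(chemical = params$name, geometry = unclass(device),
                      schedule = unclass(schedule), t_end_h = t_end,
                      quasi_steady = ctrl$quasi_steady,
                      equilibrium_interface = ctrl$equilibrium_interface))
  message("wrote ", file.path(dir, "metrics.json"))
}

cmd_report <- function(opts) {
  path <- opt_chr(opts, "metrics")
  if (!file.exists(path)) stop_usage("metrics file not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- c(pulse_depletion_percent = "pulse depletion",
              post_pulse_release_percent = "post-pulse release",
              delivered_fraction_percent = "delivered fraction of targeted exposure",
              outlet_bioavailability_percent = "outlet bioavailability",
              phase_shift_h = "phase shift (h)")
  for (k in names(fields)) {
    if (!is.null(m[[k]]) && !is.na(m[[k]])) {
      message(sprintf("%-42s %8.3g", fields[[k]], m[[k]]))
    }
  }
}
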