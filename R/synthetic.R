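#' Generate synthetic membrane-experiment datasets with known ground truth
#'
#' Emulates a diffusion-through-membrane study: for each DMSO volume
#' fraction, the partition coefficient follows the log-linear mixing law,
#' the forward membrane model produces noiseless source/sink concentration
#' time courses, and multiplicative log-normal measurement noise of the
#' requested coefficient of variation is applied per observation and
#' replicate. The draw is a pure function of its inputs and the seed.
#'
#' Defaults mirror the emulated study conditions: two 300-uL chambers across
#' an 80-um membrane, sampling at 0, 1, 2, 4, 8, 12 and 24 h, DMSO fractions
#' of 5-30%, 5% CV noise, three replicates.
#'
#' @param params True [chemical_params()] of the chemical.
#' @param assembly A [membrane_assembly()] template (its DMSO fraction is
#'   replaced by each element of `fractions`).
#' @param fractions DMSO volume fractions to simulate.
#' @param sample_times Sampling times, h.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise (>= 0; 0 reproduces the forward model exactly).
#' @param replicates Number of replicate series per fraction (>= 1).
#' @param seed Integer seed; records itself in the output manifest.
#' @param ds_eff An [effective_ds()] used as the stirred-chamber effective
#'   diffusivity truth.
#' @param control A [membrane_control()] for the forward solves.
#' @return A tibble with columns `time_h`, `compartment`, `concentration`,
#'   `fraction_dmso`, `replicate`, carrying a `"manifest"` attribute that
#'   records the truth parameters, noise model and seed.
#' @export
#' @examples
#' d <- generate_membrane_dataset(chemical("estradiol"), membrane_assembly(),
#'                                fractions = c(0.1, 0.3), replicates = 2,
#'                                noise_cv = 0.05, seed = 1)
#' attr(d, "manifest")$seed
generate_membrane_dataset <- function(params,
                                      assembly = membrane_assembly(),
                                      fractions = c(0.05, 0.10, 0.20, 0.30),
                                      sample_times = c(0, 1, 2, 4, 8, 12, 24),
                                      noise_cv = 0.05,
                                      replicates = 3L,
                                      seed = 1L,
                                      ds_eff = effective_ds(0.7),
                                      control = membrane_control()) {
  stopifnot(inherits(params, "chemical_params"),
            inherits(assembly, "membrane_assembly"))
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (replicates < 1L) stop("replicates must be >= 1")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  sigma <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  out <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    asm <- assembly
    asm$composition <- solution_composition(fractions[i])
    st <- simulate_membrane(asm, params, ds_eff = ds_eff,
                            sample_times = sample_times, control = control)
    base <- st$series
    reps <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      conc <- base$concentration
      if (sigma > 0) {
        fac <- exp(stats::rnorm(length(conc), -sigma^2 / 2, sigma))
        conc <- pmax(conc * fac, 0)
      }
      reps[[r]] <- tibble::tibble(
        time_h = base$time_h, compartment = base$compartment,
        concentration = conc, fraction_dmso = fractions[i],
        replicate = r)
    }
    out[[i]] <- do.call(rbind, reps)
  }
  res <- do.call(rbind, out)
  attr(res, "manifest") <- list(
    truth = unclass(params),
    log_ds_eff = ds_eff$log_ds_eff,
    assembly = unclass(assembly)[c("source_volume_ul", "sink_volume_ul",
                                   "membrane_thickness_mm", "area_mm2",
                                   "c0_source", "c0_sink")],
    fractions = fractions, sample_times = sample_times,
    noise = list(type = "lognormal_multiplicative", cv = noise_cv),
    replicates = replicates, seed = seed)
  res
}

#' End-to-end parameter recovery on synthetic data
#'
#' Convenience driver for the full inverse pipeline: generate a synthetic
#' dataset for a known truth, fit each DMSO fraction independently, and
#' extrapolate the fitted `log10 K_PS` values to zero DMSO. Used by the
#' recovery test suites and the pipeline `fit` subcommand.
#'
#' @inheritParams generate_membrane_dataset
#' @param fit_ctrl A [fit_control()].
#' @return A list with the per-fraction `fits`, the `extrapolation`, and the
#'   generating `manifest`.
#' @export
recover_partition_parameters <- function(params,
                                         assembly = membrane_assembly(),
                                         fractions = c(0.05, 0.10, 0.20, 0.30),
                                         sample_times = c(0, 1, 2, 4, 8, 12, 24),
                                         noise_cv = 0.05, replicates = 3L,
                                         seed = 1L,
                                         ds_eff = effective_ds(0.7),
                                         fit_ctrl = fit_control()) {
  dat <- generate_membrane_dataset(params, assembly, fractions, sample_times,
                                   noise_cv, replicates, seed, ds_eff,
                                   control = fit_ctrl$sim_control)
  fits <- lapply(fractions, function(f) {
    asm <- assembly
    asm$composition <- solution_composition(f)
    sub <- dat[dat$fraction_dmso == f, ]
    fit_membrane_experiment(sub, asm, control = fit_ctrl)
  })
  pts <- do.call(rbind, lapply(seq_along(fractions), function(i) {
    est <- fits[[i]]$estimates
    data.frame(fraction = fractions[i],
               log_kps = est$estimate[est$parameter == "log_kps"],
               se = est$se[est$parameter == "log_kps"])
  }))
  if (any(!is.finite(pts$se)) || any(pts$se <= 0)) pts$se <- NULL
  extr <- extrapolate_partition(pts)
  list(fits = fits, extrapolation = extr, data = dat,
       manifest = attr(dat, "manifest"))
}
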