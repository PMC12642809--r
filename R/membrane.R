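#' Two-chamber diffusion-through-membrane assembly
#'
#' Geometry and initial state of a diffusion-through-membrane experiment:
#' two finite liquid chambers separated by a thin PDMS membrane. The default
#' dimensions describe the bundled experimental fixture: two 300-uL chambers
#' either side of an 80-um membrane with a 38.5 mm^2 exposed circular opening
#' (7 mm diameter). The exposed interface area is an explicit, required part
#' of the geometry because fitted parameters are reported per assembly.
#'
#' @param source_volume_ul,sink_volume_ul Chamber volumes, uL (= mm^3).
#' @param membrane_thickness_mm Membrane thickness L, mm.
#' @param area_mm2 Exposed membrane area A, mm^2.
#' @param c0_source,c0_sink Initial concentrations (arbitrary units, >= 0).
#' @param dmso_fraction DMSO volume fraction of both chambers, in \[0, 1\].
#' @return An object of class `membrane_assembly`.
#' @export
membrane_assembly <- function(source_volume_ul = 300, sink_volume_ul = 300,
                              membrane_thickness_mm = 0.08, area_mm2 = 38.5,
                              c0_source = 1, c0_sink = 0, dmso_fraction = 0) {
  if (source_volume_ul <= 0 || sink_volume_ul <= 0 ||
      membrane_thickness_mm <= 0 || area_mm2 <= 0) {
    stop("volumes, membrane thickness and area must all be positive")
  }
  if (c0_source < 0 || c0_sink < 0) stop("initial concentrations must be >= 0")
  comp <- solution_composition(dmso_fraction)
  structure(
    list(source_volume_ul = source_volume_ul, sink_volume_ul = sink_volume_ul,
         membrane_thickness_mm = membrane_thickness_mm, area_mm2 = area_mm2,
         source_depth_mm = source_volume_ul / area_mm2,
         sink_depth_mm = sink_volume_ul / area_mm2,
         c0_source = c0_source, c0_sink = c0_sink, composition = comp),
    class = "membrane_assembly")
}

#' @export
print.membrane_assembly <- function(x, ...) {
  cat("<membrane_assembly>\n")
  cat(sprintf("  chambers: %.4g / %.4g uL (depths %.3g / %.3g mm), A = %.4g mm^2\n",
              x$source_volume_ul, x$sink_volume_ul, x$source_depth_mm,
              x$sink_depth_mm, x$area_mm2))
  cat(sprintf("  membrane: %.3g mm thick; DMSO fraction %.3g\n",
              x$membrane_thickness_mm, x$composition$dmso_fraction))
  invisible(x)
}

#' Solver options for the membrane forward model
#'
#' @param n_chamber Cells per chamber (chambers-as-diffusive-layers mode).
#' @param n_membrane Cells across the membrane (>= 20 recommended at default
#'   resolution; fewer is allowed for fast inner-loop fitting).
#' @param dt_h Implicit-Euler time step, h.
#' @param well_mixed If `TRUE`, chambers are single well-mixed compartments
#'   (used for closed-form oracle checks); the default resolves chamber
#'   gradients with the effective diffusivity, matching how imperfectly
#'   mixed chambers behave.
#' @return A list of class `membrane_control`.
#' @export
membrane_control <- function(n_chamber = 15L, n_membrane = 21L, dt_h = 0.02,
                             well_mixed = FALSE) {
  if (n_chamber < 1L || n_membrane < 1L || dt_h <= 0) {
    stop("mesh sizes and time step must be positive")
  }
  structure(list(n_chamber = as.integer(n_chamber),
                 n_membrane = as.integer(n_membrane),
                 dt_h = dt_h, well_mixed = isTRUE(well_mixed)),
            class = "membrane_control")
}

# Core 1-D composite solver working on linear-scale parameters.
# Domains: source chamber | membrane | sink chamber, per unit area of
# exposed membrane (masses are per-area times A). `h = 0` makes both
# interfaces impermeable. Returns sampled chamber averages plus final
# profiles and a mass ledger.
.membrane_run <- function(assembly, kps, dp, h, ds_eff, sample_times,
                          control = membrane_control()) {
  L1 <- assembly$source_depth_mm
  L2 <- assembly$sink_depth_mm
  Lm <- assembly$membrane_thickness_mm
  A <- assembly$area_mm2
  impermeable <- (h == 0) || (kps == 0)

  if (control$well_mixed) {
    n1 <- n2 <- 1L
  } else {
    n1 <- n2 <- control$n_chamber
  }
  nm <- control$n_membrane
  dz1 <- rep(L1 / n1, n1)
  dzm <- rep(Lm / nm, nm)
  dz2 <- rep(L2 / n2, n2)
  caps <- c(dz1, dzm, dz2)
  n <- length(caps)
  i1 <- seq_len(n1)                   # source cells, interface cell = n1
  im <- n1 + seq_len(nm)              # membrane cells
  i2 <- n1 + nm + seq_len(n2)         # sink cells, interface cell = first

  # For well-mixed chambers the solution-side half-cell resistance is not a
  # physical transport resistance; drop it so the interface is governed by
  # H and the membrane half-cell alone.
  dz_s1 <- if (control$well_mixed) 0 else dz1[n1]
  dz_s2 <- if (control$well_mixed) 0 else dz2[1]
  g1 <- if (impermeable) 0 else
    interface_conductance(h, kps, ds_eff, dz_s1, dp, dzm[1])
  g2 <- if (impermeable) 0 else
    interface_conductance(h, kps, ds_eff, dz_s2, dp, dzm[nm])

  A_op <- matrix(0, n, n)
  add_pair <- function(M, i, j, g) {
    # symmetric diffusive exchange, flux = g (c_j - c_i)
    M[i, i] <- M[i, i] - g / caps[i]; M[i, j] <- M[i, j] + g / caps[i]
    M[j, j] <- M[j, j] - g / caps[j]; M[j, i] <- M[j, i] + g / caps[j]
    M
  }
  if (n1 > 1) for (k in 1:(n1 - 1)) {
    A_op <- add_pair(A_op, i1[k], i1[k + 1], ds_eff / dz1[1])
  }
  if (n2 > 1) for (k in 1:(n2 - 1)) {
    A_op <- add_pair(A_op, i2[k], i2[k + 1], ds_eff / dz2[1])
  }
  if (!impermeable) {
    if (nm > 1) for (k in 1:(nm - 1)) {
      A_op <- add_pair(A_op, im[k], im[k + 1], dp / dzm[1])
    }
    # Interfaces: J = g (K c_S - c_P), positive into the membrane.
    s <- i1[n1]; p <- im[1]
    A_op[s, s] <- A_op[s, s] - g1 * kps / caps[s]
    A_op[s, p] <- A_op[s, p] + g1 / caps[s]
    A_op[p, p] <- A_op[p, p] - g1 / caps[p]
    A_op[p, s] <- A_op[p, s] + g1 * kps / caps[p]
    s <- i2[1]; p <- im[nm]
    A_op[s, s] <- A_op[s, s] - g2 * kps / caps[s]
    A_op[s, p] <- A_op[s, p] + g2 / caps[s]
    A_op[p, p] <- A_op[p, p] - g2 / caps[p]
    A_op[p, s] <- A_op[p, s] + g2 * kps / caps[p]
  }

  t_end <- max(sample_times)
  dt <- control$dt_h
  n_steps <- max(1L, ceiling(t_end / dt - 1e-9))
  dt <- t_end / n_steps
  P <- implicit_propagator(A_op, dt)

  u <- c(rep(assembly$c0_source, n1), rep(0, nm), rep(assembly$c0_sink, n2))
  t_grid <- seq(0, t_end, by = dt)
  src <- snk <- mem <- total_mass <- numeric(n_steps + 1L)
  wm1 <- dz1 / sum(dz1); wmm <- dzm / sum(dzm); wm2 <- dz2 / sum(dz2)
  record <- function(k, u) {
    src[k] <<- sum(u[i1] * wm1)
    snk[k] <<- sum(u[i2] * wm2)
    mem[k] <<- sum(u[im] * wmm)
    total_mass[k] <<- A * sum(u * caps)
  }
  record(1L, u)
  for (k in seq_len(n_steps)) {
    u <- drop(P %*% u)
    record(k + 1L, u)
  }

  list(time_grid = t_grid,
       source = interp_series(t_grid, src, sample_times),
       sink = interp_series(t_grid, snk, sample_times),
       source_grid = src, sink_grid = snk,
       sample_times = sample_times,
       membrane_profile = list(x_mm = cumsum(dzm) - dzm / 2, c_p = u[im]),
       chamber_profiles = list(
         source = list(x_mm = cumsum(dz1) - dz1 / 2, c_s = u[i1]),
         sink = list(x_mm = cumsum(dz2) - dz2 / 2, c_s = u[i2])),
       mass = total_mass,
       mass_drift = max(abs(total_mass - total_mass[1])) /
         max(total_mass[1], .Machine$double.eps))
}

#' Simulate a diffusion-through-membrane experiment
#'
#' Forward model of the two-chamber experiment: diffusion in each chamber
#' (at the effective stirred-chamber diffusivity), diffusion across the PDMS
#' membrane, and partition-driven interfacial flux `J = H (K_PS c_S - c_P)`
#' at both solution-PDMS interfaces (flux continuity holds by construction
#' of the conservative scheme). K_PS is derived from the chemical's
#' partition parameters and the assembly's DMSO fraction via the log-linear
#' mixing law, unless overridden.
#'
#' @param assembly A [membrane_assembly()].
#' @param params A [chemical_params()] object. Non-interacting chemicals
#'   yield an impermeable membrane (source stays put, sink stays empty).
#' @param ds_eff An [effective_ds()] giving the stirred-chamber effective
#'   solution diffusivity; defaults to the chemical's ideal `log_ds`.
#' @param sample_times Increasing times (h) at which concentrations are
#'   reported.
#' @param control A [membrane_control()].
#' @param override Optional named list overriding linear-scale solver inputs
#'   (`kps`, `dp`, `h`, `ds_eff`); used by the fitting routines and for
#'   impermeable-wall checks (`h = 0`).
#' @return An object of class `membrane_state`: a tibble of sampled
#'   source/sink concentrations (`$series`), final membrane and chamber
#'   profiles, and a mass ledger with the relative conservation drift.
#' @export
#' @examples
#' asm <- membrane_assembly(dmso_fraction = 0.3)
#' st <- simulate_membrane(asm, chemical("progesterone"),
#'                         sample_times = c(0, 1, 2, 4, 8, 12, 24))
#' st$series
simulate_membrane <- function(assembly, params,
                              ds_eff = NULL,
                              sample_times = c(0, 1, 2, 4, 8, 12, 24),
                              control = membrane_control(),
                              override = list()) {
  stopifnot(inherits(assembly, "membrane_assembly"),
            inherits(params, "chemical_params"))
  if (is.unsorted(sample_times, strictly = TRUE) || any(sample_times < 0)) {
    stop("sample_times must be strictly increasing and nonnegative")
  }
  if (max(sample_times) <= 0) stop("need a positive time horizon")

  if (params$interacting) {
    kps <- kps_from_fraction(params, assembly$composition)
    dp <- 10^params$log_dp
    h <- 10^params$log_h
  } else {
    kps <- 0; dp <- NA_real_; h <- 0
  }
  ds <- if (!is.null(ds_eff)) {
    stopifnot(inherits(ds_eff, "effective_ds"))
    10^ds_eff$log_ds_eff
  } else 10^params$log_ds
  for (nm in names(override)) {
    switch(nm, kps = {kps <- override$kps}, dp = {dp <- override$dp},
           h = {h <- override$h}, ds_eff = {ds <- override$ds_eff},
           stop("unknown override field: ", nm))
  }
  if (h > 0 && (!is.finite(dp) || dp <= 0)) stop("permeable membrane needs dp > 0")
  if (ds <= 0) stop("solution diffusivity must be positive")

  run <- .membrane_run(assembly, kps, dp, h, ds, sample_times, control)
  if (run$mass_drift > 1e-6) {
    stop(sprintf("mass conservation drift %.3g exceeds solver tolerance", run$mass_drift))
  }
  series <- tibble::tibble(
    time_h = rep(sample_times, 2L),
    compartment = rep(c("source", "sink"), each = length(sample_times)),
    concentration = c(run$source, run$sink))
  structure(
    list(series = series, assembly = assembly,
         params = list(kps = kps, dp = dp, h = h, ds_eff = ds),
         time_grid = run$time_grid, source_grid = run$source_grid,
         sink_grid = run$sink_grid,
         membrane_profile = run$membrane_profile,
         chamber_profiles = run$chamber_profiles,
         mass = run$mass, mass_drift = run$mass_drift),
    class = "membrane_state")
}

#' @export
print.membrane_state <- function(x, ...) {
  cat("<membrane_state>\n")
  print(x$series, n = 6)
  cat(sprintf("  mass drift: %.2e (relative)\n", x$mass_drift))
  invisible(x)
}

#' Closed-form partition equilibrium of the closed two-chamber system
#'
#' At long times the closed assembly equilibrates with a common solution
#' concentration `c_eq` in both chambers and `K_PS * c_eq` in the membrane,
#' so mass balance gives
#' `c_eq * (V_src + V_snk + K_PS * A * L) = c0_src * V_src + c0_snk * V_snk`.
#' Used as an analytic oracle for the finite-volume solver.
#'
#' @param assembly A [membrane_assembly()].
#' @param kps Linear-scale partition coefficient K_PS (>= 0).
#' @return A list with `c_eq` and the equilibrium mass fractions in source,
#'   sink and membrane.
#' @export
#' @examples
#' equilibrium_concentrations(membrane_assembly(), kps = 0)
equilibrium_concentrations <- function(assembly, kps) {
  stopifnot(inherits(assembly, "membrane_assembly"))
  if (!is.numeric(kps) || length(kps) != 1L || !is.finite(kps) || kps < 0) {
    stop("kps must be a single nonnegative number")
  }
  Vs <- assembly$source_volume_ul
  Vk <- assembly$sink_volume_ul
  Vm_eff <- kps * assembly$area_mm2 * assembly$membrane_thickness_mm
  m0 <- assembly$c0_source * Vs + assembly$c0_sink * Vk
  c_eq <- m0 / (Vs + Vk + Vm_eff)
  list(c_eq = c_eq,
       mass_fractions = c(source = c_eq * Vs / m0,
                          sink = c_eq * Vk / m0,
                          membrane = c_eq * Vm_eff / m0))
}
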