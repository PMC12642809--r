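#' Chemical-PDMS transport parameter set
#'
#' Bundles the five parameters that govern partition-diffusion transport of a
#' dissolved chemical in a PDMS device: the PDMS-water and PDMS-DMSO partition
#' coefficients (as log10), the diffusivity in PDMS, the ideal diffusivity in
#' solution, and the interfacial mass-transfer coefficient. All rates use the
#' package's canonical units: mm, hours, mm^2/h, mm/h.
#'
#' A chemical may be marked *non-interacting* (`interacting = FALSE`), in
#' which case it neither partitions into nor diffuses through PDMS and the
#' solution-PDMS interface is treated as impermeable. This is represented
#' explicitly rather than as a K -> 0 limit so that solvers can skip
#' ill-conditioned PDMS solves.
#'
#' @param name Chemical name (character scalar).
#' @param log_kpw log10 PDMS-water partition coefficient K_PW (dimensionless).
#' @param log_kpd log10 PDMS-DMSO partition coefficient K_PD (dimensionless).
#' @param log_dp log10 diffusivity in PDMS, mm^2/h.
#' @param log_ds log10 ideal diffusivity in solution, mm^2/h.
#' @param log_h log10 interfacial mass-transfer coefficient H, mm/h.
#' @param h_is_lower_bound Logical; `TRUE` when `log_h` is a non-rate-limiting
#'   lower bound rather than a point estimate.
#' @param interacting Logical; `FALSE` for chemicals that do not detectably
#'   partition into PDMS (the interface is then impermeable and the
#'   PDMS-side parameters must be `NA`).
#'
#' @return An object of class `chemical_params`.
#' @seealso [chemical()] for bundled steroid-hormone parameter sets,
#'   [kps_from_fraction()] for the cosolvent mixing law.
#' @export
#' @examples
#' estradiol <- chemical_params("estradiol",
#'   log_kpw = 1.18, log_kpd = 0.03, log_dp = -3.03,
#'   log_ds = 0.306, log_h = 1.56, h_is_lower_bound = TRUE)
#' kps_from_fraction(estradiol, 0.2)
chemical_params <- function(name, log_kpw = NA_real_, log_kpd = NA_real_,
                            log_dp = NA_real_, log_ds = NA_real_,
                            log_h = NA_real_, h_is_lower_bound = FALSE,
                            interacting = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x) is.numeric(x) && length(x) == 1L
  for (v in list(log_kpw, log_kpd, log_dp, log_ds, log_h)) {
    if (!num1(v)) stop("all log-parameters must be numeric scalars (NA allowed)")
  }
  if (!is.finite(log_ds)) stop("log_ds is required for every chemical")
  if (interacting) {
    if (!is.finite(log_kpw) || !is.finite(log_dp) || !is.finite(log_h)) {
      stop("an interacting chemical needs finite log_kpw, log_dp and log_h")
    }
  } else {
    if (any(is.finite(c(log_kpw, log_kpd, log_dp, log_h)))) {
      stop("a non-interacting chemical must leave all PDMS-side parameters NA")
    }
  }
  structure(
    list(name = name, log_kpw = log_kpw, log_kpd = log_kpd, log_dp = log_dp,
         log_ds = log_ds, log_h = log_h,
         h_is_lower_bound = isTRUE(h_is_lower_bound),
         interacting = isTRUE(interacting)),
    class = "chemical_params")
}

#' @export
print.chemical_params <- function(x, ...) {
  cat("<chemical_params> ", x$name,
      if (!x$interacting) " (non-interacting)" else "", "\n", sep = "")
  if (x$interacting) {
    cat(sprintf("  log10 K_PW = %.3g   log10 K_PD = %.3g\n", x$log_kpw, x$log_kpd))
    cat(sprintf("  log10 D_P  = %.3g mm^2/h   log10 H = %s%.3g mm/h\n",
                x$log_dp, if (x$h_is_lower_bound) ">= " else "", x$log_h))
  }
  cat(sprintf("  log10 D_S  = %.3g mm^2/h\n", x$log_ds))
  invisible(x)
}

# Fitted / calculated interaction parameters for the three steroid hormones,
# canonical units (mm^2/h, mm/h). H entries are non-rate-limiting lower
# bounds; aldosterone shows no detectable PDMS interaction.
.chemical_table <- list(
  progesterone = list(log_kpw = 3.30, log_kpd = -7.20, log_dp = -1.90,
                      log_ds = 0.336, log_h = 1.56, h_is_lower_bound = TRUE,
                      interacting = TRUE),
  estradiol    = list(log_kpw = 1.18, log_kpd = 0.03, log_dp = -3.03,
                      log_ds = 0.306, log_h = 1.56, h_is_lower_bound = TRUE,
                      interacting = TRUE),
  aldosterone  = list(log_kpw = NA_real_, log_kpd = NA_real_,
                      log_dp = NA_real_, log_ds = 0.296, log_h = NA_real_,
                      h_is_lower_bound = FALSE, interacting = FALSE)
)

#' Bundled steroid-hormone parameter sets
#'
#' Returns the measured chemical-PDMS interaction parameters for the three
#' steroid hormones shipped with the package: progesterone (strongly
#' interacting, K_PW ~ 2000), estradiol (moderately interacting, K_PW ~ 15)
#' and aldosterone (no detectable PDMS interaction).
#'
#' @param name One of `"progesterone"`, `"estradiol"`, `"aldosterone"`.
#' @return A [chemical_params()] object.
#' @export
#' @examples
#' chemical("progesterone")
chemical <- function(name = c("progesterone", "estradiol", "aldosterone")) {
  name <- match.arg(name)
  do.call(chemical_params, c(list(name = name), .chemical_table[[name]]))
}

#' @rdname chemical
#' @export
list_chemicals <- function() names(.chemical_table)

#' Solution composition (DMSO volume fraction)
#'
#' @param dmso_fraction Volume fraction of DMSO cosolvent, in \[0, 1\].
#' @return An object of class `solution_composition`.
#' @export
solution_composition <- function(dmso_fraction = 0) {
  if (!is.numeric(dmso_fraction) || length(dmso_fraction) != 1L ||
      !is.finite(dmso_fraction) || dmso_fraction < 0 || dmso_fraction > 1) {
    stop("dmso_fraction must be a single number in [0, 1]")
  }
  structure(list(dmso_fraction = dmso_fraction), class = "solution_composition")
}

#' PDMS-solution partition coefficient in a DMSO-water mixture
#'
#' The partition coefficient of a chemical between PDMS and a DMSO-water
#' mixture follows a log-linear mixing law in the DMSO volume fraction f:
#' `log10 K_PS = f * log10 K_PD + (1 - f) * log10 K_PW`. At f = 0 this
#' recovers the aqueous coefficient K_PW; at f = 1 the pure-DMSO coefficient
#' K_PD. This is the relationship used both to predict K_PS at a working
#' cosolvent fraction and (inverted, by regression) to extrapolate fitted
#' K_PS values back to zero DMSO.
#'
#' @param params A [chemical_params()] object with both partition
#'   coefficients defined.
#' @param composition A [solution_composition()], or a bare numeric DMSO
#'   fraction in \[0, 1\].
#' @return The linear-scale partition coefficient K_PS (dimensionless).
#' @export
#' @examples
#' kps_from_fraction(chemical("estradiol"), 0)    # aqueous K_PW ~ 15.1
#' kps_from_fraction(chemical("estradiol"), 0.2)
kps_from_fraction <- function(params, composition) {
  stopifnot(inherits(params, "chemical_params"))
  if (is.numeric(composition)) composition <- solution_composition(composition)
  stopifnot(inherits(composition, "solution_composition"))
  if (!params$interacting || !is.finite(params$log_kpw) ||
      !is.finite(params$log_kpd)) {
    stop("chemical '", params$name, "' has no partition parameters")
  }
  f <- composition$dmso_fraction
  10^(f * params$log_kpd + (1 - f) * params$log_kpw)
}

#' Effective solution diffusivity for stirred membrane-experiment chambers
#'
#' Chambers kept on a mixer transport solute faster than molecular diffusion
#' alone; the forward membrane model therefore uses an *effective* solution
#' diffusivity fitted from data. This value applies only to membrane
#' experiment chambers, never to channel flow (where the true `log_ds` and
#' the resolved velocity field govern transport).
#'
#' @param log_ds_eff log10 effective diffusivity, mm^2/h.
#' @return An object of class `effective_ds`.
#' @export
effective_ds <- function(log_ds_eff) {
  if (!is.numeric(log_ds_eff) || length(log_ds_eff) != 1L || !is.finite(log_ds_eff)) {
    stop("log_ds_eff must be a finite numeric scalar")
  }
  structure(list(log_ds_eff = log_ds_eff), class = "effective_ds")
}

#' Convert a volumetric flow rate from uL/min to canonical mm^3/h
#'
#' 1 uL = 1 mm^3, so the conversion is a factor of 60.
#'
#' @param q_ul_min Flow rate in microlitres per minute (>= 0).
#' @return Flow rate in mm^3/h.
#' @export
#' @examples
#' convert_flow_rate(1)    # 60
#' convert_flow_rate(100)  # 6000
convert_flow_rate <- function(q_ul_min) {
  if (!is.numeric(q_ul_min) || any(!is.finite(q_ul_min)) || any(q_ul_min < 0)) {
    stop("flow rate must be nonnegative and finite")
  }
  q_ul_min * 60
}
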