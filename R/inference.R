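#' Fitting options for the membrane inverse problem
#'
#' @param n_starts Number of multi-start initial points for the bounded
#'   Levenberg-Marquardt search (deterministic log-space offsets around the
#'   initial guess); parameters span orders of magnitude, so multiple starts
#'   mitigate local minima.
#' @param sim_control A [membrane_control()] used for forward solves inside
#'   the objective (coarser than presentation resolution by default, for
#'   speed).
#' @param h_scan log10 H grid for the identifiability scan.
#' @param h_tol Relative objective tolerance defining a "flat" H profile: H
#'   is reported as a lower bound when the residual sum of squares changes
#'   by less than this fraction across the upper part of the scan.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param lower,upper Bounds on `(log_kps, log_dp, log_h, log_ds_eff)`.
#'   The default `log_dp` upper bound of 0.5 reflects that diffusion in
#'   crosslinked PDMS cannot outpace free-solution diffusion
#'   (D_S ~ 2 mm^2/h for small steroids).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_starts = 3L,
                        sim_control = membrane_control(n_chamber = 10L,
                                                       n_membrane = 15L,
                                                       dt_h = 0.05),
                        h_scan = seq(0, 3, by = 0.25), h_tol = 0.01,
                        maxiter = 100L,
                        lower = c(-3, -6, -1, -2),
                        upper = c(6, 0.5, 3, 1.5)) {
  structure(list(n_starts = as.integer(n_starts), sim_control = sim_control,
                 h_scan = h_scan, h_tol = h_tol, maxiter = as.integer(maxiter),
                 lower = lower, upper = upper),
            class = "fit_control")
}

# Forward model for the fit: chamber-average source/sink concentrations at
# the requested times, for log-scale parameters theta.
.fit_forward <- function(theta, assembly, times, control) {
  run <- .membrane_run(assembly,
                       kps = 10^theta[1], dp = 10^theta[2], h = 10^theta[3],
                       ds_eff = 10^theta[4],
                       sample_times = times, control = control)
  list(source = run$source, sink = run$sink)
}

# Heuristic initial guess from the data: the late-time mass deficit sets
# K_PS through the closed-system equilibrium; rates start mid-range.
.fit_init <- function(series, assembly) {
  last_t <- max(series$time_h)
  late <- series[series$time_h >= 0.6 * last_t, ]
  c_src <- mean(late$concentration[late$compartment == "source"])
  c_snk <- mean(late$concentration[late$compartment == "sink"])
  m0 <- assembly$c0_source * assembly$source_volume_ul +
    assembly$c0_sink * assembly$sink_volume_ul
  m_late <- c_src * assembly$source_volume_ul + c_snk * assembly$sink_volume_ul
  vol_m <- assembly$area_mm2 * assembly$membrane_thickness_mm
  c_mean <- max(m_late / (assembly$source_volume_ul + assembly$sink_volume_ul),
                1e-6 * assembly$c0_source)
  k_guess <- max((m0 - m_late) / (c_mean * vol_m), 1)
  c(log_kps = min(max(log10(k_guess), -1), 4.5),
    log_dp = -2, log_h = 1.5, log_ds_eff = 0.5)
}

#' Fit the partition-diffusion model to membrane-experiment series
#'
#' Estimates `(log10 K_PS, log10 D_P, log10 H, log10 D_S,eff)` for one DMSO
#' fraction by bounded Levenberg-Marquardt least squares between the forward
#' membrane model and observed source/sink concentration time series.
#' Replicates are fitted jointly with shared parameters. Asymptotic standard
#' errors come from the local quadratic approximation at the optimum. When
#' the interfacial coefficient H is not rate-limiting the objective is flat
#' in `log10 H` above some threshold; the fit then reports that threshold as
#' a lower bound and sets `h_is_lower_bound`.
#'
#' @param series A tibble/data frame with columns `time_h`, `compartment`
#'   (`"source"`/`"sink"`), `concentration`, and optionally `replicate` and
#'   `fraction_dmso` (which must be constant; fit each fraction separately).
#' @param assembly The [membrane_assembly()] used in the experiment.
#' @param init Optional named initial guess
#'   `(log_kps, log_dp, log_h, log_ds_eff)`; a data-driven heuristic is used
#'   when omitted.
#' @param weights Optional per-observation weights (e.g. `1/se^2`).
#' @param control A [fit_control()].
#' @return An object of class `membrane_fit`: `$estimates` (tibble of
#'   parameter, estimate, se), `$h_is_lower_bound`, `$h_lower_bound`
#'   (log10), `$ssr`, `$convergence`, `$fitted` (predicted series) and
#'   `$n_obs`.
#' @export
fit_membrane_experiment <- function(series, assembly, init = NULL,
                                    weights = NULL,
                                    control = fit_control()) {
  series <- as.data.frame(series)
  need <- c("time_h", "compartment", "concentration")
  if (!all(need %in% names(series))) {
    stop("series needs columns: ", paste(need, collapse = ", "))
  }
  if ("fraction_dmso" %in% names(series) &&
      length(unique(series$fraction_dmso)) > 1L) {
    stop("series spans multiple DMSO fractions; fit each fraction separately")
  }
  if (any(series$concentration < 0)) stop("concentrations must be nonnegative")
  if (length(unique(series$time_h)) < 4L) {
    stop("need at least 4 time points spanning the transient")
  }
  times <- sort(unique(series$time_h))
  times_pos <- if (times[1] <= 0) times[-1] else times
  idx_src <- series$compartment == "source"
  w <- if (is.null(weights)) rep(1, nrow(series)) else weights
  if (length(w) != nrow(series)) stop("weights must match the series length")

  time_idx <- match(series$time_h, times)
  predict_obs <- function(theta) {
    fwd <- .fit_forward(theta, assembly, times_pos, control$sim_control)
    src <- if (times[1] <= 0) c(assembly$c0_source, fwd$source) else fwd$source
    snk <- if (times[1] <= 0) c(assembly$c0_sink, fwd$sink) else fwd$sink
    ifelse(idx_src, src[time_idx], snk[time_idx])
  }
  resid_fun <- function(theta) {
    sqrt(w) * (series$concentration - predict_obs(theta))
  }

  if (is.null(init)) init <- .fit_init(series, assembly)
  init <- pmin(pmax(init, control$lower + 0.01), control$upper - 0.01)
  offsets <- list(c(0, 0, 0, 0),
                  c(0.7, -0.8, 0.5, 0.4),
                  c(-0.7, 0.8, -0.5, -0.4),
                  c(1.2, 0.8, 0, 0.8),
                  c(-1.2, -0.8, 0, -0.8))
  n_starts <- min(control$n_starts, length(offsets))
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- pmin(pmax(init + offsets[[s]], control$lower), control$upper)
    fit <- try(minpack.lm::nls.lm(
      par = start, fn = resid_fun,
      lower = control$lower, upper = control$upper,
      control = minpack.lm::nls.lm.control(maxiter = control$maxiter,
                                           ptol = 1e-8, ftol = 1e-8)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("membrane fit failed to converge from any start")
  theta <- best$par
  ssr <- best$deviance
  n_obs <- nrow(series)

  # asymptotic covariance from a forward-difference Jacobian at the optimum
  J <- matrix(0, n_obs, 4L)
  r0 <- resid_fun(theta)
  step <- 1e-4
  for (j in 1:4) {
    th <- theta; th[j] <- th[j] + step
    J[, j] <- (resid_fun(th) - r0) / step
  }
  sigma2 <- ssr / max(n_obs - 4L, 1L)
  covm <- tryCatch(sigma2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, 4, 4))
  ses <- sqrt(pmax(diag(covm), 0))

  # H identifiability: scan the objective in log10 H with the other
  # parameters held at the optimum
  scan_ssr <- vapply(control$h_scan, function(lh) {
    th <- theta; th[3] <- lh
    sum(resid_fun(th)^2)
  }, numeric(1))
  ssr_min <- min(c(scan_ssr, ssr))
  flat <- scan_ssr <= (1 + control$h_tol) * ssr_min
  h_is_lb <- flat[length(flat)]   # flat all the way to the top of the scan
  h_lower_bound <- if (any(flat)) control$h_scan[which(flat)[1]] else NA_real_
  if (h_is_lb) ses[3] <- NA_real_

  fitted_series <- tibble::tibble(
    time_h = rep(times, 2L),
    compartment = rep(c("source", "sink"), each = length(times)),
    concentration = {
      fwd <- .fit_forward(theta, assembly, times_pos, control$sim_control)
      src <- if (times[1] <= 0) c(assembly$c0_source, fwd$source) else fwd$source
      snk <- if (times[1] <= 0) c(assembly$c0_sink, fwd$sink) else fwd$sink
      c(src, snk)
    })

  structure(
    list(estimates = tibble::tibble(
           parameter = c("log_kps", "log_dp", "log_h", "log_ds_eff"),
           estimate = unname(theta), se = unname(ses)),
         h_is_lower_bound = unname(h_is_lb),
         h_lower_bound = unname(h_lower_bound),
         ssr = ssr, n_obs = n_obs,
         convergence = list(info = best$info, message = best$message,
                            niter = best$niter),
         fitted = fitted_series,
         fraction_dmso = if ("fraction_dmso" %in% names(series))
           series$fraction_dmso[1] else NA_real_),
    class = "membrane_fit")
}

#' @export
print.membrane_fit <- function(x, ...) {
  cat("<membrane_fit> SSR =", format(x$ssr, digits = 4),
      "on", x$n_obs, "observations\n")
  print(x$estimates)
  if (isTRUE(x$h_is_lower_bound)) {
    cat(sprintf("  H not rate-limiting: log10 H >= %.3g (lower bound)\n",
                x$h_lower_bound))
  }
  invisible(x)
}

#' Extrapolate fitted partition coefficients to zero and pure DMSO
#'
#' Fitted `log10 K_PS` values at several DMSO volume fractions f follow the
#' log-linear mixing law, so a (weighted) linear regression of `log10 K_PS`
#' on f yields the aqueous coefficient `log10 K_PW` as the intercept and the
#' pure-DMSO coefficient `log10 K_PD` as intercept + slope, with standard
#' errors propagated from the regression covariance.
#'
#' @param points A data frame with columns `fraction` (in \[0,1\]),
#'   `log_kps`, and optionally `se` (per-point standard errors; points are
#'   then weighted `1/se^2`).
#' @return An object of class `partition_extrapolation` with `log_kpw`,
#'   `log_kpd`, their standard errors, the slope/intercept covariance and
#'   per-point residuals.
#' @export
#' @examples
#' pts <- data.frame(fraction = c(0.1, 0.3), log_kps = c(1.5, 1.1))
#' extrapolate_partition(pts)
extrapolate_partition <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("fraction", "log_kps") %in% names(points))) {
    stop("points needs columns fraction and log_kps")
  }
  if (any(points$fraction < 0 | points$fraction > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (length(unique(points$fraction)) < 2L) {
    stop("need at least 2 distinct DMSO fractions to extrapolate")
  }
  w <- if ("se" %in% names(points) && all(is.finite(points$se)) &&
           all(points$se > 0)) 1 / points$se^2 else NULL
  fit <- stats::lm(log_kps ~ fraction, data = points, weights = w)
  beta <- stats::coef(fit)
  # vcov warns on exactly collinear (zero-residual) inputs, a legitimate
  # case here (noise-free points lie on the mixing-law line)
  V <- suppressWarnings(stats::vcov(fit))
  if (!is.null(w) && nrow(points) > 2L) {
    # per-point standard errors are known, not relative weights: never let
    # the low-df residual rescaling shrink the covariance below the
    # propagated measurement-noise level
    sigma2_hat <- sum(w * stats::residuals(fit)^2) / (nrow(points) - 2L)
    if (sigma2_hat < 1) V <- V / sigma2_hat
  }
  exact <- nrow(points) <= 2L || isTRUE(all.equal(sum(stats::residuals(fit)^2), 0))
  se_kpw <- if (exact && nrow(points) == 2L) NA_real_ else sqrt(V[1, 1])
  se_kpd <- if (exact && nrow(points) == 2L) NA_real_ else
    sqrt(V[1, 1] + V[2, 2] + 2 * V[1, 2])
  structure(
    list(log_kpw = unname(beta[1]),
         log_kpd = unname(beta[1] + beta[2]),
         se_log_kpw = se_kpw, se_log_kpd = se_kpd,
         slope = unname(beta[2]), intercept = unname(beta[1]),
         covariance = V,
         residuals = stats::residuals(fit),
         points = tibble::as_tibble(points)),
    class = "partition_extrapolation")
}

#' @export
print.partition_extrapolation <- function(x, ...) {
  cat(sprintf("<partition_extrapolation> log10 K_PW = %.3f (se %.3f), log10 K_PD = %.3f (se %.3f)\n",
              x$log_kpw, x$se_log_kpw, x$log_kpd, x$se_log_kpd))
  invisible(x)
}
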