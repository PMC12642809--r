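#' Microchannel-in-slab device geometry
#'
#' A rectangular microchannel (length x width x height) embedded in a PDMS
#' slab, perfused at a volumetric flow rate Q (0 for static culture). The
#' channel is assumed centred in the slab thickness; `lateral_margin_mm` is
#' the PDMS extent beyond each side wall, which bounds how much PDMS the
#' side walls can load.
#'
#' @param length_mm,width_mm,height_mm Channel dimensions, mm.
#' @param slab_thickness_mm Total slab thickness (must exceed the channel
#'   height), mm.
#' @param lateral_margin_mm PDMS margin beyond each side wall, mm.
#' @param flow_rate_ul_min Volumetric flow rate Q, uL/min (>= 0).
#' @return An object of class `channel_device`.
#' @seealso [device_preset()] for bundled literature geometries.
#' @export
channel_device <- function(length_mm, width_mm, height_mm, slab_thickness_mm,
                           lateral_margin_mm = 2, flow_rate_ul_min = 0) {
  dims <- c(length_mm, width_mm, height_mm, slab_thickness_mm, lateral_margin_mm)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("all device dimensions must be positive")
  }
  if (height_mm >= slab_thickness_mm) {
    stop("channel height must be smaller than the slab thickness")
  }
  if (flow_rate_ul_min < 0) stop("flow rate must be >= 0")
  structure(
    list(length_mm = length_mm, width_mm = width_mm, height_mm = height_mm,
         slab_thickness_mm = slab_thickness_mm,
         lateral_margin_mm = lateral_margin_mm,
         flow_rate_ul_min = flow_rate_ul_min),
    class = "channel_device")
}

#' @export
print.channel_device <- function(x, ...) {
  cat(sprintf("<channel_device> %.4g x %.4g x %.4g mm in %.4g-mm slab (margin %.3g mm), Q = %.4g uL/min\n",
              x$length_mm, x$width_mm, x$height_mm, x$slab_thickness_mm,
              x$lateral_margin_mm, x$flow_rate_ul_min))
  invisible(x)
}

#' Bundled device geometries
#'
#' Two literature geometries used throughout the package:
#' * `"bioreactor"` — a 10.55-mm long, 1.5-mm wide, 100-um tall perfusion
#'   channel embedded in a 4-mm thick PDMS slab (thick-tissue bioreactor
#'   footprint, Markov et al. 2012-style), used for the pulse and circadian
#'   dosing scenarios.
#' * `"regehr"` — the static estrogen-depletion assay of Regehr et al.
#'   (2009): a 4.5-mm x 670-um x 250-um channel in a 10 x 10 x 0.75 mm slab.
#'
#' @param name Preset name.
#' @param flow_rate_ul_min Flow rate override, uL/min.
#' @return A [channel_device()].
#' @export
device_preset <- function(name = c("bioreactor", "regehr"),
                          flow_rate_ul_min = 0) {
  name <- match.arg(name)
  switch(name,
    bioreactor = channel_device(10.55, 1.5, 0.1, 4, lateral_margin_mm = 2,
                                flow_rate_ul_min = flow_rate_ul_min),
    regehr = channel_device(4.5, 0.67, 0.25, 0.75,
                            lateral_margin_mm = (10 - 0.67) / 2,
                            flow_rate_ul_min = flow_rate_ul_min))
}

#' Laminar velocity profile in the channel
#'
#' Fully developed plane-Poiseuille flow in the channel height coordinate
#' (the default reduced model exploits the wide, shallow cross-section):
#' `v(z) = 1.5 * v_mean * (1 - (2 z / h)^2)` with z measured from the
#' mid-height plane, zero at the walls, and mean `v_mean = Q / (width * height)`.
#'
#' @param device A [channel_device()].
#' @return An object of class `velocity_field` with fields `profile`
#'   (function of z, mm, from the mid-plane), `mean_mm_h`, `max_mm_h` and
#'   `flow_mm3_h`.
#' @export
#' @examples
#' vf <- velocity_field(device_preset("bioreactor", flow_rate_ul_min = 100))
#' vf$mean_mm_h            # 40,000 mm/h
#' vf$max_mm_h / vf$mean_mm_h  # 1.5
velocity_field <- function(device) {
  stopifnot(inherits(device, "channel_device"))
  area <- device$width_mm * device$height_mm
  if (area <= 0) stop("zero cross-section")
  q <- convert_flow_rate(device$flow_rate_ul_min)
  v_mean <- q / area
  half <- device$height_mm / 2
  profile <- function(z) {
    v <- 1.5 * v_mean * (1 - (z / half)^2)
    pmax(v, 0)
  }
  structure(list(profile = profile, mean_mm_h = v_mean,
                 max_mm_h = 1.5 * v_mean, flow_mm3_h = q,
                 height_mm = device$height_mm),
            class = "velocity_field")
}

#' Solver options for the channel model
#'
#' Defaults are sized for desk-scale runs: they resolve the channel height
#' with 7 cells over the half-height, the slab with stretched grids finest
#' at the wall, and step implicitly at 7.2-s intervals.
#'
#' @param nx Axial cells along the channel.
#' @param nz_solution Cells across the channel half-height.
#' @param nz_slab Cells through the top/bottom slab depth (stretched).
#' @param nz_side Cells through the side-wall margin depth (stretched).
#' @param dt_h Time step, h.
#' @param save_dt_h Interval at which time series are recorded, h.
#' @param stretch Geometric stretching ratio of the PDMS grids.
#' @param equilibrium_interface If `TRUE`, enforce local partition
#'   equilibrium at the walls (the limit H -> infinity) instead of the
#'   finite interfacial mass-transfer coefficient.
#' @param quasi_steady If `TRUE`, treat the in-channel field as
#'   instantaneously steady against the slowly evolving wall uptake
#'   (appropriate for multi-day runs where the residence time is far shorter
#'   than the dosing period); requires Q > 0.
#' @param init `"inlet"` (channel pre-filled at the schedule's t = 0 value,
#'   the default) or `"blank"` (chemical-free start).
#' @return A list of class `channel_control`.
#' @export
channel_control <- function(nx = 45L, nz_solution = 7L, nz_slab = 26L,
                            nz_side = 18L, dt_h = 0.002, save_dt_h = 0.01,
                            stretch = 1.18, equilibrium_interface = FALSE,
                            quasi_steady = FALSE, init = c("inlet", "blank")) {
  if (nx < 3L || nz_solution < 2L || nz_slab < 4L || nz_side < 4L) {
    stop("mesh is too coarse")
  }
  if (dt_h <= 0 || save_dt_h <= 0) stop("time steps must be positive")
  structure(list(nx = as.integer(nx), nz_solution = as.integer(nz_solution),
                 nz_slab = as.integer(nz_slab), nz_side = as.integer(nz_side),
                 dt_h = dt_h, save_dt_h = save_dt_h, stretch = stretch,
                 equilibrium_interface = isTRUE(equilibrium_interface),
                 quasi_steady = isTRUE(quasi_steady),
                 init = match.arg(init)),
            class = "channel_control")
}

# ---------------------------------------------------------------------------
# Internal discretization shared by the transient and quasi-steady drivers.
#
# Reduced 2-D model (axial x x height z), half channel by mid-plane symmetry,
# with the slab represented by two 1-D PDMS domains per axial station:
#  * top/bottom walls: width 2W, depth (slab - h)/2, fed by the wall-adjacent
#    solution cell;
#  * side walls: width 2h, depth = lateral margin, fed by the cross-section
#    mean solution concentration through a lumped lateral resistance
#    (W/4)/D_S (cross-channel mixing is fast relative to wall uptake).
# All capacities/conductances are per unit axial length for the FULL channel
# (the two symmetric halves are merged), so flows and masses are physical.
.channel_grid <- function(device, params, control) {
  W <- device$width_mm; h <- device$height_mm; L <- device$length_mm
  ns <- control$nz_solution; nt <- control$nz_slab; nd <- control$nz_side
  interacting <- params$interacting
  ds <- 10^params$log_ds
  dzs <- rep((h / 2) / ns, ns)
  z_centers <- cumsum(dzs) - dzs / 2          # from mid-plane towards wall
  cap_s <- 2 * W * dzs                        # full channel (both halves)
  depth_t <- (device$slab_thickness_mm - h) / 2
  wt <- stretched_widths(depth_t, nt, control$stretch)
  wd <- stretched_widths(device$lateral_margin_mm, nd, control$stretch)
  cap_t <- 2 * W * wt
  cap_d <- 2 * h * wd

  if (interacting) {
    kps <- kps_from_fraction(params, 0)       # channels run in aqueous media
    dp <- 10^params$log_dp
    hh <- if (control$equilibrium_interface) Inf else 10^params$log_h
    g_t <- 2 * W * interface_conductance(hh, kps, ds, dzs[ns], dp, wt[1])
    g_d <- 2 * h * interface_conductance(hh, kps, ds, W / 2, dp, wd[1])
  } else {
    kps <- 0; dp <- 0
    g_t <- g_d <- 0
  }

  n_tot <- ns + if (interacting) nt + nd else 0L
  is_ <- seq_len(ns)
  it_ <- if (interacting) ns + seq_len(nt) else integer()
  id_ <- if (interacting) ns + nt + seq_len(nd) else integer()
  caps <- c(cap_s, if (interacting) c(cap_t, cap_d))
  wmean <- cap_s / sum(cap_s)                 # cross-section averaging weights

  # Transverse operator A (du/dt = A u) for one axial station.
  A <- matrix(0, n_tot, n_tot)
  g_sz <- 2 * W * ds / dzs[1]
  for (k in seq_len(ns - 1)) {
    A[is_[k], is_[k]] <- A[is_[k], is_[k]] - g_sz / caps[is_[k]]
    A[is_[k], is_[k + 1]] <- A[is_[k], is_[k + 1]] + g_sz / caps[is_[k]]
    A[is_[k + 1], is_[k + 1]] <- A[is_[k + 1], is_[k + 1]] - g_sz / caps[is_[k + 1]]
    A[is_[k + 1], is_[k]] <- A[is_[k + 1], is_[k]] + g_sz / caps[is_[k + 1]]
  }
  if (interacting) {
    pdms_diff <- function(A, idx, widths, width_factor) {
      for (k in seq_len(length(idx) - 1)) {
        g <- width_factor * dp * 2 / (widths[k] + widths[k + 1])
        i <- idx[k]; j <- idx[k + 1]
        A[i, i] <- A[i, i] - g / caps[i]; A[i, j] <- A[i, j] + g / caps[i]
        A[j, j] <- A[j, j] - g / caps[j]; A[j, i] <- A[j, i] + g / caps[j]
      }
      A
    }
    A <- pdms_diff(A, it_, wt, 2 * W)
    A <- pdms_diff(A, id_, wd, 2 * h)
    # wall flux J_t = g_t (K c_wall - c_t1)
    sw <- is_[ns]; t1 <- it_[1]
    A[sw, sw] <- A[sw, sw] - g_t * kps / caps[sw]
    A[sw, t1] <- A[sw, t1] + g_t / caps[sw]
    A[t1, t1] <- A[t1, t1] - g_t / caps[t1]
    A[t1, sw] <- A[t1, sw] + g_t * kps / caps[t1]
    # side flux J_d = g_d (K mean(c_s) - c_d1), removed uniformly in
    # concentration from all solution cells (sum cap_s in the denominator)
    d1 <- id_[1]
    for (k in is_) {
      A[k, is_] <- A[k, is_] - (g_d * kps / sum(cap_s)) * wmean
      A[k, d1] <- A[k, d1] + g_d / sum(cap_s)
    }
    A[d1, d1] <- A[d1, d1] - g_d / caps[d1]
    A[d1, is_] <- A[d1, is_] + (g_d * kps / caps[d1]) * wmean
  }

  # Discrete velocity profile, normalized so the discrete flow equals Q.
  q <- convert_flow_rate(device$flow_rate_ul_min)
  if (q > 0) {
    vprof <- 1.5 * (1 - (z_centers / (h / 2))^2)
    v <- vprof * q / sum(vprof * cap_s)       # mm/h per cell row
  } else {
    v <- rep(0, ns)
  }

  nx <- control$nx
  dx <- L / nx
  list(W = W, h = h, L = L, ns = ns, nt = nt, nd = nd, n_tot = n_tot,
       is_ = is_, it_ = it_, id_ = id_, caps = caps, cap_s = cap_s,
       cap_t = if (interacting) cap_t else numeric(),
       cap_d = if (interacting) cap_d else numeric(),
       wmean = wmean, A_trans = A, g_t = g_t, g_d = g_d, kps = kps,
       ds = ds, v = v, q = q, nx = nx, dx = dx,
       x_centers = (seq_len(nx) - 0.5) * dx,
       interacting = interacting)
}

# Axial (advection + axial diffusion) implicit row operators for the
# solution cells. Inlet: Dirichlet at the inlet face (advective +
# diffusive); outlet: upwind advective outflow, no axial diffusion out.
# For Q = 0 both ends are no-flux. Returns per-row propagator inverses and
# the inlet source coefficients.
.axial_operators <- function(grid, dt) {
  nx <- grid$nx; dx <- grid$dx; ds <- grid$ds
  ops <- vector("list", grid$ns)
  for (i in seq_len(grid$ns)) {
    v <- grid$v[i]
    B <- matrix(0, nx, nx)
    for (x in seq_len(nx)) {
      if (v > 0) {
        B[x, x] <- B[x, x] + v / dx
        if (x > 1) B[x, x - 1] <- B[x, x - 1] - v / dx
      }
      # axial diffusion between interior cells
      if (x > 1) {
        B[x, x] <- B[x, x] + ds / dx^2
        B[x, x - 1] <- B[x, x - 1] - ds / dx^2
      }
      if (x < nx) {
        B[x, x] <- B[x, x] + ds / dx^2
        B[x, x + 1] <- B[x, x + 1] - ds / dx^2
      }
      # inlet face Dirichlet (only when flowing; a static channel is closed)
      if (x == 1 && v > 0) B[x, x] <- B[x, x] + 2 * ds / dx^2
    }
    inlet_coef <- if (v > 0) v / dx + 2 * ds / dx^2 else 0
    ops[[i]] <- list(P = solve(diag(nx) + dt * B), inlet_coef = inlet_coef,
                     v = v)
  }
  ops
}

# Transient operator-split driver. Returns recorded series and final fields.
.channel_run <- function(device, params, schedule, t_end, control,
                         fields = NULL) {
  grid <- .channel_grid(device, params, control)
  dt <- control$dt_h
  n_steps <- max(1L, ceiling(t_end / dt - 1e-9))
  dt <- t_end / n_steps
  P_trans <- implicit_propagator(grid$A_trans, dt)
  ax <- .axial_operators(grid, dt)
  save_every <- max(1L, round(control$save_dt_h / dt))

  nx <- grid$nx
  U <- matrix(0, grid$n_tot, nx)
  if (!is.null(fields)) {
    U <- fields
  } else if (control$init == "inlet") {
    U[grid$is_, ] <- evaluate_schedule(schedule, 0)
  }

  n_rec <- floor(n_steps / save_every) + 1L
  rec <- matrix(NA_real_, n_rec, 10L)
  colnames(rec) <- c("time_h", "avg_channel_conc", "outlet_conc", "inlet_conc",
                     "delivered_mass", "delivered_mass_avg", "inlet_mass",
                     "mass_solution", "mass_pdms", "mass_in_actual")
  flow_w <- grid$v * grid$cap_s
  flow_tot <- sum(flow_w)
  outlet_conc <- function(U) {
    if (flow_tot > 0) sum(flow_w * U[grid$is_, nx]) / flow_tot
    else sum(grid$wmean * U[grid$is_, nx])
  }
  avg_conc <- function(U) {
    sum(grid$wmean * (U[grid$is_, , drop = FALSE] %*% rep(1 / nx, nx)))
  }
  sol_mass <- function(U) grid$dx * sum(grid$cap_s * rowSums(U[grid$is_, , drop = FALSE]))
  pdms_mass <- function(U) {
    if (!grid$interacting) return(0)
    grid$dx * (sum(grid$cap_t * rowSums(U[grid$it_, , drop = FALSE])) +
               sum(grid$cap_d * rowSums(U[grid$id_, , drop = FALSE])))
  }
  m_out <- 0; m_out_avg <- 0; m_in_nominal <- 0; m_in_actual <- 0
  rec[1L, ] <- c(0, avg_conc(U), outlet_conc(U), evaluate_schedule(schedule, 0),
                 0, 0, 0, sol_mass(U), pdms_mass(U), 0)
  ri <- 1L
  for (k in seq_len(n_steps)) {
    t0 <- (k - 1L) * dt
    c_in <- evaluate_schedule(schedule, t0)
    # axial substep (solution rows)
    if (any(grid$v > 0) || grid$ds > 0) {
      for (i in seq_len(grid$ns)) {
        row <- U[grid$is_[i], ]
        rhs <- row
        rhs[1] <- rhs[1] + dt * ax[[i]]$inlet_coef * c_in
        new_row <- drop(ax[[i]]$P %*% rhs)
        U[grid$is_[i], ] <- new_row
        if (ax[[i]]$v > 0) {
          m_out <- m_out + dt * ax[[i]]$v * grid$cap_s[i] * new_row[nx]
          m_in_actual <- m_in_actual + dt * grid$cap_s[i] *
            (ax[[i]]$v * c_in + (2 * grid$ds / grid$dx) * (c_in - new_row[1]))
        }
      }
      m_in_nominal <- m_in_nominal + dt * grid$q * c_in
    }
    # transverse substep (wall exchange + slab diffusion)
    U <- P_trans %*% U
    m_out_avg <- m_out_avg + dt * grid$q * avg_conc(U)
    if (k %% save_every == 0L) {
      ri <- ri + 1L
      t_now <- k * dt
      rec[ri, ] <- c(t_now, avg_conc(U), outlet_conc(U),
                     evaluate_schedule(schedule, t_now),
                     m_out, m_out_avg, m_in_nominal, sol_mass(U), pdms_mass(U),
                     m_in_actual)
    }
  }
  rec <- rec[seq_len(ri), , drop = FALSE]
  list(series = tibble::as_tibble(as.data.frame(rec)), fields = U, grid = grid,
       dt = dt)
}

# Quasi-steady driver: the in-channel field is taken as the steady solution
# of advection + transverse diffusion + wall exchange against the current
# (slowly evolving) slab state; the slab advances implicitly between
# channel solves. Axial solution diffusion is neglected (advection-dominated
# regime; requires Q > 0).
.channel_run_qs <- function(device, params, schedule, t_end, control,
                            fields = NULL) {
  grid <- .channel_grid(device, params, control)
  if (grid$q <= 0) stop("quasi-steady channel mode requires Q > 0")
  ns <- grid$ns; nx <- grid$nx; dx <- grid$dx
  dt <- control$dt_h
  n_steps <- max(1L, ceiling(t_end / dt - 1e-9))
  dt <- t_end / n_steps

  # Steady in-channel operator S c = b over all (z, x) solution cells,
  # ordered z-major within columns: unknown index (x - 1) * ns + i.
  idx <- function(i, x) (x - 1L) * ns + i
  n_u <- ns * nx
  S <- matrix(0, n_u, n_u)
  g_sz <- 2 * grid$W * grid$ds / ((grid$h / 2) / ns)
  for (x in seq_len(nx)) {
    for (i in seq_len(ns)) {
      r <- idx(i, x)
      adv <- grid$v[i] * grid$cap_s[i] / dx
      S[r, r] <- S[r, r] + adv
      if (x > 1) S[r, idx(i, x - 1L)] <- S[r, idx(i, x - 1L)] - adv
      if (i > 1) {
        S[r, r] <- S[r, r] + g_sz
        S[r, idx(i - 1L, x)] <- S[r, idx(i - 1L, x)] - g_sz
      }
      if (i < ns) {
        S[r, r] <- S[r, r] + g_sz
        S[r, idx(i + 1L, x)] <- S[r, idx(i + 1L, x)] - g_sz
      }
      if (grid$interacting) {
        if (i == ns) S[r, r] <- S[r, r] + grid$g_t * grid$kps
        # distributed side-wall sink against the cross-section mean
        S[r, idx(seq_len(ns), x)] <- S[r, idx(seq_len(ns), x)] +
          (grid$cap_s[i] / sum(grid$cap_s)) * grid$g_d * grid$kps * grid$wmean
      }
    }
  }
  S_inv <- solve(S)

  # Implicit slab propagators (PDMS cells only) with a Robin wall coupling
  # term g (K c_wall - c_P1); c_wall is frozen during each slab step, so the
  # step matrices are constant and their inverses are precomputed.
  if (grid$interacting) {
    nt <- grid$nt; nd <- grid$nd
    # PDMS-interior blocks of the transverse operator already carry the
    # interface sink -g/cap on their first cell, which is exactly the Robin
    # sink term; only the source g K c_wall / cap enters through the RHS.
    A_t <- grid$A_trans[grid$it_, grid$it_, drop = FALSE]
    A_d <- grid$A_trans[grid$id_, grid$id_, drop = FALSE]
    rob_t <- grid$g_t / grid$cap_t[1]
    rob_d <- grid$g_d / grid$cap_d[1]
    M_t <- diag(nt) - dt * A_t
    M_d <- diag(nd) - dt * A_d
    M_t_inv <- solve(M_t); M_d_inv <- solve(M_d)
    CT <- matrix(0, nt, nx); CD <- matrix(0, nd, nx)
    if (!is.null(fields)) {
      CT <- fields[grid$it_, , drop = FALSE]
      CD <- fields[grid$id_, , drop = FALSE]
    }
  }

  save_every <- max(1L, round(control$save_dt_h / dt))
  n_rec <- floor(n_steps / save_every) + 1L
  rec <- matrix(NA_real_, n_rec, 10L)
  colnames(rec) <- c("time_h", "avg_channel_conc", "outlet_conc", "inlet_conc",
                     "delivered_mass", "delivered_mass_avg", "inlet_mass",
                     "mass_solution", "mass_pdms", "mass_in_actual")
  flow_w <- grid$v * grid$cap_s
  flow_tot <- sum(flow_w)
  m_out <- 0; m_out_avg <- 0; m_in <- 0
  ri <- 0L
  CS <- matrix(0, ns, nx)
  for (k in 0:n_steps) {
    t_now <- k * dt
    c_in <- evaluate_schedule(schedule, t_now)
    b <- numeric(n_u)
    b[idx(seq_len(ns), 1L)] <- grid$v * grid$cap_s / dx * c_in
    if (grid$interacting) {
      for (x in seq_len(nx)) {
        b[idx(ns, x)] <- b[idx(ns, x)] + grid$g_t * CT[1, x]
        b[idx(seq_len(ns), x)] <- b[idx(seq_len(ns), x)] +
          (grid$cap_s / sum(grid$cap_s)) * grid$g_d * CD[1, x]
      }
    }
    CS <- matrix(S_inv %*% b, ns, nx)
    if (k < n_steps && grid$interacting) {
      # advance slab one implicit step with frozen wall-side concentrations
      wall <- CS[ns, ]
      mwall <- colSums(CS * grid$wmean)
      rhs_t <- CT; rhs_t[1, ] <- rhs_t[1, ] + dt * rob_t * grid$kps * wall
      rhs_d <- CD; rhs_d[1, ] <- rhs_d[1, ] + dt * rob_d * grid$kps * mwall
      CT <- M_t_inv %*% rhs_t
      CD <- M_d_inv %*% rhs_d
    }
    if (k < n_steps) {
      c_out <- sum(flow_w * CS[, nx]) / flow_tot
      m_out <- m_out + dt * grid$q * c_out
      m_out_avg <- m_out_avg + dt * grid$q * mean(colSums(CS * grid$wmean))
      m_in <- m_in + dt * grid$q * c_in
    }
    if (k %% save_every == 0L || k == n_steps) {
      ri <- ri + 1L
      pd <- if (grid$interacting) {
        grid$dx * (sum(grid$cap_t * rowSums(CT)) + sum(grid$cap_d * rowSums(CD)))
      } else 0
      rec[ri, ] <- c(t_now, mean(colSums(CS * grid$wmean)),
                     sum(flow_w * CS[, nx]) / flow_tot, c_in,
                     m_out, m_out_avg, m_in,
                     grid$dx * sum(grid$cap_s * rowSums(CS)), pd, m_in)
    }
  }
  rec <- rec[seq_len(ri), , drop = FALSE]
  U <- matrix(0, grid$n_tot, nx)
  U[grid$is_, ] <- CS
  if (grid$interacting) {
    U[grid$it_, ] <- CT
    U[grid$id_, ] <- CD
  }
  list(series = tibble::as_tibble(as.data.frame(rec)), fields = U, grid = grid,
       dt = dt)
}

#' Simulate chemical transport through a perfused (or static) channel
#'
#' Solves the coupled partition-diffusion system in a channel embedded in a
#' PDMS slab: advection-diffusion of the dissolved chemical in the channel
#' (plane-Poiseuille flow resolved over the channel height), diffusion in
#' the surrounding PDMS, and interfacial flux `J = H (K_PS c_S - c_P)` on
#' the channel walls. The outer slab boundaries are no-flux; the inlet is
#' held at the schedule value; the outlet is an advective outflow.
#'
#' @param device A [channel_device()].
#' @param params A [chemical_params()]. Non-interacting chemicals are
#'   transported but never absorbed.
#' @param schedule A [dose_schedule] giving the inlet concentration.
#' @param t_end_h Simulation horizon, h.
#' @param control A [channel_control()].
#' @return An object of class `channel_result` containing `$series` (a
#'   tibble with time, volume-averaged channel concentration, mixing-cup
#'   outlet concentration, inlet concentration, cumulative delivered mass
#'   `M(t)`, cumulative nominal inlet mass, and the mass ledger columns),
#'   final concentration fields, and a `$ledger` summary. Mass units are
#'   concentration x mm^3.
#' @seealso [dose_metrics()], [simulate_static_device()]
#' @export
simulate_channel <- function(device, params, schedule, t_end_h,
                             control = channel_control()) {
  stopifnot(inherits(device, "channel_device"),
            inherits(params, "chemical_params"),
            inherits(schedule, "dose_schedule"))
  if (!is.numeric(t_end_h) || t_end_h <= 0) stop("t_end_h must be > 0")
  run <- if (control$quasi_steady) {
    .channel_run_qs(device, params, schedule, t_end_h, control)
  } else {
    .channel_run(device, params, schedule, t_end_h, control)
  }
  finalize_channel_result(run, device, params, schedule, control)
}

finalize_channel_result <- function(run, device, params, schedule, control) {
  s <- run$series
  n <- nrow(s)
  initial_solution <- s$mass_solution[1] + s$mass_pdms[1]
  ledger <- list(
    inflow = s$mass_in_actual[n] + initial_solution,
    content = s$mass_solution[n] + s$mass_pdms[n] + s$delivered_mass[n])
  ledger$relative_gap <- (ledger$inflow - ledger$content) /
    max(ledger$inflow, .Machine$double.eps)
  structure(
    list(series = s, fields = run$fields, grid = run$grid, device = device,
         params = params, schedule = schedule, control = control,
         ledger = ledger),
    class = "channel_result")
}

#' @export
print.channel_result <- function(x, ...) {
  cat("<channel_result> ", x$params$name, ", Q = ",
      x$device$flow_rate_ul_min, " uL/min, t_end = ",
      max(x$series$time_h), " h\n", sep = "")
  print(utils::tail(x$series[, 1:6], 3))
  cat(sprintf("  mass ledger gap: %.2e (relative)\n", x$ledger$relative_gap))
  invisible(x)
}

#' Static device loss across load/empty/refill cycles
#'
#' Emulates static-culture depletion assays: the channel is loaded with a
#' uniform solution, left static for an interval, then emptied and refilled
#' with fresh solution while the PDMS retains whatever it has absorbed.
#' Reports the percent of the loaded mass lost from solution during each
#' interval.
#'
#' @param device A [channel_device()] with `flow_rate_ul_min = 0`.
#' @param params A [chemical_params()].
#' @param c0 Loading concentration.
#' @param interval_h Duration of each static interval, h.
#' @param refills Number of empty-and-refill events after the first interval.
#' @param control A [channel_control()]; static runs need no axial
#'   resolution, so a narrow `nx` is used by default.
#' @return A tibble with one row per interval: `interval`, `loss_percent`,
#'   and the solution/PDMS masses at the interval end. The final interval's
#'   full result object is attached as attribute `"last_result"`.
#' @export
#' @examples
#' \donttest{
#' dev <- device_preset("regehr")
#' simulate_static_device(dev, chemical("estradiol"), c0 = 1,
#'                        interval_h = 24, refills = 1)
#' }
simulate_static_device <- function(device, params, c0 = 1, interval_h = 24,
                                   refills = 0,
                                   control = channel_control(nx = 4L,
                                                             dt_h = 0.01)) {
  stopifnot(inherits(device, "channel_device"))
  if (device$flow_rate_ul_min != 0) stop("static device requires Q = 0")
  if (refills < 0) stop("refills must be >= 0")
  if (c0 < 0) stop("c0 must be >= 0")
  schedule <- schedule_constant(c0)   # sets the (re)load concentration
  fields <- NULL
  out <- vector("list", refills + 1L)
  last <- NULL
  for (j in seq_len(refills + 1L)) {
    ctrl <- control
    run <- .channel_run(device, params, schedule, interval_h, ctrl,
                        fields = fields)
    # refill: reset solution cells to c0, keep the PDMS state
    fields <- run$fields
    s <- run$series
    m0 <- s$mass_solution[1]
    m1 <- s$mass_solution[nrow(s)]
    out[[j]] <- tibble::tibble(interval = j,
                               loss_percent = 100 * (m0 - m1) / m0,
                               solution_mass_end = m1,
                               pdms_mass_end = s$mass_pdms[nrow(s)])
    last <- finalize_channel_result(run, device, params, schedule, ctrl)
    fields[last$grid$is_, ] <- c0
  }
  res <- do.call(rbind, out)
  attr(res, "last_result") <- last
  res
}
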