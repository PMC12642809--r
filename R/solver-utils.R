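# Shared finite-volume helpers.
#
# All solvers in the package discretize the partition-diffusion equations in
# conservative (finite-volume) form: each cell has a capacity (volume per
# unit of the unresolved dimension) and exchanges mass with neighbours
# through conductances, so implicit Euler steps conserve total mass to
# round-off by construction.

# Geometrically stretched cell widths covering a depth `d` with `n` cells,
# finest at the interface (index 1). ratio = 1 gives a uniform grid.
stretched_widths <- function(d, n, ratio = 1.18) {
  stopifnot(d > 0, n >= 1)
  if (n == 1L) return(d)
  if (abs(ratio - 1) < 1e-12) return(rep(d / n, n))
  w1 <- d * (ratio - 1) / (ratio^n - 1)
  w1 * ratio^(0:(n - 1))
}

# Interface conductance (per unit interface area) combining the solution-side
# half-cell resistance, the interfacial mass-transfer resistance 1/H and the
# PDMS-side half-cell resistance. The flux across the interface is
#   J = g * (K * c_S - c_P)
# with c_S, c_P the adjacent cell-centre concentrations. `h = Inf` gives the
# local-equilibrium interface (c_P -> K c_S); `h = 0` an impermeable wall.
interface_conductance <- function(h, kps, ds, dz_s, dp, dz_p) {
  if (h == 0) return(0)
  r_int <- if (is.finite(h)) 1 / h else 0
  1 / (r_int + kps * dz_s / (2 * ds) + dz_p / (2 * dp))
}

# Implicit-Euler propagator for du/dt = A u: returns solve(I - dt A).
# Cheap to apply repeatedly as a dense matrix product; system sizes in this
# package are tens of cells.
implicit_propagator <- function(A, dt) {
  n <- nrow(A)
  solve(diag(n) - dt * A)
}

# Linear interpolation of a sampled series onto requested times.
interp_series <- function(t_grid, values, t_out) {
  stats::approx(t_grid, values, xout = t_out, rule = 2)$y
}
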