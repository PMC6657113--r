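#' Physical parameters for flow energetics
#'
#' Blood density and dynamic viscosity used by [kinetic_energy()] and
#' [energy_loss_rate()]. Density defaults to 1.025 g/mL; viscosity to
#' 4.0e-3 Pa.s, the Newtonian value commonly assumed for blood in
#' 4D-flow energy-loss work.
#'
#' @param rho Blood density, g/mL (> 0).
#' @param mu Dynamic viscosity, Pa.s (> 0).
#' @return An object of class `energetics_params`.
#' @export
energetics_params <- function(rho = 1.025, mu = 4.0e-3) {
  if (!is.finite(rho) || rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0", call. = FALSE)
  structure(list(rho = rho, mu = mu), class = "energetics_params")
}

# density in kg/m^3 from g/mL
rho_si <- function(params) params$rho * 1000

#' Per-phase kinetic energy of the segmented chamber
#'
#' For each cardiac phase, KE(t) = sum over in-mask voxels of
#' 1/2 * rho * dV * |v|^2, i.e. the kinetic energy of the blood inside the
#' segmented chamber, reported in millijoules.
#'
#' @param field A [velocity_field()] (m/s).
#' @param mask A [segmentation_mask()] on the same grid.
#' @param params [energetics_params()].
#' @return Numeric vector of length `nt`, mJ.
#' @export
kinetic_energy <- function(field, mask, params = energetics_params()) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(mask, "segmentation_mask"))
  if (!same_grid(field$grid, mask$grid)) stop_grid_mismatch()
  g <- field$grid
  dV <- voxel_volume_m3(g)
  half_rho_dV <- 0.5 * rho_si(params) * dV
  ke <- numeric(g$nt)
  for (t in seq_len(g$nt)) {
    sp2 <- field$v[, , , t, 1]^2 + field$v[, , , t, 2]^2 +
      field$v[, , , t, 3]^2
    ke[t] <- half_rho_dV * sum(sp2[mask$m[, , , t] == 1L])
  }
  ke * 1e3  # J -> mJ
}

# derivative of a 3-D component along one axis, mask-aware:
# central difference where both stencil neighbours are in the mask,
# one-sided where only one is, zero where neither (gradient undefined).
# h in metres, comp in m/s -> 1/s.
masked_derivative <- function(comp, inmask, h, axis) {
  vp <- shift_array(comp, axis, -1L, fill = 0)   # value at i+1
  vm <- shift_array(comp, axis, +1L, fill = 0)   # value at i-1
  mp <- shift_array(inmask, axis, -1L, fill = FALSE)
  mm <- shift_array(inmask, axis, +1L, fill = FALSE)
  mp[is.na(mp)] <- FALSE; mm[is.na(mm)] <- FALSE
  d <- array(0, dim(comp))
  both <- mp & mm
  d[both] <- (vp[both] - vm[both]) / (2 * h)
  fwd <- mp & !mm
  d[fwd] <- (vp[fwd] - comp[fwd]) / h
  bwd <- mm & !mp
  d[bwd] <- (comp[bwd] - vm[bwd]) / h
  d[!inmask] <- 0
  d
}

#' Masked velocity-gradient tensor at one cardiac phase
#'
#' Computes all nine spatial derivatives dv_i/dx_j (1/s) of the velocity at
#' phase `t`, using central differences at voxels whose stencil neighbours
#' lie inside the mask and one-sided differences at mask-boundary voxels;
#' stencils never reach across the chamber boundary, where velocities are
#' undefined. A voxel with no in-mask neighbour along an axis gets a zero
#' derivative on that axis.
#'
#' @param field A [velocity_field()].
#' @param mask A [segmentation_mask()] on the same grid.
#' @param t Phase index (1-based).
#' @return Array `[nx, ny, nz, 3, 3]`; element `[.., i, j]` is dv_i/dx_j in
#'   1/s (zero outside the mask).
#' @export
velocity_gradient <- function(field, mask, t = 1L) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(mask, "segmentation_mask"))
  if (!same_grid(field$grid, mask$grid)) stop_grid_mismatch()
  g <- field$grid
  h <- c(g$dx, g$dy, g$dz) * 1e-3  # mm -> m
  inmask <- mask$m[, , , t] == 1L
  grad <- array(0, c(dim_spatial(g), 3L, 3L))
  for (i in 1:3) {
    comp <- field$v[, , , t, i]
    for (j in 1:3)
      grad[, , , i, j] <- masked_derivative(comp, inmask, h[j], j)
  }
  grad
}

#' Per-phase viscous energy-loss rate
#'
#' Rate of irreversible kinetic-energy dissipation by viscous friction,
#' from the dissipation terms of the Navier-Stokes energy equation for a
#' Newtonian fluid. Per phase,
#' \deqn{EL(t) = \mu \sum_{voxels} dV \; \phi_v,\qquad
#'  \phi_v = \tfrac12 \sum_{i,j}\Big[\Big(\frac{\partial v_i}{\partial x_j}
#'  + \frac{\partial v_j}{\partial x_i}\Big)
#'  - \tfrac23 (\nabla\cdot v)\,\delta_{ij}\Big]^2}
#' The divergence term compensates for the fact that measured fields are
#' not exactly divergence-free; for analytic solenoidal flows it vanishes
#' and \eqn{\phi_v} reduces to the classical incompressible dissipation
#' function. Reported in milliwatts.
#'
#' @inheritParams kinetic_energy
#' @return Numeric vector of length `nt`, mW.
#' @export
energy_loss_rate <- function(field, mask, params = energetics_params()) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(mask, "segmentation_mask"))
  if (!same_grid(field$grid, mask$grid)) stop_grid_mismatch()
  g <- field$grid
  dV <- voxel_volume_m3(g)
  el <- numeric(g$nt)
  for (t in seq_len(g$nt)) {
    grad <- velocity_gradient(field, mask, t)
    div <- grad[, , , 1, 1] + grad[, , , 2, 2] + grad[, , , 3, 3]
    phi <- array(0, dim_spatial(g))
    for (i in 1:3) for (j in 1:3) {
      term <- grad[, , , i, j] + grad[, , , j, i]
      if (i == j) term <- term - (2 / 3) * div
      phi <- phi + term^2
    }
    phi <- 0.5 * phi
    el[t] <- params$mu * dV * sum(phi[mask$m[, , , t] == 1L])
  }
  el * 1e3  # W -> mW
}

#' Per-phase volume-integrated vorticity magnitude
#'
#' The vorticity field is the curl of the velocity, omega = curl v (1/s),
#' computed per voxel with the same masked stencils as
#' [velocity_gradient()]. Per phase the voxel-wise vorticity magnitude
#' |omega| is integrated over the segmented chamber volume —
#' magnitude before summation, so counter-rotating regions do not cancel —
#' giving vorticity_vol(t) in mL/s.
#'
#' @inheritParams kinetic_energy
#' @return Numeric vector of length `nt`, mL/s.
#' @export
vorticity_vol <- function(field, mask) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(mask, "segmentation_mask"))
  if (!same_grid(field$grid, mask$grid)) stop_grid_mismatch()
  g <- field$grid
  dV_ml <- voxel_volume_ml(g)  # mm^3 -> mL; |omega| in 1/s
  out <- numeric(g$nt)
  for (t in seq_len(g$nt)) {
    grad <- velocity_gradient(field, mask, t)
    wx <- grad[, , , 3, 2] - grad[, , , 2, 3]
    wy <- grad[, , , 1, 3] - grad[, , , 3, 1]
    wz <- grad[, , , 2, 1] - grad[, , , 1, 2]
    wmag <- sqrt(wx^2 + wy^2 + wz^2)
    out[t] <- dV_ml * sum(wmag[mask$m[, , , t] == 1L])
  }
  out
}

#' Per-phase energetics time series
#'
#' Bundles the three per-phase quantities for one acquisition.
#'
#' @inheritParams kinetic_energy
#' @return An object of class `energetics_series` with elements `ke_mJ`,
#'   `el_mW`, `vortvol_mL_s` (each length `nt`) and `nt`.
#' @export
energetics_series <- function(field, mask, params = energetics_params()) {
  structure(list(ke_mJ = kinetic_energy(field, mask, params),
                 el_mW = energy_loss_rate(field, mask, params),
                 vortvol_mL_s = vorticity_vol(field, mask),
                 nt = field$grid$nt),
            class = "energetics_series")
}

#' Cardiac-phase averages of an energetics time series
#'
#' Arithmetic means of per-phase KE, EL and vorticity_vol over the systolic
#' frames, the diastolic frames and the complete cycle. All phases weigh
#' equally (retrospective gating gives uniform phase spacing).
#'
#' @param series An `energetics_series` (or a list with numeric `ke_mJ`,
#'   `el_mW`, `vortvol_mL_s`).
#' @param partition A [phase_partition()] valid for the series' `nt`.
#' @return An object of class `energetics_summary`: a named numeric vector
#'   with elements `ke_avg_systole`, `ke_avg_diastole`, `ke_avg_cycle`
#'   (mJ), the `el_*` analogues (mW) and the `vortvol_*` analogues (mL/s).
#' @export
phase_average <- function(series, partition) {
  stopifnot(inherits(partition, "phase_partition"))
  nt <- length(series$ke_mJ)
  if (partition$nt != nt)
    stop("partition does not match the series' number of phases",
         call. = FALSE)
  s <- partition$systole_frames; d <- partition$diastole_frames
  out <- c(ke_avg_systole = mean(series$ke_mJ[s]),
           ke_avg_diastole = mean(series$ke_mJ[d]),
           ke_avg_cycle = mean(series$ke_mJ),
           el_avg_systole = mean(series$el_mW[s]),
           el_avg_diastole = mean(series$el_mW[d]),
           el_avg_cycle = mean(series$el_mW),
           vortvol_avg_systole = mean(series$vortvol_mL_s[s]),
           vortvol_avg_diastole = mean(series$vortvol_mL_s[d]),
           vortvol_avg_cycle = mean(series$vortvol_mL_s))
  class(out) <- c("energetics_summary", class(out))
  out
}

#' Stroke-volume-normalized cycle averages
#'
#' Divides the cycle-averaged KE, EL and vorticity_vol by the stroke
#' volume, yielding KE/SV in mJ/mL, EL/SV in mW/mL and vorticity_vol/SV in
#' 1/s.
#'
#' @param summary An `energetics_summary` from [phase_average()].
#' @param sv Stroke volume, mL (> 0).
#' @return Named numeric vector `ke_cycle_per_sv`, `el_cycle_per_sv`,
#'   `vortvol_cycle_per_sv`.
#' @export
normalize_by_sv <- function(summary, sv) {
  if (!is.finite(sv) || sv <= 0)
    stop("stroke volume must be > 0 for normalization", call. = FALSE)
  c(ke_cycle_per_sv = unname(summary["ke_avg_cycle"]) / sv,
    el_cycle_per_sv = unname(summary["el_avg_cycle"]) / sv,
    vortvol_cycle_per_sv = unname(summary["vortvol_avg_cycle"]) / sv)
}
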