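# Analytic flow phantoms. Each generator returns the sampled velocity
# field, a chamber mask, and the closed-form reference values ("oracle")
# for KE, EL and vorticity_vol, so that the discretized pipeline can be
# validated against exact physics.

# voxel-centre coordinates along each axis, mm (0-based, world = index*spacing)
axis_coords <- function(grid) {
  list(x = (seq_len(grid$nx) - 1) * grid$dx,
       y = (seq_len(grid$ny) - 1) * grid$dy,
       z = (seq_len(grid$nz) - 1) * grid$dz)
}

grid_center_mm <- function(grid) {
  c((grid$nx - 1) * grid$dx, (grid$ny - 1) * grid$dy,
    (grid$nz - 1) * grid$dz) / 2
}

# in-plane radius (mm) and axial offset (mm) of every voxel centre w.r.t.
# a cylinder axis through `center` along coordinate axis `axis`
cylinder_coords <- function(grid, axis, center) {
  co <- axis_coords(grid)
  X <- array(co$x, dim_spatial(grid))
  Y <- aperm(array(co$y, c(grid$ny, grid$nx, grid$nz)), c(2, 1, 3))
  Z <- aperm(array(co$z, c(grid$nz, grid$nx, grid$ny)), c(2, 3, 1))
  P <- list(X - center[1], Y - center[2], Z - center[3])
  ax <- match(axis, c("x", "y", "z"))
  inplane <- setdiff(1:3, ax)
  list(r = sqrt(P[[inplane[1]]]^2 + P[[inplane[2]]]^2),
       u = P[[inplane[1]]], w = P[[inplane[2]]], axial = P[[ax]],
       ax = ax, inplane = inplane)
}

replicate_phases <- function(base3d_list, grid, scales) {
  v <- array(0, c(dim_spatial(grid), grid$nt, 3L))
  for (t in seq_len(grid$nt))
    for (k in 1:3)
      v[, , , t, k] <- base3d_list[[k]] * scales[t]
  v
}

check_scales <- function(scales, grid) {
  if (is.null(scales)) scales <- rep(1, grid$nt)
  if (length(scales) != grid$nt)
    stop("per-phase scale factors must have length nt", call. = FALSE)
  scales
}

phantom_result <- function(grid, v, m, venc, oracle) {
  list(field = velocity_field(grid, v, venc),
       mask = segmentation_mask(grid, m),
       oracle = oracle)
}

#' Uniform-flow phantom
#'
#' Constant velocity `v_vec` everywhere, full-grid mask. Closed forms:
#' KE = 1/2 * rho * V * |v|^2, EL = 0 and vorticity_vol = 0 (a constant
#' field has zero gradients).
#'
#' @param grid A [voxel_grid()].
#' @param v_vec Length-3 velocity, m/s.
#' @param scales Optional per-phase scale factors (length `nt`) for
#'   pulsatile modulation; KE scales as `scales^2`.
#' @param venc Velocity-encoding limit recorded in the field, m/s.
#' @param params [energetics_params()] used for the oracle values.
#' @return List with `field`, `mask` and `oracle` (per-phase `ke_mJ`,
#'   `el_mW`, `vortvol_mL_s`, plus `volume_ml`).
#' @export
make_uniform <- function(grid, v_vec, scales = NULL, venc = 1.5,
                         params = energetics_params()) {
  stopifnot(length(v_vec) == 3L)
  scales <- check_scales(scales, grid)
  base <- lapply(1:3, function(k) array(v_vec[k], dim_spatial(grid)))
  v <- replicate_phases(base, grid, scales)
  m <- array(1L, c(dim_spatial(grid), grid$nt))
  V_m3 <- voxel_volume_m3(grid) * prod(dim_spatial(grid))
  ke <- 0.5 * rho_si(params) * V_m3 * sum(v_vec^2) * scales^2 * 1e3
  phantom_result(grid, v, m, venc,
                 list(ke_mJ = ke, el_mW = numeric(grid$nt),
                      vortvol_mL_s = numeric(grid$nt),
                      volume_ml = V_m3 * 1e6))
}

#' Rigid-rotation phantom
#'
#' Solid-body rotation v = Omega x r about `axis` through `center`, sampled
#' on a cylindrical mask. The velocity is linear in position, so central
#' differences are exact at interior voxels: |curl v| = 2*Omega everywhere,
#' giving vorticity_vol = 2*Omega*V, and the strain rate (hence EL) is
#' identically zero.
#'
#' @param grid A [voxel_grid()].
#' @param omega Rotation rate, 1/s.
#' @param axis Rotation axis, `"x"`, `"y"` or `"z"`.
#' @param center Axis point, mm; defaults to the grid centre.
#' @param radius_mm,length_mm Cylindrical mask dimensions; default to the
#'   largest cylinder fitting the grid.
#' @inheritParams make_uniform
#' @export
make_rigid_rotation <- function(grid, omega, axis = "z", center = NULL,
                                radius_mm = NULL, length_mm = NULL,
                                scales = NULL, venc = NULL,
                                params = energetics_params()) {
  if (is.null(center)) center <- grid_center_mm(grid)
  scales <- check_scales(scales, grid)
  cc <- cylinder_coords(grid, axis, center)
  ext <- c(grid$nx * grid$dx, grid$ny * grid$dy, grid$nz * grid$dz)
  if (is.null(radius_mm)) radius_mm <- min(ext[cc$inplane]) / 2 - 2
  if (is.null(length_mm)) length_mm <- ext[cc$ax] - 2
  # v = Omega x r: tangential, magnitude omega*r, in the plane normal to axis
  om_ms <- omega * 1e-3          # (1/s)*(mm) -> m/s per mm of radius
  base <- lapply(1:3, function(k) array(0, dim_spatial(grid)))
  base[[cc$inplane[1]]] <- -om_ms * cc$w
  base[[cc$inplane[2]]] <- om_ms * cc$u
  v <- replicate_phases(base, grid, scales)
  inmask <- cc$r <= radius_mm & abs(cc$axial) <= length_mm / 2
  m <- array(inmask + 0L, c(dim_spatial(grid), grid$nt))
  if (is.null(venc)) venc <- max(abs(om_ms) * radius_mm, 0.1) * 1.5
  V_ml <- sum(inmask) * voxel_volume_ml(grid)
  phantom_result(grid, v, m, venc,
                 list(ke_mJ = NA_real_,
                      el_mW = numeric(grid$nt),
                      vortvol_mL_s = 2 * abs(omega) * V_ml * abs(scales),
                      volume_ml = V_ml))
}

#' Poiseuille pipe-flow phantom
#'
#' Steady laminar pipe flow: axial velocity v(r) = v_max (1 - r^2/R^2)
#' inside a cylinder of radius `R_mm` and length `L_mm`, zero outside.
#' Closed forms over the cylinder volume V = pi R^2 L:
#' EL = 2 pi mu L v_max^2 and KE = rho v_max^2 V / 6; the vorticity
#' magnitude is |omega|(r) = 2 v_max r / R^2, integrating to
#' vorticity_vol = (4/3) v_max V / R.
#'
#' @param grid A [voxel_grid()].
#' @param R_mm Pipe radius, mm.
#' @param L_mm Pipe length, mm.
#' @param v_max Centreline velocity, m/s.
#' @param axis Pipe axis.
#' @param center Axis point, mm; defaults to the grid centre.
#' @inheritParams make_uniform
#' @export
make_poiseuille <- function(grid, R_mm, L_mm, v_max, axis = "z",
                            center = NULL, scales = NULL, venc = NULL,
                            params = energetics_params()) {
  if (is.null(center)) center <- grid_center_mm(grid)
  scales <- check_scales(scales, grid)
  cc <- cylinder_coords(grid, axis, center)
  co <- axis_coords(grid)
  rng <- list(range(co$x), range(co$y), range(co$z))
  for (ip in cc$inplane)
    if (center[ip] - R_mm < rng[[ip]][1] || center[ip] + R_mm > rng[[ip]][2])
      stop("cylinder radius exceeds the grid", call. = FALSE)
  if (center[cc$ax] - L_mm / 2 < rng[[cc$ax]][1] ||
      center[cc$ax] + L_mm / 2 > rng[[cc$ax]][2])
    stop("cylinder length exceeds the grid", call. = FALSE)
  inmask <- cc$r <= R_mm & abs(cc$axial) <= L_mm / 2
  prof <- array(0, dim_spatial(grid))
  prof[inmask] <- v_max * (1 - (cc$r[inmask] / R_mm)^2)
  base <- lapply(1:3, function(k) array(0, dim_spatial(grid)))
  base[[cc$ax]] <- prof
  v <- replicate_phases(base, grid, scales)
  m <- array(inmask + 0L, c(dim_spatial(grid), grid$nt))
  if (is.null(venc)) venc <- max(abs(v_max), 0.1) * 1.5
  V_m3 <- pi * (R_mm * 1e-3)^2 * (L_mm * 1e-3)
  el <- 2 * pi * params$mu * (L_mm * 1e-3) * v_max^2 * scales^2 * 1e3
  ke <- rho_si(params) * v_max^2 * V_m3 / 6 * scales^2 * 1e3
  vort <- (4 / 3) * abs(v_max) * V_m3 / (R_mm * 1e-3) * abs(scales) * 1e6
  phantom_result(grid, v, m, venc,
                 list(ke_mJ = ke, el_mW = el, vortvol_mL_s = vort,
                      volume_ml = V_m3 * 1e6))
}

#' Lamb-Oseen vortex phantom
#'
#' A viscous line vortex: tangential velocity
#' v_theta(r) = (Gamma / 2 pi r) (1 - exp(-r^2 / r_c^2)) about `axis`,
#' with axial vorticity omega(r) = (Gamma / pi r_c^2) exp(-r^2 / r_c^2).
#' The vorticity is single-signed, so each cross-sectional slice integrates
#' to the circulation Gamma and vorticity_vol = Gamma * L over a cylinder
#' of length `L_mm`, provided the mask radius is at least ~4 r_c (the tail
#' beyond that carries < 1e-6 of Gamma). Peak vorticity at the core centre
#' is Gamma / (pi r_c^2).
#'
#' @param grid A [voxel_grid()].
#' @param gamma Circulation, m^2/s.
#' @param r_c_mm Core radius, mm.
#' @param L_mm Cylinder (mask) length, mm.
#' @param axis Vortex axis.
#' @param center Axis point, mm; defaults to the grid centre.
#' @param mask_radius_mm Mask radius, mm; defaults to the largest fitting
#'   radius and must be >= 4 * r_c_mm.
#' @inheritParams make_uniform
#' @export
make_lamb_oseen <- function(grid, gamma, r_c_mm, L_mm, axis = "z",
                            center = NULL, mask_radius_mm = NULL,
                            scales = NULL, venc = NULL,
                            params = energetics_params()) {
  if (is.null(center)) center <- grid_center_mm(grid)
  scales <- check_scales(scales, grid)
  cc <- cylinder_coords(grid, axis, center)
  ext <- c(grid$nx * grid$dx, grid$ny * grid$dy, grid$nz * grid$dz)
  if (is.null(mask_radius_mm))
    mask_radius_mm <- min(ext[cc$inplane]) / 2 - max(grid$dx, grid$dy, grid$dz)
  if (mask_radius_mm < 4 * r_c_mm)
    stop("mask radius must be at least 4 core radii for the Gamma*L oracle",
         call. = FALSE)
  r_m <- cc$r * 1e-3
  rc_m <- r_c_mm * 1e-3
  # v_theta / r, finite at the axis: Gamma/(2 pi r^2) (1 - exp(-r^2/rc^2))
  # -> Gamma/(2 pi rc^2) as r -> 0
  vt_over_r <- array(gamma / (2 * pi * rc_m^2), dim(r_m))
  nz <- r_m > 1e-12
  vt_over_r[nz] <- gamma * (1 - exp(-(r_m[nz] / rc_m)^2)) /
    (2 * pi * r_m[nz]^2)
  base <- lapply(1:3, function(k) array(0, dim_spatial(grid)))
  base[[cc$inplane[1]]] <- -vt_over_r * (cc$w * 1e-3)
  base[[cc$inplane[2]]] <- vt_over_r * (cc$u * 1e-3)
  v <- replicate_phases(base, grid, scales)
  inmask <- cc$r <= mask_radius_mm & abs(cc$axial) <= L_mm / 2
  m <- array(inmask + 0L, c(dim_spatial(grid), grid$nt))
  vmax <- abs(gamma) / (2 * pi * rc_m) * 0.6382  # peak of the LO profile
  if (is.null(venc)) venc <- max(vmax, 0.1) * 1.5
  vort <- abs(gamma) * (L_mm * 1e-3) * 1e6 * abs(scales)  # m^3/s -> mL/s
  phantom_result(grid, v, m, venc,
                 list(ke_mJ = NA_real_, el_mW = NA_real_,
                      vortvol_mL_s = vort,
                      peak_vorticity_s = abs(gamma) / (pi * rc_m^2),
                      volume_ml = sum(inmask) * voxel_volume_ml(grid)))
}

# linear interpolation of the contraction fraction across the cycle:
# 0 at the first phase (end-diastole), ramping to 1 over the systolic
# frames (end-systole at the last one) and back to 0 over diastole
contraction_fraction <- function(nt, systole_frames) {
  s <- sort(systole_frames)
  d <- sort(setdiff(seq_len(nt), s))
  f <- numeric(nt)
  f[s] <- seq_along(s) / length(s)
  f[d] <- 1 - seq_along(d) / length(d)
  f
}

#' Beating-ellipsoid chamber phantom
#'
#' A per-phase ellipsoidal mask whose semi-axes interpolate linearly from
#' the end-diastolic values (phase 1) to the end-systolic values (last
#' systolic frame) and back across diastole, emulating a contracting
#' ventricle with analytically known volumes 4/3 pi a b c at every phase.
#'
#' @param grid A [voxel_grid()].
#' @param semi_axes_ed,semi_axes_es Length-3 semi-axes at end-diastole /
#'   end-systole, mm.
#' @param systole_frames 1-based systolic phase indices.
#' @param center Ellipsoid centre, mm; defaults to the grid centre.
#' @return A [segmentation_mask()] with attributes `semi_axes_mm`
#'   (`nt` x 3) and `volume_ml_analytic` (length `nt`).
#' @export
make_beating_ellipsoid_mask <- function(grid, semi_axes_ed, semi_axes_es,
                                        systole_frames, center = NULL) {
  stopifnot(length(semi_axes_ed) == 3L, length(semi_axes_es) == 3L)
  if (is.null(center)) center <- grid_center_mm(grid)
  half_ext <- c((grid$nx - 1) * grid$dx, (grid$ny - 1) * grid$dy,
                (grid$nz - 1) * grid$dz)
  if (any(center + pmax(semi_axes_ed, semi_axes_es) > half_ext + 1e-9) ||
      any(center - pmax(semi_axes_ed, semi_axes_es) < -1e-9))
    stop("ellipsoid does not fit in the grid", call. = FALSE)
  f <- contraction_fraction(grid$nt, systole_frames)
  axes <- outer(rep(1, grid$nt), semi_axes_ed) +
    outer(f, semi_axes_es - semi_axes_ed)
  co <- axis_coords(grid)
  X <- array(co$x, dim_spatial(grid)) - center[1]
  Y <- aperm(array(co$y, c(grid$ny, grid$nx, grid$nz)), c(2, 1, 3)) -
    center[2]
  Z <- aperm(array(co$z, c(grid$nz, grid$nx, grid$ny)), c(2, 3, 1)) -
    center[3]
  m <- array(0L, c(dim_spatial(grid), grid$nt))
  for (t in seq_len(grid$nt)) {
    a <- axes[t, ]
    m[, , , t] <- ((X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2 <= 1) + 0L
  }
  out <- segmentation_mask(grid, m)
  attr(out, "semi_axes_mm") <- axes
  attr(out, "volume_ml_analytic") <- 4 / 3 * pi * apply(axes, 1, prod) / 1000
  out
}

# run code under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Add Gaussian measurement noise to a velocity field
#'
#' I.i.d. zero-mean Gaussian noise per component per voxel, the simplest
#' model of velocity noise in phase-contrast MRI. Reproducible: the seed is
#' required whenever `sigma > 0` and the caller's RNG state is untouched.
#'
#' @param field A [velocity_field()].
#' @param sigma Noise standard deviation, m/s (>= 0).
#' @param seed Integer seed; required when `sigma > 0`.
#' @return The noisy [velocity_field()].
#' @export
add_noise <- function(field, sigma, seed = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(field)
  if (is.null(seed))
    stop("a seed is required when sigma > 0", call. = FALSE)
  field$v <- field$v + with_seed(seed,
    array(stats::rnorm(length(field$v), 0, sigma), dim(field$v)))
  field
}

#' Specification of a simulated rest-stress cohort
#'
#' Defaults reproduce the study conditions of a small Fontan rest/stress
#' cohort: n = 10 subjects, VO2max 30.2 +/- 8.6 mL/kg/min, rest metrics KE
#' 1.8 +/- 0.5 mJ, EL 0.9 +/- 0.4 mW, vorticity_vol 3441 +/- 899 mL/s.
#' For each metric the relative rest-to-stress difference (%) follows
#' `delta = intercept + slope * vo2max + N(0, noise_sd)`; the default
#' slope/intercept/noise are derived once from the reported difference
#' mean +/- SD and its correlation with VO2max via
#' `slope = r * sd_delta / sd_vo2`, `noise_sd = sd_delta * sqrt(1 - r^2)`,
#' `intercept = mean_delta - slope * mean_vo2`.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param vo2max_mean,vo2max_sd VO2max distribution, mL/kg/min.
#' @param metrics Named list; each element a list with `rest_mean`,
#'   `rest_sd`, `slope`, `intercept`, `noise_sd`.
#' @param seed Integer seed (required).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10,
                        vo2max_mean = 30.2, vo2max_sd = 8.6,
                        metrics = NULL, seed) {
  if (missing(seed) || is.null(seed))
    stop("cohort simulation requires an explicit seed", call. = FALSE)
  if (n_subjects < 3) stop("need at least 3 subjects", call. = FALSE)
  if (is.null(metrics)) {
    plant <- function(rest_mean, rest_sd, d_mean, d_sd, r) {
      slope <- r * d_sd / vo2max_sd
      list(rest_mean = rest_mean, rest_sd = rest_sd, slope = slope,
           intercept = d_mean - slope * vo2max_mean,
           noise_sd = d_sd * sqrt(1 - r^2))
    }
    metrics <- list(
      ke = plant(1.8, 0.5, 88, 52, -0.83),
      el = plant(0.9, 0.4, 108, 49, -0.80),
      vort = plant(3441, 899, 27, 19, -0.64))
  }
  if (any(vapply(metrics, function(m) m$rest_sd < 0 || m$noise_sd < 0,
                 logical(1))))
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 vo2max_mean = vo2max_mean, vo2max_sd = vo2max_sd,
                 metrics = metrics, seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_positive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a paired rest-stress cohort with planted VO2max association
#'
#' Draws per-subject VO2max and positive rest metrics, plants a linear
#' relative-difference model `delta% = intercept + slope * vo2max + noise`
#' for each metric and sets `stress = rest * (1 + delta/100)` exactly, so
#' the relative difference recomputed from the table recovers the planted
#' value bit-for-bit and the planted correlation is recoverable by
#' [correlate()].
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with columns `subject_id`, `vo2max`, and
#'   `<metric>_rest` / `<metric>_stress` per metric.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(spec$seed, {
    out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                      vo2max = stats::rnorm(n, spec$vo2max_mean,
                                            spec$vo2max_sd))
    for (nm in names(spec$metrics)) {
      m <- spec$metrics[[nm]]
      rest <- rnorm_positive(n, m$rest_mean, m$rest_sd)
      delta <- m$intercept + m$slope * out$vo2max +
        stats::rnorm(n, 0, m$noise_sd)
      out[[paste0(nm, "_rest")]] <- rest
      out[[paste0(nm, "_stress")]] <- rest * (1 + delta / 100)
    }
    out
  })
}
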