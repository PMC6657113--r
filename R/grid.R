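#' Voxel grid geometry for a 4D acquisition
#'
#' Describes the regular spatial grid and cardiac-phase axis shared by a
#' velocity field and its chamber segmentation: voxel counts, voxel spacing
#' in millimetres, the number of reconstructed cardiac phases and the
#' cardiac-cycle (RR) duration in milliseconds. Phases are assumed uniformly
#' spaced across the RR interval (retrospective gating).
#'
#' @param nx,ny,nz Voxel counts along x, y, z (>= 1).
#' @param dx,dy,dz Voxel spacing in mm (> 0). `dy`, `dz` default to `dx`
#'   (isotropic).
#' @param nt Number of cardiac phases (>= 1).
#' @param rr_ms Cardiac cycle duration in ms.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(20, 20, 20, dx = 2, nt = 30, rr_ms = 800)
#' voxel_volume_ml(g) * prod(dim_spatial(g))  # total grid volume, mL
#' @export
voxel_grid <- function(nx, ny, nz, dx, dy = dx, dz = dx, nt = 1L,
                       rr_ms = 1000) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  nt <- as.integer(nt)
  if (any(c(nx, ny, nz, nt) < 1L))
    stop("voxel counts and phase count must be >= 1", call. = FALSE)
  if (any(!is.finite(c(dx, dy, dz))) || any(c(dx, dy, dz) <= 0))
    stop("voxel spacings must be finite and > 0", call. = FALSE)
  if (!is.finite(rr_ms) || rr_ms <= 0)
    stop("rr_ms must be finite and > 0", call. = FALSE)
  structure(list(nx = nx, ny = ny, nz = nz,
                 dx = as.numeric(dx), dy = as.numeric(dy),
                 dz = as.numeric(dz),
                 nt = nt, rr_ms = as.numeric(rr_ms)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, %d phases over %g ms\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz, x$nt, x$rr_ms))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @export
dim_spatial <- function(grid) c(grid$nx, grid$ny, grid$nz)

#' Voxel volume in millilitres
#'
#' @param grid A `voxel_grid`.
#' @return dx*dy*dz converted from mm^3 to mL.
#' @export
voxel_volume_ml <- function(grid) grid$dx * grid$dy * grid$dz / 1000

# voxel volume in m^3 (internal SI bookkeeping)
voxel_volume_m3 <- function(grid) grid$dx * grid$dy * grid$dz * 1e-9

same_grid <- function(a, b, check_nt = TRUE) {
  ok <- a$nx == b$nx && a$ny == b$ny && a$nz == b$nz &&
    isTRUE(all.equal(c(a$dx, a$dy, a$dz), c(b$dx, b$dy, b$dz)))
  if (check_nt) ok <- ok && a$nt == b$nt
  ok
}

stop_grid_mismatch <- function() {
  stop("velocity field and mask are defined on different grids",
       call. = FALSE)
}

#' Systole/diastole partition of the cardiac phases
#'
#' The reconstructed cycle is split into systolic and diastolic phase
#' indices (1-based). The two sets must be disjoint, non-empty and together
#' cover all `nt` phases. In the source data this split is derived from
#' flow-time curves; here it is an input.
#'
#' @param systole_frames,diastole_frames Integer vectors of 1-based phase
#'   indices.
#' @param nt Total number of phases.
#' @return An object of class `phase_partition`.
#' @export
phase_partition <- function(systole_frames, diastole_frames, nt) {
  s <- sort(unique(as.integer(systole_frames)))
  d <- sort(unique(as.integer(diastole_frames)))
  nt <- as.integer(nt)
  if (length(s) == 0L || length(d) == 0L)
    stop("both systole and diastole must contain at least one phase",
         call. = FALSE)
  if (length(intersect(s, d)) > 0L)
    stop("systole and diastole frames overlap", call. = FALSE)
  if (!setequal(union(s, d), seq_len(nt)))
    stop("systole and diastole frames must jointly cover phases 1..nt",
         call. = FALSE)
  structure(list(systole_frames = s, diastole_frames = d, nt = nt),
            class = "phase_partition")
}

#' Rigid-body transform (rotation + translation)
#'
#' Holds a proper rotation matrix and a translation in mm, as produced by a
#' rigid registration between acquisitions. Only the application of the
#' transform to a segmentation is supported; estimating it is not.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric, mm.
#' @param tol Orthonormality tolerance.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-6) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L)
    stop("translation must have length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > tol ||
      abs(det(rotation) - 1) > tol)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Rotation about a coordinate axis
#'
#' Convenience constructor for [rigid_transform()].
#'
#' @param angle_deg Rotation angle, degrees.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param translation Length-3 numeric, mm.
#' @export
rigid_axis_rotation <- function(angle_deg, axis = c("z", "x", "y"),
                                translation = c(0, 0, 0)) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  R <- switch(axis,
    x = matrix(c(1, 0, 0, 0, c2, s2, 0, -s2, c2), 3, 3),
    y = matrix(c(c2, 0, -s2, 0, 1, 0, s2, 0, c2), 3, 3),
    z = matrix(c(c2, s2, 0, -s2, c2, 0, 0, 0, 1), 3, 3))
  rigid_transform(R, translation)
}
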