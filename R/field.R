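#' Three-component velocity field on a voxel grid
#'
#' Stores the velocity vector per voxel per cardiac phase as a 5-D array
#' `[nx, ny, nz, nt, 3]` in m/s together with the grid geometry and the
#' velocity-encoding limit (VENC) of the phase-contrast acquisition.
#' Velocities beyond +/- VENC alias (wrap) by 2*VENC; see [wrap_velocity()]
#' and [unwrap_velocity()].
#'
#' @param grid A [voxel_grid()].
#' @param v Numeric array `[nx, ny, nz, nt, 3]`, m/s. A `[nx, ny, nz, 3]`
#'   array is accepted when `nt == 1`.
#' @param venc Velocity-encoding limit, m/s (> 0).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(grid, v, venc) {
  stopifnot(inherits(grid, "voxel_grid"))
  dexp <- c(dim_spatial(grid), grid$nt, 3L)
  if (length(dim(v)) == 4L && grid$nt == 1L) dim(v) <- dexp
  if (!identical(as.integer(dim(v)), as.integer(dexp)))
    stop(sprintf("velocity array must have dim [%s]",
                 paste(dexp, collapse = ", ")), call. = FALSE)
  if (!all(is.finite(v)))
    stop("velocity field contains non-finite values", call. = FALSE)
  if (!is.finite(venc) || venc <= 0)
    stop("venc must be finite and > 0", call. = FALSE)
  structure(list(grid = grid, v = v, venc = as.numeric(venc)),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: |v| max %.3g m/s, venc %.3g m/s\n",
              max(abs(x$v)), x$venc))
  print(x$grid)
  invisible(x)
}

#' Binary chamber segmentation sharing a field's grid
#'
#' @param grid A [voxel_grid()].
#' @param m Array `[nx, ny, nz, nt]` of 0/1 (logical accepted). A 3-D array
#'   is accepted when `nt == 1`, and is recycled across phases when
#'   `recycle = TRUE`.
#' @param recycle Recycle a single 3-D mask over all phases.
#' @return An object of class `segmentation_mask` (integer 0/1 storage).
#' @export
segmentation_mask <- function(grid, m, recycle = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.logical(m)) m <- m + 0L
  if (length(dim(m)) == 3L) {
    if (recycle && grid$nt > 1L)
      m <- array(m, c(dim(m), grid$nt))
    else if (grid$nt == 1L)
      dim(m) <- c(dim(m), 1L)
  }
  dexp <- c(dim_spatial(grid), grid$nt)
  if (!identical(as.integer(dim(m)), as.integer(dexp)))
    stop(sprintf("mask array must have dim [%s]",
                 paste(dexp, collapse = ", ")), call. = FALSE)
  if (!all(m %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  storage.mode(m) <- "integer"
  structure(list(grid = grid, m = m), class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation_mask: %d-%d in-mask voxels per phase\n",
              min(apply(x$m, 4, sum)), max(apply(x$m, 4, sum))))
  print(x$grid)
  invisible(x)
}

# strip NIfTI metadata down to a bare numeric array
plain_array <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim(a))
}

grid_from_nifti <- function(img, rr_ms = 1000) {
  d <- dim(img)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L)
    stop("expected a 3-D or 4-D NIfTI volume", call. = FALSE)
  pd <- RNifti::pixdim(img)
  voxel_grid(d[1], d[2], d[3], dx = pd[1], dy = pd[2], dz = pd[3],
             nt = d[4], rr_ms = rr_ms)
}

#' Read a 3-component 4D velocity field from NIfTI files
#'
#' One 4-D volume per velocity component (x, y, z), phases along the 4th
#' axis, voxel values in m/s. Grid spacing is taken from the NIfTI header
#' (mm). All three volumes must agree in shape and spacing.
#'
#' @param paths Character vector of three file paths (vx, vy, vz).
#' @param venc Velocity-encoding limit, m/s.
#' @param rr_ms Cardiac cycle duration, ms (not stored in NIfTI).
#' @return A [velocity_field()].
#' @export
read_velocity_nifti <- function(paths, venc, rr_ms = 1000) {
  if (length(paths) != 3L)
    stop("need exactly three component files (vx, vy, vz)", call. = FALSE)
  imgs <- lapply(paths, RNifti::readNifti)
  grids <- lapply(imgs, grid_from_nifti, rr_ms = rr_ms)
  for (k in 2:3)
    if (!same_grid(grids[[1]], grids[[k]]))
      stop(sprintf("component volumes disagree in shape or spacing: %s vs %s",
                   paths[1], paths[k]), call. = FALSE)
  g <- grids[[1]]
  v <- array(0, c(dim_spatial(g), g$nt, 3L))
  for (k in 1:3) {
    a <- plain_array(imgs[[k]])
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    v[, , , , k] <- a
  }
  velocity_field(g, v, venc)
}

#' Write a velocity field to three NIfTI component files
#'
#' @param field A [velocity_field()].
#' @param paths Three output paths (vx, vy, vz).
#' @return `paths`, invisibly.
#' @export
write_velocity_nifti <- function(field, paths) {
  stopifnot(inherits(field, "velocity_field"), length(paths) == 3L)
  g <- field$grid
  for (k in 1:3) {
    img <- RNifti::asNifti(field$v[, , , , k, drop = TRUE])
    RNifti::pixdim(img) <- c(g$dx, g$dy, g$dz, 1)[seq_along(dim(img))]
    RNifti::writeNifti(img, paths[k], datatype = "double")
  }
  invisible(paths)
}

#' Read / write a 4-D segmentation mask as NIfTI
#'
#' @param path NIfTI file; values must be 0/1.
#' @param rr_ms Cardiac cycle duration, ms.
#' @return A [segmentation_mask()].
#' @export
read_mask_nifti <- function(path, rr_ms = 1000) {
  img <- RNifti::readNifti(path)
  g <- grid_from_nifti(img, rr_ms = rr_ms)
  a <- plain_array(img)
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  segmentation_mask(g, round(a))
}

#' @rdname read_mask_nifti
#' @param mask A [segmentation_mask()].
#' @export
write_mask_nifti <- function(mask, path) {
  g <- mask$grid
  img <- RNifti::asNifti(mask$m)
  RNifti::pixdim(img) <- c(g$dx, g$dy, g$dz, 1)[seq_along(dim(img))]
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Forward model of phase-contrast velocity aliasing
#'
#' Velocities outside the +/- VENC window wrap around by multiples of
#' 2*VENC, exactly as phase wraps in the acquired data: each component is
#' mapped to `((v + venc) mod 2*venc) - venc`. Used to build aliased
#' phantoms for testing the unwrapping step.
#'
#' @param field A [velocity_field()].
#' @return The aliased field; values always lie in `[-venc, venc)`.
#' @export
wrap_velocity <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  venc <- field$venc
  field$v <- ((field$v + venc) %% (2 * venc)) - venc
  field
}

#' Region-growing velocity anti-aliasing
#'
#' Single-wrap correction of aliased voxels inside the chamber. Within
#' each connected in-mask region the correction grows outward from a seed
#' voxel assumed alias-free — the voxel with the smallest speed, since
#' no-slip at the chamber wall makes the slowest voxels the most reliable.
#' Visiting masked voxels in breadth-first order, each component value
#' that differs from the median of its already-corrected in-mask
#' 6-neighbours by more than VENC is shifted by +/- 2*VENC, with the sign
#' that minimizes that difference. Deterministic; only masked voxels are
#' touched; single wraps only (|true v| < 2*VENC), which the propagation
#' resolves exactly on fields whose true voxel-to-voxel velocity jumps
#' stay below VENC. A purely local one-pass threshold rule cannot do this:
#' a coherently wrapped core agrees with its own neighbourhood, so the
#' correction must propagate from unaliased flow inward.
#'
#' @param field A [velocity_field()].
#' @param mask A [segmentation_mask()] on the same grid.
#' @return The corrected [velocity_field()].
#' @export
unwrap_velocity <- function(field, mask) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(mask, "segmentation_mask"))
  if (!same_grid(field$grid, mask$grid)) stop_grid_mismatch()
  venc <- field$venc
  g <- field$grid
  ds <- dim_spatial(g)
  for (t in seq_len(g$nt)) {
    mt <- mask$m[, , , t] == 1L
    if (!any(mt)) next
    nb <- neighbour_table(mt, ds)
    for (k in 1:3) {
      vk <- field$v[, , , t, k]
      field$v[, , , t, k] <- unwrap_component(vk, nb, venc)
    }
  }
  field
}

# 6-neighbour linear indices for every in-mask voxel: a length(idx) x 6
# matrix, NA where the neighbour is outside the grid or outside the mask
neighbour_table <- function(inmask, ds) {
  idx <- which(inmask)
  ijk <- arrayInd(idx, ds)
  n <- length(idx)
  nbs <- matrix(NA_integer_, n, 6L)
  strides <- c(1L, ds[1], ds[1] * ds[2])
  col <- 0L
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    col <- col + 1L
    ok <- if (s < 0) ijk[, ax] > 1L else ijk[, ax] < ds[ax]
    cand <- idx[ok] + s * strides[ax]
    cand[!inmask[cand]] <- NA_integer_
    nbs[ok, col] <- cand
  }
  row_of <- integer(prod(ds))
  row_of[idx] <- seq_len(n)
  list(idx = idx, nbs = nbs, row_of = row_of,
       speed_order = NULL)
}

unwrap_component <- function(vk, nb, venc) {
  n <- length(nb$idx)
  visited <- logical(n)
  queue <- integer(n)
  # seeds in order of increasing |v|: slowest voxels assumed alias-free
  seed_order <- order(abs(vk[nb$idx]))
  for (s in seed_order) {
    if (visited[s]) next
    head <- 1L; tail <- 1L
    queue[1L] <- s
    visited[s] <- TRUE
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      for (nbr in nb$nbs[cur, ]) {
        if (is.na(nbr)) next
        r <- nb$row_of[nbr]
        if (visited[r]) next
        done <- nb$nbs[r, ]
        done <- done[!is.na(done)]
        done <- done[visited[nb$row_of[done]]]
        ref <- stats::median(vk[done])
        d <- vk[nbr] - ref
        if (d > venc) vk[nbr] <- vk[nbr] - 2 * venc
        else if (d < -venc) vk[nbr] <- vk[nbr] + 2 * venc
        visited[r] <- TRUE
        tail <- tail + 1L
        queue[tail] <- r
      }
    }
  }
  vk
}

# shift a 3-D array by `s` voxels along axis `ax`, padding with `fill`
shift_array <- function(a, ax, s, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[ax]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  idx_src <- idx_dst <- lapply(d, seq_len)
  idx_src[[ax]] <- src; idx_dst[[ax]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Apply a rigid transform to a segmentation mask
#'
#' Resamples the mask on its own grid under a rigid-body transform using
#' nearest-neighbour interpolation (binary in/out, no partial-volume
#' weighting). World coordinates are voxel-centred: `world = (index - 1) *
#' spacing`. For each output voxel the inverse-transformed location is
#' looked up in the input mask; locations outside the grid map to 0.
#'
#' @param mask A [segmentation_mask()].
#' @param transform A [rigid_transform()] mapping input world coordinates to
#'   output world coordinates.
#' @return The transformed [segmentation_mask()].
#' @export
apply_rigid_to_mask <- function(mask, transform) {
  stopifnot(inherits(mask, "segmentation_mask"),
            inherits(transform, "rigid_transform"))
  g <- mask$grid
  sp <- c(g$dx, g$dy, g$dz)
  ds <- dim_spatial(g)
  # world coordinates of all output voxel centres (n x 3)
  ijk <- as.matrix(expand.grid(i = seq_len(ds[1]), j = seq_len(ds[2]),
                               k = seq_len(ds[3])))
  world <- sweep(ijk - 1, 2, sp, `*`)
  # inverse transform: x_in = R^T (x_out - t)
  src <- sweep(world, 2, transform$translation, `-`) %*% transform$rotation
  src_ijk <- round(sweep(src, 2, sp, `/`)) + 1
  inside <- src_ijk[, 1] >= 1 & src_ijk[, 1] <= ds[1] &
    src_ijk[, 2] >= 1 & src_ijk[, 2] <= ds[2] &
    src_ijk[, 3] >= 1 & src_ijk[, 3] <= ds[3]
  lin_out <- ijk[inside, 1] + (ijk[inside, 2] - 1) * ds[1] +
    (ijk[inside, 3] - 1) * ds[1] * ds[2]
  lin_src <- src_ijk[inside, 1] + (src_ijk[inside, 2] - 1) * ds[1] +
    (src_ijk[inside, 3] - 1) * ds[1] * ds[2]
  nvox <- prod(ds)
  out <- mask$m
  for (t in seq_len(g$nt)) {
    mt <- mask$m[, , , t]
    ot <- integer(nvox)
    ot[lin_out] <- mt[lin_src]
    out[, , , t] <- ot
  }
  mask$m <- out
  mask
}

#' Read a per-subject acquisition configuration
#'
#' YAML or JSON file holding, per condition, the acquisition metadata the
#' pipeline needs: `venc` (m/s), `rr_ms`, `heart_rate_bpm`, 1-based
#' `systole_frames` / `diastole_frames`, file paths for the velocity triplet
#' and mask, an optional rigid transform (12 numbers, row-major 3x4), and
#' optional `rho` / `mu` overrides.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list as stored in the file.
#' @export
read_subject_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg
}

config_transform <- function(numbers) {
  numbers <- as.numeric(numbers)
  if (length(numbers) != 12L)
    stop("rigid transform must be 12 numbers (row-major 3x4)", call. = FALSE)
  m <- matrix(numbers, 3, 4, byrow = TRUE)
  rigid_transform(m[, 1:3], m[, 4])
}
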