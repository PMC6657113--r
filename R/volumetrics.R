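#' Chamber volume per cardiac phase
#'
#' Voxel-count volumetry: V(t) = (number of in-mask voxels at phase t)
#' times the voxel volume, in mL.
#'
#' @param mask A [segmentation_mask()].
#' @return Numeric vector of length `nt`, mL.
#' @export
volume_curve <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  apply(mask$m, 4, sum) * voxel_volume_ml(mask$grid)
}

#' Global function parameters from a volume curve
#'
#' End-diastolic volume is the maximum of the curve, end-systolic the
#' minimum (volume-extremum convention); stroke volume SV = EDV - ESV,
#' ejection fraction EF = 100 * SV / EDV, cardiac output CO = SV * HR in
#' L/min.
#'
#' @param curve Per-phase volume, mL (from [volume_curve()]).
#' @param hr_bpm Heart rate, beats/min.
#' @return An object of class `volumetric_summary`: named numeric with
#'   `edv_ml`, `esv_ml`, `sv_ml`, `ef_pct`, `co_l_min`, `hr_bpm`,
#'   `ed_phase`, `es_phase`.
#' @export
summarize_volumes <- function(curve, hr_bpm) {
  if (length(curve) == 0L) stop("empty volume curve", call. = FALSE)
  if (!is.finite(hr_bpm) || hr_bpm <= 0)
    stop("heart rate must be > 0", call. = FALSE)
  if (all(curve == 0))
    stop("chamber volume is zero at every phase; EF undefined",
         call. = FALSE)
  edv <- max(curve); esv <- min(curve)
  sv <- edv - esv
  out <- c(edv_ml = edv, esv_ml = esv, sv_ml = sv,
           ef_pct = 100 * sv / edv, co_l_min = sv * hr_bpm / 1000,
           hr_bpm = hr_bpm,
           ed_phase = which.max(curve), es_phase = which.min(curve))
  class(out) <- c("volumetric_summary", class(out))
  out
}

#' Sphericity index of the chamber at one phase
#'
#' Short-to-long-axis ratio, ventricular width / ventricular height,
#' measured as the ratio of axis-aligned bounding-box extents of the mask:
#' extent along the in-plane width axis divided by extent along the
#' base-apex (long) axis. Which grid axes play those roles is a property
#' of the acquisition orientation and is passed explicitly.
#'
#' @param mask A [segmentation_mask()].
#' @param phase 1-based phase index.
#' @param width_axis,height_axis Grid axes (`"x"`, `"y"`, `"z"`).
#' @return Dimensionless ratio.
#' @export
sphericity_index <- function(mask, phase, width_axis = "x",
                             height_axis = "z") {
  stopifnot(inherits(mask, "segmentation_mask"))
  mt <- mask$m[, , , phase]
  if (!any(mt == 1L))
    stop(sprintf("mask is empty at phase %d", phase), call. = FALSE)
  extent <- function(axis) {
    ax <- match(axis, c("x", "y", "z"))
    present <- apply(mt == 1L, ax, any)
    idx <- range(which(present))
    (idx[2] - idx[1] + 1) * c(mask$grid$dx, mask$grid$dy, mask$grid$dz)[ax]
  }
  extent(width_axis) / extent(height_axis)
}

#' Full volumetric summary of a mask series
#'
#' Convenience wrapper: volume curve, [summarize_volumes()], and sphericity
#' indices at the end-diastolic and end-systolic phases.
#'
#' @inheritParams sphericity_index
#' @param hr_bpm Heart rate, beats/min.
#' @return A list with `curve_ml`, `summary` (a `volumetric_summary`),
#'   `sphericity_ed`, `sphericity_es`.
#' @export
volumetrics <- function(mask, hr_bpm, width_axis = "x", height_axis = "z") {
  curve <- volume_curve(mask)
  s <- summarize_volumes(curve, hr_bpm)
  list(curve_ml = curve, summary = s,
       sphericity_ed = sphericity_index(mask, s[["ed_phase"]],
                                        width_axis, height_axis),
       sphericity_es = sphericity_index(mask, s[["es_phase"]],
                                        width_axis, height_axis))
}
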