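# Anchor-ball alignment and ROI extraction. The composite-resin ball placed on
# the specimen's top surface is the single bright compact object in the upper
# part of both scans; its intensity-weighted centroid defines the lateral ROI
# centre and the first slice below it defines the axial ROI origin.

#' ROI specification
#'
#' @param extent_mm cuboid extents `(x, y, z)` in mm; the default is the
#'   4 x 4 x 10 mm implant-sized region.
#' @param anchor_mode how the ROI is positioned: `"ball_centroid"` (from a
#'   located anchor), `"volume_center"`, or `"explicit"`.
#' @param explicit_origin_voxel optional `(z, y, x)` origin (1-based) for
#'   `anchor_mode = "explicit"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(extent_mm = c(4, 4, 10),
                     anchor_mode = c("ball_centroid", "volume_center", "explicit"),
                     explicit_origin_voxel = NULL) {
  anchor_mode <- match.arg(anchor_mode)
  if (length(extent_mm) != 3L || any(extent_mm <= 0))
    stop("`extent_mm` must be three positive extents (x, y, z)")
  if (anchor_mode == "explicit" && is.null(explicit_origin_voxel))
    stop("explicit anchor mode needs `explicit_origin_voxel`")
  structure(list(extent_mm = extent_mm, anchor_mode = anchor_mode,
                 explicit_origin_voxel = explicit_origin_voxel),
            class = "roi_spec")
}

#' Locate the anchor ball
#'
#' Thresholds the upper third of the stack (where the ball sits) at a high
#' intensity quantile of that region, labels the bright voxels
#' (6-connectivity) and requires exactly one compact candidate component.
#' Components smaller than `min_voxels` are treated as noise, not candidates.
#'
#' @param vol a [gray_volume].
#' @param ball_threshold_quantile quantile of the upper-third intensities
#'   defining "bright" (default 0.995).
#' @param min_voxels minimum component size to count as a candidate.
#' @return An `anchor_location`: list with `centroid_voxel` (`(z, y, x)`,
#'   continuous, 1-based) and `top_surface_z` (first specimen slice below the
#'   ball).
#' @export
locate_anchor <- function(vol, ball_threshold_quantile = 0.995, min_voxels = 5L) {
  stopifnot(inherits(vol, "gray_volume"))
  d <- dim(vol$data)
  z_top <- max(1L, as.integer(ceiling(d[1] / 3)))
  top <- vol$data[seq_len(z_top), , , drop = FALSE]
  thr <- quantile(top, ball_threshold_quantile, names = FALSE)
  bright <- top > thr
  # a saturated ball can tie the quantile with the maximum; fall back to >=
  if (!any(bright)) bright <- top >= thr
  if (!any(bright)) stop("no voxels above the ball threshold quantile")
  dt <- dim(top)
  lab <- cpp_label6(array(as.integer(bright), dt), dt)
  sizes <- tabulate(lab)
  cand <- which(sizes >= min_voxels)
  if (length(cand) == 0L) stop("no anchor-ball candidate found in the upper third")
  if (length(cand) > 1L) stop(length(cand), " anchor-ball candidates found; expected one")
  sel <- lab == cand
  w <- top[sel]
  zi <- slice.index(lab, 1)[sel]
  yi <- slice.index(lab, 2)[sel]
  xi <- slice.index(lab, 3)[sel]
  centroid <- c(sum(w * zi), sum(w * yi), sum(w * xi)) / sum(w)
  top_z <- max(zi) + 1L
  if (top_z > d[1]) stop("anchor ball touches the bottom of the search region")
  structure(list(centroid_voxel = centroid, top_surface_z = top_z),
            class = "anchor_location")
}

#' Extract an aligned ROI cuboid
#'
#' The cuboid is centred laterally on the anchor centroid and extends from
#' `top_surface_z` inward (increasing z). Output dimensions are computed
#' independently at each resolution as `round(extent_mm / voxel_mm)` per axis
#' (round half away from zero), mirroring physical-ROI alignment between
#' scanners.
#'
#' @param vol a [gray_volume].
#' @param anchor an `anchor_location` from [locate_anchor()] (ignored for
#'   `anchor_mode = "volume_center"` / `"explicit"`).
#' @param roi a [roi_spec].
#' @return A [gray_volume] cropped to the ROI; voxel size preserved.
#' @export
extract_roi <- function(vol, anchor = NULL, roi = roi_spec()) {
  stopifnot(inherits(vol, "gray_volume"), inherits(roi, "roi_spec"))
  d <- dim(vol$data)
  nd <- as.integer(rnd_half_away(rev(roi$extent_mm) / vol$voxel_mm)) # (z, y, x)
  if (any(nd < 1L)) stop("ROI smaller than one voxel along some axis")
  origin <- switch(roi$anchor_mode,
    ball_centroid = {
      if (is.null(anchor)) stop("ball_centroid mode needs an anchor location")
      ctr <- as.integer(rnd_half_away(anchor$centroid_voxel))
      c(anchor$top_surface_z, ctr[2] - nd[2] %/% 2L, ctr[3] - nd[3] %/% 2L)
    },
    volume_center = as.integer(floor((d - nd) / 2)) + 1L,
    explicit = as.integer(roi$explicit_origin_voxel))
  end <- origin + nd - 1L
  if (any(origin < 1L) || any(end > d))
    stop(sprintf("ROI [%s]..[%s] exceeds volume bounds [%s]",
                 paste(origin, collapse = ","), paste(end, collapse = ","),
                 paste(d, collapse = ",")))
  out <- vol$data[origin[1]:end[1], origin[2]:end[2], origin[3]:end[3], drop = FALSE]
  v <- gray_volume(out, vol$voxel_mm, vol$modality, vol$bit_depth)
  attr(v, "roi_origin_voxel") <- origin
  v
}
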