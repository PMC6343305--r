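# Trabecular morphometry on binary volumes. TbTh and TbSp use the
# Hildebrand-Ruegsegger model-independent definition: the local thickness at a
# voxel is the diameter of the largest sphere fully contained in the phase
# that covers the voxel, averaged over the phase. The digital convention is
# fixed and exact: a sphere centred at voxel c has radius EDT(c) - 0.5 voxels
# (EDT = exact Euclidean distance to the nearest off-phase or out-of-volume
# voxel centre), so an isolated voxel measures 1 voxel and a solid 9-cube
# measures 9 voxels across. Spheres must fit inside the ROI (no mirror
# padding); the resulting edge bias is identical across compared groups.
# TbN uses the ratio convention TbN = (BV/TV) / TbTh.

phase_mask <- function(mask, phase) {
  stopifnot(inherits(mask, "binary_volume"))
  phase <- match.arg(phase, c("foreground", "background"))
  m <- if (phase == "foreground") mask$mask else !mask$mask
  list(m = m, phase = phase)
}

thickness_map <- function(tau_vox, mask, phase) {
  structure(list(tau = tau_vox * mask$voxel_mm, phase = phase,
                 voxel_mm = mask$voxel_mm),
            class = "thickness_map")
}

#' Bone volume fraction (BV/TV)
#'
#' @param mask a [binary_volume].
#' @return Percentage of voxels that are foreground.
#' @export
bone_volume_fraction <- function(mask) {
  stopifnot(inherits(mask, "binary_volume"))
  if (length(mask$mask) == 0L) stop("zero-size volume")
  100 * sum(mask$mask) / length(mask$mask)
}

#' Model-independent local thickness
#'
#' For every in-phase voxel, the diameter (mm) of the largest sphere fully
#' contained in the phase and covering that voxel. Exact with respect to the
#' digital definition (distance ridge + sphere propagation, no approximation);
#' [brute_force_thickness()] is the definitional oracle it must match
#' voxel-for-voxel.
#'
#' @param mask a [binary_volume].
#' @param phase `"foreground"` (trabeculae, for TbTh) or `"background"`
#'   (marrow, for TbSp).
#' @return A `thickness_map`: list with `tau` (3D array, mm; 0 off-phase),
#'   `phase`, `voxel_mm`.
#' @export
local_thickness <- function(mask, phase = "foreground") {
  pm <- phase_mask(mask, phase)
  if (!any(pm$m)) stop("empty phase: ", pm$phase)
  d <- dim(pm$m)
  tau <- cpp_local_thickness(array(as.integer(pm$m), d), d)
  thickness_map(tau, mask, pm$phase)
}

#' Brute-force thickness oracle
#'
#' Direct evaluation of the sphere-fitting definition by enumerating every
#' in-phase candidate centre with its radius from the exact Euclidean distance
#' transform. Definitionally correct and intentionally unoptimised; guarded to
#' small volumes.
#'
#' @inheritParams local_thickness
#' @return A `thickness_map`.
#' @export
brute_force_thickness <- function(mask, phase = "foreground") {
  pm <- phase_mask(mask, phase)
  if (prod(dim(pm$m)) > 40^3) stop("brute-force oracle limited to 40^3 voxels")
  if (!any(pm$m)) stop("empty phase: ", pm$phase)
  d <- dim(pm$m)
  tau <- cpp_brute_thickness(array(as.integer(pm$m), d), d)
  thickness_map(tau, mask, pm$phase)
}

#' Mean thickness of a phase
#'
#' Unweighted mean of the local thickness over in-phase voxels, in mm: TbTh
#' for the foreground map, TbSp for the background map.
#'
#' @param tmap a `thickness_map`.
#' @return Mean thickness in mm.
#' @export
mean_thickness <- function(tmap) {
  stopifnot(inherits(tmap, "thickness_map"))
  v <- tmap$tau[tmap$tau > 0]
  if (length(v) == 0L) stop("empty phase: no thickness values")
  mean(v)
}

#' Trabecular number (TbN)
#'
#' The ratio convention: `TbN = (BV/TV) / TbTh`, trabeculae per millimetre;
#' 0 when BV/TV is 0.
#'
#' @param bv_tv bone volume fraction in percent.
#' @param tb_th mean trabecular thickness in mm.
#' @return TbN in 1/mm.
#' @export
trabecular_number <- function(bv_tv, tb_th) {
  if (bv_tv == 0) return(0)
  if (tb_th <= 0) stop("tb_th must be positive when bv_tv > 0")
  (bv_tv / 100) / tb_th
}

#' Compute the four microarchitectural parameters
#'
#' BV/TV by voxel counting; TbTh and TbSp as mean foreground/background local
#' thickness; TbN by the ratio rule. All-foreground (or all-background)
#' volumes report TbSp (resp. TbTh and TbN) as 0 with a `degenerate` flag.
#'
#' @param mask a [binary_volume].
#' @param specimen_id,group identifiers carried into the result.
#' @param params subset of `c("bv_tv", "tb_th", "tb_n", "tb_sp")` to compute
#'   (thickness transforms dominate the cost; `tb_n` requires `tb_th`).
#' @return A `morphometry_result`: list with `specimen_id`, `group`, `bv_tv`
#'   (percent), `tb_th` (mm), `tb_n` (1/mm), `tb_sp` (mm), `degenerate` flag.
#'   Parameters not requested are `NA`.
#' @export
compute_morphometry <- function(mask, specimen_id = NA_character_,
                                group = mask$provenance,
                                params = c("bv_tv", "tb_th", "tb_n", "tb_sp")) {
  stopifnot(inherits(mask, "binary_volume"))
  if (length(mask$mask) == 0L) stop("zero-size volume")
  params <- match.arg(params, several.ok = TRUE)
  if ("tb_n" %in% params && !"tb_th" %in% params) params <- c(params, "tb_th")
  n_fg <- sum(mask$mask)
  n <- length(mask$mask)
  bv <- 100 * n_fg / n
  degenerate <- n_fg == 0L || n_fg == n
  th <- sp <- tn <- NA_real_
  if ("tb_th" %in% params)
    th <- if (n_fg == 0L) 0 else mean_thickness(local_thickness(mask, "foreground"))
  if ("tb_sp" %in% params)
    sp <- if (n_fg == n) 0 else mean_thickness(local_thickness(mask, "background"))
  if ("tb_n" %in% params)
    tn <- if (n_fg == 0L) 0 else trabecular_number(bv, th)
  structure(list(specimen_id = specimen_id, group = group,
                 bv_tv = if ("bv_tv" %in% params) bv else NA_real_,
                 tb_th = th, tb_n = tn, tb_sp = sp, degenerate = degenerate),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry> %s %s: BV/TV %.2f%%, TbTh %.3f mm, TbN %.3f /mm, TbSp %.3f mm%s\n",
              x$specimen_id, x$group, x$bv_tv, x$tb_th, x$tb_n, x$tb_sp,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

morphometry_row <- function(res) {
  data.frame(specimen_id = res$specimen_id, group = res$group,
             bv_tv_pct = res$bv_tv, tb_th_mm = res$tb_th,
             tb_n_per_mm = res$tb_n, tb_sp_mm = res$tb_sp,
             stringsAsFactors = FALSE)
}
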