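# The cumulative preprocessing ladder applied to CBCT volumes before
# binarization:
#   G0  micro-CT reference, global isodata threshold, no filters
#   G1  raw CBCT, global isodata threshold
#   G2  sharpen -> despeckle -> global threshold
#   G3  sharpen -> despeckle -> per-slice threshold
#   G4  G3 followed by removal of voxels at or below the zero-BMD grayscale
# Filters operate 2D per slice (the workflow this mirrors processed slice
# images in a 2D tool). Filter order is fixed: sharpen before despeckle.

#' Sharpen a volume (per slice)
#'
#' Classic 3x3 unsharp kernel — centre 12, neighbours -1, divided by 4 (the
#' default "sharpen" of the common 2D imaging tools); edge replication; output
#' clipped to the volume's representable grayscale range.
#'
#' @param vol a [gray_volume].
#' @return A sharpened [gray_volume].
#' @export
sharpen <- function(vol) {
  stopifnot(inherits(vol, "gray_volume"))
  rng <- gray_range(vol)
  out <- cpp_sharpen(vol$data, dim(vol$data), rng[1], rng[2])
  gray_volume(out, vol$voxel_mm, vol$modality, vol$bit_depth)
}

#' Despeckle a volume (per slice)
#'
#' Replaces each pixel with the median of its 3x3 in-slice neighbourhood,
#' with edge replication.
#'
#' @param vol a [gray_volume].
#' @return A despeckled [gray_volume].
#' @export
despeckle <- function(vol) {
  stopifnot(inherits(vol, "gray_volume"))
  out <- cpp_median3(vol$data, dim(vol$data))
  gray_volume(out, vol$voxel_mm, vol$modality, vol$bit_depth)
}

#' Isodata automatic threshold
#'
#' Ridler-Calvard iteration: starting from the overall mean, the threshold is
#' repeatedly replaced by the midpoint of the means of the two classes it
#' induces (values <= T vs values > T) until the update is below
#' `1e-6 * (max - min)`. Foreground is strictly greater than the returned
#' threshold; ties go to background.
#'
#' @param values numeric vector (or 3D array) of grayscales with at least two
#'   distinct values.
#' @param scope,slice_index bookkeeping tags recorded in the result.
#' @return A `threshold_result`: list with `value`, `scope`, `slice_index`,
#'   `iterations`.
#' @export
isodata_threshold <- function(values, scope = "global", slice_index = NULL) {
  v <- as.numeric(values)
  if (length(v) < 2L || !all(is.finite(v))) stop("need >= 2 finite values")
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("constant input: no threshold exists")
  s <- sort(v)
  cs <- cumsum(s)
  n <- length(s)
  tol <- 1e-6 * (hi - lo)
  t_cur <- mean(v)
  iter <- 0L
  repeat {
    k <- findInterval(t_cur, s)
    k <- min(max(k, 1L), n - 1L)
    t_new <- (cs[k] / k + (cs[n] - cs[k]) / (n - k)) / 2
    iter <- iter + 1L
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
    if (iter > 1000L) break # histogram cycles cannot occur, but stay safe
  }
  structure(list(value = t_cur, scope = scope, slice_index = slice_index,
                 iterations = iter),
            class = "threshold_result")
}

#' Global isodata binarization
#'
#' One isodata threshold from all voxels; the mask is `volume > T`.
#'
#' @param vol a [gray_volume].
#' @param provenance group tag recorded on the mask.
#' @return A [binary_volume].
#' @export
binarize_global <- function(vol, provenance = "G1") {
  stopifnot(inherits(vol, "gray_volume"))
  thr <- isodata_threshold(vol$data, scope = "global")
  m <- vol$data > thr$value
  out <- binary_volume(m, vol$voxel_mm, provenance)
  attr(out, "threshold") <- thr
  out
}

#' Per-slice isodata binarization
#'
#' An isodata threshold computed independently from each z-slice's data, so
#' that any per-slice affine intensity distortion (e.g. axial shading) cancels
#' out. Constant slices inherit the threshold of the nearest non-constant
#' slice.
#'
#' @param vol a [gray_volume].
#' @param provenance group tag recorded on the mask.
#' @return A [binary_volume] with per-slice thresholds in
#'   `attr(, "thresholds")`.
#' @export
binarize_per_slice <- function(vol, provenance = "G3") {
  stopifnot(inherits(vol, "gray_volume"))
  d <- dim(vol$data)
  thr <- rep(NA_real_, d[1])
  for (z in seq_len(d[1])) {
    sl <- vol$data[z, , ]
    if (min(sl) < max(sl))
      thr[z] <- isodata_threshold(sl, scope = "slice", slice_index = z)$value
  }
  if (all(is.na(thr))) stop("all slices constant: no threshold exists")
  if (anyNA(thr)) {
    ok <- which(!is.na(thr))
    for (z in which(is.na(thr))) thr[z] <- thr[ok[which.min(abs(ok - z))]]
  }
  m <- vol$data > thr # thresholds recycle along z, the fastest index
  dim(m) <- d
  out <- binary_volume(m, vol$voxel_mm, provenance)
  attr(out, "thresholds") <- thr
  out
}

#' Fit the HA-phantom density calibration
#'
#' Ordinary least squares of mean insert grayscale on known bone mineral
#' density. The grayscale at zero BMD (the fitted intercept) defines the
#' air cutoff: any voxel at or below it carries no mineral signal.
#'
#' @param pairs data.frame with columns `density_mg_cm3` and `mean_grayscale`
#'   (as produced by [generate_calibration_scan()]), or a 2-column matrix.
#' @return A `calibration_model`: list with `slope`, `intercept`, `r_squared`,
#'   `air_cutoff_gv`.
#' @export
fit_calibration <- function(pairs) {
  if (is.matrix(pairs)) pairs <- data.frame(density_mg_cm3 = pairs[, 1],
                                            mean_grayscale = pairs[, 2])
  x <- pairs$density_mg_cm3
  y <- pairs$mean_grayscale
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("need >= 2 distinct densities for the calibration fit")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (slope <= 0) stop("calibration slope must be positive (got ", slope, ")")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 air_cutoff_gv = intercept),
            class = "calibration_model")
}

#' Remove air voxels from a bone mask
#'
#' Voxels whose grayscale is at or below the calibration's zero-BMD cutoff
#' are set to background; all other voxels are unchanged. Idempotent.
#'
#' @param mask a [binary_volume].
#' @param gray the [gray_volume] the mask was derived from (same dims).
#' @param calib a `calibration_model` from [fit_calibration()].
#' @return A [binary_volume] with provenance `"G4"`.
#' @export
remove_air <- function(mask, gray, calib) {
  stopifnot(inherits(mask, "binary_volume"), inherits(gray, "gray_volume"),
            inherits(calib, "calibration_model"))
  if (!identical(dim(mask$mask), dim(gray$data)))
    stop("mask and grayscale volume dimensions differ")
  m <- mask$mask & (gray$data > calib$air_cutoff_gv)
  dim(m) <- dim(mask$mask)
  binary_volume(m, mask$voxel_mm, "G4")
}

#' Run one preprocessing group
#'
#' Dispatches the ladder: `G0` global threshold on the micro-CT input; `G1`
#' global threshold on the raw CBCT input; `G2` sharpen, despeckle, global
#' threshold; `G3` sharpen, despeckle, per-slice threshold; `G4` is `G3`
#' followed by [remove_air()] (which requires a calibration).
#'
#' @param gray the input [gray_volume] (micro-CT for G0, CBCT for G1-G4).
#' @param group one of `"G0".."G4"`.
#' @param calib a `calibration_model`; required for `"G4"`.
#' @return A [binary_volume] with the group recorded as provenance.
#' @export
run_group <- function(gray, group = c("G0", "G1", "G2", "G3", "G4"), calib = NULL) {
  group <- match.arg(group)
  if (group == "G4" && is.null(calib))
    stop("G4 requires a calibration model (zero-BMD air cutoff)")
  switch(group,
    G0 = binarize_global(gray, "G0"),
    G1 = binarize_global(gray, "G1"),
    G2 = binarize_global(despeckle(sharpen(gray)), "G2"),
    G3 = binarize_per_slice(despeckle(sharpen(gray)), "G3"),
    G4 = {
      filtered <- despeckle(sharpen(gray))
      g3 <- binarize_per_slice(filtered, "G3")
      remove_air(g3, filtered, calib)
    })
}
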