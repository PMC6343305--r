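# Minimal DICOM series support: explicit VR little endian, one file per slice,
# uncompressed 16-bit monochrome. This is the dialect dental CBCT consoles
# export and exactly what write_dicom_series() emits; geometry comes from
# PixelSpacing / ImagePositionPatient and intensities are mapped through
# RescaleSlope / RescaleIntercept.

dcm_str <- function(x, pad = charToRaw(" ")) {
  b <- charToRaw(x)
  if (length(b) %% 2L) b <- c(b, pad)
  b
}

dcm_element <- function(group, elem, vr, value_raw) {
  le2 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  le4 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")
  head <- c(le2(group), le2(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UN", "SQ", "UT"))
    c(head, as.raw(c(0, 0)), le4(length(value_raw)), value_raw)
  else
    c(head, le2(length(value_raw)), value_raw)
}

#' Write a volume as a DICOM series
#'
#' One explicit-VR little-endian file per slice, `slice_%04d.dcm`, with pixel
#' spacing, slice positions along z, and a rescale slope/intercept chosen so
#' the stored 16-bit integers reproduce the grayscale data.
#'
#' @param vol a [gray_volume]; voxel size must be isotropic (it is, by
#'   construction).
#' @param dir output directory, created if needed.
#' @param slope,intercept rescale mapping `value = slope * stored + intercept`;
#'   the default intercept shifts negative values into range.
#' @param slice_step_mm spacing between slice positions; defaults to the voxel
#'   size (isotropic). Other values exist so tests can build anisotropic
#'   fixtures.
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(vol, dir, slope = 1, intercept = NULL,
                               slice_step_mm = NULL) {
  stopifnot(inherits(vol, "gray_volume"))
  d <- dim(vol$data)
  if (is.null(intercept)) intercept <- min(0, floor(min(vol$data)))
  if (is.null(slice_step_mm)) slice_step_mm <- vol$voxel_mm
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- vol$voxel_mm
  us <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  for (z in seq_len(d[1])) {
    stored <- rnd_half_away((t(vol$data[z, , ]) - intercept) / slope) # x fastest
    stored <- pmin(pmax(stored, 0), 65535)
    pix <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
    meta_ts <- dcm_element(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1", as.raw(0)))
    body <- c(
      dcm_element(0x0008, 0x0060, "CS", dcm_str("CT")),
      dcm_element(0x0018, 0x0050, "DS", dcm_str(format(sp))),
      dcm_element(0x0020, 0x0013, "IS", dcm_str(as.character(z))),
      dcm_element(0x0020, 0x0032, "DS",
                  dcm_str(paste(0, 0, format((z - 1) * slice_step_mm), sep = "\\"))),
      dcm_element(0x0020, 0x0037, "DS", dcm_str("1\\0\\0\\0\\1\\0")),
      dcm_element(0x0028, 0x0002, "US", us(1L)),
      dcm_element(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
      dcm_element(0x0028, 0x0010, "US", us(d[2])),  # Rows = ny
      dcm_element(0x0028, 0x0011, "US", us(d[3])),  # Columns = nx
      dcm_element(0x0028, 0x0030, "DS", dcm_str(paste(format(sp), format(sp), sep = "\\"))),
      dcm_element(0x0028, 0x0100, "US", us(16L)),
      dcm_element(0x0028, 0x0101, "US", us(16L)),
      dcm_element(0x0028, 0x0102, "US", us(15L)),
      dcm_element(0x0028, 0x0103, "US", us(0L)),
      dcm_element(0x0028, 0x1052, "DS", dcm_str(format(intercept))),
      dcm_element(0x0028, 0x1053, "DS", dcm_str(format(slope))),
      dcm_element(0x7FE0, 0x0010, "OW", pix))
    meta <- c(dcm_element(0x0002, 0x0000, "UL",
                          writeBin(length(meta_ts), raw(), size = 4, endian = "little")),
              meta_ts)
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", z)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L # 1-based, next byte to read
  rd_int <- function(n, size, signed = TRUE) {
    v <- readBin(raw[pos:(pos + n * size - 1)], "integer", n = n, size = size,
                 endian = "little", signed = if (size < 4L) signed else TRUE)
    pos <<- pos + n * size
    v
  }
  out <- list()
  while (pos + 7L <= length(raw)) {
    group <- rd_int(1, 2, signed = FALSE)
    elem <- rd_int(1, 2, signed = FALSE)
    vr <- rawToChar(raw[pos:(pos + 1)]); pos <- pos + 2L
    if (vr %in% c("OB", "OW", "UN", "SQ", "UT")) {
      pos <- pos + 2L
      len <- rd_int(1, 4)
    } else len <- rd_int(1, 2, signed = FALSE)
    val <- raw[pos:(pos + len - 1)]
    pos <- pos + len
    key <- sprintf("%04X%04X", group, elem)
    out[[key]] <- list(vr = vr, val = val)
  }
  get_str <- function(key) {
    e <- out[[key]]
    if (is.null(e)) return(NULL)
    trimws(rawToChar(e$val[e$val != as.raw(0)]))
  }
  get_us <- function(key) {
    e <- out[[key]]
    if (is.null(e)) return(NULL)
    readBin(e$val, "integer", n = 1, size = 2, endian = "little", signed = FALSE)
  }
  rows <- get_us("00280010"); cols <- get_us("00280011")
  spacing <- as.numeric(strsplit(get_str("00280030"), "\\\\")[[1]])
  posv <- as.numeric(strsplit(get_str("00200032"), "\\\\")[[1]])
  slope <- as.numeric(get_str("00281053") %||% "1")
  inter <- as.numeric(get_str("00281052") %||% "0")
  pd <- out[["7FE00010"]]
  if (is.null(pd)) stop("missing PixelData in ", path)
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns in ", path)
  if (is.null(spacing) || length(spacing) != 2L) stop("missing PixelSpacing in ", path)
  stored <- readBin(pd$val, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = FALSE)
  slice <- matrix(stored * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)
  list(slice = slice, spacing = spacing, z = posv[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a DICOM series as a volume
#'
#' Files may be supplied in any order; slices are sorted by their position
#' along the slice normal. Rescale slope/intercept are applied. The voxel size
#' is taken from PixelSpacing and the slice-position step, which must agree
#' within 1% (isotropic voxels).
#'
#' @param path directory containing one series of `.dcm` files.
#' @return A [gray_volume] with `modality = "cbct"`.
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) stop("no DICOM files found in ", path)
  slices <- lapply(files, parse_dicom_file)
  zs <- vapply(slices, function(s) s$z, numeric(1))
  slices <- slices[order(zs)]
  zs <- sort(zs)
  sp <- slices[[1]]$spacing
  steps <- if (length(zs) > 1L) diff(zs) else sp[1]
  step <- mean(steps)
  tol <- 0.01
  if (abs(sp[1] - sp[2]) > tol * mean(sp))
    stop("anisotropic in-plane pixel spacing: ", sp[1], " vs ", sp[2])
  if (length(zs) > 1L && (abs(step - mean(sp)) > tol * mean(sp)))
    stop("slice spacing ", step, " differs from pixel spacing ", mean(sp),
         " by more than 1% (anisotropic voxels)")
  shp <- vapply(slices, function(s) dim(s$slice), integer(2))
  if (any(shp != shp[, 1])) stop("mixed slice shapes in ", path)
  vol <- array(0, dim = c(length(slices), shp[1, 1], shp[2, 1]))
  for (z in seq_along(slices)) vol[z, , ] <- slices[[z]]$slice
  gray_volume(vol, mean(sp), "cbct", bit_depth = 16L)
}
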