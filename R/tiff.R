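# Minimal baseline TIFF: uncompressed 8/16-bit grayscale, little- or big-endian
# on read, little-endian on write, single- or multi-page. Micro-CT exports in
# this dialect are plain slice stacks; vendor resolution tags are inconsistent,
# so the voxel size is always supplied by the caller and TIFF tags are not
# trusted for geometry.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_counts = 279L, sample_format = 339L)

tiff_type_size <- function(type) switch(as.character(type),
  "1" = 1L, "3" = 2L, "4" = 4L, stop("unsupported TIFF field type: ", type))

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file: ", path)
  rd <- function(off, n, size, signed = TRUE) # off is 0-based
    readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = endian, signed = if (size < 4L) signed else TRUE)
  if (rd(2, 1, 2, signed = TRUE) != 42L) stop("bad TIFF magic in ", path)
  ifd_off <- rd(4, 1, 4)
  pages <- list()
  while (ifd_off != 0L) {
    n_ent <- rd(ifd_off, 1, 2, signed = FALSE)
    tags <- list()
    for (i in seq_len(n_ent)) {
      ent <- ifd_off + 2 + (i - 1) * 12
      tag <- rd(ent, 1, 2, signed = FALSE)
      type <- rd(ent + 2, 1, 2, signed = FALSE)
      count <- rd(ent + 4, 1, 4)
      sz <- tiff_type_size(type)
      val_off <- if (count * sz <= 4L) ent + 8 else rd(ent + 8, 1, 4)
      vals <- rd(val_off, count, sz, signed = FALSE)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- g(TIFF_TAGS[["width"]]); h <- g(TIFF_TAGS[["length"]])
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions in ", path)
    bits <- g(TIFF_TAGS[["bits"]], 8L)[1]
    if (!bits %in% c(8L, 16L)) stop("unsupported bit depth ", bits, " in ", path)
    if (g(TIFF_TAGS[["compression"]], 1L)[1] != 1L)
      stop("compressed TIFF not supported: ", path)
    offs <- g(TIFF_TAGS[["strip_offsets"]])
    cnts <- g(TIFF_TAGS[["strip_counts"]], as.integer(w * h * bits / 8))
    pix <- integer(0)
    for (k in seq_along(offs))
      pix <- c(pix, rd(offs[k], cnts[k] / (bits / 8), bits / 8, signed = FALSE))
    # pixel order: row-major, x fastest -> R matrix (y, x)
    pages[[length(pages) + 1L]] <- matrix(pix, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- rd(ifd_off + 2 + n_ent * 12, 1, 4)
  }
  pages
}

#' Read a TIFF slice stack as a volume
#'
#' Accepts either one multi-page TIFF file or a directory of single-slice
#' TIFFs; in the directory case natural-numeric filename order defines the z
#' axis (`s2.tif` sorts before `s10.tif`).
#'
#' @param path a `.tif`/`.tiff` file or a directory containing them.
#' @param voxel_mm isotropic voxel size in mm, supplied by the caller.
#' @param modality modality tag for the resulting volume.
#' @return A [gray_volume].
#' @export
read_tiff_stack <- function(path, voxel_mm, modality = "micro_ct") {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    files <- files[natural_order(basename(files))]
    pages <- unlist(lapply(files, read_tiff_pages), recursive = FALSE)
  } else if (file.exists(path)) {
    pages <- read_tiff_pages(path)
  } else stop("no such file or directory: ", path)
  if (length(pages) == 0L) stop("zero TIFF slices in ", path)
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("mixed slice shapes in ", path)
  vol <- array(0, dim = c(length(pages), shp[1, 1], shp[2, 1]))
  for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
  bits <- if (max(vol) > 255) 16L else 8L
  gray_volume(vol, voxel_mm, modality, bit_depth = bits)
}

# order strings by the first embedded integer, ties broken lexicographically
natural_order <- function(x) {
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*([0-9]+).*$", "\\1", x)))
  num[is.na(num)] <- Inf
  order(num, x)
}

write_tiff_page <- function(con, slice, bits) {
  h <- nrow(slice); w <- ncol(slice)
  bpp <- bits / 8L
  nbytes <- as.integer(w * h * bpp)
  vals <- as.integer(rnd_half_away(pmin(pmax(t(slice), 0), 2^bits - 1)))
  list(width = w, height = h, bits = bits, nbytes = nbytes, vals = vals)
}

#' Write a volume as a TIFF slice stack
#'
#' Writes little-endian uncompressed grayscale TIFF. If `path` ends in
#' `.tif`/`.tiff` a single multi-page file is produced, otherwise `path` is
#' treated as a directory and one `slice_%04d.tif` per slice is written.
#' Values are rounded and clipped to the requested bit depth.
#'
#' @param vol a [gray_volume].
#' @param path output file or directory.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(vol, path, bits = vol$bit_depth) {
  stopifnot(inherits(vol, "gray_volume"), bits %in% c(8L, 16L))
  nz <- dim(vol$data)[1]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    write_tiff_file(path, lapply(seq_len(nz), function(z) vol$data[z, , ]), bits)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (z in seq_len(nz))
      write_tiff_file(file.path(path, sprintf("slice_%04d.tif", z)),
                      list(vol$data[z, , ]), bits)
  }
  invisible(path)
}

write_tiff_file <- function(file, slices, bits) {
  con <- file(file, "wb")
  on.exit(close(con))
  wr <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  writeChar("II", con, eos = NULL)
  wr(42L, 2)
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  # layout: header(8) | per page: pixel data then IFD
  offset <- 8L
  pages <- lapply(slices, function(s) write_tiff_page(con, s, bits))
  data_off <- integer(length(pages)); ifd_off <- integer(length(pages))
  for (i in seq_along(pages)) {
    data_off[i] <- offset
    offset <- offset + pages[[i]]$nbytes + (pages[[i]]$nbytes %% 2L)
    ifd_off[i] <- offset
    offset <- offset + ifd_size
  }
  wr(ifd_off[1], 4)
  entry <- function(tag, type, count, value) {
    wr(tag, 2); wr(type, 2); wr(count, 4)
    if (type == 3L) { wr(value, 2); wr(0L, 2) } else wr(value, 4)
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    writeBin(p$vals, con, size = bits / 8L, endian = "little")
    if (p$nbytes %% 2L) writeBin(as.raw(0), con)
    wr(n_entries, 2)
    entry(256L, 4L, 1L, p$width)
    entry(257L, 4L, 1L, p$height)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)     # no compression
    entry(262L, 3L, 1L, 1L)     # BlackIsZero
    entry(273L, 4L, 1L, data_off[i])
    entry(278L, 4L, 1L, p$height)
    entry(279L, 4L, 1L, p$nbytes)
    entry(339L, 3L, 1L, 1L)     # unsigned integer samples
    wr(if (i < length(pages)) ifd_off[i + 1] else 0L, 4)
  }
  invisible(file)
}
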