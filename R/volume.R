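#' @useDynLib trabmorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd pt quantile median
#' @importFrom utils write.csv
NULL

#' 3D grayscale volume
#'
#' The container every filter, threshold and morphometric measure operates on:
#' a 3D scalar grid indexed `(slice z, row y, column x)` with an isotropic
#' voxel size in millimetres. `z` is the scanner slice axis; slice 1 is the
#' top of the stack (where the anchor ball sits).
#'
#' @param data 3D numeric array, `dim = c(nz, ny, nx)`, finite and non-negative.
#' @param voxel_mm isotropic voxel size in mm (> 0).
#' @param modality one of `"micro_ct"`, `"cbct"`, `"synthetic"`.
#' @param bit_depth nominal grayscale bit depth (8 or 16); used only to clip
#'   filter output to the representable range.
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(data, voxel_mm, modality = c("synthetic", "micro_ct", "cbct"),
                        bit_depth = 8L) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || !is.finite(voxel_mm) || voxel_mm <= 0)
    stop("`voxel_mm` must be a single positive number")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!all(is.finite(data))) stop("grayscale values must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_mm = voxel_mm, modality = modality,
                 bit_depth = as.integer(bit_depth)),
            class = "gray_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gray_volume> %d x %d x %d (z,y,x), voxel %.4g mm, %s, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_mm, x$modality, min(x$data), max(x$data)))
  invisible(x)
}

#' Binary bone/background mask
#'
#' @param mask 3D logical array, `TRUE` = bone.
#' @param voxel_mm isotropic voxel size in mm.
#' @param provenance processing-group tag, one of `"G0".."G4"` (or `"truth"`
#'   for a generator ground truth).
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, voxel_mm, provenance = "G0") {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  if (!is.logical(mask)) stop("`mask` must be logical")
  if (anyNA(mask)) stop("`mask` must not contain NA")
  if (!is.numeric(voxel_mm) || voxel_mm <= 0) stop("`voxel_mm` must be positive")
  if (!provenance %in% c("G0", "G1", "G2", "G3", "G4", "truth"))
    stop("unknown provenance tag: ", provenance)
  structure(list(mask = mask, voxel_mm = voxel_mm, provenance = provenance),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d (z,y,x), voxel %.4g mm, %s, %.2f%% foreground\n",
              d[1], d[2], d[3], x$voxel_mm, x$provenance, 100 * mean(x$mask)))
  invisible(x)
}

gray_range <- function(vol) c(0, 2^vol$bit_depth - 1)

# round half away from zero; the one mm->voxel rounding convention of the package
rnd_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# RNG state is untouched. All generators route their randomness through this.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# deterministic child seed derivation; stays below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483629 * 48271 + as.double(i) * 7919) %% 2147483629)
}
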