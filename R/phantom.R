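# Synthetic cancellous-bone phantoms with known ground truth. The trabecular
# structure is a thresholded Gaussian random field: seeded white noise is
# smoothed with a Gaussian of SD feature_sigma_mm (the trabecular correlation
# length) and thresholded at the order statistic that realises the target bone
# volume fraction exactly (to within one voxel's fraction of the volume). The
# quantile and the correlation length independently control BV/TV and TbTh.

#' Phantom specification
#'
#' @param shape_mm physical extents `(x, y, z)` in mm. The physical specimens
#'   this emulates are 20 x 20 x 20 mm cubes; desk-scale runs use smaller
#'   blocks.
#' @param voxel_mm micro-resolution voxel size in mm (default 0.02; chosen
#'   over the scanner's native 0.018 so the CBCT downsample factor is the
#'   integer 5).
#' @param target_bvtv target bone volume fraction, strictly in (0, 1).
#' @param feature_sigma_mm Gaussian correlation length controlling trabecular
#'   feature size, must exceed `voxel_mm`.
#' @param seed integer RNG seed; the phantom is a pure function of it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_mm = c(20, 20, 20), voxel_mm = 0.02,
                         target_bvtv = 0.25, feature_sigma_mm = 0.1, seed = 1L) {
  if (!(target_bvtv > 0 && target_bvtv < 1))
    stop("`target_bvtv` must be strictly in (0, 1)")
  if (feature_sigma_mm <= voxel_mm)
    stop("`feature_sigma_mm` must exceed `voxel_mm`")
  if (length(shape_mm) != 3L || any(shape_mm <= 0))
    stop("`shape_mm` must be three positive extents (x, y, z)")
  structure(list(shape_mm = shape_mm, voxel_mm = voxel_mm,
                 target_bvtv = target_bvtv, feature_sigma_mm = feature_sigma_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Scanner intensity model
#'
#' Mean grayscale assigned to each tissue class plus per-voxel Gaussian
#' texture noise. Stands in for the scanner grayscale response; the defaults
#' put bone/marrow/air at 180/60/10 on an 8-bit scale.
#'
#' @param bone_gv,marrow_gv,air_gv class mean grayscales; must satisfy
#'   `air_gv < marrow_gv < bone_gv`.
#' @param texture_sigma per-voxel Gaussian noise SD (>= 0).
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(bone_gv = 180, marrow_gv = 60, air_gv = 10,
                            texture_sigma = 5) {
  if (!(air_gv < marrow_gv && marrow_gv < bone_gv))
    stop("need air_gv < marrow_gv < bone_gv")
  if (texture_sigma < 0) stop("`texture_sigma` must be >= 0")
  structure(list(bone_gv = bone_gv, marrow_gv = marrow_gv, air_gv = air_gv,
                 texture_sigma = texture_sigma),
            class = "intensity_model")
}

#' CBCT degradation specification
#'
#' Phenomenological model of the resolution/noise gap between an 18-20 um
#' micro-CT scan and a 100 um dental CBCT scan: axial intensity shading,
#' Gaussian point-spread blur, block-average downsampling, and additive noise.
#' No physics-based projection/reconstruction is modelled.
#'
#' @param psf_sigma_mm Gaussian PSF SD in mm.
#' @param downsample_factor integer >= 2; the default 5 maps 0.02 mm voxels to
#'   the CBCT's 0.10 mm.
#' @param noise_sigma additive Gaussian noise SD at the CBCT scale.
#' @param axial_shading_amplitude fractional linear intensity gradient along
#'   the slice axis (field spans `1 - a .. 1 + a` from top to bottom).
#' @param seed integer RNG seed for the noise.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(psf_sigma_mm = 0.15, downsample_factor = 5L,
                             noise_sigma = 8, axial_shading_amplitude = 0.15,
                             seed = 1L) {
  if (downsample_factor != as.integer(downsample_factor) || downsample_factor < 1L)
    stop("`downsample_factor` must be a positive integer")
  if (psf_sigma_mm < 0 || noise_sigma < 0 || axial_shading_amplitude < 0)
    stop("amplitudes must be >= 0")
  structure(list(psf_sigma_mm = psf_sigma_mm,
                 downsample_factor = as.integer(downsample_factor),
                 noise_sigma = noise_sigma,
                 axial_shading_amplitude = axial_shading_amplitude,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Calibration phantom specification
#'
#' A multi-insert hydroxyapatite (HA) phantom: cylindrical inserts of known
#' bone mineral density, including a zero-density insert that defines the
#' air/zero-BMD grayscale.
#'
#' @param densities known BMD values in mg HA/cm^3, non-negative, strictly
#'   increasing, first element 0.
#' @param insert_radius_mm insert radius in mm (sets the voxel count averaged
#'   per insert).
#' @param seed integer RNG seed.
#' @return An object of class `calibration_phantom_spec`.
#' @export
calibration_phantom_spec <- function(densities = c(0, 200, 400, 600, 800),
                                     insert_radius_mm = 5, seed = 1L) {
  if (length(densities) < 2L) stop("need at least 2 insert densities")
  if (any(densities < 0) || any(diff(densities) <= 0) || densities[1] != 0)
    stop("`densities` must be non-negative, strictly increasing, starting at 0")
  if (insert_radius_mm <= 0) stop("`insert_radius_mm` must be positive")
  structure(list(densities = densities, insert_radius_mm = insert_radius_mm,
                 seed = as.integer(seed)),
            class = "calibration_phantom_spec")
}

#' Generate a trabecular bone phantom
#'
#' Returns the micro-resolution grayscale volume and its binary ground truth.
#' The ground truth is a thresholded Gaussian random field whose realised
#' foreground fraction matches `target_bvtv` to within half a voxel's fraction
#' of the volume. Grayscale rendering assigns `bone_gv` / `marrow_gv`, renders
#' air pockets inside the marrow at `air_gv` (an excised wet specimen is
#' scanned in air, so part of the pore space is drained: pockets are drawn
#' from an independent Gaussian random field at the trabecular correlation
#' length and cover `air_fraction` of the background), adds texture noise,
#' then applies a mild micro-CT-level blur of SD 0.5 voxel. Bit-for-bit
#' reproducible for a fixed seed.
#'
#' @param spec a [phantom_spec].
#' @param intensity an [intensity_model].
#' @param air_fraction fraction of the background (marrow) phase rendered as
#'   air pockets; 0 disables them.
#' @return A list with elements `gray` ([gray_volume]), `truth`
#'   ([binary_volume] with provenance `"truth"`), and `realized_bvtv`.
#' @export
generate_trabecular_phantom <- function(spec = phantom_spec(),
                                        intensity = intensity_model(),
                                        air_fraction = 0.2) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(intensity, "intensity_model"))
  d <- as.integer(rnd_half_away(rev(spec$shape_mm) / spec$voxel_mm)) # (z, y, x)
  if (any(d < 10L)) stop("degenerate phantom: every extent must span >= 10 voxels")
  n <- prod(d)
  sig_vox <- spec$feature_sigma_mm / spec$voxel_mm
  with_seed(spec$seed, {
    noise <- array(rnorm(n), dim = d)
    sm <- cpp_gauss_blur(noise, d, rep(sig_vox, 3))
    k <- as.integer(round(n * (1 - spec$target_bvtv)))
    k <- min(max(k, 1L), n - 1L)
    thr <- sort(sm, partial = k)[k]
    truth <- sm > thr
    g <- intensity$marrow_gv + (intensity$bone_gv - intensity$marrow_gv) * truth
    # drained-pore air pockets: an independent GRF at the same correlation
    # length, thresholded inside the marrow phase to cover air_fraction of it
    if (air_fraction > 0) {
      af <- cpp_gauss_blur(array(rnorm(n), dim = d), d, rep(sig_vox, 3))
      bg <- !truth
      qa <- quantile(af[bg], 1 - air_fraction, names = FALSE)
      g[bg & af > qa] <- intensity$air_gv
    }
    if (intensity$texture_sigma > 0) g <- g + rnorm(n) * intensity$texture_sigma
    g <- cpp_gauss_blur(g, d, rep(0.5, 3))
    g <- pmin(pmax(g, 0), 255)
    dim(g) <- d
    list(gray = gray_volume(g, spec$voxel_mm, "synthetic", bit_depth = 8L),
         truth = binary_volume(array(truth, d), spec$voxel_mm, "truth"),
         realized_bvtv = sum(truth) / n)
  })
}

#' Embed the composite-resin anchor ball
#'
#' Pads the top of the volume with air slices and renders a bright sphere
#' tangent to the specimen's top surface, centred on the top-surface central
#' axis. Everything below the original top surface is unchanged.
#'
#' @param vol a [gray_volume].
#' @param radius_mm ball radius in mm.
#' @param ball_gv ball grayscale; must exceed every specimen grayscale for the
#'   ball to anchor alignment.
#' @param air_gv grayscale of the padded air above the surface.
#' @return A [gray_volume] with `attr(, "top_surface_z")` set to the first
#'   specimen slice.
#' @export
embed_anchor_ball <- function(vol, radius_mm = 0.5, ball_gv = 255, air_gv = 10) {
  stopifnot(inherits(vol, "gray_volume"))
  d <- dim(vol$data)
  r_vox <- radius_mm / vol$voxel_mm
  pad <- as.integer(ceiling(2 * r_vox)) + 2L
  if (2 * r_vox >= min(d[2], d[3]))
    stop("ball radius too large for the volume cross-section")
  out <- array(air_gv, dim = c(d[1] + pad, d[2], d[3]))
  out[(pad + 1):(pad + d[1]), , ] <- vol$data
  # sphere tangent to the surface plane z = pad + 0.5, centred on the axis
  zc <- pad + 0.5 - r_vox
  yc <- (1 + d[2]) / 2
  xc <- (1 + d[3]) / 2
  zr <- max(1L, floor(zc - r_vox)):min(pad, ceiling(zc + r_vox))
  yr <- max(1L, floor(yc - r_vox)):min(d[2], ceiling(yc + r_vox))
  xr <- max(1L, floor(xc - r_vox)):min(d[3], ceiling(xc + r_vox))
  for (z in zr) for (y in yr) {
    dz2 <- (z - zc)^2 + (y - yc)^2
    if (dz2 > r_vox^2) next
    sel <- xr[(xr - xc)^2 <= r_vox^2 - dz2]
    if (length(sel)) out[z, y, sel] <- ball_gv
  }
  v <- gray_volume(out, vol$voxel_mm, vol$modality, vol$bit_depth)
  attr(v, "top_surface_z") <- pad + 1L
  v
}

#' Simulate a calibration phantom scan
#'
#' Produces per-insert mean grayscales under a linear grayscale response
#' `intercept + slope * density` with per-voxel Gaussian noise averaged over
#' the insert's voxels.
#'
#' @param spec a [calibration_phantom_spec].
#' @param intensity_slope grayscale per (mg HA/cm^3).
#' @param intensity_intercept grayscale at zero BMD.
#' @param noise_sigma per-voxel noise SD.
#' @param voxel_mm voxel size used to derive the insert voxel count (CBCT
#'   scale by default).
#' @return A data.frame with columns `density_mg_cm3`, `mean_grayscale`,
#'   `n_voxels`, in density order.
#' @export
generate_calibration_scan <- function(spec = calibration_phantom_spec(),
                                      intensity_slope = 0.2,
                                      intensity_intercept = 60,
                                      noise_sigma = 2, voxel_mm = 0.1) {
  stopifnot(inherits(spec, "calibration_phantom_spec"))
  n_vox <- max(1L, as.integer(round((4 / 3) * pi * spec$insert_radius_mm^3 / voxel_mm^3)))
  with_seed(spec$seed, {
    mg <- vapply(spec$densities, function(dens) {
      intensity_intercept + intensity_slope * dens +
        (if (noise_sigma > 0) mean(rnorm(n_vox)) * noise_sigma else 0)
    }, numeric(1))
    data.frame(density_mg_cm3 = spec$densities, mean_grayscale = mg, n_voxels = n_vox)
  })
}

#' Degrade a micro-resolution volume to CBCT quality
#'
#' The pipeline is exactly: (1) multiply by the axial shading field
#' `1 + a * (2 z / Z - 1)` (z = 0..Z-1 slice index); (2) convolve with a
#' Gaussian PSF of SD `psf_sigma_mm`; (3) block-average downsample by
#' `downsample_factor` (edge-replicating to a multiple first if needed);
#' (4) add Gaussian noise. The output voxel size is the input voxel size times
#' the factor.
#'
#' @param vol a [gray_volume] at micro resolution.
#' @param spec a [degradation_spec].
#' @return A [gray_volume] with `modality = "cbct"` and `bit_depth = 16`.
#' @export
degrade_to_cbct <- function(vol, spec = degradation_spec()) {
  stopifnot(inherits(vol, "gray_volume"), inherits(spec, "degradation_spec"))
  d <- dim(vol$data)
  a <- spec$axial_shading_amplitude
  g <- vol$data
  if (a > 0 && d[1] > 1L) {
    z0 <- seq_len(d[1]) - 1L
    field <- 1 + a * (2 * z0 / (d[1] - 1) - 1)
    g <- g * field # field recycles along z, the fastest index
  }
  if (spec$psf_sigma_mm > 0)
    g <- cpp_gauss_blur(g, d, rep(spec$psf_sigma_mm / vol$voxel_mm, 3))
  f <- spec$downsample_factor
  pad_to <- function(arr, dd) {
    need <- (f - dd %% f) %% f
    if (all(need == 0L)) return(arr)
    out <- array(0, dd + need)
    out[1:dd[1], 1:dd[2], 1:dd[3]] <- arr
    if (need[1]) out[(dd[1] + 1):(dd[1] + need[1]), , ] <-
      out[rep(dd[1], need[1]), , ]
    if (need[2]) out[, (dd[2] + 1):(dd[2] + need[2]), ] <-
      out[, rep(dd[2], need[2]), ]
    if (need[3]) out[, , (dd[3] + 1):(dd[3] + need[3])] <-
      out[, , rep(dd[3], need[3])]
    out
  }
  dim(g) <- d
  g <- pad_to(g, d)
  g <- cpp_block_mean(g, dim(g), f)
  if (spec$noise_sigma > 0) {
    g <- with_seed(spec$seed, g + array(rnorm(length(g)) * spec$noise_sigma, dim(g)))
  }
  od <- dim(g)
  g <- pmax(g, 0)
  dim(g) <- od
  gray_volume(g, vol$voxel_mm * f, "cbct", bit_depth = 16L)
}

#' Generate a cohort of specimens
#'
#' Draws per-specimen target bone volume fractions uniformly from
#' `bvtv_range` (the micro-CT-measured cohort range 9-40% by default) with
#' deterministically derived child seeds, and returns for each specimen the
#' ground truth, the micro-resolution grayscale (with anchor ball unless
#' `ball_radius_mm` is `NULL`), and the CBCT-degraded grayscale.
#'
#' @param n number of specimens (>= 3); the emulated design used 30.
#' @param seed master seed.
#' @param bvtv_range range to draw target fractions from.
#' @param degradation a [degradation_spec]; its seed is re-derived per
#'   specimen.
#' @param shape_mm,voxel_mm,feature_sigma_mm phantom geometry (desk-scale
#'   defaults).
#' @param intensity an [intensity_model].
#' @param ball_radius_mm anchor ball radius, or `NULL` for no ball.
#' @return List of per-specimen lists with elements `specimen_id`,
#'   `target_bvtv`, `truth`, `micro`, `cbct`, `top_surface_z`.
#' @export
generate_cohort <- function(n = 30L, seed = 1L, bvtv_range = c(0.09, 0.40),
                            degradation = degradation_spec(),
                            shape_mm = c(3, 3, 6), voxel_mm = 0.02,
                            feature_sigma_mm = 0.1,
                            intensity = intensity_model(),
                            ball_radius_mm = 0.5) {
  if (n < 3L) stop("need n >= 3 specimens")
  if (length(bvtv_range) != 2L || bvtv_range[1] > bvtv_range[2] ||
      bvtv_range[1] <= 0 || bvtv_range[2] >= 1)
    stop("`bvtv_range` must be an interval inside (0, 1)")
  targets <- with_seed(seed, runif(n, bvtv_range[1], bvtv_range[2]))
  lapply(seq_len(n), function(i)
    build_specimen(i, targets[i], seed, degradation, shape_mm, voxel_mm,
                   feature_sigma_mm, intensity, ball_radius_mm))
}

# one specimen of the cohort; shared by generate_cohort and run_experiment
build_specimen <- function(i, target, seed, degradation, shape_mm, voxel_mm,
                           feature_sigma_mm, intensity, ball_radius_mm) {
  ps <- phantom_spec(shape_mm, voxel_mm, target, feature_sigma_mm,
                     seed = derive_seed(seed, i))
  ph <- generate_trabecular_phantom(ps, intensity)
  micro <- ph$gray
  top_z <- 1L
  if (!is.null(ball_radius_mm)) {
    micro <- embed_anchor_ball(micro, ball_radius_mm, ball_gv = 255,
                               air_gv = intensity$air_gv)
    top_z <- attr(micro, "top_surface_z")
  }
  dspec <- degradation
  dspec$seed <- derive_seed(seed, 100000L + i)
  cbct <- degrade_to_cbct(micro, dspec)
  list(specimen_id = sprintf("S%02d", i), target_bvtv = target,
       truth = ph$truth, micro = micro, cbct = cbct, top_surface_z = top_z)
}

#' Write a phantom to disk as a TIFF stack with a JSON sidecar
#'
#' @param ph result of [generate_trabecular_phantom()].
#' @param dir output directory.
#' @param spec the [phantom_spec] used (stored in the sidecar).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir, spec) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tiff_stack(ph$gray, file.path(dir, "gray"))
  tr <- gray_volume(array(255 * ph$truth$mask, dim(ph$truth$mask)),
                    ph$truth$voxel_mm, "synthetic")
  write_tiff_stack(tr, file.path(dir, "truth"))
  meta <- list(voxel_mm = spec$voxel_mm, seed = spec$seed,
               target_bvtv = spec$target_bvtv,
               feature_sigma_mm = spec$feature_sigma_mm,
               realized_bvtv = ph$realized_bvtv)
  jsonlite::write_json(meta, file.path(dir, "phantom.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
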