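# End-to-end cohort experiment: generate specimens, align and extract matched
# ROIs at both resolutions, run the preprocessing ladder, measure morphometry,
# and report summary + comparison tables. Rerunning the same config is
# byte-identical.

#' Default experiment configuration
#'
#' A desk-scale analog of the emulated 30-specimen design: 3 x 3 x 6 mm
#' phantoms at 0.02 mm voxels, anchor ball alignment, a 2 x 2 x 5 mm ROI, and
#' the default CBCT degradation (factor 5 to 0.1 mm voxels).
#'
#' @param n cohort size.
#' @param seed master seed; every stage derives its own child seed from it.
#' @param out_dir optional output directory for the CSV reports.
#' @return A nested configuration list.
#' @export
default_config <- function(n = 30L, seed = 1L, out_dir = NULL) {
  list(
    n = as.integer(n), seed = as.integer(seed),
    phantom = list(shape_mm = c(3, 3, 6), voxel_mm = 0.02,
                   feature_sigma_mm = 0.1, bvtv_range = c(0.09, 0.40)),
    intensity = list(bone_gv = 180, marrow_gv = 60, air_gv = 10, texture_sigma = 5),
    degradation = list(psf_sigma_mm = 0.15, downsample_factor = 5L,
                       noise_sigma = 8, axial_shading_amplitude = 0.15),
    calibration = list(densities = c(0, 200, 400, 600, 800), insert_radius_mm = 5,
                       slope = 0.2, intercept = 60, noise_sigma = 2),
    roi = list(extent_mm = c(2, 2, 5), anchor_mode = "ball_centroid",
               ball_radius_mm = 0.5),
    groups = c("G0", "G1", "G2", "G3", "G4"),
    params = c("bv_tv", "tb_th", "tb_n", "tb_sp"),
    alpha = 0.05,
    out_dir = out_dir)
}

validate_config <- function(config) {
  need <- c("n", "seed", "phantom", "intensity", "degradation", "roi",
            "groups", "params", "alpha")
  missing <- setdiff(need, names(config))
  if (length(missing)) stop("config is missing blocks: ", paste(missing, collapse = ", "))
  if ("G4" %in% config$groups && is.null(config$calibration))
    stop("config requests G4 but has no calibration block")
  if (config$n < 3L) stop("need n >= 3 specimens")
  invisible(config)
}

#' Run the cohort experiment
#'
#' For each specimen: generate the phantom, embed the anchor ball, degrade to
#' CBCT, locate the anchor in both scans, extract the matched physical ROI at
#' each resolution, binarize micro-CT as G0 and CBCT as G1-G4, and measure
#' morphometry. Then summarize per group and compare every CBCT group against
#' G0. Any stage failure aborts with the stage name and specimen id.
#'
#' @param config a configuration list as produced by [default_config()].
#' @param progress print per-specimen progress to stderr.
#' @return List with `results`, `summary`, `comparison` data.frames, the
#'   fitted `calibration`, and `config`. If `config$out_dir` is set,
#'   `results.csv`, `summary.csv`, `comparison.csv` and `run_log.json` are
#'   written there.
#' @export
run_experiment <- function(config = default_config(), progress = FALSE) {
  validate_config(config)
  calib <- NULL
  if ("G4" %in% config$groups) {
    cb <- config$calibration
    cal_scan <- generate_calibration_scan(
      calibration_phantom_spec(cb$densities, cb$insert_radius_mm,
                               seed = derive_seed(config$seed, 999L)),
      intensity_slope = cb$slope, intensity_intercept = cb$intercept,
      noise_sigma = cb$noise_sigma)
    calib <- fit_calibration(cal_scan)
  }
  targets <- with_seed(config$seed,
                       runif(config$n, config$phantom$bvtv_range[1],
                             config$phantom$bvtv_range[2]))
  intensity <- do.call(intensity_model, config$intensity)
  dspec <- do.call(degradation_spec, config$degradation)
  roi <- roi_spec(config$roi$extent_mm, config$roi$anchor_mode)
  rows <- list()
  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s, specimen %s] %s", what, id, conditionMessage(e)),
           call. = FALSE))
  }
  for (i in seq_len(config$n)) {
    id <- sprintf("S%02d", i)
    spx <- stage("generate", id,
      build_specimen(i, targets[i], config$seed, dspec,
                     config$phantom$shape_mm, config$phantom$voxel_mm,
                     config$phantom$feature_sigma_mm, intensity,
                     if (roi$anchor_mode == "ball_centroid") config$roi$ball_radius_mm else NULL))
    roi_micro <- stage("roi_micro", id, {
      anc <- if (roi$anchor_mode == "ball_centroid") locate_anchor(spx$micro) else NULL
      extract_roi(spx$micro, anc, roi)
    })
    roi_cbct <- stage("roi_cbct", id, {
      anc <- if (roi$anchor_mode == "ball_centroid") locate_anchor(spx$cbct) else NULL
      extract_roi(spx$cbct, anc, roi)
    })
    for (g in config$groups) {
      input <- if (g == "G0") roi_micro else roi_cbct
      m <- stage(paste0("binarize_", g), id, run_group(input, g, calib))
      res <- stage(paste0("morphometry_", g), id,
                   compute_morphometry(m, specimen_id = id, group = g,
                                       params = config$params))
      rows[[length(rows) + 1L]] <- morphometry_row(res)
    }
    if (progress) message(sprintf("specimen %s done (%d/%d)", id, i, config$n))
  }
  results <- do.call(rbind, rows)
  summary <- summarize_cohort(results)
  comparison <- compare_groups(results, alpha = config$alpha)
  out <- list(results = results, summary = summary, comparison = comparison,
              calibration = calib, config = config)
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

write_experiment <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    df_fmt <- df
    for (col in names(df_fmt))
      if (is.numeric(df_fmt[[col]]))
        df_fmt[[col]] <- sprintf("%.10g", df_fmt[[col]])
    write.csv(df_fmt, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wcsv(out$results, "results.csv")
  wcsv(out$summary, "summary.csv")
  wcsv(out$comparison, "comparison.csv")
  log <- list(config = out$config,
              calibration = if (!is.null(out$calibration))
                out$calibration[c("slope", "intercept", "r_squared", "air_cutoff_gv")]
              else NULL,
              n_results = nrow(out$results))
  jsonlite::write_json(log, file.path(dir, "run_log.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read an experiment configuration file
#'
#' JSON always works; YAML works when the `yaml` package is installed.
#'
#' @param path a `.json` / `.yaml` / `.yml` file.
#' @return A configuration list merged over [default_config()].
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the `yaml` package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  modify <- function(base, new) {
    for (nm in names(new))
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
        modify(base[[nm]], new[[nm]]) else new[[nm]]
    base
  }
  modify(base, cfg)
}
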