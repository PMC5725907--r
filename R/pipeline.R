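#' Analyze one image through all enabled stages
#'
#' Runs bead detection, sprout segmentation, skeleton morphometry, nucleus
#' detection and classification, pericyte coverage, and cell density,
#' respecting `params$outputs` and the channels actually present.
#' Measurements whose stage is disabled or whose channel is absent come
#' back missing (NA), never zero.
#'
#' @param img a `sprout_image` (project stacks first with
#'   [max_intensity_projection()]).
#' @param params [analysis_params()].
#' @param keep_objects also return the intermediate stage objects.
#' @return one-row measurement data.frame (see [measurement_row()]); with
#'   `keep_objects = TRUE`, a list with `row` and `objects`.
#' @export
analyze_image <- function(img, params = analysis_params(), keep_objects = FALSE) {
  img <- max_intensity_projection(img)
  on <- function(stage) stage %in% params$outputs
  obj <- list()
  vals <- list()

  obj$beads <- detect_beads(img, params)
  if (on("beads")) vals$n_beads <- obj$beads$n_beads

  if (on("sprouts") || on("morphometry") || on("coverage") || on("branch_points")) {
    obj$sprouts <- segment_sprouts(img, obj$beads, params)
    obj$skeleton <- skeletonize_sprouts(obj$sprouts, obj$beads, params)
    if (on("sprouts")) {
      cnt <- sprout_count(obj$sprouts, obj$skeleton, obj$beads,
                          params$sprout$count_mode)
      vals$n_sprouts <- cnt$total
      vals$sprout_area <- obj$sprouts$sprout_area_um2
      vals$unattached_sprout_area <- obj$sprouts$unattached_area_um2
    }
    if (on("morphometry")) {
      len <- measure_lengths(obj$skeleton)
      vals$total_sprout_length <- len$total_sprout_length_um
      vals$avg_sprout_length <- len$avg_sprout_length_um
      vals$avg_sprout_width <- measure_width(obj$sprouts, obj$skeleton)
    }
    if (on("branch_points"))
      vals$avg_branch_points <- count_branch_points(obj$skeleton)$avg_branch_points
  }

  if (on("nuclei") && !is.null(img$planes$nuclei)) {
    obj$nuclei <- detect_nuclei(img, params)
    vals$n_nuclei <- obj$nuclei$n_nuclei
    if (on("classes") && !is.null(img$planes$ec_marker)) {
      obj$nuclei <- classify_nuclei(obj$nuclei, img, params)
      vals$n_ec <- obj$nuclei$n_ec
      vals$n_pericyte <- obj$nuclei$n_pericyte
      vals$ec_pericyte_ratio <- obj$nuclei$ec_pericyte_ratio %||% NA_real_
    }
    if (!is.null(obj$sprouts))
      vals$cell_density <- measure_cell_density(obj$nuclei, obj$sprouts)
  }

  if (on("coverage") && !is.null(img$planes$pericyte_marker) &&
      !is.null(obj$sprouts)) {
    obj$coverage <- measure_coverage(img, obj$sprouts, params)
    vals$pericyte_area <- obj$coverage$pericyte_area_um2
    vals$pericyte_coverage <- obj$coverage$coverage
  }

  row <- do.call(measurement_row, c(list(source_id = img$source_id), vals))
  if (keep_objects) list(row = row, objects = obj) else row
}

#' Analyze a folder of images with frozen parameters
#'
#' Every TIFF in the folder is processed with the same configuration (the
#' screening workflow tunes parameters once on representative projections,
#' then applies them dataset-wide). Failures are logged and skipped, never
#' aborting the batch. The result table, the exact parameters used (JSON
#' sidecar), and a per-image run log are written to the output directory;
#' re-running with the same inputs reproduces the CSV byte-identically.
#'
#' @param input directory containing TIFF images (searched non-recursively
#'   for `.tif`/`.tiff`).
#' @param config a list as returned by [read_run_config()], or a path to a
#'   YAML config.
#' @param out_dir output directory.
#' @param overlays write QC overlay PNGs per image.
#' @return the result data.frame, invisibly, with attribute `n_failed`.
#' @export
analyze_folder <- function(input, config, out_dir, overlays = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  files <- sort(list.files(input, pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stop_usage("no TIFF images found in ", input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- file(log_path, "w")
  on.exit(close(logf))
  rows <- list()
  n_failed <- 0L
  for (f in files) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      img <- read_image(f, config$channel_map, config$pixel_size)
      out <- analyze_image(max_intensity_projection(img), config$params,
                           keep_objects = overlays)
      row <- if (overlays) out$row else out
      if (overlays)
        write_qc_overlay(file.path(out_dir, paste0(tools::file_path_sans_ext(
          basename(f)), "_overlay.png")),
          max_intensity_projection(img), out$objects)
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      writeLines(sprintf("FAIL %s: %s", basename(f), conditionMessage(res)), logf)
    } else {
      rows[[length(rows) + 1L]] <- res
      writeLines(sprintf("OK   %s: %d beads, %d sprouts (%.1fs)",
                         basename(f), as.integer(res$n_beads),
                         as.integer(res$n_sprouts),
                         proc.time()[["elapsed"]] - t0), logf)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else measurement_row("")[0, ]
  write_results(df, file.path(out_dir, "results.csv"))
  write_params_json(config$params, file.path(out_dir, "params.json"),
                    pixel_size = config$pixel_size)
  attr(df, "n_failed") <- n_failed
  if (n_failed)
    warning(n_failed, " image(s) failed; see ", log_path, call. = FALSE)
  invisible(df)
}

#' Derive a frozen configuration from one representative image
#'
#' Computes the automatic thresholds of every stage on the given image and
#' emits a config in which they are frozen as manual levels, so a whole
#' dataset can then be analyzed with identical parameters.
#'
#' @param img a `sprout_image`.
#' @param params starting [analysis_params()].
#' @return an [analysis_params()] object with manual thresholds set.
#' @export
tune_params <- function(img, params = analysis_params()) {
  img <- max_intensity_projection(img)
  px <- img$pixel_size
  p <- unclass(params)
  actin <- img$planes$actin
  p$bead$threshold_method <- "manual"
  p$bead$manual_threshold <-
    otsu_threshold(gblur_px(actin, params$bead$blur_sigma_um / px))
  blurred <- gblur_px(actin, params$sprout$blur_sigma_um / px)
  p$sprout$threshold_method <- "manual"
  p$sprout$manual_threshold <- otsu_threshold(blurred)
  if (!is.null(img$planes$nuclei)) {
    p$nucleus$threshold_method <- "manual"
    p$nucleus$manual_threshold <-
      otsu_threshold(gblur_px(img$planes$nuclei, params$nucleus$blur_sigma_um / px))
  }
  class(p) <- "sprout_params"
  validate_params(p)
  p
}
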