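#' Analysis parameters for the sprout quantification pipeline
#'
#' Bundles every tunable of the five analysis stages (bead detection, sprout
#' segmentation, nucleus detection, cell classification, pericyte coverage)
#' plus skeleton options. All lengths are in micrometers, areas in square
#' micrometers; conversion to pixels happens inside each stage using the
#' image's pixel size.
#'
#' Threshold methods: "otsu" (between-class variance, the default for the
#' bright, well-populated actin structures), "triangle" (geometric method
#' for sparse foregrounds), "manual" (fixed level).
#'
#' @param bead list; `min_radius_um` / `max_radius_um` gates on the
#'   equivalent radius (defaults 50 / 150, matching dextran microcarrier
#'   beads of roughly 150-250 um diameter), `min_circularity` gate on
#'   4*pi*A/P^2 (default 0.6), `threshold_method` ("otsu" or "manual"),
#'   `manual_threshold`, `blur_sigma_um` Gaussian pre-smoothing before
#'   thresholding (default 2; suppressing pixel noise keeps the automatic
#'   threshold stable when beads cover a small fraction of a large field).
#' @param sprout list; `threshold_method`, `manual_threshold`,
#'   `blur_sigma_um` Gaussian pre-smoothing (default 2),
#'   `min_sprout_area_um2` component gate (default 200),
#'   `min_sprout_length_um` minimum skeleton length for a counted sprout
#'   (default 20), `band_width_um` width of the bead perimeter band used for
#'   sprout attachment and counting (default 20), `count_mode`
#'   ("crossings" counts skeleton crossings of the perimeter band,
#'   "components" counts attached connected components).
#' @param nucleus list; `threshold_method` (default "triangle": nuclei
#'   occupy a tiny fraction of the field, where Otsu's criterion is
#'   unreliable), `manual_threshold`,
#'   `blur_sigma_um` (default 1), `min_area_um2` / `max_area_um2` nucleus
#'   area gates (defaults 50 / 400: an 8 um nucleus projects to about
#'   50 um2, anything smaller is a fragment or speck), `split_touching`
#'   distance-transform watershed splitting (default TRUE).
#' @param classify list; `ec_marker_threshold_mode` ("otsu" object-level
#'   Otsu on per-nucleus mean marker intensity, or "manual"),
#'   `manual_threshold`.
#' @param coverage list; `threshold_method`, `manual_threshold`,
#'   `blur_sigma_um` Gaussian pre-smoothing (default 2, matching the sprout
#'   stage so both mask boundaries sit on comparable contours), `scope`
#'   ("attached" restricts the denominator to bead-attached sprout area,
#'   "all" uses every sprout component).
#' @param skeleton list; `prune_length_um` spur-pruning length (default 10).
#' @param outputs character vector of enabled measurement groups, subset of
#'   `c("beads", "sprouts", "morphometry", "nuclei", "classes", "coverage",
#'   "branch_points")`.
#' @return an object of class `sprout_params`.
#' @export
analysis_params <- function(bead = list(), sprout = list(), nucleus = list(),
                            classify = list(), coverage = list(),
                            skeleton = list(), outputs = NULL) {
  defaults <- list(
    bead = list(min_radius_um = 50, max_radius_um = 150, min_circularity = 0.6,
                threshold_method = "otsu", manual_threshold = NA_real_,
                blur_sigma_um = 2),
    sprout = list(threshold_method = "otsu", manual_threshold = NA_real_,
                  blur_sigma_um = 2, min_sprout_area_um2 = 200,
                  min_sprout_length_um = 20, band_width_um = 20,
                  count_mode = "crossings"),
    nucleus = list(threshold_method = "triangle", manual_threshold = NA_real_,
                   blur_sigma_um = 1, min_area_um2 = 50, max_area_um2 = 400,
                   split_touching = TRUE),
    classify = list(ec_marker_threshold_mode = "otsu",
                    manual_threshold = NA_real_),
    coverage = list(threshold_method = "otsu", manual_threshold = NA_real_,
                    blur_sigma_um = 2, scope = "attached"),
    skeleton = list(prune_length_um = 10),
    outputs = c("beads", "sprouts", "morphometry", "nuclei", "classes",
                "coverage", "branch_points")
  )
  p <- defaults
  for (grp in c("bead", "sprout", "nucleus", "classify", "coverage", "skeleton")) {
    extra <- setdiff(names(get(grp)), names(defaults[[grp]]))
    if (length(extra))
      stop_config("unknown ", grp, " parameter(s): ", paste(extra, collapse = ", "))
    p[[grp]] <- modifyList(defaults[[grp]], get(grp))
  }
  if (!is.null(outputs)) {
    bad <- setdiff(outputs, defaults$outputs)
    if (length(bad)) stop_config("unknown outputs: ", paste(bad, collapse = ", "))
    p$outputs <- outputs
  }
  validate_params(p)
  structure(p, class = "sprout_params")
}

validate_params <- function(p) {
  pos <- c(bead = "min_radius_um", bead = "max_radius_um",
           sprout = "blur_sigma_um", sprout = "min_sprout_area_um2",
           sprout = "min_sprout_length_um", sprout = "band_width_um",
           nucleus = "min_area_um2", nucleus = "max_area_um2")
  for (i in seq_along(pos)) {
    v <- p[[names(pos)[i]]][[pos[i]]]
    if (!is.numeric(v) || v <= 0)
      stop_config(names(pos)[i], "$", pos[i], " must be a positive number")
  }
  if (p$skeleton$prune_length_um < 0)
    stop_config("skeleton$prune_length_um must be non-negative")
  if (p$bead$min_radius_um >= p$bead$max_radius_um)
    stop_config("bead$min_radius_um must be below bead$max_radius_um")
  if (p$nucleus$min_area_um2 >= p$nucleus$max_area_um2)
    stop_config("nucleus$min_area_um2 must be below nucleus$max_area_um2")
  if (p$bead$min_circularity < 0 || p$bead$min_circularity > 1)
    stop_config("bead$min_circularity must lie in [0, 1]")
  match.arg(p$sprout$count_mode, c("crossings", "components"))
  match.arg(p$coverage$scope, c("attached", "all"))
  invisible(p)
}

#' @export
print.sprout_params <- function(x, ...) {
  cat("sprout analysis parameters\n")
  for (grp in setdiff(names(x), "outputs")) {
    vals <- vapply(x[[grp]], function(v) paste(format(v), collapse = ","), "")
    cat(sprintf("  %-9s %s\n", grp, paste(names(vals), vals, sep = "=", collapse = " ")))
  }
  cat("  outputs  ", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}

#' Map stain roles to channel indices
#'
#' @param ... named role assignments, e.g. `actin = 1, nuclei = 2`
#'   (1-based channel indices). Valid roles: actin, nuclei, ec_marker,
#'   pericyte_marker. Missing roles are allowed (EC-only assays have no
#'   marker channels).
#' @return named integer vector of class `channel_map`.
#' @export
channel_map <- function(...) {
  m <- c(...)
  if (!length(m)) stop_config("channel map must assign at least one role")
  bad <- setdiff(names(m), SPROUTR_ROLES)
  if (length(bad)) stop_config("unknown stain role(s): ", paste(bad, collapse = ", "))
  m <- vapply(m, as.integer, integer(1))
  if (anyDuplicated(m)) stop_config("channel indices must be unique")
  if (any(m < 1)) stop_config("channel indices are 1-based and must be >= 1")
  structure(m, class = "channel_map")
}

#' Read a run configuration from YAML
#'
#' The file holds `pixel_size` (um per pixel), a `channels` block mapping
#' stain roles to 1-based channel indices, and an optional `params` block
#' with any subset of [analysis_params()] groups.
#'
#' @param path YAML file.
#' @return list with elements `pixel_size`, `channel_map`, `params`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$channels)) stop_config("config is missing a 'channels' block")
  cm <- do.call(channel_map, as.list(y$channels))
  pg <- y$params %||% list()
  params <- analysis_params(
    bead = pg$bead %||% list(), sprout = pg$sprout %||% list(),
    nucleus = pg$nucleus %||% list(), classify = pg$classify %||% list(),
    coverage = pg$coverage %||% list(), skeleton = pg$skeleton %||% list(),
    outputs = pg$outputs
  )
  ps <- y$pixel_size
  if (is.null(ps)) {
    warning("config does not set pixel_size; assuming 1 um/px -- all lengths ",
            "and areas will be in pixel units", call. = FALSE)
    ps <- 1
  }
  if (ps <= 0) stop_config("pixel_size must be positive")
  list(pixel_size = as.numeric(ps), channel_map = cm, params = params)
}

#' Write the parameters used by a run as a JSON sidecar
#'
#' @param params `sprout_params` object.
#' @param path output JSON file.
#' @param pixel_size optional um/px recorded alongside.
#' @export
write_params_json <- function(params, path, pixel_size = NULL) {
  x <- unclass(params)
  if (!is.null(pixel_size)) x$pixel_size <- pixel_size
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
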