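#' Detect cell nuclei
#'
#' The nuclei (DAPI) plane is lightly smoothed and thresholded; touching
#' nuclei are split by a distance-transform watershed when
#' `split_touching` is set; components outside the area gates are dropped.
#' Classes are unset until [classify_nuclei()] is applied.
#'
#' @param img a `sprout_image` with a nuclei plane.
#' @param params [analysis_params()]; the `nucleus` group is used.
#' @return object of class `nucleus_set`: label matrix plus per-nucleus
#'   table (`label`, `row`, `col`, `area_um2`, `mean_ec_marker`, `class`).
#' @export
detect_nuclei <- function(img, params = analysis_params()) {
  plane <- img$planes$nuclei
  if (is.null(plane)) stop_config("nucleus detection needs a nuclei plane")
  px <- img$pixel_size
  np <- params$nucleus
  empty <- function() new_nucleus_set(matrix(0L, nrow(plane), ncol(plane)), px)
  if (diff(range(plane)) == 0) return(empty())
  sm <- gblur_px(plane, np$blur_sigma_um / px)
  thr <- auto_threshold(sm, np$threshold_method, np$manual_threshold)
  mask <- sm > thr
  if (!any(mask)) return(empty())
  mask <- fill_holes(mask)
  if (isTRUE(np$split_touching)) {
    dm <- as_matrix(EBImage::distmap(mask * 1))
    lab <- as_matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
    storage.mode(lab) <- "integer"
  } else {
    lab <- label8(mask)
  }
  st <- label_stats(lab)
  a <- st$area_px * px^2
  keep <- st$label[a >= np$min_area_um2 & a <= np$max_area_um2]
  lab <- relabel_keep(lab, keep)
  new_nucleus_set(lab, px)
}

new_nucleus_set <- function(lab, px) {
  st <- label_stats(lab)
  nuclei <- data.frame(label = st$label, row = st$row, col = st$col,
                       area_um2 = st$area_px * px^2,
                       mean_ec_marker = rep(NA_real_, nrow(st)),
                       class = rep("unclassified", nrow(st)),
                       stringsAsFactors = FALSE)
  structure(list(labels = lab, nuclei = nuclei, n_nuclei = nrow(nuclei),
                 n_ec = NA_integer_, n_pericyte = NA_integer_,
                 pixel_size = px),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("nucleus_set: %d nuclei (EC %s, pericyte %s)\n", x$n_nuclei,
              ifelse(is.na(x$n_ec), "?", x$n_ec),
              ifelse(is.na(x$n_pericyte), "?", x$n_pericyte)))
  invisible(x)
}

#' Classify nuclei into endothelial cells and pericytes
#'
#' The presence or absence of the nuclear endothelial marker (Erg) decides
#' the class: for each nucleus a core marker intensity (mean of its
#' brightest pixel quartile, which resists dilution by the dim rim of the
#' nucleus mask) is computed, and nuclei above the threshold are
#' endothelial, the rest pericyte-derived. The default threshold is an
#' object-level Otsu on the per-nucleus intensity distribution, accepted
#' only when that distribution is genuinely bimodal; degenerate
#' single-class wells -- all nuclei positive, or none -- are called
#' against the plane background instead of being force-split. When the
#' marker plane is absent all nuclei stay unclassified (soft error,
#' warned).
#'
#' @param nuclei a `nucleus_set`.
#' @param img the `sprout_image` providing the `ec_marker` plane.
#' @param params [analysis_params()]; the `classify` group is used.
#' @return the `nucleus_set` with classes, counts and `ec_pericyte_ratio`
#'   filled in (ratio missing when there are no pericytes).
#' @export
classify_nuclei <- function(nuclei, img, params = analysis_params()) {
  plane <- img$planes$ec_marker
  if (is.null(plane)) {
    warning("no ec_marker plane: nuclei left unclassified", call. = FALSE)
    return(nuclei)
  }
  if (!nuclei$n_nuclei) {
    nuclei$n_ec <- 0L; nuclei$n_pericyte <- 0L
    nuclei$ec_pericyte_ratio <- NA_real_
    return(nuclei)
  }
  lab <- nuclei$labels
  idx <- which(lab > 0L)
  # robust core intensity per nucleus: mean of the brightest quartile of its
  # pixels, which resists dilution by the dim halo of the nucleus mask
  means <- as.numeric(tapply(plane[idx],
                             factor(lab[idx], levels = nuclei$nuclei$label),
                             function(v) mean(v[v >= quantile(v, 0.75)])))
  cp <- params$classify
  if (cp$ec_marker_threshold_mode == "manual") {
    if (!is.finite(cp$manual_threshold))
      stop_config("manual classification threshold requested but not set")
    thr <- cp$manual_threshold
  } else {
    # Object-level Otsu on the per-nucleus core intensities, accepted only
    # when the split is genuinely bimodal (Ashman's D >= 3.5; an Otsu split
    # of a unimodal sample shows D of about 2.7 by construction). Otherwise
    # the well is single-class and positivity is called against the plane
    # background.
    bg <- plane[lab == 0L]
    thr <- otsu_threshold(means)
    lo <- means[means <= thr]; hi <- means[means > thr]
    D <- if (length(lo) && length(hi)) {
      (mean(hi) - mean(lo)) /
        sqrt((max(var_or0(lo), 1e-12) + max(var_or0(hi), 1e-12)) / 2)
    } else 0
    if (D < 3.5) {
      floor_ <- median(bg) + 2 * mad(bg)
      thr <- if (mean(means) > floor_) -Inf else Inf  # all EC / all pericyte
    }
  }
  cls <- ifelse(means > thr, "EC", "pericyte")
  nuclei$nuclei$mean_ec_marker <- means
  nuclei$nuclei$class <- cls
  nuclei$n_ec <- sum(cls == "EC")
  nuclei$n_pericyte <- sum(cls == "pericyte")
  nuclei$ec_pericyte_ratio <-
    if (nuclei$n_pericyte > 0) nuclei$n_ec / nuclei$n_pericyte else NA_real_
  nuclei
}

#' Measure pericyte area and coverage
#'
#' The pericyte-marker (NG2) plane is thresholded and the resulting mask
#' reported as pericyte area; coverage is the fraction of the sprout area
#' overlapped by it. The automatic threshold is estimated from the sprout
#' neighbourhood (sprout mask dilated by 20 um), where positive and
#' negative pixels are balanced, and applied to the whole plane. The
#' coverage denominator follows `params$coverage$scope`: bead-attached
#' sprout components only (default) or all components.
#'
#' @param img a `sprout_image` with a pericyte_marker plane.
#' @param sproutmask the `sprout_mask` of the same image.
#' @param params [analysis_params()]; the `coverage` group is used.
#' @return object of class `pericyte_mask` with `mask`, `pericyte_area_um2`
#'   and `coverage` (fraction in `[0, 1]`, missing when the sprout mask is
#'   empty or the marker plane absent).
#' @export
measure_coverage <- function(img, sproutmask, params = analysis_params()) {
  plane <- img$planes$pericyte_marker
  px <- img$pixel_size
  if (is.null(plane)) {
    warning("no pericyte_marker plane: coverage missing", call. = FALSE)
    return(structure(list(mask = NULL, pericyte_area_um2 = NA_real_,
                          coverage = NA_real_), class = "pericyte_mask"))
  }
  cp <- params$coverage
  denom_mask <- if (cp$scope == "attached") {
    attached_mask(sproutmask)
  } else sproutmask$mask
  if (diff(range(plane)) == 0) {
    mask <- matrix(FALSE, nrow(plane), ncol(plane))
  } else {
    # smooth with the same sigma as sprout segmentation so the marker and
    # sprout mask boundaries sit on comparable half-height contours
    sm_plane <- gblur_px(plane, cp$blur_sigma_um / px)
    region <- dilate_disc(sproutmask$mask, 20 / px)
    thr <- auto_threshold(sm_plane, cp$threshold_method, cp$manual_threshold,
                          region = if (any(region)) region else NULL)
    mask <- sm_plane > thr
  }
  cov <- if (any(denom_mask)) sum(mask & denom_mask) / sum(denom_mask) else NA_real_
  structure(list(mask = mask, pericyte_area_um2 = sum(mask) * px^2,
                 coverage = cov),
            class = "pericyte_mask")
}

var_or0 <- function(x) if (length(x) > 1) stats::var(x) else 0

attached_mask <- function(sproutmask) {
  ct <- sproutmask$component_table
  keep <- ct$label[ct$attached]
  m <- sproutmask$components
  matrix(m %in% keep, nrow(m), ncol(m))
}

#' @export
print.pericyte_mask <- function(x, ...) {
  cat(sprintf("pericyte_mask: area %.0f um2, coverage %s\n",
              x$pericyte_area_um2,
              ifelse(is.na(x$coverage), "NA", sprintf("%.3f", x$coverage))))
  invisible(x)
}

#' Cell density in sprouts
#'
#' Nuclei whose centroid lies inside the (bead-attached) sprout mask,
#' expressed per 10^4 um^2 of sprout area. Nuclei sitting on the beads are
#' excluded -- density is a sprout property. Missing when the sprout area
#' is zero.
#'
#' @param nuclei a `nucleus_set`.
#' @param sproutmask a `sprout_mask`.
#' @return density (nuclei per 1e4 um^2), NA when sprout area is 0.
#' @export
measure_cell_density <- function(nuclei, sproutmask) {
  area <- sproutmask$sprout_area_um2
  if (!is.finite(area) || area <= 0) return(NA_real_)
  am <- attached_mask(sproutmask)
  rs <- pmin(pmax(round(nuclei$nuclei$row), 1), nrow(am))
  cs <- pmin(pmax(round(nuclei$nuclei$col), 1), ncol(am))
  inside <- am[cbind(rs, cs)]
  sum(inside) / area * 1e4
}
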