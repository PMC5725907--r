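#' Segment the sprout area connected to beads
#'
#' The actin plane is Gaussian-smoothed, thresholded (Otsu or manual), bead
#' pixels are removed, small gaps (<= 2 px) are closed, components below the
#' minimum sprout area are dropped, and each remaining component is tested
#' for attachment to a bead via overlap with the bead perimeter band.
#' Components touching the bands of two or more beads (anastomoses) are
#' assigned to all of them and flagged.
#'
#' @param img a `sprout_image` with an actin plane.
#' @param beads the `bead_set` detected on the same image.
#' @param params [analysis_params()]; the `sprout` group is used.
#' @return object of class `sprout_mask`: binary sprout mask (bead pixels
#'   excluded), labeled components, per-component table with bead
#'   attachment, and total attached / unattached sprout area in um^2.
#' @export
segment_sprouts <- function(img, beads, params = analysis_params()) {
  if (!inherits(img, "sprout_image")) stop_input("img must be a sprout_image")
  plane <- img$planes$actin
  if (is.null(plane)) stop_config("sprout segmentation needs an actin plane")
  px <- img$pixel_size
  sp <- params$sprout
  bead_mask <- beads$mask > 0L
  blurred <- gblur_px(plane, sp$blur_sigma_um / px)
  mask <- if (diff(range(blurred)) == 0) {
    matrix(FALSE, nrow(plane), ncol(plane))
  } else {
    blurred > auto_threshold(blurred, sp$threshold_method, sp$manual_threshold)
  }
  mask <- mask & !bead_mask
  if (any(mask)) {
    closed <- as_matrix(EBImage::closing(mask * 1, EBImage::makeBrush(5, "disc"))) > 0
    mask <- closed & !bead_mask
  }
  lab <- label8(mask)
  st <- label_stats(lab)
  keep <- st$label[st$area_px * px^2 >= sp$min_sprout_area_um2]
  lab <- relabel_keep(lab, keep)
  st <- label_stats(lab)
  bands <- bead_perimeter_band_cached(beads, sp$band_width_um)
  comp_beads <- lapply(st$label, function(l) {
    inl <- lab == l
    which(vapply(bands, function(b) any(b & inl), TRUE))
  })
  components <- data.frame(
    label = st$label,
    area_um2 = st$area_px * px^2,
    attached = lengths(comp_beads) > 0,
    anastomosis = lengths(comp_beads) > 1,
    touches_border = vapply(st$label, function(l) touches_border(lab, l), TRUE)
  )
  components$beads <- comp_beads
  structure(list(
    mask = lab > 0L,
    components = lab,
    component_table = components,
    sprout_area_um2 = sum(components$area_um2[components$attached]),
    unattached_area_um2 = sum(components$area_um2[!components$attached]),
    pixel_size = px
  ), class = "sprout_mask")
}

# per-bead bands; memoized on the bead_set within one call chain
bead_perimeter_band_cached <- function(beads, width_um) {
  if (!beads$n_beads) return(list())
  bead_perimeter_band(beads, width_um, per_bead = TRUE)
}

#' @export
print.sprout_mask <- function(x, ...) {
  cat(sprintf(paste0("sprout_mask: %d component(s), attached area %.0f um2",
                     " (unattached %.0f um2)\n"),
              nrow(x$component_table), x$sprout_area_um2, x$unattached_area_um2))
  invisible(x)
}

#' Count sprouts per bead
#'
#' A bead's sprout number is the number of distinct skeleton branches
#' crossing its perimeter band (a sprout that bifurcates distally still
#' counts once). With `count_mode = "components"` the number of attached
#' connected components is used instead.
#'
#' @param sproutmask a `sprout_mask`.
#' @param skeleton the `sprout_skeleton` computed from it.
#' @param beads the `bead_set`.
#' @param count_mode "crossings" (default) or "components".
#' @return list with `per_bead` (data.frame `bead`, `n_sprouts`) and
#'   `total`.
#' @export
sprout_count <- function(sproutmask, skeleton, beads, count_mode = "crossings") {
  count_mode <- match.arg(count_mode, c("crossings", "components"))
  if (!beads$n_beads)
    return(list(per_bead = data.frame(bead = integer(), n_sprouts = integer()),
                total = 0L))
  if (count_mode == "crossings") {
    tab <- table(factor(skeleton$crossings$bead, levels = seq_len(beads$n_beads)))
  } else {
    ct <- sproutmask$component_table
    counts <- integer(beads$n_beads)
    for (i in seq_len(nrow(ct)))
      for (b in ct$beads[[i]]) counts[b] <- counts[b] + 1L
    tab <- counts
  }
  per_bead <- data.frame(bead = seq_len(beads$n_beads),
                         n_sprouts = as.integer(tab))
  list(per_bead = per_bead, total = sum(per_bead$n_sprouts))
}
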