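#' Detect microcarrier beads
#'
#' Beads are cell-coated and therefore bright in the actin channel. The
#' plane is thresholded (Otsu by default, or a manual level), a
#' morphological opening with a disc of half the minimum bead radius
#' detaches the thin sprouts, and holes (dark bead cores) are filled per
#' label. Touching beads are separated by a
#' distance-transform watershed seeded at regional maxima of the distance
#' map. Connected components passing the equivalent-radius and circularity
#' gates become beads.
#'
#' @param img a `sprout_image` with an actin plane.
#' @param params [analysis_params()]; the `bead` group is used.
#' @return object of class `bead_set`: labeled mask, per-bead geometry table
#'   (`label`, `row`, `col`, `equivalent_radius_um`, `circularity`,
#'   `area_um2`, `touches_border`), and `n_beads`. Zero beads is a valid
#'   result.
#' @export
detect_beads <- function(img, params = analysis_params()) {
  if (!inherits(img, "sprout_image")) stop_input("img must be a sprout_image")
  plane <- img$planes$actin
  if (is.null(plane)) stop_config("bead detection needs an actin plane")
  px <- img$pixel_size
  bp <- params$bead
  empty <- function() {
    new_bead_set(matrix(0L, nrow(plane), ncol(plane)),
                 data.frame(label = integer(), row = numeric(), col = numeric(),
                            equivalent_radius_um = numeric(), circularity = numeric(),
                            area_um2 = numeric(), touches_border = logical()),
                 px)
  }
  if (diff(range(plane)) == 0) return(empty())
  # pre-smoothing keeps the automatic threshold out of the background mode
  # when beads occupy only a few percent of the field
  plane <- gblur_px(plane, bp$blur_sigma_um / px)
  thr <- auto_threshold(plane, bp$threshold_method, bp$manual_threshold)
  mask <- plane > thr
  if (!any(mask)) return(empty())
  # a small closing solidifies pixel-scale noise holes in the bead interior;
  # the opening then severs sprouts and stray noise bridges BEFORE any hole
  # filling, so loops closed by such bridges are never filled as "holes"
  # (genuine dark bead cores are reclaimed per label afterwards)
  mask <- as_matrix(EBImage::closing(mask * 1, EBImage::makeBrush(5, "disc"))) > 0
  r_open <- max(2, bp$min_radius_um / px / 2)
  opened <- disc_open(mask, r_open)
  if (!any(opened)) return(empty())
  # watershed split of touching beads
  dm <- as_matrix(EBImage::distmap(opened * 1))
  tol <- max(1, bp$min_radius_um / px / 4)
  lab <- as_matrix(EBImage::watershed(dm, tolerance = tol, ext = 1))
  storage.mode(lab) <- "integer"
  lab <- fill_label_holes(lab)
  st <- label_stats(lab)
  if (!nrow(st)) return(empty())
  per <- label_perimeter(lab, nrow(st))
  area_um2 <- st$area_px * px^2
  req <- sqrt(st$area_px / pi) * px
  circ <- 4 * pi * st$area_px / per^2
  keep <- st$label[req >= bp$min_radius_um & req <= bp$max_radius_um &
                     circ >= bp$min_circularity]
  lab2 <- relabel_keep(lab, keep)
  st2 <- label_stats(lab2)
  beads <- data.frame(
    label = st2$label, row = st2$row, col = st2$col,
    equivalent_radius_um = sqrt(st2$area_px / pi) * px,
    circularity = circ[match_label_order(lab, lab2, st2$label)],
    area_um2 = st2$area_px * px^2,
    touches_border = vapply(st2$label, function(l) touches_border(lab2, l), TRUE)
  )
  new_bead_set(lab2, beads, px)
}

# hole filling per label, preserving label identities
fill_label_holes <- function(lab) {
  filled <- fill_holes(lab > 0)
  add <- filled & !(lab > 0)
  if (any(add)) {
    # claim hole pixels for the surrounding label by iterative label growth
    while (any(lab[filled] == 0L)) {
      grown <- grow_labels_once(lab, filled)
      if (identical(grown, lab)) break
      lab <- grown
    }
  }
  lab
}

grow_labels_once <- function(lab, within) {
  out <- lab
  nr <- nrow(lab); nc <- ncol(lab)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    src <- lab[max(1, 1 - s[1]):min(nr, nr - s[1]),
               max(1, 1 - s[2]):min(nc, nc - s[2]), drop = FALSE]
    ri <- max(1, 1 + s[1]):min(nr, nr + s[1])
    ci <- max(1, 1 + s[2]):min(nc, nc + s[2])
    tgt <- out[ri, ci, drop = FALSE]
    w <- within[ri, ci, drop = FALSE]
    fill <- (tgt == 0L) & w & (src > 0L)
    tgt[fill] <- src[fill]
    out[ri, ci] <- tgt
  }
  out
}

match_label_order <- function(lab_old, lab_new, labels_new) {
  vapply(labels_new, function(l) {
    i <- which(lab_new == l)[1]
    lab_old[i]
  }, integer(1))
}

# Crofton-style perimeter from EBImage shape features
label_perimeter <- function(lab, n) {
  feats <- EBImage::computeFeatures.shape(lab)
  per <- rep(NA_real_, n)
  rn <- as.integer(rownames(feats) %||% seq_len(nrow(feats)))
  per[rn] <- feats[, "s.perimeter"]
  per
}

new_bead_set <- function(mask, beads, pixel_size) {
  structure(list(mask = mask, beads = beads, n_beads = nrow(beads),
                 pixel_size = pixel_size),
            class = "bead_set")
}

#' @export
print.bead_set <- function(x, ...) {
  cat(sprintf("bead_set: %d bead(s)\n", x$n_beads))
  if (x$n_beads) print(x$beads, digits = 4)
  invisible(x)
}

#' Perimeter band around detected beads
#'
#' The annulus of pixels lying within `width_um` outside the bead
#' boundaries. Sprout attachment and sprout counting are defined on this
#' band. Overlapping annuli of neighbouring beads merge without double
#' counting in the merged mask; the per-bead variant keeps them separate.
#'
#' @param beads a `bead_set`.
#' @param width_um band width in micrometers (> 0).
#' @param per_bead return a list of one logical mask per bead instead of the
#'   merged mask.
#' @return logical matrix (or list of them when `per_bead = TRUE`).
#' @export
bead_perimeter_band <- function(beads, width_um, per_bead = FALSE) {
  if (width_um <= 0) stop_config("width_um must be positive")
  px <- beads$pixel_size
  w <- width_um / px
  any_bead <- beads$mask > 0L
  if (!beads$n_beads) {
    e <- matrix(FALSE, nrow(beads$mask), ncol(beads$mask))
    return(if (per_bead) list() else e)
  }
  if (!per_bead) {
    d <- distance_to(any_bead)
    return(d <= w & !any_bead)
  }
  lapply(seq_len(beads$n_beads), function(k) {
    d <- distance_to(beads$mask == k)
    d <= w & !any_bead
  })
}
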