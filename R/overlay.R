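#' Write a QC overlay PNG
#'
#' Renders the actin channel in gray with colored outlines of the detected
#' objects: bead outlines in cyan, sprout mask in green, skeleton in
#' yellow with junctions in red, nucleus outlines colored by class
#' (EC yellow, pericyte magenta), pericyte mask in red.
#'
#' @param path output PNG.
#' @param img the analyzed `sprout_image`.
#' @param objects list of stage objects as returned by
#'   `analyze_image(..., keep_objects = TRUE)$objects` (any subset of
#'   `beads`, `sprouts`, `skeleton`, `nuclei`, `coverage`).
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(path, img, objects) {
  base <- img$planes$actin
  rng <- range(base)
  g <- if (diff(rng) > 0) (base - rng[1]) / diff(rng) else base * 0
  rgb <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  paint <- function(mask, col, alpha = 1) {
    if (is.null(mask) || !any(mask)) return(invisible())
    for (k in 1:3) {
      ch <- rgb[, , k]
      ch[mask] <- (1 - alpha) * ch[mask] + alpha * col[k]
      rgb[, , k] <<- ch
    }
  }
  outline <- function(mask) mask & nbcount8(mask) < 8
  if (!is.null(objects$sprouts)) paint(objects$sprouts$mask, c(0, 0.7, 0), 0.35)
  if (!is.null(objects$coverage) && !is.null(objects$coverage$mask))
    paint(outline(objects$coverage$mask), c(1, 0.2, 0.2))
  if (!is.null(objects$beads)) paint(outline(objects$beads$mask > 0), c(0, 1, 1))
  if (!is.null(objects$skeleton)) {
    paint(objects$skeleton$skeleton, c(1, 1, 0))
    jl <- objects$skeleton$junctions
    if (nrow(jl)) {
      jm <- matrix(FALSE, nrow(g), ncol(g))
      jm[cbind(pmin(pmax(round(jl$row), 1), nrow(g)),
               pmin(pmax(round(jl$col), 1), ncol(g)))] <- TRUE
      paint(dilate_disc(jm, 2), c(1, 0, 0))
    }
  }
  if (!is.null(objects$nuclei) && objects$nuclei$n_nuclei) {
    lab <- objects$nuclei$labels
    cls <- objects$nuclei$nuclei$class
    ol <- (lab > 0) & nbcount8(lab > 0) < 8
    ec_lab <- objects$nuclei$nuclei$label[cls == "EC"]
    pc_lab <- objects$nuclei$nuclei$label[cls == "pericyte"]
    un_lab <- objects$nuclei$nuclei$label[cls == "unclassified"]
    paint(ol & matrix(lab %in% ec_lab, nrow(lab)), c(1, 1, 0.2))
    paint(ol & matrix(lab %in% pc_lab, nrow(lab)), c(1, 0.2, 1))
    paint(ol & matrix(lab %in% un_lab, nrow(lab)), c(0.7, 0.7, 1))
  }
  png::writePNG(rgb, path)
  invisible(path)
}
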