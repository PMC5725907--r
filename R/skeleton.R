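#' Skeletonize the sprout mask and build the branch graph
#'
#' The sprout mask is thinned to a 1-px-wide, 8-connected skeleton
#' (Zhang-Suen thinning with a topology-preserving cleanup pass). Spur
#' branches shorter than `prune_length_um` -- thinning artifacts on noisy
#' edges -- are removed iteratively. The skeleton is decomposed into
#' junction clusters (8-connected groups of pixels with >= 3 skeleton
#' neighbours, one biological branch point each) and branch segments whose
#' lengths are measured by chordal resampling: Euclidean chords between
#' every 5th pixel along the ordered branch path, which removes the
#' systematic overestimate of per-pixel chain codes at intermediate angles.
#' For every bead, the skeleton pixels inside the bead's perimeter band are
#' grouped into crossings (one per sprout); the gap between each crossing
#' and the bead boundary (where thinning retracts the root) is measured on
#' the bead distance map and added back to the sprout length.
#'
#' @param sproutmask a `sprout_mask`.
#' @param beads the `bead_set` of the same image.
#' @param params [analysis_params()]; `skeleton` and `sprout` groups used.
#' @return object of class `sprout_skeleton` with fields `skeleton` (logical
#'   matrix), `branches`, `junctions`, `crossings` (data.frames), `per_bead`
#'   summary and image-level `totals`.
#' @export
skeletonize_sprouts <- function(sproutmask, beads, params = analysis_params()) {
  px <- sproutmask$pixel_size
  prune_px <- params$skeleton$prune_length_um / px
  bead_mask <- beads$mask > 0L
  # Thin the union of sprouts and beads, then drop the bead interior: tube
  # centerlines then run smoothly up to the bead rim instead of forking at
  # the flat cut left by bead-pixel removal.
  skel <- thin_mask(sproutmask$mask | bead_mask) & !bead_mask & sproutmask$mask
  skel <- thin_mask(skel)
  # iterative spur pruning
  for (it in seq_len(25)) {
    parts <- decompose_skeleton(skel)
    if (!nrow(parts$branches)) break
    spur <- parts$branches$has_endpoint & parts$branches$n_junctions >= 1 &
      parts$branches$length_px < prune_px
    if (!any(spur)) break
    drop <- parts$branch_lab %in% parts$branches$id[spur]
    skel[drop] <- FALSE
    skel <- thin_mask(skel)  # re-thin to clean junction remnants
  }
  parts <- decompose_skeleton(skel)
  comp_lab <- label8(skel)
  branches <- parts$branches
  bpix <- label_pixels(parts$branch_lab)
  branches$component <- vapply(seq_len(nrow(branches)), function(i)
    comp_lab[bpix[[i]][1]], integer(1))
  branches$length_um <- branches$length_px * px
  junctions <- parts$junctions
  junctions$component <- if (nrow(junctions)) {
    jpix <- label_pixels(parts$junction_lab)
    vapply(seq_len(nrow(junctions)), function(i)
      comp_lab[jpix[[i]][1]], integer(1))
  } else integer()

  # map skeleton components to sprout-mask components and bead attachment
  attach_tab <- sproutmask$component_table
  comp_attached <- function(mask_comp) {
    i <- match(mask_comp, attach_tab$label)
    if (is.na(i)) FALSE else attach_tab$attached[i]
  }
  n_comp <- max(comp_lab, 0L)
  comp_mask_label <- integer(n_comp)
  for (k in seq_len(n_comp)) {
    i <- which(comp_lab == k)[1]
    comp_mask_label[k] <- sproutmask$components[i]
  }
  attached_comp <- vapply(comp_mask_label, comp_attached, TRUE)

  # crossings of the bead perimeter bands
  crossings <- data.frame(bead = integer(), component = integer(),
                          crossing = integer(), root_gap_um = numeric())
  if (beads$n_beads) {
    w_px <- params$sprout$band_width_um / px
    min_len_px <- params$sprout$min_sprout_length_um / px
    comp_len_px <- tapply(branches$length_px,
                          factor(branches$component, levels = seq_len(n_comp)),
                          sum)
    comp_len_px[is.na(comp_len_px)] <- 0
    any_bead <- beads$mask > 0L
    cid <- 0L
    for (b in seq_len(beads$n_beads)) {
      d_bead <- distance_to(beads$mask == b)
      inband <- skel & d_bead <= w_px & !any_bead
      if (!any(inband)) next
      cl <- label8(inband)
      for (pix in label_pixels(cl)) {
        comp <- comp_lab[pix[1]]
        if (comp_len_px[comp] < min_len_px) next
        cid <- cid + 1L
        crossings <- rbind(crossings, data.frame(
          bead = b, component = comp, crossing = cid,
          root_gap_um = min(d_bead[pix]) * px))
      }
    }
  }

  bead_attached <- attached_comp
  tot_len <- sum(branches$length_um[bead_attached[branches$component]]) +
    sum(crossings$root_gap_um)
  n_sprouts <- nrow(crossings)
  n_junctions <- if (nrow(junctions))
    sum(bead_attached[junctions$component]) else 0L
  per_bead <- if (beads$n_beads) {
    data.frame(bead = seq_len(beads$n_beads),
               n_sprouts = as.integer(table(factor(crossings$bead,
                                                   levels = seq_len(beads$n_beads)))))
  } else data.frame(bead = integer(), n_sprouts = integer())

  structure(list(
    skeleton = skel, branches = branches, junctions = junctions,
    crossings = crossings, per_bead = per_bead,
    component_attached = attached_comp,
    totals = list(total_length_um = tot_len, n_sprouts = n_sprouts,
                  n_branch_points = n_junctions),
    unattached_length_um =
      sum(branches$length_um[!bead_attached[branches$component]]),
    pixel_size = px
  ), class = "sprout_skeleton")
}

#' @export
print.sprout_skeleton <- function(x, ...) {
  cat(sprintf(paste0("sprout_skeleton: %d sprout(s), total length %.1f um, ",
                     "%d branch point(s)\n"),
              x$totals$n_sprouts, x$totals$total_length_um,
              x$totals$n_branch_points))
  invisible(x)
}

# Decompose a skeleton into junction clusters and branch segments.
# Returns branch/junction label matrices plus summary tables with lengths
# (in px, chordal resampling) and endpoint/junction adjacency.
decompose_skeleton <- function(skel) {
  nb <- nbcount8(skel)
  junction_px <- skel & nb >= 3
  jlab <- label8(junction_px)
  seg_mask <- skel & !junction_px
  blab <- label8(seg_mask)
  nseg <- max(blab, 0L)
  njun <- max(jlab, 0L)
  branches <- data.frame(id = seq_len(nseg), n_px = integer(nseg),
                         length_px = numeric(nseg), has_endpoint = logical(nseg),
                         n_junctions = integer(nseg))
  if (nseg) {
    nr <- nrow(skel)
    pix_of <- label_pixels(blab)
    for (k in seq_len(nseg)) {
      pix <- pix_of[[k]]
      rr <- (pix - 1L) %% nr + 1L
      cc <- (pix - 1L) %/% nr + 1L
      branches$n_px[k] <- length(pix)
      branches$length_px[k] <- chordal_length(rr, cc)
      branches$has_endpoint[k] <- any(nb[pix] == 1L)
      branches$n_junctions[k] <- n_adjacent_junctions(rr, cc, jlab)
    }
  }
  junctions <- data.frame(id = seq_len(njun), n_px = integer(njun),
                          row = numeric(njun), col = numeric(njun))
  if (njun) {
    st <- label_stats(jlab)
    junctions$n_px <- st$area_px
    junctions$row <- st$row
    junctions$col <- st$col
  }
  list(branches = branches, junctions = junctions,
       branch_lab = blab, junction_lab = jlab)
}

# Path length by Euclidean chords over every `stride`th ordered pixel.
chordal_length <- function(rr, cc, stride = 5L) {
  n <- length(rr)
  if (n < 2L) return(0)
  ord <- order_path(as.integer(rr), as.integer(cc))
  o <- order(ord)
  rr <- rr[o]; cc <- cc[o]
  anchors <- unique(c(seq(1L, n, by = stride), n))
  sum(sqrt(diff(rr[anchors])^2 + diff(cc[anchors])^2))
}

n_adjacent_junctions <- function(rr, cc, jlab) {
  if (!max(jlab)) return(0L)
  nr <- nrow(jlab); nc <- ncol(jlab)
  seen <- integer(0)
  for (i in seq_along(rr)) {
    r0 <- max(1L, rr[i] - 1L):min(nr, rr[i] + 1L)
    c0 <- max(1L, cc[i] - 1L):min(nc, cc[i] + 1L)
    v <- jlab[r0, c0]
    seen <- c(seen, v[v > 0L])
  }
  length(unique(seen))
}

#' Sprout length measurements
#'
#' Total length is the summed branch length of all bead-attached skeleton
#' components plus the root gaps between skeleton and bead boundary;
#' average length divides by the sprout count (missing when there are no
#' sprouts).
#'
#' @param skeleton a `sprout_skeleton`.
#' @return list with `total_sprout_length_um` and `avg_sprout_length_um`.
#' @export
measure_lengths <- function(skeleton) {
  tot <- skeleton$totals$total_length_um
  n <- skeleton$totals$n_sprouts
  list(total_sprout_length_um = tot,
       avg_sprout_length_um = if (n >= 1) tot / n else NA_real_)
}

#' Average sprout width
#'
#' Area-weighted mean width: attached sprout area divided by total skeleton
#' length. Parameter-free and stable under resolution changes; missing when
#' the total length is zero.
#'
#' @param sproutmask a `sprout_mask`.
#' @param skeleton the matching `sprout_skeleton`.
#' @return average width in micrometers (NA when length is 0).
#' @export
measure_width <- function(sproutmask, skeleton) {
  tot <- skeleton$totals$total_length_um
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sproutmask$sprout_area_um2 / tot
}

#' Branch points per sprout
#'
#' Junction clusters (8-connected groups of skeleton pixels with >= 3
#' neighbours) count once each; the average divides the junction count on
#' bead-attached skeletons by the sprout count.
#'
#' @param skeleton a `sprout_skeleton`.
#' @param per_bead also return the per-bead variant (junctions per bead).
#' @return list with `n_branch_points` and `avg_branch_points` (NA when
#'   there are no sprouts).
#' @export
count_branch_points <- function(skeleton, per_bead = FALSE) {
  n_j <- skeleton$totals$n_branch_points
  n_s <- skeleton$totals$n_sprouts
  out <- list(n_branch_points = n_j,
              avg_branch_points = if (n_s >= 1) n_j / n_s else NA_real_)
  if (per_bead && nrow(skeleton$per_bead)) {
    jb <- merge(skeleton$junctions,
                unique(skeleton$crossings[, c("bead", "component")]),
                by = "component")
    out$per_bead <- as.integer(table(factor(jb$bead,
                                            levels = skeleton$per_bead$bead)))
  }
  out
}
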