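#' Synthetic bead-sprouting scene specification
#'
#' Describes a synthetic assay field: bright circular microcarrier beads,
#' tubular sprouts emanating from their perimeters (stroked polylines with
#' hemispherical caps, gently curved via waypoints, optionally branching),
#' blob-like nuclei, an endothelial nuclear marker colocalized with the EC
#' nuclei, and pericyte-marker ribbons painted over a controlled fraction
#' of each tube. Rendering degrades the ideal planes with a Gaussian PSF
#' and shot noise. All geometry is in micrometers, origin at the top-left
#' corner, rows growing downward.
#'
#' @param seed integer; rendering is bit-identical for a fixed spec.
#' @param field_um field size `c(height, width)` in micrometers.
#' @param pixel_size micrometers per pixel.
#' @param beads list of `list(center = c(row_um, col_um), radius_um = r)`.
#' @param sprouts list of `list(bead =, angle_deg =, length_um =,
#'   width_um =, wiggle_um = numeric lateral waypoint offsets, branches =
#'   list(list(at_frac =, angle_offset_deg =, length_um =, width_um =)))`.
#'   `angle_deg` 0 points east, counterclockwise positive; the realized
#'   centerline arc length equals `length_um` exactly.
#' @param nuclei data.frame with `row_um`, `col_um`, `radius_um`, `class`
#'   ("EC" or "pericyte"), `on_bead` (logical).
#' @param coverage_fraction fraction of each tube's arc length painted with
#'   pericyte marker (`NA` = no pericyte channel content).
#' @param roles which stain channels to render.
#' @param optics list: `psf_sigma_um` (default 2), `background` photon
#'   level (default 100), `noise` ("poisson" or "gaussian"), `snr` signal
#'   amplitude over background noise SD (default 5), `marker_contrast` EC
#'   over pericyte nuclear-marker amplitude ratio (default 5).
#' @param n_planes render a simple z-stack with this many planes (objects
#'   weighted by a Gaussian focal profile); used to exercise projections.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(seed, field_um = c(768, 768), pixel_size = 1,
                       beads = list(), sprouts = list(),
                       nuclei = NULL, coverage_fraction = NA_real_,
                       roles = SPROUTR_ROLES, optics = list(), n_planes = 1L) {
  optics <- modifyList(list(psf_sigma_um = 2, background = 100,
                            noise = "poisson", snr = 5, marker_contrast = 5),
                       optics)
  match.arg(optics$noise, c("poisson", "gaussian"))
  if (is.null(nuclei))
    nuclei <- data.frame(row_um = numeric(), col_um = numeric(),
                         radius_um = numeric(), class = character(),
                         on_bead = logical(), stringsAsFactors = FALSE)
  if (!is.na(coverage_fraction) &&
      (coverage_fraction < 0 || coverage_fraction > 1))
    stop_generation("coverage_fraction must lie in [0, 1]")
  for (s in sprouts) {
    if (s$bead < 1 || s$bead > length(beads))
      stop_generation("sprout references bead ", s$bead, " which does not exist")
  }
  spec <- structure(list(seed = as.integer(seed), field_um = field_um,
                         pixel_size = pixel_size, beads = beads,
                         sprouts = sprouts, nuclei = nuclei,
                         coverage_fraction = coverage_fraction,
                         roles = intersect(SPROUTR_ROLES, roles),
                         optics = optics, n_planes = as.integer(n_planes)),
                    class = "scene_spec")
  # geometric feasibility: every centerline point must stay in the field
  for (i in seq_along(sprouts)) {
    pl <- sprout_polylines(spec, i)
    pts <- do.call(rbind, lapply(pl, `[[`, "points"))
    if (any(pts[, 1] < 0) || any(pts[, 2] < 0) ||
        any(pts[, 1] > field_um[1]) || any(pts[, 2] > field_um[2]))
      stop_generation("sprout ", i, " extends beyond the field")
  }
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0("scene_spec (seed %d): %g x %g um, %d bead(s), ",
                     "%d sprout(s), %d nuclei\n"),
              x$seed, x$field_um[1], x$field_um[2], length(x$beads),
              length(x$sprouts), nrow(x$nuclei)))
  invisible(x)
}

# Realized centerline polylines (um) for sprout i: main path rescaled to the
# requested arc length, plus straight branch paths. Returns a list of
# list(points = n x 2 matrix, width_um, length_um, role = "main"|"branch").
sprout_polylines <- function(spec, i) {
  s <- spec$sprouts[[i]]
  bead <- spec$beads[[s$bead]]
  a <- s$angle_deg * pi / 180
  dir <- c(-sin(a), cos(a))          # (row, col); 0 deg = east, ccw positive
  perp <- c(-cos(a), -sin(a))
  start <- bead$center + bead$radius_um * dir
  wiggle <- s$wiggle_um %||% numeric()
  k <- length(wiggle)
  fr <- if (k) seq_len(k) / (k + 1) else numeric()
  raw <- rbind(start,
               if (k) t(vapply(seq_len(k), function(j)
                 start + s$length_um * fr[j] * dir + wiggle[j] * perp,
                 numeric(2))),
               start + s$length_um * dir)
  # reparameterize so the realized arc length equals length_um exactly
  seg <- diff(raw)
  seglen <- sqrt(rowSums(seg^2))
  scale <- s$length_um / sum(seglen)
  pts <- matrix(0, nrow(raw), 2)
  pts[1, ] <- start
  for (j in seq_len(nrow(seg)))
    pts[j + 1, ] <- pts[j, ] + seg[j, ] * scale
  out <- list(list(points = pts, width_um = s$width_um,
                   length_um = s$length_um, role = "main"))
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  for (br in (s$branches %||% list())) {
    at <- br$at_frac * s$length_um
    j <- max(which(cum <= at + 1e-9))
    j <- min(j, nrow(pts) - 1L)
    t0 <- (at - cum[j]) / (cum[j + 1] - cum[j])
    p0 <- pts[j, ] + t0 * (pts[j + 1, ] - pts[j, ])
    d0 <- (pts[j + 1, ] - pts[j, ])
    d0 <- d0 / sqrt(sum(d0^2))
    b <- br$angle_offset_deg * pi / 180
    db <- c(d0[1] * cos(b) - d0[2] * sin(b), d0[1] * sin(b) + d0[2] * cos(b))
    out[[length(out) + 1L]] <- list(
      points = rbind(p0, p0 + br$length_um * db),
      width_um = br$width_um %||% s$width_um,
      length_um = br$length_um, role = "branch")
  }
  out
}

# Rasterize one polyline tube: squared distance and arc-length maps over the
# pixel grid (px units). Updates dist2/arc in place semantics via return.
rasterize_tube <- function(dist2, arc, pts_um, px, halfw_px) {
  nr <- nrow(dist2); nc <- ncol(dist2)
  p <- pts_um / px + 0.5              # pixel-center coordinates
  cum <- 0
  pad <- ceiling(halfw_px) + 2
  for (j in seq_len(nrow(p) - 1L)) {
    a <- p[j, ]; b <- p[j + 1, ]
    v <- b - a
    L <- sqrt(sum(v^2))
    if (L == 0) next
    ri <- max(1, floor(min(a[1], b[1]) - pad)):min(nr, ceiling(max(a[1], b[1]) + pad))
    ci <- max(1, floor(min(a[2], b[2]) - pad)):min(nc, ceiling(max(a[2], b[2]) + pad))
    if (!length(ri) || !length(ci)) { cum <- cum + L; next }
    Rm <- matrix(ri, length(ri), length(ci))
    Cm <- matrix(ci, length(ri), length(ci), byrow = TRUE)
    tt <- pmin(1, pmax(0, ((Rm - a[1]) * v[1] + (Cm - a[2]) * v[2]) / L^2))
    d2 <- (Rm - (a[1] + tt * v[1]))^2 + (Cm - (a[2] + tt * v[2]))^2
    old <- dist2[ri, ci]
    upd <- d2 < old
    if (any(upd)) {
      old[upd] <- d2[upd]
      dist2[ri, ci] <- old
      ar <- arc[ri, ci]
      ar[upd] <- (cum + tt[upd] * L)
      arc[ri, ci] <- ar
    }
    cum <- cum + L
  }
  list(dist2 = dist2, arc = arc)
}

render_blobs <- function(plane, rows_px, cols_px, sigma_px, amps) {
  nr <- nrow(plane); nc <- ncol(plane)
  for (i in seq_along(rows_px)) {
    s <- sigma_px[i]
    rad <- ceiling(3 * s)
    ri <- max(1, floor(rows_px[i] - rad)):min(nr, ceiling(rows_px[i] + rad))
    ci <- max(1, floor(cols_px[i] - rad)):min(nc, ceiling(cols_px[i] + rad))
    Rm <- matrix(ri, length(ri), length(ci))
    Cm <- matrix(ci, length(ri), length(ci), byrow = TRUE)
    g <- exp(-((Rm - rows_px[i])^2 + (Cm - cols_px[i])^2) / (2 * s^2))
    plane[ri, ci] <- pmax(plane[ri, ci], amps[i] * g)
  }
  plane
}

#' Render a synthetic scene
#'
#' Produces the multi-channel image (or z-stack) plus the exact ground
#' truth for every measurement, derived from the pre-noise geometry masks.
#' Rendering is bit-identical for identical specs.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (a `sprout_image`, or `sprout_stack` when
#'   `n_planes > 1`) and `truth` (see Details). `truth$masks` holds the
#'   pre-noise bead / sprout / ribbon masks for oracle comparisons.
#' @export
render_scene <- function(spec) {
  px <- spec$pixel_size
  nr <- round(spec$field_um[1] / px)
  nc <- round(spec$field_um[2] / px)
  op <- spec$optics
  A <- op$snr * sqrt(op$background)

  bead_mask <- matrix(FALSE, nr, nc)
  for (b in spec$beads) {
    r_px <- b$radius_um / px
    c_px <- b$center / px + 0.5
    ri <- max(1, floor(c_px[1] - r_px - 1)):min(nr, ceiling(c_px[1] + r_px + 1))
    ci <- max(1, floor(c_px[2] - r_px - 1)):min(nc, ceiling(c_px[2] + r_px + 1))
    Rm <- matrix(ri, length(ri), length(ci))
    Cm <- matrix(ci, length(ri), length(ci), byrow = TRUE)
    disk <- (Rm - c_px[1])^2 + (Cm - c_px[2])^2 <= r_px^2
    bead_mask[ri, ci] <- bead_mask[ri, ci] | disk
  }

  tube_mask <- matrix(FALSE, nr, nc)
  ribbon_mask <- matrix(FALSE, nr, nc)
  lengths_um <- numeric(length(spec$sprouts))
  n_branch_points <- 0L
  for (i in seq_along(spec$sprouts)) {
    pls <- sprout_polylines(spec, i)
    for (pl in pls) {
      d2 <- matrix(Inf, nr, nc)
      ar <- matrix(NA_real_, nr, nc)
      halfw <- pl$width_um / 2 / px
      ras <- rasterize_tube(d2, ar, pl$points, px, halfw)
      inside <- ras$dist2 <= halfw^2
      tube_mask <- tube_mask | inside
      if (!is.na(spec$coverage_fraction) && spec$coverage_fraction > 0) {
        lim <- spec$coverage_fraction * (pl$length_um / px)
        ribbon_mask <- ribbon_mask | (inside & !is.na(ras$arc) & ras$arc <= lim)
      }
      lengths_um[i] <- lengths_um[i] + pl$length_um
    }
    n_branch_points <- n_branch_points + length(spec$sprouts[[i]]$branches %||% list())
  }

  sprout_mask <- tube_mask & !bead_mask
  ribbon_mask <- ribbon_mask & !bead_mask

  ideal <- list()
  if ("actin" %in% spec$roles)
    ideal$actin <- A * ((bead_mask | tube_mask) * 1)
  if ("nuclei" %in% spec$roles || "ec_marker" %in% spec$roles) {
    nuc <- spec$nuclei
    rows_px <- nuc$row_um / px + 0.5
    cols_px <- nuc$col_um / px + 0.5
    sig_px <- nuc$radius_um / 1.7 / px
    if ("nuclei" %in% spec$roles)
      ideal$nuclei <- render_blobs(matrix(0, nr, nc), rows_px, cols_px,
                                   sig_px, rep(A, nrow(nuc)))
    if ("ec_marker" %in% spec$roles) {
      amps <- ifelse(nuc$class == "EC", A, A / op$marker_contrast)
      ideal$ec_marker <- render_blobs(matrix(0, nr, nc), rows_px, cols_px,
                                      sig_px, amps)
    }
  }
  if ("pericyte_marker" %in% spec$roles)
    ideal$pericyte_marker <- A * (ribbon_mask * 1)

  sigma_px <- op$psf_sigma_um / px
  degrade <- function(lambda) {
    if (op$noise == "poisson") {
      matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda)) * 1.0
    } else {
      lambda + rnorm(length(lambda), 0, sqrt(op$background))
    }
  }
  image <- with_seed(spec$seed, {
    if (spec$n_planes == 1L) {
      planes <- lapply(ideal, function(pl)
        degrade(op$background + gblur_px(pl, sigma_px)))
      multichannel_image(planes, px, paste0("scene-", spec$seed))
    } else {
      zc <- (spec$n_planes + 1) / 2
      wz <- exp(-(seq_len(spec$n_planes) - zc)^2 / (2 * 1.5^2))
      planes <- lapply(ideal, function(pl) {
        blurred <- gblur_px(pl, sigma_px)
        lapply(wz, function(w) degrade(op$background + w * blurred))
      })
      new_stack(planes, px, paste0("scene-", spec$seed))
    }
  })

  n_sprouts_per_bead <- as.integer(table(factor(
    vapply(spec$sprouts, `[[`, numeric(1), "bead"),
    levels = seq_along(spec$beads))))
  n_sprouts <- length(spec$sprouts)
  area_um2 <- sum(sprout_mask) * px^2
  nuc <- spec$nuclei
  in_sprout <- if (nrow(nuc)) {
    rs <- pmin(pmax(round(nuc$row_um / px + 0.5), 1), nr)
    cs <- pmin(pmax(round(nuc$col_um / px + 0.5), 1), nc)
    sprout_mask[cbind(rs, cs)]
  } else logical()
  n_ec <- sum(nuc$class == "EC")
  n_pc <- sum(nuc$class == "pericyte")
  truth <- list(
    n_beads = length(spec$beads),
    bead_centers_px = if (length(spec$beads))
      t(vapply(spec$beads, function(b) b$center / px + 0.5, numeric(2)))
    else matrix(0, 0, 2),
    bead_radii_um = vapply(spec$beads, `[[`, numeric(1), "radius_um"),
    n_sprouts = n_sprouts,
    n_sprouts_per_bead = n_sprouts_per_bead,
    sprout_lengths_um = lengths_um,
    total_sprout_length_um = sum(lengths_um),
    avg_sprout_length_um = if (n_sprouts) mean(lengths_um) else NA_real_,
    sprout_widths_um = vapply(spec$sprouts, `[[`, numeric(1), "width_um"),
    sprout_area_um2 = area_um2,
    pericyte_coverage = if (!is.na(spec$coverage_fraction) && area_um2 > 0)
      sum(ribbon_mask & sprout_mask) / sum(sprout_mask) else NA_real_,
    pericyte_area_um2 = sum(ribbon_mask) * px^2,
    n_nuclei = nrow(nuc),
    n_ec = n_ec, n_pericyte = n_pc,
    ec_pericyte_ratio = if (n_pc > 0) n_ec / n_pc else NA_real_,
    cell_density = if (area_um2 > 0) sum(in_sprout) / area_um2 * 1e4 else NA_real_,
    n_branch_points = n_branch_points,
    avg_branch_points = if (n_sprouts) n_branch_points / n_sprouts else NA_real_,
    masks = list(beads = bead_mask, sprouts = sprout_mask,
                 ribbon = ribbon_mask & sprout_mask)
  )
  list(image = image, truth = truth)
}

#' Sample a random scene specification
#'
#' Places beads without overlap by rejection sampling, draws sprouts with a
#' minimum angular spacing of 25 degrees per bead and rejection tests
#' against collisions with other beads and tubes, seeds nuclei along the
#' tube centerlines and on the bead surfaces, and trims the nucleus list so
#' the EC:pericyte count ratio is exact (default 10:1, the assay's seeding
#' ratio). Fully reproducible for a fixed seed.
#'
#' @param seed integer seed; also the rendering seed of the returned spec.
#' @param n_beads number of beads.
#' @param sprouts_per_bead integer vector sampled per bead (realized counts
#'   may be lower when geometry runs out of room; the returned spec is the
#'   ground truth either way).
#' @param field_um field size `c(height, width)` um.
#' @param pixel_size um per pixel.
#' @param bead_radius_um range of bead radii.
#' @param sprout_length_um range of sprout lengths.
#' @param sprout_width_um range (or single value) of tube widths.
#' @param n_waypoints range of curvature waypoints per sprout.
#' @param wiggle_um maximal lateral waypoint offset.
#' @param nuclei_spacing_um spacing of nuclei along tubes.
#' @param nucleus_radius_um nucleus radius.
#' @param bead_nuclei nuclei placed on each bead surface.
#' @param ec_pericyte_ratio EC:pericyte count ratio (NA = EC only).
#' @param coverage_fraction pericyte ribbon fraction (NA = none).
#' @param roles channels to render.
#' @param snr,psf_sigma_um,background,noise,marker_contrast optics, see
#'   [scene_spec()].
#' @return a [scene_spec()].
#' @export
random_scene <- function(seed, n_beads = 3, sprouts_per_bead = 2:6,
                         field_um = c(1000, 1000), pixel_size = 1,
                         bead_radius_um = c(75, 110),
                         sprout_length_um = c(150, 400),
                         sprout_width_um = c(20, 30),
                         n_waypoints = 0:2, wiggle_um = 12,
                         nuclei_spacing_um = 30, nucleus_radius_um = 5,
                         bead_nuclei = 6, ec_pericyte_ratio = 10,
                         coverage_fraction = NA_real_,
                         roles = SPROUTR_ROLES,
                         snr = 5, psf_sigma_um = 2, background = 100,
                         noise = "poisson", marker_contrast = 5) {
  with_seed(seed, {
    H <- field_um[1]; W <- field_um[2]
    margin <- 12
    beads <- list()
    for (b in seq_len(n_beads)) {
      placed <- FALSE
      for (try in seq_len(500)) {
        r <- runif(1, bead_radius_um[1], bead_radius_um[2])
        ctr <- c(runif(1, r + margin, H - r - margin),
                 runif(1, r + margin, W - r - margin))
        ok <- all(vapply(beads, function(o)
          sqrt(sum((o$center - ctr)^2)) >= o$radius_um + r + 30, TRUE))
        if (ok) { beads[[b]] <- list(center = ctr, radius_um = r); placed <- TRUE; break }
      }
      if (!placed) stop_generation("could not place ", n_beads,
                                   " non-overlapping beads in the field")
    }
    samples_of <- function(pts) {
      # points every ~5 um along a polyline, for collision tests
      out <- pts[1, , drop = FALSE]
      for (j in seq_len(nrow(pts) - 1L)) {
        v <- pts[j + 1, ] - pts[j, ]
        L <- sqrt(sum(v^2))
        ts <- seq(0, 1, length.out = max(2, ceiling(L / 5) + 1))
        out <- rbind(out, sweep(outer(ts[-1], v), 2, pts[j, ], "+"))
      }
      out
    }
    sprouts <- list()
    tube_samples <- list()
    for (b in seq_along(beads)) {
      target <- if (length(sprouts_per_bead) == 1) sprouts_per_bead
        else sample(sprouts_per_bead, 1)
      angles <- numeric()
      for (sidx in seq_len(target)) {
        for (try in seq_len(80)) {
          a <- runif(1, 0, 360)
          if (length(angles) &&
              min(pmin(abs(a - angles), 360 - abs(a - angles))) < 25) next
          len <- runif(1, sprout_length_um[1], sprout_length_um[2])
          w <- if (length(sprout_width_um) == 1) sprout_width_um
            else runif(1, sprout_width_um[1], sprout_width_um[2])
          k <- if (length(n_waypoints) == 1) n_waypoints
            else sample(n_waypoints, 1)
          cand <- list(bead = b, angle_deg = a, length_um = len, width_um = w,
                       wiggle_um = if (k) runif(k, -wiggle_um, wiggle_um)
                                   else numeric(),
                       branches = list())
          tmp <- list(beads = beads, sprouts = list(cand), pixel_size = pixel_size)
          pts <- sprout_polylines(tmp, 1)[[1]]$points
          smp <- samples_of(pts)
          pad <- w / 2 + 8
          if (any(smp[, 1] < pad + 3) || any(smp[, 2] < pad + 3) ||
              any(smp[, 1] > H - pad - 3) || any(smp[, 2] > W - pad - 3)) next
          hit_bead <- FALSE
          for (ob in seq_along(beads)) {
            if (ob == b) next
            d <- sqrt((smp[, 1] - beads[[ob]]$center[1])^2 +
                        (smp[, 2] - beads[[ob]]$center[2])^2)
            if (any(d < beads[[ob]]$radius_um + w / 2 + 10)) { hit_bead <- TRUE; break }
          }
          if (hit_bead) next
          hit_tube <- FALSE
          for (ts in tube_samples) {
            dmin <- min_pair_dist(smp, ts$pts)
            if (dmin < (w + ts$w) / 2 + 6) { hit_tube <- TRUE; break }
          }
          if (hit_tube) next
          sprouts[[length(sprouts) + 1L]] <- cand
          tube_samples[[length(tube_samples) + 1L]] <- list(pts = smp, w = w)
          angles <- c(angles, a)
          break
        }
      }
    }
    # nuclei along tubes and on beads
    nuc <- list()
    tmp_spec <- list(beads = beads, sprouts = sprouts, pixel_size = pixel_size)
    for (i in seq_along(sprouts)) {
      pl <- sprout_polylines(tmp_spec, i)[[1]]
      pts <- pl$points
      cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
      L <- pl$length_um
      w <- pl$width_um
      ss <- seq(18, max(18, L - 12), by = nuclei_spacing_um)
      ss <- ss + runif(length(ss), -4, 4)
      ss <- ss[ss > 5 & ss < L - 5]
      for (s0 in ss) {
        j <- max(which(cum <= s0))
        j <- min(j, nrow(pts) - 1L)
        tfrac <- (s0 - cum[j]) / (cum[j + 1] - cum[j])
        p0 <- pts[j, ] + tfrac * (pts[j + 1, ] - pts[j, ])
        d0 <- pts[j + 1, ] - pts[j, ]; d0 <- d0 / sqrt(sum(d0^2))
        off_max <- max(0, w / 2 - nucleus_radius_um - 1)
        off <- if (off_max > 0) runif(1, -off_max, off_max) else 0
        p0 <- p0 + off * c(-d0[2], d0[1])
        nuc[[length(nuc) + 1L]] <- c(p0, FALSE)
      }
    }
    for (b in seq_along(beads)) {
      if (!bead_nuclei) next
      aa <- seq(0, 360, length.out = bead_nuclei + 1)[-1] +
        runif(bead_nuclei, -10, 10)
      for (a in aa) {
        p0 <- beads[[b]]$center + 0.6 * beads[[b]]$radius_um *
          c(-sin(a * pi / 180), cos(a * pi / 180))
        nuc[[length(nuc) + 1L]] <- c(p0, TRUE)
      }
    }
    nuclei <- if (length(nuc)) {
      m <- do.call(rbind, nuc)
      df <- data.frame(row_um = m[, 1], col_um = m[, 2],
                       radius_um = nucleus_radius_um,
                       class = "EC", on_bead = m[, 3] > 0,
                       stringsAsFactors = FALSE)
      # drop nuclei too close to an earlier one (keeps blobs separable)
      keep <- rep(TRUE, nrow(df))
      for (i in seq_len(nrow(df))[-1]) {
        d <- sqrt((df$row_um[seq_len(i - 1)][keep[seq_len(i - 1)]] - df$row_um[i])^2 +
                    (df$col_um[seq_len(i - 1)][keep[seq_len(i - 1)]] - df$col_um[i])^2)
        if (length(d) && min(d) < 2.4 * nucleus_radius_um) keep[i] <- FALSE
      }
      df <- df[keep, , drop = FALSE]
      if (!is.na(ec_pericyte_ratio) && nrow(df) >= ec_pericyte_ratio + 1) {
        n_pc <- floor(nrow(df) / (ec_pericyte_ratio + 1))
        n_keep <- n_pc * (ec_pericyte_ratio + 1)
        df <- df[seq_len(n_keep), , drop = FALSE]
        df$class[sample(n_keep, n_pc)] <- "pericyte"
      }
      rownames(df) <- NULL
      df
    } else NULL
    scene_spec(seed = seed, field_um = field_um, pixel_size = pixel_size,
               beads = beads, sprouts = sprouts, nuclei = nuclei,
               coverage_fraction = coverage_fraction, roles = roles,
               optics = list(psf_sigma_um = psf_sigma_um,
                             background = background, noise = noise,
                             snr = snr, marker_contrast = marker_contrast))
  })
}

min_pair_dist <- function(a, b) {
  # smallest distance between two point sets (n and m small)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}

#' Rotate a scene around the field center
#'
#' Rotates bead centers, sprout angles, and nucleus positions; used to test
#' rotation invariance of the morphometry.
#'
#' @param spec a [scene_spec()].
#' @param deg rotation angle, counterclockwise.
#' @return the rotated [scene_spec()].
#' @export
rotate_scene <- function(spec, deg) {
  a <- deg * pi / 180
  ctr <- spec$field_um / 2
  rot <- function(p) {
    d <- p - ctr
    # (row, col) with rows growing downward: ccw rotation
    ctr + c(cos(a) * d[1] - sin(a) * d[2], sin(a) * d[1] + cos(a) * d[2])
  }
  spec$beads <- lapply(spec$beads, function(b) {
    b$center <- rot(b$center); b
  })
  spec$sprouts <- lapply(spec$sprouts, function(s) {
    s$angle_deg <- s$angle_deg + deg; s
  })
  if (nrow(spec$nuclei)) {
    m <- t(apply(spec$nuclei[, c("row_um", "col_um")], 1, rot))
    spec$nuclei$row_um <- m[, 1]
    spec$nuclei$col_um <- m[, 2]
  }
  spec
}

#' Write a rendered scene as a multi-channel TIFF with a ground-truth JSON
#'
#' Channels are written as interleaved 16-bit grayscale directories in the
#' canonical role order; the matching [channel_map()] is returned. The
#' ground truth (without pixel masks) goes to `<path>.truth.json`.
#'
#' @param scene output of [render_scene()].
#' @param path TIFF path.
#' @return the [channel_map()] of the written file, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  img <- scene$image
  if (!inherits(img, "sprout_image")) stop_input("expected a single-plane scene")
  roles <- names(img$planes)
  frames <- lapply(img$planes, function(p) {
    pmin(pmax(round(p), 0), 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  truth <- scene$truth
  truth$masks <- NULL
  truth$bead_centers_px <- unname(apply(truth$bead_centers_px, 1, c,
                                        simplify = FALSE))
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(do.call(channel_map, as.list(setNames(seq_along(roles), roles))))
}

#' Emit the standard synthetic fixture set
#'
#' Writes a small set of rendered scenes (TIFF + ground-truth JSON) and a
#' matching run configuration to a directory.
#'
#' @param dir output directory (created if needed).
#' @param seeds integer seeds, one scene each.
#' @param ... forwarded to [random_scene()].
#' @return paths of the written TIFFs, invisibly.
#' @export
make_fixtures <- function(dir, seeds = 1:3, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  cmap <- NULL
  for (s in seeds) {
    sc <- render_scene(random_scene(seed = s, coverage_fraction = 0.4, ...))
    p <- file.path(dir, sprintf("scene-%03d.tif", s))
    cmap <- write_scene_tiff(sc, p)
    paths <- c(paths, p)
  }
  cfg <- list(pixel_size = 1,
              channels = as.list(unclass(cmap)))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(paths)
}
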