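# Internal image helpers. Planes are plain numeric matrices [row, col];
# EBImage results are unwrapped back to matrices immediately.

`%||%` <- function(a, b) if (is.null(a)) b else a

as_matrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes the between-class variance of the two classes induced by a
#' threshold. For short vectors (object-level statistics) every midpoint
#' between consecutive sorted values is tried exhaustively; for full image
#' planes a 256-bin histogram spanning the data range is used, which makes
#' the threshold equivariant under affine intensity scaling.
#'
#' @param x numeric vector (or matrix) of intensities.
#' @param levels number of histogram bins for the binned variant.
#' @return threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) return(max(x, -Inf))
  if (length(x) <= 2L * levels) {
    s <- sort(x)
    cand <- (s[-1] + s[-length(s)]) / 2
    cand <- unique(cand)
    bc <- vapply(cand, function(t) {
      lo <- x[x <= t]; hi <- x[x > t]
      if (!length(lo) || !length(hi)) return(-Inf)
      (length(lo) * length(hi)) / length(x)^2 * (mean(hi) - mean(lo))^2
    }, numeric(1))
    return(cand[which.max(bc)])
  }
  rg <- range(x)
  h <- tabulate(pmin(levels, 1L + floor((x - rg[1]) / diff(rg) * levels)), levels)
  mids <- rg[1] + (seq_len(levels) - 0.5) / levels * diff(rg)
  w <- cumsum(h); m <- cumsum(h * mids)
  wt <- w[levels]; mt <- m[levels]
  w1 <- w[-levels]; m1 <- m[-levels]
  w2 <- wt - w1
  ok <- w1 > 0 & w2 > 0
  bc <- rep(-Inf, levels - 1L)
  bc[ok] <- (m1[ok] / w1[ok] - (mt - m1[ok]) / w2[ok])^2 * w1[ok] * w2[ok]
  k <- which.max(bc)
  rg[1] + k / levels * diff(rg)
}

#' Triangle threshold of a numeric vector
#'
#' Geometric threshold for strongly skewed histograms (sparse bright
#' foreground over a dominant background mode): the threshold is placed at
#' the histogram bin furthest from the straight line joining the histogram
#' peak to the far end of the intensity range. Robust where Otsu's
#' between-class criterion collapses because the foreground class is a tiny
#' fraction of the pixels.
#'
#' @param x numeric vector (or matrix) of intensities.
#' @param levels number of histogram bins.
#' @return threshold value; pixels strictly above it are foreground.
#' @export
triangle_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) return(max(x, -Inf))
  rg <- range(x)
  h <- tabulate(pmin(levels, 1L + floor((x - rg[1]) / diff(rg) * levels)), levels)
  pk <- which.max(h)
  # far end on the side with the longer tail
  last <- max(which(h > 0)); first <- min(which(h > 0))
  end <- if ((last - pk) >= (pk - first)) last else first
  if (end == pk) return(rg[1] + pk / levels * diff(rg))
  ks <- if (end > pk) pk:end else end:pk
  # distance of (k, h[k]) from the line peak -> end
  x1 <- pk; y1 <- h[pk]; x2 <- end; y2 <- h[end]
  d <- abs((y2 - y1) * ks - (x2 - x1) * h[ks] + x2 * y1 - y2 * x1)
  k <- ks[which.max(d)]
  rg[1] + k / levels * diff(rg)
}

# Resolve a threshold for a plane given method ("otsu" | "triangle" |
# "manual") and an optional restriction region (logical matrix) the
# histogram is drawn from.
auto_threshold <- function(plane, method, manual = NA_real_, region = NULL) {
  method <- match.arg(method, c("otsu", "triangle", "manual"))
  if (method == "manual") {
    if (!is.finite(manual)) stop_config("manual threshold requested but not set")
    return(manual)
  }
  vals <- if (is.null(region)) plane else plane[region]
  if (!length(vals) || diff(range(vals)) == 0) return(Inf)
  if (method == "triangle") triangle_threshold(vals) else otsu_threshold(vals)
}

gblur_px <- function(plane, sigma_px) {
  if (!is.finite(sigma_px) || sigma_px <= 0) return(plane)
  as_matrix(EBImage::gblur(plane, sigma = sigma_px))
}

# Euclidean distance of every pixel to the nearest TRUE pixel of `mask`
# (0 on the mask itself).
distance_to <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  as_matrix(EBImage::distmap(1 - mask))
}

# Morphological opening by a disc of radius r_px, computed with two distance
# transforms (fast for large radii): erosion = {d_in >= r}, then dilation.
disc_open <- function(mask, r_px) {
  mode(mask) <- "integer"
  if (!any(mask == 1L)) return(mask > 0)
  din <- as_matrix(EBImage::distmap(mask))
  seeds <- din >= r_px
  if (!any(seeds)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  (distance_to(seeds) <= r_px) & (mask > 0)
}

dilate_disc <- function(mask, r_px) {
  if (!any(mask)) return(mask)
  mask | (distance_to(mask) <= r_px)
}

fill_holes <- function(mask) {
  as_matrix(EBImage::fillHull(mask * 1)) > 0
}

# 8-connected labelling (compiled); returns integer matrix, labels 1..n in
# raster-scan order.
label8 <- function(mask) {
  m <- mask * 1L
  storage.mode(m) <- "integer"
  label_components8(m)
}

thin_mask <- function(mask) {
  m <- mask * 1L
  storage.mode(m) <- "integer"
  thin_zhangsuen(m) > 0
}

nbcount8 <- function(mask) {
  m <- mask * 1L
  storage.mode(m) <- "integer"
  neighbor_count8(m)
}

# centroids and pixel areas of a label matrix; rows ordered by label 1..n
label_stats <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      row = numeric(), col = numeric()))
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  rr <- (idx - 1) %% nrow(lab) + 1
  cc <- (idx - 1) %/% nrow(lab) + 1
  data.frame(
    label = seq_len(n),
    area_px = tabulate(l, n),
    row = as.numeric(tapply(rr, factor(l, levels = seq_len(n)), mean)),
    col = as.numeric(tapply(cc, factor(l, levels = seq_len(n)), mean))
  )
}

# keep only the listed labels, renumbering contiguously in raster order
relabel_keep <- function(lab, keep) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (!length(keep)) return(out)
  keep <- keep[order(match(keep, lab))]      # first-occurrence raster order
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  nz <- lab > 0L
  out[nz] <- map[lab[nz]]
  out
}

# pixel index lists per label, ordered 1..max(lab)
label_pixels <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(list())
  idx <- which(lab > 0L)
  split(idx, factor(lab[idx], levels = seq_len(n)))
}

touches_border <- function(lab, label) {
  any(lab[1, ] == label) || any(lab[nrow(lab), ] == label) ||
    any(lab[, 1] == label) || any(lab[, ncol(lab)] == label)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
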