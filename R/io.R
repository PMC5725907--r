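#' Multi-channel calibrated image
#'
#' Container for one field of view: one 2D intensity plane per stain role,
#' plus the pixel size tying pixel geometry to micrometers.
#'
#' @param planes named list of numeric matrices (identical dimensions,
#'   non-negative intensities), names drawn from
#'   `c("actin", "nuclei", "ec_marker", "pericyte_marker")`. The actin role
#'   must be present: it drives all morphometry.
#' @param pixel_size micrometers per pixel (isotropic, > 0).
#' @param source_id opaque identifier (file name, well id).
#' @return object of class `sprout_image`.
#' @export
multichannel_image <- function(planes, pixel_size = 1, source_id = "") {
  if (!is.list(planes) || is.null(names(planes)))
    stop_input("planes must be a named list of matrices")
  bad <- setdiff(names(planes), SPROUTR_ROLES)
  if (length(bad)) stop_config("unknown stain role(s): ", paste(bad, collapse = ", "))
  if (!"actin" %in% names(planes))
    stop_config("an 'actin' plane is required for morphometry")
  dims <- lapply(planes, dim)
  if (any(vapply(dims, is.null, TRUE)))
    stop_input("all planes must be 2D matrices")
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop_input("all planes must share identical dimensions")
  if (any(vapply(planes, function(p) any(p < 0), TRUE)))
    stop_input("intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_config("pixel_size must be a positive scalar")
  structure(list(planes = planes, pixel_size = pixel_size,
                 source_id = as.character(source_id)),
            class = "sprout_image")
}

#' @export
print.sprout_image <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("sprout_image '%s': %d x %d px (%.3g um/px), roles: %s\n",
              x$source_id, d[1], d[2], x$pixel_size,
              paste(names(x$planes), collapse = ", ")))
  invisible(x)
}

new_stack <- function(planes, pixel_size, source_id) {
  structure(list(planes = planes, pixel_size = pixel_size,
                 source_id = as.character(source_id)),
            class = "sprout_stack")
}

#' @export
print.sprout_stack <- function(x, ...) {
  d <- dim(x$planes[[1]][[1]])
  cat(sprintf("sprout_stack '%s': %d x %d px, %d planes, roles: %s\n",
              x$source_id, d[1], d[2], length(x$planes[[1]]),
              paste(names(x$planes), collapse = ", ")))
  invisible(x)
}

#' Read a (multi-channel, optionally multi-plane) TIFF image
#'
#' Intensities are read as stored, without rescaling. Multi-channel data may
#' be stored as a samples-per-pixel dimension within each TIFF directory, or
#' as interleaved grayscale directories (channel fastest, then z); both are
#' handled. With more than one z-plane the result is a stack, which
#' [max_intensity_projection()] reduces to a single image.
#'
#' @param path TIFF file.
#' @param channel_map [channel_map()] binding stain roles to channel indices.
#' @param pixel_size micrometers per pixel. A default of 1 is used, with a
#'   warning, when not supplied.
#' @param n_channels number of channels in the file when stored as
#'   interleaved grayscale directories; defaults to the largest mapped index.
#' @return a `sprout_image`, or a `sprout_stack` when the file holds more
#'   than one z-plane.
#' @export
read_image <- function(path, channel_map, pixel_size = NULL, n_channels = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                     error = function(e) stop_input("unreadable TIFF '", path, "': ",
                                                    conditionMessage(e)))
  if (!is.list(frames)) frames <- list(frames)
  if (is.null(pixel_size)) {
    warning("pixel_size not supplied; assuming 1 um/px -- all lengths and ",
            "areas will be in pixel units", call. = FALSE)
    pixel_size <- 1
  }
  cm <- channel_map
  if (length(dim(frames[[1]])) == 3L) {
    # channels stored as samples per pixel
    nch <- dim(frames[[1]])[3]
    if (any(cm > nch))
      stop_config("channel index out of range: file has ", nch, " channels")
    per_role <- lapply(cm, function(ch) lapply(frames, function(f) f[, , ch]))
  } else {
    nch <- n_channels %||% max(cm)
    if (length(frames) %% nch != 0L)
      stop_config("frame count ", length(frames),
                  " is not a multiple of the channel count ", nch)
    if (any(cm > nch))
      stop_config("channel index out of range: file has ", nch, " channels")
    nz <- length(frames) %/% nch
    per_role <- lapply(cm, function(ch) frames[(seq_len(nz) - 1L) * nch + ch])
  }
  names(per_role) <- names(cm)
  src <- basename(path)
  if (length(per_role[[1]]) == 1L) {
    multichannel_image(lapply(per_role, `[[`, 1L), pixel_size, src)
  } else {
    new_stack(per_role, pixel_size, src)
  }
}

#' Maximum intensity projection
#'
#' Collapses a z-stack to a single plane per stain role: each output pixel
#' is the maximum over the stack at that position. Projecting an
#' already-projected image returns it unchanged, and the result does not
#' depend on plane order.
#'
#' @param x a `sprout_stack` (or a `sprout_image`, returned as-is).
#' @return a `sprout_image`.
#' @export
max_intensity_projection <- function(x) {
  if (inherits(x, "sprout_image")) return(x)
  if (!inherits(x, "sprout_stack")) stop_input("expected a sprout_stack or sprout_image")
  if (!length(x$planes) || !length(x$planes[[1]])) stop_input("empty stack")
  planes <- lapply(x$planes, function(pl) Reduce(pmax, pl))
  multichannel_image(planes, x$pixel_size, x$source_id)
}

#' @rdname max_intensity_projection
#' @export
mip <- max_intensity_projection

# Result-table schema: stable column order and units. Missing measurements
# (disabled stage or absent channel) are NA, never 0.
MEASUREMENT_COLUMNS <- c(
  source_id = "", n_beads = "count", n_sprouts = "count",
  total_sprout_length = "um", avg_sprout_length = "um",
  avg_sprout_width = "um", sprout_area = "um2", unattached_sprout_area = "um2",
  n_nuclei = "count", n_ec = "count", n_pericyte = "count",
  ec_pericyte_ratio = "ratio", cell_density = "nuclei per 1e4 um2",
  pericyte_area = "um2", pericyte_coverage = "fraction",
  avg_branch_points = "per sprout"
)

#' Construct one result-table row
#'
#' @param source_id image/well identity; remaining arguments are the
#'   measurements of the schema (see [write_results()]); omitted ones are NA.
#' @return one-row data.frame with the canonical column order.
#' @export
measurement_row <- function(source_id, ...) {
  vals <- list(...)
  bad <- setdiff(names(vals), names(MEASUREMENT_COLUMNS))
  if (length(bad)) stop_config("unknown measurement(s): ", paste(bad, collapse = ", "))
  row <- as.list(rep(NA_real_, length(MEASUREMENT_COLUMNS)))
  names(row) <- names(MEASUREMENT_COLUMNS)
  row$source_id <- as.character(source_id)
  for (nm in names(vals)) row[[nm]] <- vals[[nm]]
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Write / read the result table
#'
#' One row per image or well, stable column order, units documented in
#' commented header lines. Numeric values survive the round trip at full
#' double precision.
#'
#' @param rows data.frame of measurement rows (see [measurement_row()]).
#' @param path output CSV file.
#' @export
write_results <- function(rows, path) {
  if (nrow(rows)) {
    missing_cols <- setdiff(names(MEASUREMENT_COLUMNS), names(rows))
    for (nm in missing_cols) rows[[nm]] <- NA_real_
    rows <- rows[, names(MEASUREMENT_COLUMNS), drop = FALSE]
  } else {
    rows <- measurement_row("")[0, , drop = FALSE]
  }
  units <- MEASUREMENT_COLUMNS[nzchar(MEASUREMENT_COLUMNS)]
  hdr <- c("# bead sprouting assay result table",
           paste0("# units: ", paste(names(units), units, sep = " [",
                                     collapse = "], "), "]"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_input("cannot write: ", path))
  on.exit(close(con))
  writeLines(hdr, con)
  out <- rows
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                          formatC(out[[nm]], digits = 17, format = "g"))
  }
  write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (nm in setdiff(names(MEASUREMENT_COLUMNS), "source_id"))
    if (nm %in% names(df)) df[[nm]] <- as.numeric(df[[nm]])
  df
}
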