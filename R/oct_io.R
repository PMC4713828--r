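#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

BOUNDARY_NAMES <- c("ILM", "RPE_inner", "RPE_outer", "CSJ")

#' Construct a B-scan object
#'
#' A B-scan is a single grayscale OCT cross-section: a numeric matrix of
#' intensities (rows = axial depth, top row = vitreous side; columns =
#' lateral position) together with its physical pixel scales in micrometres
#' per pixel. OCT pixels are anisotropic, so the lateral and axial scales are
#' kept separately and both enter every area conversion.
#'
#' @param pixels Numeric matrix of intensities in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Integer, 8 or 16.
#' @param lateral_scale,axial_scale Micrometres per pixel, both `> 0`.
#' @param scan_id Identifier carried through to metric rows.
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, bit_depth = 8L, lateral_scale, axial_scale,
                  scan_id = "scan") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix (rows = depth, cols = lateral).")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    abort("`bit_depth` must be 8 or 16.")
  }
  check_scales(lateral_scale, axial_scale)
  maxval <- 2^bit_depth - 1
  rng <- range(pixels, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > maxval) {
    abort(sprintf("pixel values must lie in [0, %d] for a %d-bit image.",
                  maxval, bit_depth))
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         lateral_scale = lateral_scale, axial_scale = axial_scale,
         scan_id = scan_id),
    class = "bscan"
  )
}

check_scales <- function(lateral_scale, axial_scale) {
  if (!is.numeric(lateral_scale) || length(lateral_scale) != 1 ||
      !is.finite(lateral_scale) || lateral_scale <= 0) {
    abort("`lateral_scale` must be a single positive number (um/px).")
  }
  if (!is.numeric(axial_scale) || length(axial_scale) != 1 ||
      !is.finite(axial_scale) || axial_scale <= 0) {
    abort("`axial_scale` must be a single positive number (um/px).")
  }
  invisible(TRUE)
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan '%s'> %d x %d px, %d-bit, %.3g x %.3g um/px (lateral x axial)\n",
              x$scan_id, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$lateral_scale, x$axial_scale))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

#' Read a B-scan image from PNG or TIFF
#'
#' Reads a single-channel (or RGB with identical channels) 8- or 16-bit
#' image and attaches the physical pixel scales, which are required
#' metadata: OCT exports do not embed them reliably, so they must be taken
#' from the device ruler and supplied by the caller.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param lateral_scale,axial_scale Micrometres per pixel (`> 0`).
#' @param scan_id Identifier; defaults to the file name without extension.
#' @return A [bscan] with integer intensities on the native bit depth.
#' @export
read_bscan <- function(path, lateral_scale, axial_scale, scan_id = NULL) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  check_scales(lateral_scale, axial_scale)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    bit_depth <- as.integer(attr(img, "info")$bit.depth %||% 8L)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bit_depth <- as.integer(attr(img, "bits.per.sample") %||%
                              attr(img, "info")$bits.per.sample %||% 8L)
  } else {
    abort(sprintf("unsupported image format '.%s' (use PNG or TIFF).", ext))
  }
  if (!bit_depth %in% c(8L, 16L)) {
    abort(sprintf("unsupported bit depth %d (8 or 16 expected).", bit_depth))
  }
  if (length(dim(img)) == 3) {
    # RGB(A): collapse identical channels; reject genuinely coloured input
    ch <- dim(img)[3]
    base <- img[, , 1]
    for (k in seq_len(min(ch, 3))[-1]) {
      if (max(abs(img[, , k] - base)) > 1e-6) {
        abort("multi-channel image with differing channels; expected grayscale.")
      }
    }
    img <- base
  }
  pixels <- round(img * (2^bit_depth - 1))
  pixels <- matrix(as.vector(pixels), nrow(pixels), ncol(pixels))  # drop codec attrs
  bscan(pixels, bit_depth, lateral_scale, axial_scale,
        scan_id = scan_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a B-scan to PNG or TIFF
#'
#' @param image A [bscan].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(image, path) {
  stopifnot(inherits(image, "bscan"))
  scaled <- image$pixels / (2^image$bit_depth - 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = image$bit_depth)
  } else {
    abort(sprintf("unsupported image format '.%s' (use PNG or TIFF).", ext))
  }
  invisible(path)
}

#' Construct a boundary set
#'
#' Per-column row positions of the four segmented layer boundaries: the
#' internal limiting membrane (ILM), the inner and outer borders of the RPE
#' complex, and the choroid-sclera junction (CSJ). Rows are 1-based (row 1 =
#' top of the image, vitreous side) and may be fractional; `NA` marks columns
#' where a boundary was not segmented. Wherever all four boundaries are
#' defined they must be ordered ILM <= RPE_inner <= RPE_outer <= CSJ.
#'
#' @param boundaries Named list with numeric vectors `ILM`, `RPE_inner`,
#'   `RPE_outer`, `CSJ`, all the same length (the image width).
#' @param scan_id Identifier.
#' @param fovea_x Optional 1-based column of the foveal centre.
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(boundaries, scan_id = "scan", fovea_x = NULL) {
  missing_names <- setdiff(BOUNDARY_NAMES, names(boundaries))
  if (length(missing_names) > 0) {
    abort(sprintf("missing boundary name(s): %s",
                  paste(missing_names, collapse = ", ")))
  }
  boundaries <- boundaries[BOUNDARY_NAMES]
  lens <- lengths(boundaries)
  if (length(unique(lens)) != 1) {
    abort("all boundary vectors must have the same length (the image width).")
  }
  bad <- first_order_violation(boundaries)
  if (!is.na(bad)) {
    abort(sprintf(
      "boundary ordering violated at column %d: expected ILM <= RPE_inner <= RPE_outer <= CSJ.",
      bad - 1L  # reported in the 0-based x coordinate of the interchange JSON
    ), class = "choroidcvi_boundary_order")
  }
  structure(
    list(boundaries = lapply(boundaries, as.numeric),
         scan_id = scan_id,
         fovea_x = if (is.null(fovea_x)) NA_integer_ else as.integer(fovea_x),
         width = lens[[1]]),
    class = "boundary_set"
  )
}

# first column (1-based) where the vertical ordering is broken, NA if none
first_order_violation <- function(b) {
  m <- rbind(b$ILM, b$RPE_inner, b$RPE_outer, b$CSJ)
  defined <- colSums(is.na(m)) == 0
  if (!any(defined)) return(NA_integer_)
  d <- m[, defined, drop = FALSE]
  ok <- d[1, ] <= d[2, ] & d[2, ] <= d[3, ] & d[3, ] <= d[4, ]
  if (all(ok)) return(NA_integer_)
  which(defined)[which(!ok)[1]]
}

#' @export
print.boundary_set <- function(x, ...) {
  ndef <- vapply(x$boundaries, function(v) sum(!is.na(v)), integer(1))
  cat(sprintf("<boundary_set '%s'> width %d px, fovea_x %s\n", x$scan_id,
              x$width, ifelse(is.na(x$fovea_x), "unset", x$fovea_x)))
  cat("  defined columns:",
      paste(sprintf("%s %d", names(ndef), ndef), collapse = ", "), "\n")
  invisible(x)
}

#' Read layer boundaries from the interchange JSON
#'
#' The JSON format stores each boundary as a sparse polyline of
#' `[x, row]` vertices in 0-based pixel coordinates (row 0 = top).
#' On load the polylines are densified to one row value per image column by
#' linear interpolation between vertices; columns outside a polyline's
#' x-extent are undefined. All coordinates are converted to the package's
#' 1-based convention.
#'
#' @param path Path to a boundary `.json` file.
#' @param width Image width in pixels. If `NULL`, the maximum vertex x + 1
#'   across boundaries is used.
#' @return A [boundary_set]; pixel scales and `fovea_x` from the file are
#'   attached as attributes `lateral_scale`/`axial_scale` when present.
#' @export
read_boundaries <- function(path, width = NULL) {
  if (!file.exists(path)) abort(sprintf("boundary file not found: %s", path))
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(spec$boundaries)) abort("boundary JSON lacks a 'boundaries' object.")
  missing_names <- setdiff(BOUNDARY_NAMES, names(spec$boundaries))
  if (length(missing_names) > 0) {
    abort(sprintf("boundary JSON missing required boundary name(s): %s",
                  paste(missing_names, collapse = ", ")))
  }
  polys <- lapply(spec$boundaries[BOUNDARY_NAMES], function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) abort("each polyline must be a list of [x, row] pairs.")
    p[order(p[, 1]), , drop = FALSE]
  })
  if (is.null(width)) {
    width <- max(vapply(polys, function(p) max(p[, 1]), numeric(1))) + 1
  }
  dense <- lapply(polys, densify_polyline, width = width)
  fovea_x <- spec$fovea_x
  if (!is.null(fovea_x) && !is.na(fovea_x)) fovea_x <- as.integer(fovea_x) + 1L
  bs <- boundary_set(dense, scan_id = spec$scan_id %||% "scan",
                     fovea_x = if (is.null(fovea_x) || is.na(fovea_x)) NULL else fovea_x)
  attr(bs, "lateral_scale") <- spec$lateral_scale_um_per_px
  attr(bs, "axial_scale") <- spec$axial_scale_um_per_px
  bs
}

# 0-based polyline vertices -> 1-based per-column rows of length `width`
densify_polyline <- function(p, width) {
  out <- rep(NA_real_, width)
  xs <- p[, 1] + 1   # to 1-based columns
  rows <- p[, 2] + 1 # to 1-based rows
  lo <- max(1L, ceiling(min(xs)))
  hi <- min(width, floor(max(xs)))
  if (lo > hi) return(out)
  if (length(xs) == 1) {
    out[lo] <- rows
    return(out)
  }
  out[lo:hi] <- stats::approx(xs, rows, xout = lo:hi, ties = "ordered")$y
  out
}

#' Write layer boundaries to the interchange JSON
#'
#' Inverse of [read_boundaries()]: each per-column boundary is stored as a
#' dense polyline with one vertex per defined column, in 0-based
#' coordinates.
#'
#' @param boundaries A [boundary_set].
#' @param path Output path.
#' @param lateral_scale,axial_scale Optional scales to embed (um/px).
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path,
                             lateral_scale = NULL, axial_scale = NULL) {
  stopifnot(inherits(boundaries, "boundary_set"))
  polys <- lapply(boundaries$boundaries, function(v) {
    idx <- which(!is.na(v))
    cbind(idx - 1L, v[idx] - 1)
  })
  obj <- list(
    scan_id = boundaries$scan_id,
    lateral_scale_um_per_px = lateral_scale,
    axial_scale_um_per_px = axial_scale,
    fovea_x = if (is.na(boundaries$fovea_x)) NULL else boundaries$fovea_x - 1L,
    boundaries = polys
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

METRICS_HEADER <- c("eye_id", "visit", "TCA_mm2", "LA_mm2", "SA_mm2",
                    "CVI", "LA_SA", "SFCT_um")

#' Write choroid metric rows to CSV
#'
#' Fixed-header CSV (`eye_id,visit,TCA_mm2,LA_mm2,SA_mm2,CVI,LA_SA,SFCT_um`)
#' with full-precision floats so that a read round-trips the values.
#'
#' @param rows A data frame of choroid metrics, e.g. from
#'   [compute_choroid_metrics()] (extra columns are dropped).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) abort("refusing to write an empty metrics table.")
  missing_cols <- setdiff(METRICS_HEADER, names(rows))
  if (length(missing_cols) > 0) {
    abort(sprintf("metrics table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- rows[, METRICS_HEADER]
  for (cl in METRICS_HEADER[-(1:2)]) out[[cl]] <- format_sig(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

format_sig <- function(x, digits = 12) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "g"))
}

#' Read a choroid metrics CSV
#'
#' @param path CSV written by [write_metrics()].
#' @return A tibble with the fixed metric columns as doubles.
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) abort(sprintf("metrics file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(eye_id = "character", visit = "character"))
  missing_cols <- setdiff(METRICS_HEADER, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("metrics CSV lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  as_tibble(df)
}
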