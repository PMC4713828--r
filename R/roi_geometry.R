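#' Locate the foveal centre column
#'
#' If the boundary set carries an explicit `fovea_x` (e.g. from the
#' interchange JSON) it is returned unchanged. Otherwise the fovea is taken
#' as the column with the thinnest retina (smallest ILM to inner-RPE
#' distance), the anatomical signature of the foveal pit; ties break to the
#' lowest column index.
#'
#' @param boundaries A [boundary_set].
#' @return A 1-based column index.
#' @export
locate_fovea <- function(boundaries) {
  stopifnot(inherits(boundaries, "boundary_set"))
  if (!is.na(boundaries$fovea_x)) return(boundaries$fovea_x)
  thick <- boundaries$boundaries$RPE_inner - boundaries$boundaries$ILM
  defined <- !is.na(thick)
  if (mean(defined) < 0.5) {
    abort(paste("ILM and RPE_inner are defined over fewer than half of the",
                "columns; supply fovea_x explicitly."))
  }
  which.min(thick)  # NA columns never win; ties -> lowest index
}

#' Build the subfoveal choroidal region of interest
#'
#' Constructs the pixel mask of the choroidal block beneath a line of
#' `width_um` micrometres centred at the fovea: columns
#' `[fovea_x - floor(w/2), fovea_x - floor(w/2) + w)` where
#' `w = round(width_um / lateral_scale)`, and within each column the rows
#' strictly below the outer RPE border down to and including the
#' choroid-sclera junction (`RPE_outer(c) < r <= CSJ(c)`). A boundary pixel
#' is owned by the layer beneath its inner boundary. A window that runs off
#' the image is clipped with a warning when more than 10% of the requested
#' width is lost.
#'
#' @param image A [bscan].
#' @param boundaries A [boundary_set] for the same scan.
#' @param fovea_x 1-based foveal column; default [locate_fovea()].
#' @param width_um Width of the subfoveal line in micrometres (default 1500,
#'   the standard subfoveal window).
#' @return An object of class `subfoveal_roi` with fields `fovea_x`,
#'   `width_um`, `col_start`/`col_stop` (half-open, 1-based), `mask`
#'   (logical matrix, `TRUE` = choroidal ROI pixel) and `n_pixels`.
#' @export
build_subfoveal_roi <- function(image, boundaries,
                                fovea_x = locate_fovea(boundaries),
                                width_um = 1500) {
  stopifnot(inherits(image, "bscan"), inherits(boundaries, "boundary_set"))
  if (width_um < 0) abort("`width_um` must be non-negative.")
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (boundaries$width != nc) {
    abort(sprintf("boundary width (%d) does not match image width (%d).",
                  boundaries$width, nc))
  }
  w <- as.integer(round(width_um / image$lateral_scale))
  fovea_x <- as.integer(fovea_x)
  col_start <- fovea_x - w %/% 2L
  col_stop <- col_start + w
  clipped_start <- max(col_start, 1L)
  clipped_stop <- min(col_stop, nc + 1L)
  lost <- w - max(0L, clipped_stop - clipped_start)
  if (w > 0 && lost / w > 0.10) {
    warn(sprintf("subfoveal window clipped: %d of %d requested columns fall outside the image.",
                 lost, w))
  }
  mask <- matrix(FALSE, nr, nc)
  cols <- if (clipped_start < clipped_stop) clipped_start:(clipped_stop - 1L) else integer(0)
  rpe <- boundaries$boundaries$RPE_outer
  csj <- boundaries$boundaries$CSJ
  if (length(cols) > 0 && anyNA(c(rpe[cols], csj[cols]))) {
    abort("RPE_outer or CSJ undefined inside the subfoveal window.")
  }
  for (cc in cols) {
    top <- floor(rpe[cc]) + 1L  # first integer row strictly below RPE_outer
    bottom <- floor(csj[cc])    # last integer row at-or-above CSJ
    if (top <= bottom && bottom >= 1 && top <= nr) {
      mask[max(top, 1L):min(bottom, nr), cc] <- TRUE
    }
  }
  structure(
    list(fovea_x = fovea_x, width_um = width_um,
         col_start = clipped_start, col_stop = clipped_stop,
         mask = mask, n_pixels = sum(mask)),
    class = "subfoveal_roi"
  )
}

#' @export
print.subfoveal_roi <- function(x, ...) {
  cat(sprintf("<subfoveal_roi> fovea_x %d, %g um wide, cols [%d, %d), %d px\n",
              x$fovea_x, x$width_um, x$col_start, x$col_stop, x$n_pixels))
  invisible(x)
}

#' Physical area of a region of interest
#'
#' Converts a pixel count to square millimetres using the anisotropic pixel
#' area `lateral_scale x axial_scale` (um^2 per pixel).
#'
#' @param roi A [subfoveal_roi] built against `image`.
#' @param image The [bscan] the ROI belongs to.
#' @return Area in mm^2.
#' @export
roi_area_mm2 <- function(roi, image) {
  stopifnot(inherits(roi, "subfoveal_roi"), inherits(image, "bscan"))
  pixel_area_mm2(image) * roi$n_pixels
}

pixel_area_mm2 <- function(image) {
  image$lateral_scale * image$axial_scale * 1e-6
}
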