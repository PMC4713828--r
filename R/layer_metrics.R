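LAYER_NAMES <- c("retina", "RPE", "choroid")

#' Bundle a raster of segmented B-scans
#'
#' An ordered set of (image, boundaries) pairs for one eye-visit, e.g. the
#' 7 equally spaced horizontal sections of a 20 x 15 degree macular raster,
#' plus the physical spacing between adjacent sections. All scans must share
#' width and pixel scales.
#'
#' @param scans List of `list(image = <bscan>, boundaries = <boundary_set>)`.
#' @param inter_scan_spacing Micrometres between adjacent B-scans (`> 0`).
#' @return An object of class `raster_set`.
#' @export
raster_set <- function(scans, inter_scan_spacing) {
  if (length(scans) < 2) abort("a raster needs at least 2 scans.")
  if (!is.numeric(inter_scan_spacing) || inter_scan_spacing <= 0) {
    abort("`inter_scan_spacing` must be a positive number of micrometres.")
  }
  for (s in scans) {
    if (!inherits(s$image, "bscan") || !inherits(s$boundaries, "boundary_set")) {
      abort("each scan must be list(image = <bscan>, boundaries = <boundary_set>).")
    }
  }
  ref <- scans[[1]]$image
  same <- vapply(scans, function(s) {
    ncol(s$image$pixels) == ncol(ref$pixels) &&
      s$image$lateral_scale == ref$lateral_scale &&
      s$image$axial_scale == ref$axial_scale
  }, logical(1))
  if (!all(same)) abort("all scans must share width and pixel scales.")
  structure(list(scans = scans, inter_scan_spacing = inter_scan_spacing),
            class = "raster_set")
}

#' Top and bottom rows of an anatomical layer
#'
#' Maps a layer name to its bounding segmentations: retina = (ILM,
#' RPE_inner), RPE complex = (RPE_inner, RPE_outer), choroid = (RPE_outer,
#' CSJ).
#'
#' @param boundaries A [boundary_set].
#' @param layer `"retina"`, `"RPE"` or `"choroid"`.
#' @return A list with per-column numeric vectors `top` and `bottom`.
#' @export
layer_band <- function(boundaries, layer) {
  stopifnot(inherits(boundaries, "boundary_set"))
  if (!layer %in% LAYER_NAMES) {
    abort(sprintf("unknown layer '%s' (expected one of: %s).",
                  layer, paste(LAYER_NAMES, collapse = ", ")))
  }
  b <- boundaries$boundaries
  switch(layer,
         retina = list(top = b$ILM, bottom = b$RPE_inner),
         RPE = list(top = b$RPE_inner, bottom = b$RPE_outer),
         choroid = list(top = b$RPE_outer, bottom = b$CSJ))
}

#' Per-column thickness of a layer band
#'
#' @param band A band from [layer_band()].
#' @param axial_scale Micrometres per pixel axially.
#' @return Per-column thickness in micrometres (`NA` where undefined).
#' @export
thickness_profile <- function(band, axial_scale) {
  (band$bottom - band$top) * axial_scale
}

#' Layer volume over a raster
#'
#' Per-scan cross-sectional area is the column sum of thickness times the
#' lateral scale; the areas are then integrated across scans by the
#' trapezoidal rule at the inter-scan spacing and converted to mm^3.
#'
#' @param raster A [raster_set].
#' @param layer Layer name.
#' @return Volume in mm^3.
#' @export
layer_volume <- function(raster, layer) {
  stopifnot(inherits(raster, "raster_set"))
  areas <- vapply(raster$scans, function(s) {
    prof <- thickness_profile(layer_band(s$boundaries, layer),
                              s$image$axial_scale)
    sum(prof, na.rm = TRUE) * s$image$lateral_scale  # um^2
  }, numeric(1))
  n <- length(areas)
  trap <- sum((areas[-1] + areas[-n]) / 2) * raster$inter_scan_spacing # um^3
  trap * 1e-9
}

#' Mean normalized intensity of a layer band
#'
#' Mean 8-bit pixel value inside the band (rows strictly below the top
#' boundary down to and including the bottom boundary, the same ownership
#' rule as the choroidal ROI), divided by 255 to land on a 0-1 scale.
#'
#' @param image An 8-bit [bscan].
#' @param band A band from [layer_band()].
#' @return Mean intensity in `[0, 1]`, or `NA` for an empty band.
#' @export
layer_intensity <- function(image, band) {
  stopifnot(inherits(image, "bscan"))
  if (image$bit_depth != 8L) abort("`layer_intensity` expects an 8-bit image.")
  nr <- nrow(image$pixels)
  total <- 0; count <- 0L
  for (cc in seq_len(ncol(image$pixels))) {
    top <- band$top[cc]; bottom <- band$bottom[cc]
    if (is.na(top) || is.na(bottom)) next
    r1 <- max(floor(top) + 1L, 1L)
    r2 <- min(floor(bottom), nr)
    if (r1 > r2) next
    total <- total + sum(image$pixels[r1:r2, cc])
    count <- count + (r2 - r1 + 1L)
  }
  if (count == 0L) return(NA_real_)
  (total / count) / 255
}

#' Thickness, volume and intensity for all layers of a raster
#'
#' The per-eye-visit summary table: for each of retina, RPE complex and
#' choroid, the mean thickness across all defined columns of all scans
#' (micrometres), the raster volume (mm^3) and the mean normalized
#' intensity.
#'
#' @param raster A [raster_set].
#' @param eye_id,visit Identifiers for the output rows.
#' @return A tibble with columns `eye_id, visit, layer, mean_thickness_um,
#'   volume_mm3, mean_intensity`.
#' @export
compute_layer_metrics <- function(raster, eye_id = "eye", visit = "baseline") {
  stopifnot(inherits(raster, "raster_set"))
  purrr::map_dfr(LAYER_NAMES, function(layer) {
    profs <- unlist(lapply(raster$scans, function(s) {
      thickness_profile(layer_band(s$boundaries, layer), s$image$axial_scale)
    }))
    intens <- vapply(raster$scans, function(s) {
      layer_intensity(to_8bit(s$image), layer_band(s$boundaries, layer))
    }, numeric(1))
    tibble(
      eye_id = eye_id, visit = visit, layer = layer,
      mean_thickness_um = mean(profs, na.rm = TRUE),
      volume_mm3 = layer_volume(raster, layer),
      mean_intensity = mean(intens, na.rm = TRUE)
    )
  })
}
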