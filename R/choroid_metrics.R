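#' Choroid metrics from a partitioned subfoveal ROI
#'
#' Computes the headline indices of the subfoveal choroid for one eye-visit:
#'
#' * `TCA_mm2` -- total subfoveal choroidal area (all ROI pixels);
#' * `LA_mm2` / `SA_mm2` -- luminal (dark) and stromal (light) areas;
#' * `CVI` -- the choroidal vascularity index, `LA / TCA`, a proportion in
#'   `[0, 1]` (multiply by 100 for the conventional percent);
#' * `LA_SA` -- the luminal-to-stromal ratio;
#' * `SFCT_um` -- subfoveal choroidal thickness, outer RPE to CSJ at the
#'   foveal column;
#' * `CT_um` -- mean choroidal thickness over the ROI columns.
#'
#' Areas use the anisotropic pixel area (`lateral_scale * axial_scale`), so
#' `LA + SA = TCA` exactly in pixels and hence in mm^2. `CVI` is undefined
#' (`NA`) when the ROI is empty, and `LA_SA` when there is no stromal pixel.
#'
#' @param image The [bscan] the ROI was built on.
#' @param roi A [subfoveal_roi].
#' @param partition A [cvi_partition] of the same ROI.
#' @param boundaries The [boundary_set], needed for the thickness columns;
#'   may be `NULL`, in which case `SFCT_um`/`CT_um` are `NA`.
#' @param eye_id,visit Identifiers carried into the output row.
#' @return A one-row tibble of class `choroid_metrics`.
#' @export
compute_choroid_metrics <- function(image, roi, partition, boundaries = NULL,
                                    eye_id = image$scan_id, visit = "baseline") {
  stopifnot(inherits(image, "bscan"), inherits(roi, "subfoveal_roi"),
            inherits(partition, "cvi_partition"))
  n_lum <- sum(partition$luminal)
  n_str <- sum(partition$stromal)
  if (n_lum + n_str != roi$n_pixels) {
    abort("partition does not cover the ROI exactly.")
  }
  apx <- pixel_area_mm2(image)
  la <- n_lum * apx
  sa <- n_str * apx
  tca <- roi$n_pixels * apx
  sfct <- ct <- NA_real_
  if (!is.null(boundaries)) {
    depth <- boundaries$boundaries$CSJ - boundaries$boundaries$RPE_outer
    sfct <- depth[roi$fovea_x] * image$axial_scale
    cols <- if (roi$col_start < roi$col_stop) roi$col_start:(roi$col_stop - 1L) else integer(0)
    ct <- if (length(cols) > 0) mean(depth[cols]) * image$axial_scale else NA_real_
  }
  metrics_row(eye_id, visit, tca, la, sa, sfct, ct)
}

#' Choroid metrics from areas alone
#'
#' Builds the same metric row as [compute_choroid_metrics()] directly from
#' luminal and stromal (or total) areas in mm^2 -- useful for published
#' group means, where only the areas are available. For example, with the
#' normative means `LA = 1.21`, `SA = 0.63` mm^2 the CVI is
#' `1.21 / 1.84 = 65.76%`.
#'
#' @param LA_mm2 Luminal area, mm^2.
#' @param SA_mm2 Stromal area, mm^2. Exactly one of `SA_mm2`/`TCA_mm2` must
#'   be given.
#' @param TCA_mm2 Total area, mm^2 (then `SA = TCA - LA`).
#' @param SFCT_um Optional subfoveal choroidal thickness.
#' @param eye_id,visit Identifiers.
#' @return A one-row tibble of class `choroid_metrics`.
#' @export
choroid_metrics_from_areas <- function(LA_mm2, SA_mm2 = NULL, TCA_mm2 = NULL,
                                       SFCT_um = NA_real_,
                                       eye_id = "summary", visit = "baseline") {
  if (is.null(SA_mm2) == is.null(TCA_mm2)) {
    abort("supply exactly one of `SA_mm2` or `TCA_mm2`.")
  }
  if (is.null(SA_mm2)) SA_mm2 <- TCA_mm2 - LA_mm2
  if (LA_mm2 < 0 || SA_mm2 < 0) abort("areas must be non-negative.")
  metrics_row(eye_id, visit, LA_mm2 + SA_mm2, LA_mm2, SA_mm2, SFCT_um, NA_real_)
}

metrics_row <- function(eye_id, visit, tca, la, sa, sfct, ct) {
  out <- tibble(
    eye_id = as.character(eye_id), visit = as.character(visit),
    TCA_mm2 = tca, LA_mm2 = la, SA_mm2 = sa,
    CVI = if (tca > 0) la / tca else NA_real_,
    LA_SA = if (sa > 0) la / sa else NA_real_,
    SFCT_um = sfct, CT_um = ct
  )
  class(out) <- c("choroid_metrics", class(out))
  out
}

#' Percent change between baseline and follow-up
#'
#' `100 * (baseline - followup) / baseline`: positive when the metric
#' decreased at follow-up. Vectorized over paired values; a zero baseline
#' yields `NA` with a warning.
#'
#' @param baseline,followup Numeric vectors of paired metric values.
#' @return Percent change, same length as the inputs.
#' @export
percent_change <- function(baseline, followup) {
  if (length(baseline) != length(followup)) {
    abort("`baseline` and `followup` must have equal length.")
  }
  zero <- !is.na(baseline) & baseline == 0
  if (any(zero)) {
    warn(sprintf("%d zero baseline value(s); percent change undefined there.",
                 sum(zero)))
  }
  out <- 100 * (baseline - followup) / baseline
  out[zero] <- NA_real_
  out
}

#' End-to-end CVI pipeline for one B-scan
#'
#' Convenience wrapper running the full chain: 8-bit conversion, subfoveal
#' ROI construction, binarization, and metric computation.
#'
#' @param image A [bscan] (8- or 16-bit).
#' @param boundaries A [boundary_set] for the scan.
#' @param params A [binarization_params].
#' @param fovea_x Foveal column; default [locate_fovea()].
#' @param width_um Subfoveal window width in micrometres (default 1500).
#' @param eye_id,visit Identifiers for the output row.
#' @return A one-row `choroid_metrics` tibble; the realized
#'   [cvi_partition] and [subfoveal_roi] are attached as attributes
#'   `"partition"` and `"roi"` for inspection and plotting.
#' @export
cvi_pipeline <- function(image, boundaries, params = binarization_params(),
                         fovea_x = locate_fovea(boundaries), width_um = 1500,
                         eye_id = image$scan_id, visit = "baseline") {
  img8 <- to_8bit(image)
  roi <- build_subfoveal_roi(img8, boundaries, fovea_x = fovea_x,
                             width_um = width_um)
  part <- partition_roi(img8, roi, params)
  out <- compute_choroid_metrics(img8, roi, part, boundaries,
                                 eye_id = eye_id, visit = visit)
  attr(out, "partition") <- part
  attr(out, "roi") <- roi
  out
}
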