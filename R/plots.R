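#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_boxplot
#'   scale_fill_gradient scale_fill_manual scale_y_reverse coord_fixed labs
#'   theme_minimal facet_wrap position_dodge
#' @export
ggplot2::autoplot

bscan_df <- function(pixels, value_name = "value") {
  df <- expand.grid(row = seq_len(nrow(pixels)), col = seq_len(ncol(pixels)))
  df[[value_name]] <- as.vector(pixels)
  df
}

#' Plot a B-scan with its layer boundaries
#'
#' @param image A [bscan].
#' @param boundaries Optional [boundary_set] drawn as coloured lines.
#' @return A ggplot (depth increases downwards, as on the device display).
#' @export
plot_bscan <- function(image, boundaries = NULL) {
  stopifnot(inherits(image, "bscan"))
  df <- bscan_df(image$pixels)
  p <- ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    scale_y_reverse() + coord_fixed() + theme_minimal() +
    labs(x = "lateral (px)", y = "depth (px)", title = image$scan_id)
  if (!is.null(boundaries)) {
    bdf <- purrr::map_dfr(names(boundaries$boundaries), function(nm) {
      v <- boundaries$boundaries[[nm]]
      tibble(col = seq_along(v), row = v, boundary = nm)
    })
    p <- p + geom_line(
      data = bdf[!is.na(bdf$row), ],
      aes(x = .data$col, y = .data$row, colour = .data$boundary),
      inherit.aes = FALSE)
  }
  p
}

#' Plot a luminal/stromal partition
#'
#' Autoplot method for [partition_roi()] results: luminal pixels black,
#' stromal white, non-ROI grey -- the conventional binarized-overlay
#' rendering.
#'
#' @param object A `cvi_partition`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cvi_partition <- function(object, ...) {
  lab <- matrix("outside", nrow(object$luminal), ncol(object$luminal))
  lab[object$stromal] <- "stromal"
  lab[object$luminal] <- "luminal"
  df <- bscan_df(lab, "compartment")
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$compartment)) +
    geom_raster() +
    scale_fill_manual(values = c(luminal = "black", stromal = "white",
                                 outside = "grey70")) +
    scale_y_reverse() + coord_fixed() + theme_minimal() +
    labs(x = "lateral (px)", y = "depth (px)",
         title = sprintf("binarized choroid (%s)", object$params$method))
}

#' Plot a phantom beside its ground truth
#'
#' Autoplot method for [generate_phantom()] results: the rendered phantom
#' next to its ground-truth lumen mask.
#'
#' @param object A `phantom_truth`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phantom_truth <- function(object, ...) {
  a <- bscan_df(object$image$pixels); a$panel <- "phantom"
  b <- bscan_df(object$lumen_mask * 255); b$panel <- "true lumens"
  ggplot(rbind(a, b), aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    scale_y_reverse() + coord_fixed() + facet_wrap(~panel) + theme_minimal() +
    labs(x = "lateral (px)", y = "depth (px)",
         title = sprintf("f_true %.2f, achieved %.3f",
                         object$f_true, object$achieved_fraction))
}

#' Box plot of a cohort metric by group and visit
#'
#' @param table A `paired_cohort` data frame.
#' @param metric Metric name to plot (default `"CVI"`).
#' @return A ggplot.
#' @export
plot_cohort_metric <- function(table, metric = "CVI") {
  sub <- dplyr::filter(table, .data$metric == !!metric)
  if (nrow(sub) == 0) abort(sprintf("no rows for metric '%s'.", metric))
  ggplot(sub, aes(x = .data$group, y = .data$value, fill = .data$visit)) +
    geom_boxplot(position = position_dodge(width = 0.8)) +
    theme_minimal() +
    labs(x = NULL, y = metric,
         title = sprintf("%s by group and visit", metric))
}
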