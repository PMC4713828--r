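#' Binarization parameters
#'
#' Bundles the tunables of the choroid binarization chain. Niblack local
#' thresholding (`T = mean + k * sd` over a square sliding window) is the
#' default, the method that best separates choroidal lumens from stroma on
#' EDI-OCT; Phansalkar and Otsu (windowed or global) are alternatives for
#' comparison.
#'
#' @param method One of `"niblack"`, `"phansalkar"`, `"otsu_local"`,
#'   `"otsu_global"`.
#' @param radius Window half-width in pixels (window is
#'   `(2*radius+1) x (2*radius+1)`); default 15, the customary default of
#'   ImageJ-style auto local thresholding. Ignored by `otsu_global`.
#' @param k Unitless Niblack/Phansalkar coefficient. Defaults to 0.2 for
#'   Niblack and 0.25 for Phansalkar.
#' @param brightness_offset Signed 8-bit units added to every pixel (then
#'   clamped) before thresholding; default 0. Exposed because choroidal
#'   vessels are customarily made more conspicuous by reducing brightness.
#' @return An object of class `binarization_params`.
#' @export
binarization_params <- function(method = c("niblack", "phansalkar",
                                           "otsu_local", "otsu_global"),
                                radius = 15L, k = NULL,
                                brightness_offset = 0) {
  method <- match.arg(method)
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1) {
    abort("`radius` must be a single integer >= 1.")
  }
  if (is.null(k)) k <- if (method == "phansalkar") 0.25 else 0.2
  structure(
    list(method = method, radius = as.integer(radius), k = k,
         brightness_offset = brightness_offset),
    class = "binarization_params"
  )
}

#' @export
print.binarization_params <- function(x, ...) {
  cat(sprintf("<binarization_params> method %s, radius %d px, k %g, brightness %+g\n",
              x$method, x$radius, x$k, x$brightness_offset))
  invisible(x)
}

#' Convert a B-scan to 8-bit
#'
#' 8-bit images pass through unchanged. 16-bit images are linearly rescaled
#' by their own min-max to `[0, 255]` and rounded half-up, mirroring the
#' usual 8-bit conversion applied before auto-thresholding. A constant
#' 16-bit image maps to all zeros.
#'
#' @param image A [bscan].
#' @return An 8-bit [bscan].
#' @export
to_8bit <- function(image) {
  stopifnot(inherits(image, "bscan"))
  if (image$bit_depth == 8L) return(image)
  px <- image$pixels
  mn <- min(px); mx <- max(px)
  px <- if (mx > mn) floor((px - mn) * 255 / (mx - mn) + 0.5) else px * 0
  bscan(px, 8L, image$lateral_scale, image$axial_scale, image$scan_id)
}

#' Adjust the brightness of an 8-bit B-scan
#'
#' Adds `offset` to every pixel and clamps to `[0, 255]`.
#'
#' @param image An 8-bit [bscan].
#' @param offset Signed brightness offset in 8-bit units.
#' @return The adjusted [bscan].
#' @export
adjust_brightness <- function(image, offset) {
  stopifnot(inherits(image, "bscan"))
  if (image$bit_depth != 8L) abort("`adjust_brightness` expects an 8-bit image.")
  px <- pmin(pmax(image$pixels + offset, 0), 255)
  bscan(px, 8L, image$lateral_scale, image$axial_scale, image$scan_id)
}

# Reflection (symmetric, edge-inclusive) padding by `r` on all sides.
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

# Windowed mean and population sd over a (2r+1)^2 square window with
# reflection padding, via summed-area tables.
box_stats <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_reflect(m, r)
  int_sum <- function(x) {
    s <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed after second apply
    s <- t(s)
    rbind(0, cbind(0, s))
  }
  w <- 2L * r + 1L
  win <- function(I) {
    I[(1:nr) + w, (1:nc) + w, drop = FALSE] -
      I[(1:nr) + w, 1:nc, drop = FALSE] -
      I[1:nr, (1:nc) + w, drop = FALSE] +
      I[1:nr, 1:nc, drop = FALSE]
  }
  n <- w^2
  mu <- win(int_sum(p)) / n
  ex2 <- win(int_sum(p^2)) / n
  list(mean = mu, sd = sqrt(pmax(ex2 - mu^2, 0)))
}

# Otsu threshold on integer 8-bit values: returns t + 0.5 where t is the
# bin maximizing the between-class variance of the split {<= t} vs {> t}.
# On a tied plateau (e.g. a two-level histogram, where every split between
# the levels is equivalent) the plateau midpoint is taken, the convention of
# the common ImageJ implementation. A constant sample yields value - 0.5, so
# that the strict-less luminal rule classifies constants as stromal.
otsu_threshold <- function(values) {
  h <- as.numeric(tabulate(values + 1L, nbins = 256L))
  n <- sum(h)
  lev <- 0:255
  if (sum(h > 0) <= 1) return(values[1] - 0.5)
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mt <- m0[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mt * w0[valid] / n - m0[valid])^2 / (w0[valid] / n * w1[valid] / n) / n
  plateau <- which(bcv >= max(bcv) - 1e-9)
  (plateau[ceiling(length(plateau) / 2)] - 1L) + 0.5
}

#' Per-pixel threshold grid for an 8-bit B-scan
#'
#' Computes the threshold surface `T` used to split choroidal pixels into
#' luminal (`value < T`) and stromal (`value >= T`):
#'
#' * `niblack`: `T = mean + k * sd` over the sliding window;
#' * `phansalkar`: `T = mean * (1 + p*exp(-q*mean/255) + k*(sd/R - 1))`
#'   with `p = 2`, `q = 10`, `R = 127.5`;
#' * `otsu_local`: Otsu's between-class-variance criterion within each
#'   window (quadratic in window size -- intended for modest images);
#' * `otsu_global`: one Otsu threshold from the histogram of `roi` pixels
#'   (or the whole image when `roi` is `NULL`), replicated at every pixel.
#'
#' Window statistics use reflection padding at the image edges.
#'
#' @param image An 8-bit [bscan].
#' @param params A [binarization_params].
#' @param roi Optional [subfoveal_roi] restricting the `otsu_global`
#'   histogram to the region of interest.
#' @return A numeric matrix of thresholds, same shape as the image.
#' @export
local_threshold <- function(image, params = binarization_params(), roi = NULL) {
  stopifnot(inherits(image, "bscan"), inherits(params, "binarization_params"))
  if (image$bit_depth != 8L) abort("`local_threshold` expects an 8-bit image (see `to_8bit()`).")
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  r <- params$radius
  if (params$method != "otsu_global" && 2L * r + 1L > min(nr, nc)) {
    abort(sprintf("window (2*%d+1 px) exceeds the image extent (%d x %d).",
                  r, nr, nc))
  }
  switch(params$method,
    niblack = {
      s <- box_stats(px, r)
      s$mean + params$k * s$sd
    },
    phansalkar = {
      s <- box_stats(px, r)
      p <- 2; q <- 10; R <- 0.5 * 255
      s$mean * (1 + p * exp(-q * s$mean / 255) + params$k * (s$sd / R - 1))
    },
    otsu_local = {
      pad <- pad_reflect(px, r)
      out <- matrix(NA_real_, nr, nc)
      for (j in seq_len(nc)) {
        for (i in seq_len(nr)) {
          out[i, j] <- otsu_threshold(pad[i:(i + 2 * r), j:(j + 2 * r)])
        }
      }
      out
    },
    otsu_global = {
      vals <- if (is.null(roi)) as.vector(px) else px[roi$mask]
      t0 <- if (length(vals) == 0) Inf else otsu_threshold(vals)
      matrix(t0, nr, nc)
    }
  )
}

#' Partition the subfoveal ROI into luminal and stromal pixels
#'
#' Applies the brightness offset from `params`, computes the threshold
#' surface with [local_threshold()], and splits the ROI: pixels strictly
#' below their threshold are luminal (dark, vascular), pixels at or above it
#' are stromal (light, interstitial). The two masks partition the ROI
#' exactly; pixels outside the ROI are `FALSE` in both.
#'
#' @param image An 8-bit [bscan].
#' @param roi A [subfoveal_roi] of matching shape.
#' @param params A [binarization_params].
#' @return An object of class `cvi_partition` with logical matrices
#'   `luminal` and `stromal` and the realized `threshold` surface.
#' @export
partition_roi <- function(image, roi, params = binarization_params()) {
  stopifnot(inherits(image, "bscan"), inherits(roi, "subfoveal_roi"))
  if (!all(dim(roi$mask) == dim(image$pixels))) {
    abort("ROI and image shapes do not match.")
  }
  if (params$brightness_offset != 0) {
    image <- adjust_brightness(image, params$brightness_offset)
  }
  thr <- local_threshold(image, params, roi = roi)
  luminal <- roi$mask & (image$pixels < thr)
  stromal <- roi$mask & !luminal
  structure(list(luminal = luminal, stromal = stromal, threshold = thr,
                 params = params),
            class = "cvi_partition")
}

#' @export
print.cvi_partition <- function(x, ...) {
  nl <- sum(x$luminal); ns <- sum(x$stromal)
  cat(sprintf("<cvi_partition> %d luminal + %d stromal px (%s), luminal share %.3f\n",
              nl, ns, x$params$method,
              if (nl + ns > 0) nl / (nl + ns) else NA_real_))
  invisible(x)
}

#' Write a binarized overlay image
#'
#' Renders luminal pixels black and stromal pixels white over the untouched
#' background, the conventional presentation of a binarized choroid.
#'
#' @param image An 8-bit [bscan].
#' @param partition A [cvi_partition] from [partition_roi()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, partition, path) {
  stopifnot(inherits(image, "bscan"), inherits(partition, "cvi_partition"))
  px <- image$pixels / 255
  px[partition$luminal] <- 0
  px[partition$stromal] <- 1
  png::writePNG(px, path)
  invisible(path)
}
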