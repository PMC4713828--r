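test_that("to_8bit is the identity on 8-bit input and rescales 16-bit min-max", {
  img8 <- flat_bscan(10, 10, value = 77)
  expect_identical(to_8bit(img8)$pixels, img8$pixels)
  m <- matrix(c(0, 65535, 32768, 100), 2, 2)
  img16 <- bscan(m, 16L, 1, 1)
  out <- to_8bit(img16)
  expect_identical(out$bit_depth, 8L)
  expect_equal(out$pixels[1, 1], 0)
  expect_equal(out$pixels[2, 1], 255)
  # 16-bit ramp maps to a monotone non-decreasing 8-bit ramp
  ramp <- bscan(matrix(seq(0, 65535, length.out = 128), 1), 16L, 1, 1)
  r8 <- to_8bit(ramp)$pixels
  expect_true(all(diff(as.vector(r8)) >= 0))
  expect_equal(range(r8), c(0, 255))
  # constant 16-bit image maps to zeros (documented degenerate case)
  expect_true(all(to_8bit(bscan(matrix(500, 3, 3), 16L, 1, 1))$pixels == 0))
})

test_that("brightness adjustment adds and clamps", {
  img <- bscan(matrix(c(10, 200, 0, 255), 2, 2), 8L, 1, 1)
  expect_identical(adjust_brightness(img, 0)$pixels, img$pixels)
  dark <- adjust_brightness(img, -40)$pixels
  expect_equal(dark[1, 1], 0)    # 10 - 40 clamps to 0
  expect_equal(dark[2, 1], 160)  # 200 - 40
  bright <- adjust_brightness(img, 60)$pixels
  expect_equal(bright[2, 2], 255)
})

test_that("niblack on a constant image returns the constant (zero variance)", {
  img <- flat_bscan(20, 20, value = 97)
  thr <- local_threshold(img, binarization_params("niblack", radius = 3))
  expect_equal(thr, matrix(97, 20, 20))
})

test_that("niblack matches the brute-force sliding-window oracle exactly", {
  set.seed(31)
  for (rep in 1:20) {
    nr <- sample(8:32, 1); nc <- sample(8:32, 1)
    radius <- sample(1:min(3, (min(nr, nc) - 1) %/% 2), 1)
    m <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
    img <- bscan(m, 8L, 1, 1)
    ours <- local_threshold(img, binarization_params("niblack", radius = radius))
    expect_equal(ours, oracle_niblack(m, radius, 0.2), tolerance = 1e-9)
  }
})

test_that("phansalkar follows its stated formula against windowed statistics", {
  set.seed(32)
  m <- matrix(sample(0:255, 12 * 14, replace = TRUE), 12, 14)
  img <- bscan(m, 8L, 1, 1)
  k <- 0.25; radius <- 2
  ours <- local_threshold(img, binarization_params("phansalkar", radius = radius))
  mu_k0 <- oracle_niblack(m, radius, 0)            # windowed mean
  sd_o <- (oracle_niblack(m, radius, 1) - mu_k0)   # windowed sd
  expected <- mu_k0 * (1 + 2 * exp(-10 * mu_k0 / 255) + k * (sd_o / 127.5 - 1))
  expect_equal(ours, expected, tolerance = 1e-9)
})

test_that("global otsu separates a two-level image and agrees with EBImage", {
  set.seed(33)
  m <- matrix(sample(c(50, 200), 40 * 40, replace = TRUE, prob = c(0.4, 0.6)),
              40, 40)
  img <- bscan(m, 8L, 1, 1)
  thr <- local_threshold(img, binarization_params("otsu_global"))[1, 1]
  expect_true(thr > 50 && thr < 200)
  # independent route: EBImage's Otsu on the same histogram
  eb <- EBImage::otsu(EBImage::Image(m / 255), range = c(0, 1), levels = 256) * 255
  expect_lt(abs(thr - eb), 1.5)
})

test_that("local otsu thresholds each window between its two levels", {
  m <- matrix(60, 9, 9); m[4:6, 4:6] <- 190
  img <- bscan(m, 8L, 1, 1)
  thr <- local_threshold(img, binarization_params("otsu_local", radius = 4))
  expect_true(all(thr > 60 & thr < 190))
  part_lum <- m < thr
  expect_identical(part_lum, m == 60)
})

test_that("an oversized window is a validation error", {
  img <- flat_bscan(10, 10)
  expect_error(local_threshold(img, binarization_params("niblack", radius = 6)),
               "window")
})

test_that("luminal and stromal masks partition the ROI for any input", {
  set.seed(34)
  for (method in c("niblack", "phansalkar", "otsu_global")) {
    m <- matrix(sample(0:255, 60 * 80, replace = TRUE), 60, 80)
    img <- bscan(m, 8L, 10, 5)
    bs <- flat_boundaries(80, ilm = 2, rpe_inner = 8, rpe_outer = 10, csj = 50)
    roi <- build_subfoveal_roi(img, bs, fovea_x = 40, width_um = 600)
    part <- partition_roi(img, roi, binarization_params(method, radius = 4))
    expect_identical(sum(part$luminal) + sum(part$stromal), roi$n_pixels)
    expect_false(any(part$luminal & part$stromal))
    expect_identical(part$luminal | part$stromal, roi$mask)
    expect_false(any((part$luminal | part$stromal) & !roi$mask))
  }
})

test_that("a constant-zero ROI has no luminal pixels under niblack (tie rule)", {
  img <- flat_bscan(40, 40, value = 0)
  bs <- flat_boundaries(40, ilm = 1, rpe_inner = 4, rpe_outer = 5, csj = 35)
  roi <- build_subfoveal_roi(img, bs, fovea_x = 20, width_um = 300)
  part <- partition_roi(img, roi, binarization_params("niblack", radius = 3))
  expect_identical(sum(part$luminal), 0L)
  expect_identical(sum(part$stromal), roi$n_pixels)
})

test_that("darkening a pixel under a fixed threshold can only become luminal", {
  set.seed(35)
  m <- matrix(sample(0:255, 30 * 30, replace = TRUE), 30, 30)
  img <- bscan(m, 8L, 10, 5)
  bs <- flat_boundaries(30, ilm = 1, rpe_inner = 4, rpe_outer = 5, csj = 25)
  roi <- build_subfoveal_roi(img, bs, fovea_x = 15, width_um = 250)
  thr <- local_threshold(img, binarization_params("otsu_global"), roi = roi)
  roi_px <- which(roi$mask & m > 0)
  for (px in sample(roi_px, 20)) {
    before_luminal <- m[px] < thr[px]
    darker <- m; darker[px] <- m[px] - sample.int(m[px], 1)
    after_luminal <- darker[px] < thr[px]
    expect_true(after_luminal >= before_luminal)  # never luminal -> stromal
  }
})

test_that("a uniform non-clamping offset leaves the global-otsu partition unchanged", {
  set.seed(36)
  m <- matrix(sample(30:200, 50 * 50, replace = TRUE), 50, 50)
  img <- bscan(m, 8L, 10, 5)
  bs <- flat_boundaries(50, ilm = 2, rpe_inner = 6, rpe_outer = 8, csj = 45)
  roi <- build_subfoveal_roi(img, bs, fovea_x = 25, width_um = 400)
  p0 <- partition_roi(img, roi, binarization_params("otsu_global"))
  p1 <- partition_roi(adjust_brightness(img, 20), roi,
                      binarization_params("otsu_global"))
  expect_identical(p1$luminal, p0$luminal)
  expect_identical(p1$stromal, p0$stromal)
})

test_that("noiseless phantom lumens are recovered exactly by global otsu", {
  ph <- generate_phantom(phantom_spec(f_true = 0.6, speckle_var = 0, seed = 41))
  img <- ph$image
  w_full <- ncol(img$pixels) * img$lateral_scale
  roi <- build_subfoveal_roi(img, ph$boundaries,
                             fovea_x = ph$boundaries$fovea_x,
                             width_um = w_full)
  part <- partition_roi(img, roi, binarization_params("otsu_global"))
  expect_identical(part$luminal, ph$lumen_mask & roi$mask)
})

test_that("the overlay writer renders luminal black and stromal white", {
  ph <- generate_phantom(phantom_spec(f_true = 0.6, speckle_var = 0, seed = 42))
  roi <- build_subfoveal_roi(ph$image, ph$boundaries)
  part <- partition_roi(ph$image, roi, binarization_params("otsu_global"))
  path <- tempfile(fileext = ".png")
  write_overlay(ph$image, part, path)
  out <- png::readPNG(path)
  expect_true(all(out[part$luminal] == 0))
  expect_true(all(out[part$stromal] == 1))
})
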