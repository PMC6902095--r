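test_that("integrate_spot has zero integral on any constant image", {
  for (v in c(0, 7, 500)) {
    img <- matrix(v, 50, 50)
    m <- integrate_spot(img, c(25, 25), 8)
    expect_equal(m$integral, 0)
    expect_equal(m$local_background, v)
  }
})

test_that("integrate_spot recovers a single bright pixel", {
  img <- matrix(0, 40, 40)
  img[20, 20] <- 1234
  m <- integrate_spot(img, c(20, 20), 5)
  expect_equal(m$integral, 1234)
  expect_false(m$low_signal)
})

test_that("integrate_spot matches the closed-form Gaussian integral", {
  # A = 1000, sigma = 3: untruncated integral 2*pi*A*sigma^2 = 56548.67
  img <- raw_gaussian_image(n = 60, A = 1000, sigma = 3)
  closed <- 2 * pi * 1000 * 9
  # at radius 3*sigma the footprint holds (1 - exp(-4.5)) of the mass
  m9 <- integrate_spot(img, c(30.5, 30.5), 9)
  expect_equal(m9$integral, (1 - exp(-4.5)) * closed, tolerance = 2e-3)
  # a 4*sigma footprint recovers the untruncated closed form within 1%
  m12 <- integrate_spot(img, c(30.5, 30.5), 12)
  expect_equal(m12$integral, closed, tolerance = 0.01)
})

test_that("integrate_spot validates annulus geometry", {
  img <- matrix(0, 40, 40)
  expect_error(integrate_spot(img, c(20, 20), 8, annulus = c(6, 14)), ">=")
  expect_error(integrate_spot(img, c(20, 20), 8, annulus = c(10, 10)),
               "exceed")
  expect_error(integrate_spot(img, c(5, 5), 8), "beyond")
})

test_that("saturation flag fires iff >1% of disk pixels at raster max", {
  img <- matrix(0, 50, 50)
  attr(img, "bit_depth") <- 8L
  m <- integrate_spot(img + 0, c(25, 25), 8)
  expect_false(m$saturated)
  img2 <- img
  img2[17:33, 17:33] <- 255  # whole disk saturated
  attr(img2, "bit_depth") <- 8L
  expect_true(integrate_spot(img2, c(25, 25), 8)$saturated)
  img3 <- img
  img3[25, 25] <- 255  # 1 of ~197 disk pixels: below 1%
  attr(img3, "bit_depth") <- 8L
  expect_false(integrate_spot(img3, c(25, 25), 8)$saturated)
})

test_that("locate_spots keeps exact centres and flags blanks", {
  mb <- noiseless_membrane()
  ref <- locate_spots(mb$image, mb$layout, search_window = 5)
  expect_equal(ref$row, mb$layout$row, tolerance = 0.01)
  expect_equal(ref$col, mb$layout$col, tolerance = 0.01)
  expect_false(any(ref$low_signal))
  # a blank position: flag low_signal, centre unchanged
  lay2 <- mb$layout
  lay2$row[1] <- lay2$row[1] + 0  # keep geometry valid
  blank <- lay2[1, ]
  blank$spot_id <- "BLANK"; blank$col <- blank$col + 300
  img2 <- cbind(mb$image, matrix(0, nrow(mb$image), 320))
  lay3 <- rbind(lay2, blank)
  ref2 <- locate_spots(img2, lay3, search_window = 5)
  expect_true(ref2$low_signal[nrow(ref2)])
  expect_equal(ref2$row[nrow(ref2)], blank$row)
  expect_equal(ref2$col[nrow(ref2)], blank$col)
})

test_that("locate_spots recovers a uniform +2 px grid shift", {
  mb <- noiseless_membrane()
  shifted <- mb$layout
  shifted$row <- shifted$row - 2  # nominal grid off by +2 px in truth
  shifted$col <- shifted$col - 2
  ref <- locate_spots(mb$image, shifted, search_window = 6)
  expect_true(all(abs(ref$row - mb$layout$row) < 0.5))
  expect_true(all(abs(ref$col - mb$layout$col) < 0.5))
  expect_error(locate_spots(mb$image, mb$layout, search_window = 1e4),
               "beyond")
})

test_that("measure_membrane matches the generator forward model", {
  mb <- noiseless_membrane()
  meas <- measure_membrane(mb)
  # background cancels: measured integral = target - background_level
  expected <- mb$truth$target_integral - 0  # annulus background is 0 here
  expect_equal(meas$integral, expected, tolerance = 1e-8)
  # quantized raster agrees within 1%
  mbq <- noiseless_membrane(quantize = TRUE)
  measq <- measure_membrane(mbq)
  expect_equal(measq$integral, mbq$truth$target_integral, tolerance = 0.01)
  # triplicates of equal content, zero noise: identical integrals
  trip <- meas[meas$sample_id %in% "S1" & !is.na(meas$sample_id), ]
  expect_equal(diff(range(trip$integral)), 0, tolerance = 1e-9)
})

test_that("measurements are invariant to a constant offset", {
  mb <- noiseless_membrane()
  m1 <- measure_membrane(mb$image, mb$layout)
  m2 <- measure_membrane(mb$image + 500, mb$layout)
  expect_equal(m1$integral, m2$integral, tolerance = 1e-9)
})

test_that("linearity: scaling the raster scales corrected integrals", {
  mb <- noiseless_membrane()
  m1 <- measure_membrane(mb$image, mb$layout)
  m3 <- measure_membrane(mb$image * 3, mb$layout)
  expect_equal(m3$integral, 3 * m1$integral, tolerance = 1e-9)
})

test_that("translation equivariance for joint image+layout shifts", {
  mb <- noiseless_membrane()
  dr <- 4L; dc <- 6L
  big <- matrix(0, nrow(mb$image) + dr, ncol(mb$image) + dc)
  big[(dr + 1):(dr + nrow(mb$image)), (dc + 1):(dc + ncol(mb$image))] <-
    mb$image
  lay2 <- mb$layout
  lay2$row <- lay2$row + dr; lay2$col <- lay2$col + dc
  m1 <- measure_membrane(mb$image, mb$layout)
  m2 <- measure_membrane(big, lay2)
  expect_equal(m2$integral, m1$integral, tolerance = 1e-9)
})
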