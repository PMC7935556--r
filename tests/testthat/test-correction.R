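test_that("plateProfile averages the plate's scan columns", {
  arr <- array(5, c(6, 4, 3))
  cube <- HyperCube(arr, c(500, 600, 700))
  reg <- PlateRegion(0.5, c(2, 4), c(1, 4))
  prof <- plateProfile(cube, reg)
  expect_identical(dim(prof@values), c(4L, 3L))
  expect_equal(unname(prof@values), matrix(5, 4, 3))
  # non-constant case: columns 2..4 of band 1 hold 2, 3, 4 at every y
  arr2 <- arr
  arr2[2, , 1] <- 2; arr2[3, , 1] <- 3; arr2[4, , 1] <- 4
  prof2 <- plateProfile(HyperCube(arr2, c(500, 600, 700)), reg)
  expect_equal(unname(prof2@values[, 1]), rep(3, 4))
})

test_that("partial-height plates are filled by nearest neighbor with warning", {
  arr <- array(rep(1:4, each = 6), c(6, 4, 1))   # value = y index
  cube <- HyperCube(arr, 500)
  reg <- PlateRegion(0.5, c(1, 6), c(2, 3))
  expect_warning(prof <- plateProfile(cube, reg), "nearest")
  expect_equal(unname(prof@values[, 1]), c(2, 2, 3, 3))
})

test_that("estimateNoise reproduces the hand-computed two-plate solution", {
  # f1 = 7, f2 = 103 with L = 100, true xi = 5:
  # (0.02 * 103 - 0.98 * 7) / (0.02 - 0.98) = 5
  p1 <- new("PlateProfile", values = matrix(7, 2, 3),
            region = PlateRegion(0.02, c(1, 1), c(1, 2)))
  p2 <- new("PlateProfile", values = matrix(103, 2, 3),
            region = PlateRegion(0.98, c(2, 2), c(1, 2)))
  xi <- estimateNoise(p1, p2)
  expect_equal(unname(xi@values), matrix(5, 2, 3), tolerance = 1e-12)
})

test_that("noise-free plates give an identically zero noise field", {
  L <- matrix(c(90, 100, 110, 120), 2, 2)
  p1 <- new("PlateProfile", values = 0.02 * L,
            region = PlateRegion(0.02, c(1, 1), c(1, 2)))
  p2 <- new("PlateProfile", values = 0.98 * L,
            region = PlateRegion(0.98, c(2, 2), c(1, 2)))
  expect_equal(unname(estimateNoise(p1, p2)@values), matrix(0, 2, 2),
               tolerance = 1e-12)
})

test_that("degenerate calibration (R1 == R2) is rejected", {
  p <- new("PlateProfile", values = matrix(1, 2, 2),
           region = PlateRegion(0.5, c(1, 1), c(1, 2)))
  expect_error(estimateNoise(p, p), "degenerate")
})

test_that("subtractNoise broadcasts along the scan axis", {
  cube <- HyperCube(array(10, c(3, 2, 2)), c(500, 600))
  zero <- new("NoiseField", values = matrix(0, 2, 2))
  expect_equal(cubeData(subtractNoise(cube, zero)), cubeData(cube),
               tolerance = 0)
  four <- new("NoiseField", values = matrix(4, 2, 2))
  expect_equal(unname(cubeData(subtractNoise(cube, four))),
               array(6, c(3, 2, 2)))
  expect_error(subtractNoise(cube, matrix(0, 3, 3)), "extents")
})

test_that("reflectance inversion is self-consistent on the calibration plate", {
  spec <- smallScene(seed = 21L, sensorSigma = 0)
  sc <- renderScene(spec)
  co <- doublePlateCorrect(sc$cube, lowPlate(spec), highPlate(spec))
  p98 <- highPlate(spec)
  expect_equal(plateMeanSpectrum(co$reflectance, p98),
               rep(0.98, spec@nbands), tolerance = 1e-9)
  expect_identical(valueKind(co$reflectance), "reflectance")
})

test_that("double-plate recovery is exact without sensor noise", {
  # algebraic identity: any xi field and any illumination cancel exactly
  spec <- smallScene(seed = 22L, sensorSigma = 0,
                     noiseAmplitude = 0.2 * 4095)
  sc <- renderScene(spec)
  co <- doublePlateCorrect(sc$cube, lowPlate(spec), highPlate(spec))
  err <- max(abs(cubeData(co$reflectance) -
                 cubeData(sc$truth@reflectanceCube)))
  expect_lt(err, 1e-12)
  expect_equal(co$noise@values, sc$truth@noiseField, tolerance = 1e-10)
})

test_that("recovered 50% plate reflectance is unbiased at default noise", {
  spec <- smallScene(seed = 23L)
  sc <- renderScene(spec)
  co <- doublePlateCorrect(sc$cube, lowPlate(spec), highPlate(spec))
  spec50 <- plateMeanSpectrum(co$reflectance, midPlate(spec))
  p50 <- midPlate(spec)
  npix <- (diff(p50@xInterval) + 1) * (diff(p50@yInterval) + 1) *
    spec@nbands
  se <- spec@sensorSigma / (0.5 * mean(sc$truth@illumination)) / sqrt(npix)
  expect_lt(abs(mean(spec50) - 0.5), 3 * 0.5 * se + 1e-6)
})

test_that("black-and-white correction matches its closed form", {
  # ref = R (f - fmin) / (fref - fmin); 0.98 * 50 / 100 = 0.49
  cube <- HyperCube(array(60, c(2, 2, 2)), c(500, 600))
  white <- matrix(110, 2, 2)
  dark <- matrix(10, 2, 2)
  bw <- blackWhiteCorrect(cube, white, dark, R = 0.98)
  expect_equal(unname(cubeData(bw)), array(0.49, c(2, 2, 2)),
               tolerance = 1e-12)
  atRef <- blackWhiteCorrect(HyperCube(array(110, c(2, 2, 2)), c(500, 600)),
                             white, dark, R = 0.98)
  expect_equal(unname(cubeData(atRef)), array(0.98, c(2, 2, 2)))
  atMin <- blackWhiteCorrect(HyperCube(array(10, c(2, 2, 2)), c(500, 600)),
                             white, dark, R = 0.98)
  expect_equal(unname(cubeData(atMin)), array(0, c(2, 2, 2)))
  expect_error(blackWhiteCorrect(cube, dark, dark), "denominator")
})

test_that("double-plate beats black-and-white under dark-current drift", {
  # stale dark frame: drawn from a different structured-noise realization
  spec <- smallScene(seed = 24L)
  sc <- renderScene(spec)
  refs <- renderReferences(spec, sc)
  stale <- renderScene(smallScene(seed = 25L))$truth@darkFrame
  co <- doublePlateCorrect(sc$cube, lowPlate(spec), highPlate(spec))
  bw <- blackWhiteCorrect(sc$cube, refs$whiteProfile, stale, R = 0.98)
  p50 <- midPlate(spec)
  mseD <- mean((plateMeanSpectrum(co$reflectance, p50) - 0.5)^2)
  mseB <- mean((plateMeanSpectrum(bw, p50) - 0.5)^2)
  expect_lt(mseD, mseB)
})

test_that("correctionMse applies the closed form and the window", {
  wl <- seq(400, 1000, length.out = 7)
  a <- rep(0.5, 7)
  expect_equal(correctionMse(a, a)$mse, 0)
  expect_equal(correctionMse(a + 0.01, a)$mse, 1e-4, tolerance = 1e-12)
  b <- a; b[wl < 500 | wl > 900] <- 10   # junk outside the window
  r <- correctionMse(b, a, wavelengths = wl, window = c(500, 900))
  expect_equal(r$mse, 0)
  expect_true(all(is.na(r$perBand[wl < 500 | wl > 900])))
  expect_error(correctionMse(a, a[1:3]), "equal length")
  expect_error(correctionMse(a, a, wavelengths = wl, window = c(1, 2)),
               "empty")
})

test_that("non-positive calibration DN raises a calibration error", {
  cube <- HyperCube(array(1, c(2, 2, 2)), c(500, 600))
  calib <- matrix(c(1, 0, 1, 1), 2, 2)
  expect_error(reflectanceInvert(cube, calib, Rcalib = 0.98),
               "calibration DN")
})
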