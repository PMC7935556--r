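test_that("projection matrix is symmetric, idempotent and interpolating at n = 2m", {
  for (p in list(c(2, 2), c(3, 4), c(7, 3), c(5, 6))) {
    B <- sgProjectionMatrix(p[1], p[2])
    expect_equal(B, t(B), tolerance = 1e-12)
    expect_equal(B %*% B, B, tolerance = 1e-10)
  }
  expect_equal(sgProjectionMatrix(3, 6), diag(7), tolerance = 1e-9)
  expect_error(sgProjectionMatrix(2, 5), "order")
})

test_that("kernel coefficients match the classical published weights", {
  expect_equal(sgKernel(2, 2)@coefficients, c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
  expect_equal(sgKernel(3, 4)@coefficients,
               c(5, -30, 75, 131, 75, -30, 5) / 231, tolerance = 1e-12)
  k73 <- sgKernel(7, 3)
  expect_length(k73@coefficients, 15L)
  expect_equal(sum(k73@coefficients), 1, tolerance = 1e-12)
  expect_equal(k73@coefficients, rev(k73@coefficients), tolerance = 1e-12)
  # delta kernel at full order
  expect_equal(sgKernel(4, 8)@coefficients,
               c(rep(0, 4), 1, rep(0, 4)), tolerance = 1e-9)
})

test_that("kernels agree with the brute-force least-squares oracle", {
  for (p in list(c(1, 1), c(2, 3), c(4, 2), c(7, 3), c(3, 4), c(6, 5))) {
    expect_equal(sgKernel(p[1], p[2])@coefficients, oracleKernel(p[1], p[2]),
                 tolerance = 1e-10,
                 label = sprintf("m=%d n=%d", p[1], p[2]))
  }
})

test_that("spectral filtering reproduces polynomials and constants", {
  nb <- 31
  wl <- seq(400, 1000, length.out = nb)
  i <- seq_len(nb)
  poly3 <- 2 + 0.1 * i - 0.02 * i^2 + 1e-3 * i^3
  cube <- HyperCube(array(rep(poly3, each = 4), c(2, 2, nb)), wl)
  for (pad in c("mirror", "polynomial-edge")) {
    sm <- sgFilterSpectra(cube, m = 4, n = 3, padding = pad)
    interior <- 5:(nb - 4)
    expect_equal(cubeData(sm)[1, 1, interior], poly3[interior],
                 tolerance = 1e-9)
  }
  const <- HyperCube(array(7, c(2, 2, nb)), wl)
  expect_equal(cubeData(sgFilterSpectra(const, 7, 3)),
               cubeData(const), tolerance = 1e-10)
  expect_error(sgFilterSpectra(tinyCube(2, 2, 5), m = 7, n = 3), "bands")
})

test_that("white-noise variance shrinks by the kernel's sum of squares", {
  set.seed(101)
  nb <- 200
  n <- 3000
  cube <- HyperCube(array(rnorm(n * nb), c(n, 1, nb)),
                    seq(400, 1000, length.out = nb))
  sm <- sgFilterSpectra(cube, 7, 3)
  interior <- 8:(nb - 7)
  vr <- var(as.vector(cubeData(sm)[, 1, interior]))
  factor <- sum(sgKernel(7, 3)@coefficients^2)
  expect_equal(vr, factor, tolerance = 0.05)
})

test_that("TSG kernel realizes the four-direction construction", {
  # m=1, n=1: 1D kernel (1,1,1)/3 -> center 1/3, all eight neighbors 1/12
  tk <- tsgKernel(1, 1, renormalize = FALSE)
  expect_equal(tk@grid,
               matrix(c(1, 1, 1, 1, 4, 1, 1, 1, 1) / 12, 3, 3),
               tolerance = 1e-12)
  expect_equal(sum(tk@grid), 1, tolerance = 1e-12)
  # m=3, n=4 unnormalized: diagonal offset 3 overflows the distance index
  tk34 <- tsgKernel(3, 4, renormalize = FALSE)
  expect_equal(sum(tk34@grid), 226 / 231, tolerance = 1e-12)
  b <- sgKernel(3, 4)@coefficients
  expect_equal(tk34@grid[4, 4], b[4], tolerance = 1e-12)       # center
  expect_equal(tk34@grid[4, 5], b[5] / 4, tolerance = 1e-12)   # axis d=1
  expect_equal(tk34@grid[5, 5], b[5] / 4, tolerance = 1e-12)   # diag d=1
  expect_equal(tk34@grid[6, 6], b[6] / 4, tolerance = 1e-12)   # diag d=2
  expect_equal(tk34@grid[7, 7], 0)                             # diag d=4 -> 0
  expect_equal(tk34@grid[5, 6], 0)                             # off-direction
  # delta 1D kernel -> 2D delta
  tkd <- tsgKernel(2, 4, renormalize = FALSE)
  expect_equal(tkd@grid, diag(5) * 0 + outer(1:5 == 3, 1:5 == 3) * 1,
               tolerance = 1e-9)
})

test_that("TSG kernels keep dihedral symmetry for all m up to 5", {
  for (m in 1:5) for (n in c(1L, min(2L * m, 4L))) {
    g <- tsgKernel(m, n)@grid
    k <- 2 * m + 1
    expect_equal(g, t(g), tolerance = 1e-12)
    expect_equal(g, g[k:1, k:1], tolerance = 1e-12)
    expect_equal(g, g[k:1, ], tolerance = 1e-12)
  }
})

test_that("renormalized TSG filtering preserves constants; impulse returns the kernel", {
  wl <- c(500, 600)
  const <- HyperCube(array(3.5, c(9, 9, 2)), wl)
  out <- tsgFilter(const, 3, 4)
  expect_equal(cubeData(out), cubeData(const), tolerance = 1e-10)
  imp <- array(0, c(9, 9, 1))
  imp[5, 5, 1] <- 1
  impCube <- HyperCube(imp, 550)
  res <- tsgFilter(impCube, 1, 1, padding = "zero", method = "direct",
                   renormalize = FALSE)
  expect_equal(cubeData(res)[4:6, 4:6, 1], tsgKernel(1, 1, FALSE)@grid,
               tolerance = 1e-12)
  expect_error(tsgFilter(tinyCube(4, 4, 2), 3, 4), "smaller")
})

test_that("fft and direct convolution agree on random cubes", {
  set.seed(202)
  cube <- HyperCube(array(rnorm(30 * 20 * 3), c(30, 20, 3)),
                    c(500, 600, 700))
  for (pad in c("mirror", "zero")) {
    a <- tsgFilter(cube, 3, 4, padding = pad, method = "fft")
    b <- tsgFilter(cube, 3, 4, padding = pad, method = "direct")
    relerr <- max(abs(cubeData(a) - cubeData(b))) /
      max(abs(cubeData(b)))
    expect_lt(relerr, 1e-8)
  }
})

test_that("TSG filtering is linear", {
  set.seed(203)
  wl <- c(500, 600)
  A <- array(rnorm(200), c(10, 10, 2))
  B <- array(rnorm(200), c(10, 10, 2))
  mix <- HyperCube(2 * A - 3 * B, wl)
  fa <- cubeData(tsgFilter(HyperCube(A, wl), 2, 2))
  fb <- cubeData(tsgFilter(HyperCube(B, wl), 2, 2))
  fmix <- cubeData(tsgFilter(mix, 2, 2))
  expect_equal(fmix, 2 * fa - 3 * fb, tolerance = 1e-10)
})

dilate <- function(mask, times) {
  for (i in seq_len(times)) {
    d <- mask
    d[-1, ] <- d[-1, ] | mask[-nrow(mask), ]
    d[-nrow(d), ] <- d[-nrow(d), ] | mask[-1, ]
    d[, -1] <- d[, -1] | mask[, -ncol(mask)]
    d[, -ncol(d)] <- d[, -ncol(d)] | mask[, -1]
    mask <- d
  }
  mask
}

test_that("TSG filtering shrinks the noise variance of flat regions", {
  spec <- smallScene(seed = 31L)
  sc <- renderScene(spec)
  co <- doublePlateCorrect(sc$cube, lowPlate(spec), highPlate(spec))
  sm <- tsgFilter(co$reflectance, 3, 4)
  truth <- cubeData(sc$truth@reflectanceCube)
  # background pixels away from plate and blob edges (kernel reach is 3)
  interior <- maskGrid(plateFreeMask(spec, margin = 6L)) &
    !dilate(maskGrid(sc$truth@foregroundMask), 4L)
  for (b in c(10, 30, 50)) {
    r0 <- (cubeData(co$reflectance)[, , b] - truth[, , b])[interior]
    r1 <- (cubeData(sm)[, , b] - truth[, , b])[interior]
    expect_lt(var(r1), var(r0))
  }
})

test_that("TSG filtering reduces truth RMSE in a noise-dominated scene", {
  spec <- smallScene(seed = 32L, sensorSigma = 0.05 * 4095)
  sc <- renderScene(spec)
  co <- doublePlateCorrect(sc$cube, lowPlate(spec), highPlate(spec))
  sm <- tsgFilter(co$reflectance, 3, 4)
  truth <- cubeData(sc$truth@reflectanceCube)
  rmse <- function(cube) sqrt(mean((cubeData(cube) - truth)^2))
  expect_lt(rmse(sm), rmse(co$reflectance))
})
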