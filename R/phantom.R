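# Synthetic line-scan hyperspectral scene generator.
#
# Sensor model: DN f(x,y,l) = L(y,l) * rho(x,y,l) + xi(y,l) + eps, where L is
# the illumination gain of the line sensor (independent of the scan position
# x), rho the true reflectance, xi a structured additive dark-current-like
# field constant along the scan axis at fixed (detector row, band), and eps
# i.i.d. zero-mean sensor noise.

# Evaluate expr with a private RNG stream; global .Random.seed is restored.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Reference reflectance spectra for the phantom scene
#'
#' Smooth synthetic reflectance spectra for the three surface classes of the
#' phantom: a bright, spectrally flat stage \code{background} (~0.9), a
#' \code{healthy} seed (dark brown visible region with a logistic red-edge
#' rise to a NIR plateau) and an \code{infected} seed (whitish/pinkish:
#' brighter visible reflectance, flatter red edge). At the default contrast
#' the two seed classes differ by at least 0.1 reflectance inside a
#' red-edge-like window (600-750 nm).
#'
#' @param class \code{"healthy"}, \code{"infected"} or \code{"background"}.
#' @param wavelengths increasing wavelength grid in nm.
#' @param contrast multiplier on the healthy/infected spectral separation
#'   (default 1 gives a peak separation >= 0.1).
#' @return numeric reflectance spectrum in \eqn{(0, 1)}, one value per band.
#' @export
makeSignature <- function(class = c("healthy", "infected", "background"),
                          wavelengths, contrast = 1) {
  class <- match.arg(class)
  wl <- as.numeric(wavelengths)
  if (length(wl) > 1L && any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  s <- switch(class,
    background = rep(0.90, length(wl)),
    healthy = 0.15 + 0.35 / (1 + exp(-(wl - 720) / 25)),
    infected = {
      base <- 0.15 + 0.35 / (1 + exp(-(wl - 720) / 25))
      # brighter visible plateau + flatter red edge, scaled by contrast
      lift <- 0.16 / (1 + exp((wl - 730) / 40)) + 0.05
      base + contrast * lift
    })
  pmin(pmax(s, 1e-3), 1 - 1e-3)
}

#' Specify a synthetic line-scan scene
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 270-band 400-1000 nm sensor; a 12-bit detector (full scale
#' 4095); 2% and 98% calibration plates crossing the full field-of-view line
#' at the two ends of the scan and a 50% target plate mid-scan; structured
#' additive noise with amplitude 5% of full scale; sensor noise with
#' standard deviation 0.5% of full scale; illumination with a mild parabolic
#' fall-off toward the extreme detector rows.
#'
#' @param nx,ny,nbands scene extents (scan, line, spectral).
#' @param wavelengths wavelength grid in nm.
#' @param nBlobs number of elliptical seed blobs.
#' @param blobRadiusRange c(min, max) ellipse semi-axis in pixels.
#' @param blobSpacing minimum edge-to-edge spacing between blobs in pixels.
#' @param infectedFraction fraction of blobs labelled \code{infected}.
#' @param plates list of [PlateRegion-class]; defaults place 2%, 50% and 98%
#'   plates as full-height bands at scan positions start/middle/end.
#' @param illumPeak illumination gain at the central detector row (DN per
#'   unit reflectance).
#' @param illumFalloff fractional gain loss at the extreme rows.
#' @param noiseAmplitude amplitude of the structured additive field, DN.
#' @param sensorSigma std of i.i.d. sensor noise, DN.
#' @param fullScale detector full-scale DN.
#' @param seed integer RNG seed; all randomness flows from it.
#' @return a [SceneSpec-class]
#' @export
sceneSpec <- function(nx = 150L, ny = 80L, nbands = 270L,
                      wavelengths = seq(400, 1000, length.out = nbands),
                      nBlobs = 12L, blobRadiusRange = c(4L, 6L),
                      blobSpacing = 3, infectedFraction = 0.5,
                      plates = NULL,
                      illumPeak = 3000, illumFalloff = 0.12,
                      noiseAmplitude = 0.05 * fullScale,
                      sensorSigma = 0.005 * fullScale,
                      fullScale = 4095, seed = 20260101L) {
  if (is.null(plates)) {
    pw <- max(8L, round(nx / 12))
    mid <- round(nx / 2)
    plates <- list(
      PlateRegion(0.02, c(1L, pw), c(1L, ny)),
      PlateRegion(0.50, c(mid - pw %/% 2, mid + pw %/% 2), c(1L, ny)),
      PlateRegion(0.98, c(nx - pw + 1L, nx), c(1L, ny)))
  }
  new("SceneSpec", nx = as.integer(nx), ny = as.integer(ny),
      nbands = as.integer(nbands), wavelengths = as.numeric(wavelengths),
      nBlobs = as.integer(nBlobs),
      blobRadiusRange = as.integer(blobRadiusRange),
      blobSpacing = as.numeric(blobSpacing),
      infectedFraction = as.numeric(infectedFraction),
      plates = plates, illumPeak = as.numeric(illumPeak),
      illumFalloff = as.numeric(illumFalloff),
      noiseAmplitude = as.numeric(noiseAmplitude),
      sensorSigma = as.numeric(sensorSigma),
      fullScale = as.numeric(fullScale), seed = as.integer(seed))
}

# Illumination gain field L(y, lambda): parabolic in y, flat in lambda.
.illumField <- function(spec) {
  y <- seq_len(spec@ny)
  yc <- (spec@ny + 1) / 2
  half <- max((spec@ny - 1) / 2, 1)
  gain <- spec@illumPeak * (1 - spec@illumFalloff * ((y - yc) / half)^2)
  matrix(gain, spec@ny, spec@nbands)
}

# Structured additive field xi(y, lambda): positive, smooth, low-frequency
# sum of random sinusoids over (y, lambda), scaled to peak at the amplitude.
.structuredNoise <- function(spec) {
  yhat <- seq(0, 1, length.out = spec@ny)
  lhat <- seq(0, 1, length.out = spec@nbands)
  field <- matrix(0, spec@ny, spec@nbands)
  for (k in 1:4) {
    fy <- stats::runif(1, 0.5, 2.5)
    fl <- stats::runif(1, 0.5, 3.0)
    ph <- stats::runif(1, 0, 2 * pi)
    ck <- stats::runif(1, 0.3, 1)
    field <- field + ck * sin(2 * pi * (fy * outer(yhat, rep(1, spec@nbands)) +
                                        fl * outer(rep(1, spec@ny), lhat)) + ph)
  }
  if (max(abs(field)) > 0) field <- field / max(abs(field))
  spec@noiseAmplitude * (0.6 + 0.4 * field)
}

# x-intervals between plates (inflated by margin) where blobs may be placed
.freeXIntervals <- function(spec, margin) {
  occ <- rep(FALSE, spec@nx)
  for (p in spec@plates) {
    lo <- max(1L, p@xInterval[1L] - margin)
    hi <- min(spec@nx, p@xInterval[2L] + margin)
    occ[lo:hi] <- TRUE
  }
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values))
    if (!r$values[i]) out[[length(out) + 1L]] <- c(starts[i], ends[i])
  out
}

.placeBlobs <- function(spec) {
  rmax <- spec@blobRadiusRange[2L]
  free <- .freeXIntervals(spec, margin = rmax + 2L)
  xs <- unlist(lapply(free, function(iv) {
    lo <- iv[1L] + rmax; hi <- iv[2L] - rmax
    if (hi >= lo) lo:hi else integer(0)
  }))
  ylo <- rmax + 1L; yhi <- spec@ny - rmax
  if (!length(xs) || yhi < ylo)
    stop("scene too small to place blobs outside the plates", call. = FALSE)
  blobs <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0))
  tries <- 0L
  maxTries <- 400L * spec@nBlobs
  while (nrow(blobs) < spec@nBlobs) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop(sprintf(
        "could not place %d non-overlapping blobs after %d attempts",
        spec@nBlobs, maxTries), call. = FALSE)
    cx <- xs[sample.int(length(xs), 1L)]
    cy <- (ylo:yhi)[sample.int(yhi - ylo + 1L, 1L)]
    ab <- sort(stats::runif(2, spec@blobRadiusRange[1L],
                            spec@blobRadiusRange[2L]), decreasing = TRUE)
    th <- stats::runif(1, 0, pi)
    if (nrow(blobs)) {
      dist <- sqrt((blobs$cx - cx)^2 + (blobs$cy - cy)^2)
      if (any(dist < blobs$a + ab[1L] + spec@blobSpacing)) next
    }
    blobs <- rbind(blobs, data.frame(cx = cx, cy = cy, a = ab[1L],
                                     b = ab[2L], theta = th))
  }
  blobs
}

#' Render the phantom scene
#'
#' Renders the DN cube \code{L * rho + xi + eps} together with its ground
#' truth. The structured field \code{xi} is exactly constant along the scan
#' axis at fixed (row, band); identical seeds give bit-identical output.
#' Plates are rendered with their exact constant reflectance; each seed blob
#' carries a radial brightness gradient (darker rim) emulating the 3D shading
#' that makes plain thresholding hard.
#'
#' @param spec a [SceneSpec-class]
#' @param shadingDepth fractional brightness loss at the blob rim.
#' @return list with elements \code{cube} (DN [HyperCube-class]) and
#'   \code{truth} (a [SceneTruth-class]).
#' @export
renderScene <- function(spec, shadingDepth = 0.35) {
  stopifnot(is(spec, "SceneSpec"))
  .withSeed(spec@seed, {
    nx <- spec@nx; ny <- spec@ny; nb <- spec@nbands
    wl <- spec@wavelengths

    nInf <- round(spec@nBlobs * spec@infectedFraction)
    classes <- sample(c(rep("infected", nInf),
                        rep("healthy", spec@nBlobs - nInf)))
    blobs <- .placeBlobs(spec)
    blobs$class <- classes

    sigBg <- makeSignature("background", wl)
    sigs <- list(healthy = makeSignature("healthy", wl),
                 infected = makeSignature("infected", wl))

    # reflectance cube: background, then plates, then shaded blobs
    rho <- array(rep(sigBg, each = nx * ny), c(nx, ny, nb))
    for (p in spec@plates) {
      xr <- p@xInterval[1L]:p@xInterval[2L]
      yr <- p@yInterval[1L]:p@yInterval[2L]
      pr <- if (length(p@reflectance) == 1L) rep(p@reflectance, nb)
            else p@reflectance
      for (b in seq_len(nb)) rho[xr, yr, b] <- pr[b]
    }

    labelMap <- matrix(0L, nx, ny)
    xg <- matrix(seq_len(nx), nx, ny)
    yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    for (i in seq_len(nrow(blobs))) {
      bl <- blobs[i, ]
      dx <- xg - bl$cx; dy <- yg - bl$cy
      u <- (dx * cos(bl$theta) + dy * sin(bl$theta)) / bl$a
      v <- (-dx * sin(bl$theta) + dy * cos(bl$theta)) / bl$b
      r2 <- u^2 + v^2
      inside <- which(r2 <= 1)
      shade <- 1 - shadingDepth * r2[inside]
      sig <- sigs[[bl$class]]
      for (b in seq_len(nb))
        rho[inside + (b - 1L) * nx * ny] <- sig[b] * shade
      labelMap[inside] <- i
    }
    fg <- labelMap > 0L

    L <- .illumField(spec)          # (ny, nb)
    xi <- .structuredNoise(spec)    # (ny, nb)

    # broadcast L and xi along x
    Lx <- aperm(array(L, c(ny, nb, nx)), c(3L, 1L, 2L))
    xix <- aperm(array(xi, c(ny, nb, nx)), c(3L, 1L, 2L))
    dn <- Lx * rho + xix
    if (spec@sensorSigma > 0)
      dn <- dn + array(stats::rnorm(nx * ny * nb, 0, spec@sensorSigma),
                       c(nx, ny, nb))
    darkFrame <- xi
    if (spec@sensorSigma > 0)
      darkFrame <- darkFrame + matrix(stats::rnorm(ny * nb, 0,
                                                   spec@sensorSigma), ny, nb)

    cube <- HyperCube(dn, wl, "dn",
                      metadata = list(source = "cubeprep phantom",
                                      seed = spec@seed))
    truth <- new("SceneTruth",
                 reflectanceCube = HyperCube(rho, wl, "reflectance"),
                 noiseField = xi,
                 foregroundMask = BinaryMask(fg),
                 labels = data.frame(blob = seq_len(nrow(blobs)),
                                     class = blobs$class,
                                     cx = blobs$cx, cy = blobs$cy,
                                     a = blobs$a, b = blobs$b),
                 labelMap = labelMap,
                 darkFrame = darkFrame,
                 illumination = L)
    list(cube = cube, truth = truth)
  })
}

#' Render the reference measurements for black-and-white correction
#'
#' The dark frame is a realization of the additive field plus sensor noise
#' with the illumination term zeroed (lens capped); the white profile is the
#' per-(row, band) mean DN over the 98% plate footprint of the rendered
#' scene.
#'
#' @param spec a [SceneSpec-class]; must contain a 98% plate.
#' @param scene optional output of [renderScene()] for this spec (re-rendered
#'   from the spec's seed when omitted).
#' @return list with \code{darkFrame} and \code{whiteProfile}, both
#'   \code{(ny, nbands)} matrices, plus \code{whitePlate}, the
#'   [PlateRegion-class] used.
#' @export
renderReferences <- function(spec, scene = NULL) {
  stopifnot(is(spec, "SceneSpec"))
  refl <- vapply(spec@plates, function(p) p@reflectance[1L], numeric(1))
  iw <- which(abs(refl - 0.98) < 1e-9)
  if (!length(iw))
    stop("scene spec has no 98% reflectance plate", call. = FALSE)
  if (is.null(scene)) scene <- renderScene(spec)
  plate <- spec@plates[[iw[1L]]]
  prof <- plateProfile(scene$cube, plate)
  list(darkFrame = scene$truth@darkFrame,
       whiteProfile = prof@values,
       whitePlate = plate)
}
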