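# Shared fixtures: tiny deterministic cubes and a reduced phantom scene that
# keeps the unit tests fast while exercising the same code paths as the
# full-size defaults.

tinyCube <- function(nx = 4, ny = 3, nb = 5, seed = 42,
                     valueKind = "dn") {
  set.seed(seed)
  HyperCube(array(runif(nx * ny * nb, 0, 100), c(nx, ny, nb)),
            wavelengths = seq(400, 1000, length.out = nb),
            valueKind = valueKind)
}

# small but fully featured line-scan scene (plates + blobs)
smallScene <- function(seed = 1L, ...) {
  sceneSpec(nx = 100L, ny = 40L, nbands = 60L, nBlobs = 4L,
            blobRadiusRange = c(3L, 5L), seed = as.integer(seed), ...)
}

lowPlate <- function(spec) {
  refl <- vapply(spec@plates, function(p) p@reflectance[1L], numeric(1))
  spec@plates[[which.min(refl)]]
}

highPlate <- function(spec) {
  refl <- vapply(spec@plates, function(p) p@reflectance[1L], numeric(1))
  spec@plates[[which.max(refl)]]
}

midPlate <- function(spec) {
  refl <- vapply(spec@plates, function(p) p@reflectance[1L], numeric(1))
  spec@plates[[which.min(abs(refl - 0.5))]]
}

# mean spectrum over a plate's footprint
plateMeanSpectrum <- function(cube, plate) {
  xr <- plate@xInterval[1L]:plate@xInterval[2L]
  yr <- plate@yInterval[1L]:plate@yInterval[2L]
  apply(cubeData(cube)[xr, yr, , drop = FALSE], 3, mean)
}
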