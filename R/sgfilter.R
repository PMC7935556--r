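# Savitzky-Golay smoothing: local least-squares polynomial fit of order n
# over a symmetric window of 2m+1 samples, realized as a fixed convolution
# kernel; plus the four-direction 2D spatial extension (TSG) applied per
# band.

#' Savitzky-Golay projection matrix
#'
#' The least-squares projection \eqn{B = X (X^T X)^{-1} X^T} onto
#' polynomials of order \code{n} over the window positions
#' \eqn{x = -m, \dots, m}. Computed via QR on a rescaled design
#' (\eqn{x/m}) for numerical stability; the projection is invariant under
#' the rescaling. B is symmetric and idempotent.
#'
#' @param m half-window (window length \code{2m + 1}).
#' @param n polynomial order, \code{n < 2m + 1}.
#' @return \code{(2m+1) x (2m+1)} numeric matrix.
#' @export
sgProjectionMatrix <- function(m, n) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (n < 0L || n >= 2L * m + 1L)
    stop("polynomial order must satisfy 0 <= n < 2m + 1", call. = FALSE)
  if (n == 2L * m)        # full-order fit interpolates every window point
    return(diag(2L * m + 1L))
  x <- (-m):m / m
  X <- outer(x, 0:n, `^`)
  qrX <- qr(X)
  stopifnot(qrX$rank == n + 1L)   # Vandermonde on distinct nodes
  Q <- qr.Q(qrX)
  B <- tcrossprod(Q)
  (B + t(B)) / 2
}

#' Savitzky-Golay 1D smoothing kernel
#'
#' The center row of [sgProjectionMatrix()]: the weights that evaluate the
#' local least-squares polynomial fit at the window center. Symmetric, unit
#' sum; \code{n = 2m} gives the identity (delta) kernel.
#'
#' @inheritParams sgProjectionMatrix
#' @return an [SGKernel1D-class]
#' @examples
#' sgKernel(2, 2)  # the classical quadratic 5-point weights (-3,12,17,12,-3)/35
#' @export
sgKernel <- function(m, n) {
  B <- sgProjectionMatrix(m, n)
  cf <- B[m + 1L, ]
  cf <- (cf + rev(cf)) / 2
  cf <- cf / sum(cf)
  new("SGKernel1D", m = as.integer(m), n = as.integer(n), coefficients = cf)
}

#' Smooth every pixel spectrum of a cube with a Savitzky-Golay kernel
#'
#' @param cube a [HyperCube-class] with at least \code{2m + 1} bands.
#' @inheritParams sgProjectionMatrix
#' @param padding \code{"mirror"} reflects the spectrum about its end
#'   samples; \code{"polynomial-edge"} evaluates the edge windows' own
#'   least-squares fits (the off-center rows of the projection matrix).
#' @return the filtered [HyperCube-class]
#' @export
sgFilterSpectra <- function(cube, m, n,
                            padding = c("mirror", "polynomial-edge")) {
  stopifnot(is(cube, "HyperCube"))
  padding <- match.arg(padding)
  m <- as.integer(m)
  d <- dim(cube@data)
  nb <- d[3L]
  if (nb < 2L * m + 1L)
    stop(sprintf("cube has %d bands; need at least 2m + 1 = %d", nb,
                 2L * m + 1L), call. = FALSE)
  kern <- sgKernel(m, n)
  cf <- kern@coefficients
  X <- matrix(cube@data, d[1L] * d[2L], nb)
  out <- matrix(0, nrow(X), nb)
  if (padding == "mirror") {
    pad <- cbind(X[, (m + 1L):2L, drop = FALSE], X,
                 X[, (nb - 1L):(nb - m), drop = FALSE])
    for (j in seq_len(2L * m + 1L))
      out <- out + cf[j] * pad[, j:(j + nb - 1L), drop = FALSE]
  } else {
    for (j in seq_len(2L * m + 1L))
      out[, (m + 1L):(nb - m)] <- out[, (m + 1L):(nb - m)] +
        cf[j] * X[, j:(j + nb - 2L * m - 1L), drop = FALSE]
    B <- sgProjectionMatrix(m, n)
    w <- 2L * m + 1L
    out[, 1:m] <- X[, 1:w] %*% t(B[1:m, , drop = FALSE])
    out[, (nb - m + 1L):nb] <-
      X[, (nb - w + 1L):nb] %*% t(B[(m + 2L):w, , drop = FALSE])
  }
  HyperCube(array(out, d), cube@wavelengths, cube@valueKind, cube@metadata)
}

#' Four-direction 2D Savitzky-Golay (TSG) kernel
#'
#' Builds the \code{(2m+1) x (2m+1)} spatial kernel whose support is the
#' horizontal, vertical and both diagonal directions through the center.
#' With \code{b} the 1D kernel indexed by distance \code{d = 0..m}, the
#' center weight is \code{b[0]} and an offset \eqn{(i, j)} on exactly one of
#' the four directions gets \code{b[floor(sqrt(i^2 + j^2))] / 4}; diagonal
#' offsets whose distance index exceeds \code{m} (e.g. \eqn{(3,3)} with
#' \eqn{\lfloor\sqrt{18}\rfloor = 4}) fall outside the 1D window and get 0.
#' All other cells are 0.
#'
#' Because of the distance-index overflow the unnormalized grid can sum to
#' slightly less than 1 (226/231 at \code{m = 3, n = 4}), i.e. DC gain below
#' one; \code{renormalize = TRUE} (default) divides by the grid sum to avoid
#' a systematic brightness loss.
#'
#' @inheritParams sgProjectionMatrix
#' @param renormalize divide the grid by its sum (unit DC gain).
#' @return a [TSGKernel2D-class]
#' @export
tsgKernel <- function(m, n, renormalize = TRUE) {
  kern <- sgKernel(m, n)
  m <- as.integer(m)
  b <- kern@coefficients[(m + 1L):(2L * m + 1L)]   # b[d], d = 0..m
  k <- 2L * m + 1L
  grid <- matrix(0, k, k)
  for (i in (-m):m) for (j in (-m):m) {
    if (i == 0L && j == 0L) {
      grid[i + m + 1L, j + m + 1L] <- b[1L]
    } else if (i == 0L || j == 0L || i == j || i == -j) {
      dd <- floor(sqrt(i^2 + j^2))
      if (dd <= m) grid[i + m + 1L, j + m + 1L] <- b[dd + 1L] / 4
    }
  }
  if (renormalize) grid <- grid / sum(grid)
  new("TSGKernel2D", m = m, n = as.integer(n), grid = grid,
      renormalized = isTRUE(renormalize))
}

.padImage <- function(im, m, padding) {
  nx <- nrow(im); ny <- ncol(im)
  if (padding == "zero") {
    out <- matrix(0, nx + 2L * m, ny + 2L * m)
    out[(m + 1L):(m + nx), (m + 1L):(m + ny)] <- im
    return(out)
  }
  # mirror: reflect about the edge samples (edge not repeated)
  xi <- c((m + 1L):2L, 1L:nx, (nx - 1L):(nx - m))
  yi <- c((m + 1L):2L, 1L:ny, (ny - 1L):(ny - m))
  im[xi, yi, drop = FALSE]
}

.convolve2dDirect <- function(pad, grid, m, nx, ny) {
  out <- matrix(0, nx, ny)
  nz <- which(grid != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1L] - m - 1L
    j <- nz[r, 2L] - m - 1L
    w <- grid[nz[r, 1L], nz[r, 2L]]
    out <- out + w * pad[(m + 1L + i):(m + nx + i),
                         (m + 1L + j):(m + ny + j), drop = FALSE]
  }
  out
}

.convolve2dFFT <- function(pad, grid, m, nx, ny) {
  px <- nrow(pad); py <- ncol(pad)
  kwrap <- matrix(0, px, py)
  idx <- function(off, len) (off %% len) + 1L
  for (i in (-m):m) for (j in (-m):m) {
    w <- grid[i + m + 1L, j + m + 1L]
    if (w != 0) kwrap[idx(-i, px), idx(-j, py)] <-
        kwrap[idx(-i, px), idx(-j, py)] + w
  }
  full <- Re(stats::fft(stats::fft(pad) * stats::fft(kwrap),
                        inverse = TRUE)) / (px * py)
  full[(m + 1L):(m + nx), (m + 1L):(m + ny), drop = FALSE]
}

#' Joint spatial filtering of every band with the TSG kernel
#'
#' Convolves each band image of the cube with the [tsgKernel()], either by
#' direct sparse summation over the kernel's four directions or via the 2D
#' fast Fourier transform; the two methods agree to high precision. Output
#' extents equal input extents.
#'
#' @param cube a [HyperCube-class]; both spatial extents must be at least
#'   \code{2m + 1}.
#' @inheritParams tsgKernel
#' @param padding boundary handling: \code{"mirror"} (default; avoids edge
#'   darkening) or \code{"zero"}.
#' @param method \code{"fft"} or \code{"direct"}.
#' @return the filtered [HyperCube-class]
#' @export
tsgFilter <- function(cube, m, n, padding = c("mirror", "zero"),
                      method = c("fft", "direct"), renormalize = TRUE) {
  stopifnot(is(cube, "HyperCube"))
  padding <- match.arg(padding)
  method <- match.arg(method)
  m <- as.integer(m)
  d <- dim(cube@data)
  if (d[1L] < 2L * m + 1L || d[2L] < 2L * m + 1L)
    stop(sprintf("spatial extents %d x %d smaller than kernel window %d",
                 d[1L], d[2L], 2L * m + 1L), call. = FALSE)
  grid <- tsgKernel(m, n, renormalize)@grid
  out <- array(0, d)
  for (b in seq_len(d[3L])) {
    pad <- .padImage(cube@data[, , b], m, padding)
    out[, , b] <- if (method == "direct")
      .convolve2dDirect(pad, grid, m, d[1L], d[2L])
    else
      .convolve2dFFT(pad, grid, m, d[1L], d[2L])
  }
  HyperCube(out, cube@wavelengths, cube@valueKind, cube@metadata)
}
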