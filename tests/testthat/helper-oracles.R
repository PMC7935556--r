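# Independent brute-force oracle for Savitzky-Golay kernels: least-squares
# polynomial fit over one window via orthogonal polynomials, evaluated at
# the window center; the kernel is recovered by fitting unit impulses.

oracleCenterFit <- function(v, n) {
  m <- (length(v) - 1L) / 2L
  xs <- (-m):m
  if (n == 0) return(mean(v))
  fit <- stats::lm(v ~ poly(xs, n))
  unname(stats::predict(fit, newdata = data.frame(xs = 0)))
}

oracleKernel <- function(m, n) {
  w <- 2L * m + 1L
  if (n == 2L * m)    # closed form: the full-order fit interpolates
    return(as.numeric(seq_len(w) == m + 1L))
  vapply(seq_len(w),
         function(j) oracleCenterFit(as.numeric(seq_len(w) == j), n),
         numeric(1))
}
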