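# Compact periodic Daubechies-4 discrete wavelet transform, used for
# detrending wide-field pixel traces (zeroing the lowest-frequency
# approximation coefficients of a multi-level decomposition).

D4_H <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
D4_G <- rev(D4_H) * c(1, -1, 1, -1) # quadrature mirror

dwt_step <- function(x) {
  n <- length(x)
  k <- seq(0, n / 2 - 1)
  idx <- function(m) (2 * k + m) %% n + 1
  a <- d <- numeric(n / 2)
  for (m in 0:3) {
    a <- a + D4_H[m + 1] * x[idx(m)]
    d <- d + D4_G[m + 1] * x[idx(m)]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  n <- 2 * length(a)
  x <- numeric(n)
  k <- seq(0, n / 2 - 1)
  for (m in 0:3) {
    pos <- (2 * k + m) %% n + 1
    add <- D4_H[m + 1] * a + D4_G[m + 1] * d
    # accumulate with possible index collisions (periodic wrap)
    for (j in seq_along(pos)) x[pos[j]] <- x[pos[j]] + add[j]
  }
  x
}

#' Discrete-wavelet-transform detrending of a signal
#'
#' Decomposes the trace with a periodic Daubechies-4 wavelet to `levels`
#' levels, zeroes the lowest-frequency approximation coefficients, and
#' reconstructs, removing slow drifts while preserving faster structure.
#' Inputs whose length is not a multiple of `2^levels` are reflected-padded
#' before the transform and cropped after.
#'
#' @param x numeric vector with at least `2^levels` samples.
#' @param levels decomposition depth (default 6).
#' @return the detrended vector, same length as `x`.
#' @export
dwt_detrend <- function(x, levels = 6) {
  n <- length(x)
  block <- 2^levels
  if (n < block) stop("need at least 2^levels samples")
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    pad <- rev(x)[seq_len(n_pad - n)]
    xp <- c(x, pad)
  } else {
    xp <- x
  }
  details <- vector("list", levels)
  a <- xp
  for (l in seq_len(levels)) {
    s <- dwt_step(a)
    details[[l]] <- s$d
    a <- s$a
  }
  a[] <- 0 # drop the approximation (lowest-frequency) coefficients
  for (l in rev(seq_len(levels))) {
    a <- idwt_step(a, details[[l]])
  }
  a[seq_len(n)]
}
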