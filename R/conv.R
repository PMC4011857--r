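# 1D convolution (correlation) of a 3D array along one axis via banded
# matrix multiplication; outside-grid values are treated as zero. `kernel`
# is indexed by offsets -m..m.
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  m <- (length(kernel) - 1L) %/% 2L
  n <- d[axis]
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (t in -m:m) {
    j <- idx + t
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- kernel[t + m + 1L]
  }
  if (axis == 1L) {
    out <- K %*% matrix(arr, d[1], d[2] * d[3])
  } else if (axis == 3L) {
    out <- matrix(arr, d[1] * d[2], d[3]) %*% t(K)
  } else {
    tK <- t(K)
    out <- array(0, d)
    for (z in seq_len(d[3])) out[, , z] <- arr[, , z] %*% tK
    return(out)
  }
  array(out, d)
}

# separable 3D convolution with per-axis kernels (list of 3)
conv_separable <- function(arr, kernels) {
  out <- arr
  for (ax in 1:3) out <- conv_axis(out, kernels[[ax]], ax)
  out
}
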