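## Independent brute-force oracles used across tests; all are plain-loop
## implementations kept deliberately separate from the package's code
## paths.

## direct O(n * k) 1-D convolution with zero padding
conv1_brute <- function(x, kernel) {
  r <- (length(kernel) - 1L) / 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (o in -r:r) {
      j <- i + o
      if (j >= 1L && j <= n) acc <- acc + kernel[o + r + 1L] * x[j]
    }
    out[i] <- acc
  }
  out
}

## brute-force 6-connected dilation of a logical array
dilate_brute <- function(m) {
  d <- dim(m)
  out <- m
  idx <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]; k <- idx[r, 3L]
    if (i > 1L) out[i - 1L, j, k] <- TRUE
    if (i < d[1L]) out[i + 1L, j, k] <- TRUE
    if (j > 1L) out[i, j - 1L, k] <- TRUE
    if (j < d[2L]) out[i, j + 1L, k] <- TRUE
    if (k > 1L) out[i, j, k - 1L] <- TRUE
    if (k < d[3L]) out[i, j, k + 1L] <- TRUE
  }
  out
}

## small uniform box image for quick checks
box_image <- function(dim = c(8L, 8L, 8L), value = 1, spacing = 1,
                      unit = "cps") {
  scalar_image(array(value, dim = dim), rep(spacing, 3L), unit = unit)
}

## a quick low-resolution simulation configuration for Monte-Carlo style
## checks (coarse grid keeps the Poisson loop cheap)
tiny_tube <- function(activity_MBq = 2) {
  phantom_tube(activity_MBq, spect_spacing = 1.2, ct_spacing = 0.8)
}
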