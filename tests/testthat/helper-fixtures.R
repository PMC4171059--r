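# shared fixtures and independent oracles, built in code at test time

# direct double-sum convolution oracle: B[x0, y0] = sum K[x0-x, y0-y] I[x, y]
# (0-based response index r maps to x0 = r; kernel offsets -half..half)
brute_convolve <- function(img, even, odd) {
  k <- nrow(even)
  half <- (k - 1L) / 2L
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0 + 0i, H + k - 1L, W + k - 1L)
  for (r in seq_len(H + k - 1L) - 1L) for (cc in seq_len(W + k - 1L) - 1L) {
    s <- 0 + 0i
    for (dx in -half:half) for (dy in -half:half) {
      x <- (r - half) - dx
      y <- (cc - half) - dy
      if (x >= 0 && x < H && y >= 0 && y < W)
        s <- s + (even[dx + half + 1L, dy + half + 1L] +
                  1i * odd[dx + half + 1L, dy + half + 1L]) * img[x + 1L, y + 1L]
    }
    out[r + 1L, cc + 1L] <- s
  }
  out
}

# exhaustive max over a perturbation window (row/col +-radius, orientation
# wrapped +-steps), ties by smallest (row, col, orientation)
brute_local_max <- function(arr3, row, col, oi, radius, steps) {
  nr <- dim(arr3)[1]; nc <- dim(arr3)[2]; n <- dim(arr3)[3]
  best <- -Inf; arg <- NULL
  for (r in max(0, row - radius):min(nr - 1, row + radius))
    for (cc in max(0, col - radius):min(nc - 1, col + radius))
      for (o in sort(unique((oi + (-steps:steps)) %% n))) {
        v <- arr3[r + 1, cc + 1, o + 1]
        if (v > best) { best <- v; arg <- c(r, cc, o) }
      }
  list(value = best, arg = arg)
}

small_dict <- function() gabor_dictionary(8L, 1L, 17L)

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
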