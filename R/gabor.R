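## Ventral-stream front end: Gabor wavelet dictionary, filter-bank convolution,
## sigmoid/whitening transform and MAX-pooling over local perturbations.

#' Build a Gabor wavelet dictionary
#'
#' Constructs the filter bank used by the form pathway: `n_orientations`
#' equally spaced orientations \eqn{\theta_k = k\pi/n, k = 0, \dots, n-1}
#' at `n_scales` scales. Each element is a quadrature (cosine/sine) Gabor
#' pair; the cosine part is mean-subtracted and both parts are normalised to
#' unit L2 norm. Kernel width doubles per scale and the carrier frequency is
#' chosen so the envelope holds about 2.5 cycles at every scale.
#'
#' Orientation convention: `orientation_index` k denotes an edge/bar whose
#' axis is rotated by \eqn{\theta_k} clockwise from the image column
#' (vertical) axis, so index 0 responds maximally to a vertical bar.
#'
#' @param n_orientations number of orientations (>= 1).
#' @param n_scales number of scales (>= 1).
#' @param base_size odd kernel side length in pixels at the finest scale.
#' @param cycles carrier cycles per envelope; default 2.5.
#' @return An object of class `gabor_dictionary`.
#' @export
gabor_dictionary <- function(n_orientations = 8L, n_scales = 1L,
                             base_size = 17L, cycles = 2.5) {
  n <- check_count(n_orientations, "n_orientations")
  m <- check_count(n_scales, "n_scales")
  bs <- check_count(base_size, "base_size", min = 3L)
  if (bs %% 2L == 0L) stopf("`base_size` must be odd")
  thetas <- (seq_len(n) - 1L) * pi / n
  sizes <- integer(m); omegas <- numeric(m)
  kernels <- vector("list", m)
  for (s in seq_len(m)) {
    size <- bs * 2L^(s - 1L)
    if (size %% 2L == 0L) size <- size + 1L
    sizes[s] <- size
    omega <- cycles / size            # cycles / pixel along the carrier
    omegas[s] <- omega
    half <- (size - 1L) / 2L
    sigma <- size / 5                 # envelope ~ +-2.5 sigma inside kernel
    off <- seq(-half, half)
    x <- matrix(off, size, size, byrow = TRUE)   # column offset
    y <- matrix(off, size, size)                 # row offset
    env <- exp(-(x^2 + y^2) / (2 * sigma^2))
    ks <- vector("list", n)
    for (k in seq_len(n)) {
      th <- thetas[k]
      u <- x * cos(th) + y * sin(th)  # carrier runs perpendicular to the bar
      even <- env * cos(2 * pi * omega * u)
      odd <- env * sin(2 * pi * omega * u)
      even <- even - mean(even)
      even <- even / sqrt(sum(even^2))
      odd <- odd / sqrt(sum(odd^2))
      ks[[k]] <- list(even = even, odd = odd)
    }
    kernels[[s]] <- ks
  }
  structure(list(n_orientations = n, n_scales = m, base_size = bs,
                 cycles = cycles, thetas = thetas, sizes = sizes,
                 omegas = omegas, half_sizes = (sizes - 1L) %/% 2L,
                 kernels = kernels, fft_cache = new.env(parent = emptyenv())),
            class = "gabor_dictionary")
}

#' @export
print.gabor_dictionary <- function(x, ...) {
  cat(sprintf("Gabor dictionary: %d orientations x %d scales (base size %d px)\n",
              x$n_orientations, x$n_scales, x$base_size))
  invisible(x)
}

#' Create a Gabor element reference
#'
#' A single dictionary element at a position on the padded response lattice.
#' Coordinates are 0-based, row-major, origin at the top-left; response
#' lattice index `(row, col)` corresponds to a kernel centred on image pixel
#' `(row - half, col - half)` at that element's scale.
#'
#' @param row,col 0-based position on the response lattice.
#' @param orientation_index integer in `[0, n_orientations)`.
#' @param scale_index integer in `[0, n_scales)`.
#' @param dict the `gabor_dictionary` the element refers to.
#' @return An object of class `gabor_element`.
#' @export
gabor_element <- function(row, col, orientation_index, scale_index = 0L, dict) {
  o <- check_count(orientation_index, "orientation_index", min = 0L)
  s <- check_count(scale_index, "scale_index", min = 0L)
  if (o >= dict$n_orientations) stopf("orientation_index out of range")
  if (s >= dict$n_scales) stopf("scale_index out of range")
  structure(list(row = check_count(row, "row", min = 0L),
                 col = check_count(col, "col", min = 0L),
                 orientation_index = o, scale_index = s,
                 theta = dict$thetas[o + 1L], omega = dict$omegas[s + 1L]),
            class = "gabor_element")
}

# padded FFT sizes with small prime factors
good_fft_size <- function(n) stats::nextn(n, c(2L, 3L, 5L))

#' Convolve an image with the full Gabor bank
#'
#' Computes the full (zero-padded) convolution of the frame with every
#' dictionary kernel, so a kernel of side k on an H x W frame yields an
#' (H+k-1) x (W+k-1) response map. The complex raw response per element is
#' kept alongside its squared magnitude (the local Gabor energy).
#'
#' @param image numeric matrix (grayscale frame). Normalised internally to
#'   zero mean and unit variance (constant frames are left at zero).
#' @param dict a [gabor_dictionary()].
#' @param normalize normalise the frame first (default `TRUE`).
#' @param keep_raw keep the complex raw responses (default `TRUE`).
#' @return An object of class `response_stack`: per scale a 3-D array
#'   `[row, col, orientation]` of energies `|c|^2`.
#' @export
convolve_bank <- function(image, dict, normalize = TRUE, keep_raw = TRUE) {
  image <- check_matrix(image, "image")
  if (nrow(image) < 1L || ncol(image) < 1L) stopf("image must be at least 1x1")
  if (normalize) {
    s <- stats::sd(image)
    image <- if (is.na(s) || s < 1e-12) image * 0 else (image - mean(image)) / s
  }
  H <- nrow(image); W <- ncol(image)
  energy <- vector("list", dict$n_scales)
  raw <- if (keep_raw) vector("list", dict$n_scales) else NULL
  for (s in seq_len(dict$n_scales)) {
    k <- dict$sizes[s]
    oH <- H + k - 1L; oW <- W + k - 1L
    P1 <- good_fft_size(oH); P2 <- good_fft_size(oW)
    key <- sprintf("s%d_%dx%d", s, P1, P2)
    cache <- dict$fft_cache
    if (is.null(cache[[key]])) {
      kf <- vector("list", dict$n_orientations)
      for (o in seq_len(dict$n_orientations)) {
        kc <- matrix(0 + 0i, P1, P2)
        kc[seq_len(k), seq_len(k)] <-
          dict$kernels[[s]][[o]]$even + 1i * dict$kernels[[s]][[o]]$odd
        kf[[o]] <- stats::fft(kc)
      }
      cache[[key]] <- kf
    }
    ip <- matrix(0, P1, P2)
    ip[seq_len(H), seq_len(W)] <- image
    Fi <- stats::fft(ip)
    e <- array(0, c(oH, oW, dict$n_orientations))
    r <- if (keep_raw) array(0 + 0i, c(oH, oW, dict$n_orientations)) else NULL
    for (o in seq_len(dict$n_orientations)) {
      conv <- stats::fft(Fi * cache[[key]][[o]], inverse = TRUE) / (P1 * P2)
      conv <- conv[seq_len(oH), seq_len(oW), drop = FALSE]
      e[, , o] <- Re(conv)^2 + Im(conv)^2
      if (keep_raw) r[, , o] <- conv
    }
    energy[[s]] <- e
    if (keep_raw) raw[[s]] <- r
  }
  structure(list(n_orientations = dict$n_orientations,
                 n_scales = dict$n_scales, base_size = dict$base_size,
                 sizes = dict$sizes, half_sizes = dict$half_sizes,
                 image_dim = c(H, W), energy = energy, raw = raw,
                 transformed = NULL, saturation = NULL),
            class = "response_stack")
}

#' Sigmoid and whitening transform of Gabor energies
#'
#' Applies the nonlinearity of the form pathway: each squared magnitude is
#' divided by the local average energy pooled over all orientations of its
#' scale (whitening) inside a square window, then passed through a saturating
#' sigmoid `saturation * tanh(.)`. Output values lie in `[0, saturation]` and
#' are monotone in the raw magnitude for a fixed local energy.
#'
#' @param stack a [convolve_bank()] result.
#' @param saturation positive saturation bound of the sigmoid; default 6.
#' @param local_norm_window odd window side (pixels) for the whitening
#'   average; default 15.
#' @param epsilon guard added to the local energy to avoid division by zero
#'   in flat regions.
#' @return The stack with a `transformed` field (same layout as `energy`).
#' @export
sigmoid_whiten <- function(stack, saturation = 6, local_norm_window = 15L,
                           epsilon = 1e-10) {
  if (!inherits(stack, "response_stack")) stopf("`stack` must be a response_stack")
  saturation <- check_number(saturation, "saturation", min = 0, strict = TRUE)
  w <- check_count(local_norm_window, "local_norm_window", min = 1L)
  rad <- (w - 1L) %/% 2L
  out <- vector("list", stack$n_scales)
  for (s in seq_len(stack$n_scales)) {
    e <- stack$energy[[s]]
    d <- dim(e)
    pooled <- matrix(rowSums(matrix(e, d[1] * d[2], d[3])) / d[3], d[1], d[2])
    sbar <- cpp_box_mean(pooled, rad) + epsilon
    out[[s]] <- array(saturation * tanh(e / as.vector(sbar)), d)
  }
  stack$transformed <- out
  stack$saturation <- saturation
  stack$local_norm_window <- w
  stack
}

#' Local maximum response over a perturbation window
#'
#' MAX-pooling step of the active basis model: the transformed response of an
#' element is the maximum over a window of +-`perturb_radius` pixels in row
#' and column and +-`perturb_orient` orientation steps (orientations wrap
#' modulo `n_orientations`). Ties are broken by the smallest
#' `(row, col, orientation)` lexicographic index.
#'
#' @param stack a whitened [response_stack][convolve_bank()] (run
#'   [sigmoid_whiten()] first).
#' @param element a [gabor_element()].
#' @param perturb_radius spatial perturbation radius in pixels.
#' @param perturb_orient orientation perturbation in steps.
#' @return A list with `value`, `row`, `col`, `orientation_index` (0-based
#'   argmax position).
#' @export
local_max_response <- function(stack, element, perturb_radius = 3L,
                               perturb_orient = 1L) {
  if (is.null(stack$transformed))
    stopf("stack has no transformed responses; call sigmoid_whiten() first")
  pr <- check_count(perturb_radius, "perturb_radius", min = 0L)
  po <- check_count(perturb_orient, "perturb_orient", min = 0L)
  s <- element$scale_index + 1L
  t <- stack$transformed[[s]]
  nr <- dim(t)[1]; nc <- dim(t)[2]; n <- dim(t)[3]
  if (element$row < 0L || element$row >= nr || element$col < 0L || element$col >= nc)
    stopf("element lies outside the response lattice")
  rows <- max(0L, element$row - pr):min(nr - 1L, element$row + pr)
  cols <- max(0L, element$col - pr):min(nc - 1L, element$col + pr)
  os <- sort(unique((element$orientation_index + (-po:po)) %% n))
  best <- -Inf; arg <- NULL
  for (r in rows) for (cc in cols) for (o in os) {
    v <- t[r + 1L, cc + 1L, o + 1L]
    if (v > best) {
      best <- v
      arg <- c(r, cc, o)
    }
  }
  list(value = best, row = arg[1], col = arg[2], orientation_index = arg[3])
}

## internal: per-scale 3-D array of MAX-pooled responses (spatial square
## window + wrapped orientation neighbourhood), matching local_max_response
## with border clipping.
maxpool_stack <- function(stack, perturb_radius, perturb_orient) {
  out <- vector("list", stack$n_scales)
  n <- stack$n_orientations
  for (s in seq_len(stack$n_scales)) {
    t <- stack$transformed[[s]]
    sp <- array(0, dim(t))
    for (o in seq_len(n)) sp[, , o] <- cpp_max_filter(t[, , o], perturb_radius)
    if (perturb_orient > 0L && n > 1L) {
      pooled <- array(-Inf, dim(t))
      for (o in seq_len(n)) {
        idx <- ((o - 1L + (-perturb_orient:perturb_orient)) %% n) + 1L
        pooled[, , o] <- apply(sp[, , unique(idx), drop = FALSE], c(1, 2), max)
      }
      out[[s]] <- pooled
    } else out[[s]] <- sp
  }
  out
}
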