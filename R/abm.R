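## Active basis templates: shared sketch learning and match scoring.

#' Learn an active basis template with the shared sketch algorithm
#'
#' Greedy element selection over all lattice positions, orientations and
#' scales: at each step the element maximising the sum over training images
#' of the MAX-pooled (locally perturbed) transformed response is selected,
#' and nearby correlated candidates are suppressed (matching-pursuit
#' inhibition: centre distance below the kernel half size and wrapped
#' orientation difference of at most one step, at the same scale). When a
#' motion prior is supplied, candidate scores are multiplied by the prior
#' (normalised to peak 1) at the candidate location — the motion pathway
#' visually guiding the sketch.
#'
#' Per element, the weight `delta_i` is the average pooled response across
#' training images; `lambda_i` tilts a pooled background response histogram
#' (exponential family) so its mean equals `delta_i`, fitted by monotone
#' bisection, and `log_z` is the log normaliser of that tilted model.
#'
#' @param images list of numeric matrices (same shape).
#' @param dict a [gabor_dictionary()].
#' @param n_elements number of elements to select (`>= 0`).
#' @param flow_prior optional per-pixel non-negative weight map with the
#'   image's shape.
#' @param saturation,local_norm_window passed to [sigmoid_whiten()].
#' @param perturb_radius,perturb_orient local perturbation window (pixels /
#'   orientation steps), stored with the template.
#' @param n_bins histogram resolution for the background response model.
#' @return An object of class `active_basis_template`.
#' @export
ssa_train <- function(images, dict, n_elements, flow_prior = NULL,
                      saturation = 6, local_norm_window = 15L,
                      perturb_radius = 3L, perturb_orient = 1L,
                      n_bins = 50L) {
  if (!is.list(images) || length(images) == 0L)
    stopf("`images` must be a non-empty list of matrices")
  n_elements <- check_count(n_elements, "n_elements", min = 0L)
  d0 <- dim(images[[1]])
  for (im in images) {
    check_matrix(im, "images[[i]]")
    if (!identical(dim(im), d0)) stopf("all training images must share a shape")
  }
  M <- length(images)
  nOr <- dict$n_orientations; nSc <- dict$n_scales

  sum_map <- sum_plain <- NULL
  breaks <- seq(0, saturation, length.out = n_bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- numeric(n_bins)
  for (im in images) {
    st <- sigmoid_whiten(convolve_bank(im, dict, keep_raw = FALSE),
                         saturation, local_norm_window)
    mp <- maxpool_stack(st, perturb_radius, perturb_orient)
    if (is.null(sum_map)) {
      sum_map <- mp
      sum_plain <- st$transformed
    } else {
      for (s in seq_len(nSc)) {
        sum_map[[s]] <- sum_map[[s]] + mp[[s]]
        sum_plain[[s]] <- sum_plain[[s]] + st$transformed[[s]]
      }
    }
    for (s in seq_len(nSc)) {
      v <- pmin(as.numeric(st$transformed[[s]]), saturation - 1e-12)
      counts <- counts + tabulate(findInterval(v, breaks, all.inside = TRUE),
                                  nbins = n_bins)
    }
  }
  q <- counts / sum(counts)

  prior_maps <- NULL
  if (!is.null(flow_prior)) {
    flow_prior <- check_matrix(flow_prior, "flow_prior")
    if (!identical(dim(flow_prior), d0))
      stopf("`flow_prior` must match the image shape")
    if (any(flow_prior < 0)) stopf("`flow_prior` must be non-negative")
    mx <- max(flow_prior)
    fp <- if (mx > 0) flow_prior / mx else flow_prior + 1
    prior_maps <- vector("list", nSc)
    for (s in seq_len(nSc)) {
      half <- dict$half_sizes[s]
      pm <- matrix(0, d0[1] + dict$sizes[s] - 1L, d0[2] + dict$sizes[s] - 1L)
      pm[half + seq_len(d0[1]), half + seq_len(d0[2])] <- fp
      prior_maps[[s]] <- pm
    }
  }

  allowed <- lapply(sum_map, function(a) array(TRUE, dim(a)))
  sel <- list()
  for (it in seq_len(n_elements)) {
    best <- -Inf; best_arg <- NULL
    for (s in seq_len(nSc)) {
      sc <- sum_map[[s]]
      if (!is.null(prior_maps))
        sc <- sc * array(rep(prior_maps[[s]], nOr), dim(sc))
      sc[!allowed[[s]]] <- -Inf
      m <- max(sc)
      if (m <= best) next
      w <- which(sc == m, arr.ind = TRUE)
      # ties from the orientation pooling are broken by the candidate's own
      # (unpooled) response, then by lexicographic (row, col, orientation)
      own <- sum_plain[[s]][w]
      w <- w[own == max(own), , drop = FALSE]
      w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
      best <- m
      best_arg <- c(w[1, 1] - 1L, w[1, 2] - 1L, w[1, 3] - 1L, s - 1L)
    }
    if (is.null(best_arg) || !is.finite(best)) break  # candidate pool exhausted
    r <- best_arg[1]; cc <- best_arg[2]; o <- best_arg[3]; s <- best_arg[4] + 1L
    sel[[length(sel) + 1L]] <- list(
      row = r, col = cc, orientation_index = o, scale_index = s - 1L,
      delta = sum_map[[s]][r + 1L, cc + 1L, o + 1L] / M)
    # inhibition at this scale
    half <- dict$half_sizes[s]
    dms <- dim(sum_map[[s]])
    rows <- max(0L, r - half + 1L):min(dms[1] - 1L, r + half - 1L)
    cols <- max(0L, cc - half + 1L):min(dms[2] - 1L, cc + half - 1L)
    for (rr in rows) for (c2 in cols) {
      if ((rr - r)^2 + (c2 - cc)^2 >= half^2) next
      for (oo in seq_len(nOr) - 1L) {
        dod <- abs(oo - o)
        if (min(dod, nOr - dod) <= 1L)
          allowed[[s]][rr + 1L, c2 + 1L, oo + 1L] <- FALSE
      }
    }
  }

  k <- length(sel)
  elements <- data.frame(row = integer(k), col = integer(k),
                         orientation_index = integer(k),
                         scale_index = integer(k), theta = numeric(k),
                         omega = numeric(k))
  weights <- lambdas <- log_z <- numeric(k)
  for (i in seq_len(k)) {
    e <- sel[[i]]
    elements$row[i] <- e$row
    elements$col[i] <- e$col
    elements$orientation_index[i] <- e$orientation_index
    elements$scale_index[i] <- e$scale_index
    elements$theta[i] <- dict$thetas[e$orientation_index + 1L]
    elements$omega[i] <- dict$omegas[e$scale_index + 1L]
    weights[i] <- e$delta
    fit <- fit_exponential_tilt(q, centers, e$delta)
    lambdas[i] <- fit$lambda
    log_z[i] <- fit$log_z
  }
  structure(list(elements = elements, weights = weights, lambdas = lambdas,
                 log_z = log_z, perturb_radius = as.integer(perturb_radius),
                 perturb_orient = as.integer(perturb_orient),
                 saturation = saturation,
                 local_norm_window = as.integer(local_norm_window),
                 dict_meta = list(n_orientations = nOr, n_scales = nSc,
                                  base_size = dict$base_size,
                                  cycles = dict$cycles),
                 background = list(centers = centers, q = q),
                 image_dim = d0),
            class = "active_basis_template")
}

## Solve for lambda so that the exponentially tilted background histogram
## q(r) * exp(lambda * r) / Z has mean `target`; returns log Z as well.
## The tilted mean is strictly increasing in lambda (variance > 0), so
## monotone bisection applies. Degenerate histograms fall back to lambda = 0.
fit_exponential_tilt <- function(q, centers, target, lo = -200, hi = 200,
                                 tol = 1e-10, max_iter = 200L) {
  pos <- q > 0
  if (sum(pos) < 2L) return(list(lambda = 0, log_z = 0))
  rng <- range(centers[pos])
  target <- min(max(target, rng[1] + 1e-9), rng[2] - 1e-9)
  tilt_mean <- function(l) {
    lw <- log(q[pos]) + l * centers[pos]
    lw <- lw - max(lw)
    w <- exp(lw)
    sum(w * centers[pos]) / sum(w)
  }
  f_lo <- tilt_mean(lo) - target
  f_hi <- tilt_mean(hi) - target
  if (f_lo > 0) { hi <- lo } else if (f_hi < 0) { lo <- hi }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (tilt_mean(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  lambda <- (lo + hi) / 2
  lw <- log(q[q > 0]) + lambda * centers[q > 0]
  mx <- max(lw)
  list(lambda = lambda, log_z = mx + log(sum(exp(lw - mx))))
}

#' @export
print.active_basis_template <- function(x, ...) {
  cat(sprintf("Active basis template: %d elements (%d orientations x %d scales)\n",
              nrow(x$elements), x$dict_meta$n_orientations, x$dict_meta$n_scales))
  invisible(x)
}

#' Match score of a template against a response stack
#'
#' Log-likelihood-ratio template score: the sum over selected elements of
#' `delta_i * r_i - log_z_i`, where `r_i` is the MAX-pooled transformed
#' response of element i in the test frame (local perturbations absorbed by
#' [local_max_response()]) and `log_z_i` the element's log normaliser. An
#' empty template scores 0.
#'
#' @param template an [ssa_train()] result.
#' @param stack a whitened [response_stack][convolve_bank()] built with a
#'   dictionary of the same geometry.
#' @return A single numeric score.
#' @export
match_score <- function(template, stack) {
  if (!inherits(template, "active_basis_template"))
    stopf("`template` must be an active_basis_template")
  if (!inherits(stack, "response_stack")) stopf("`stack` must be a response_stack")
  dm <- template$dict_meta
  if (stack$n_orientations != dm$n_orientations ||
      stack$n_scales != dm$n_scales || stack$base_size != dm$base_size)
    stopf("stack was built with a different dictionary geometry")
  if (is.null(stack$transformed))
    stopf("stack has no transformed responses; call sigmoid_whiten() first")
  k <- nrow(template$elements)
  if (k == 0L) return(0)
  total <- 0
  for (i in seq_len(k)) {
    el <- list(row = template$elements$row[i], col = template$elements$col[i],
               orientation_index = template$elements$orientation_index[i],
               scale_index = template$elements$scale_index[i])
    r <- local_max_response(stack, el, template$perturb_radius,
                            template$perturb_orient)
    total <- total + template$weights[i] * r$value - template$log_z[i]
  }
  total
}

#' Serialise an active basis template to a text archive
#'
#' Plain-text archive: a metadata record (dictionary geometry, perturbation
#' window, transform constants) plus flat numeric arrays for the element
#' coordinates, weights, lambdas, log normalisers and the background
#' histogram. Numeric values round-trip bit-exactly.
#'
#' @param template an [ssa_train()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  write_archive(path, "active_basis_template",
                meta = list(n_orientations = template$dict_meta$n_orientations,
                            n_scales = template$dict_meta$n_scales,
                            base_size = template$dict_meta$base_size,
                            cycles = template$dict_meta$cycles,
                            perturb_radius = template$perturb_radius,
                            perturb_orient = template$perturb_orient,
                            saturation = template$saturation,
                            local_norm_window = template$local_norm_window,
                            image_dim = template$image_dim),
                arrays = list(row = template$elements$row,
                              col = template$elements$col,
                              orientation_index = template$elements$orientation_index,
                              scale_index = template$elements$scale_index,
                              theta = template$elements$theta,
                              omega = template$elements$omega,
                              weights = template$weights,
                              lambdas = template$lambdas,
                              log_z = template$log_z,
                              bg_centers = template$background$centers,
                              bg_q = template$background$q))
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  a <- read_archive(path, "active_basis_template")
  m <- a$meta; v <- a$arrays
  k <- length(v$row)
  structure(list(
    elements = data.frame(row = as.integer(v$row), col = as.integer(v$col),
                          orientation_index = as.integer(v$orientation_index),
                          scale_index = as.integer(v$scale_index),
                          theta = as.numeric(v$theta),
                          omega = as.numeric(v$omega)),
    weights = as.numeric(v$weights), lambdas = as.numeric(v$lambdas),
    log_z = as.numeric(v$log_z),
    perturb_radius = as.integer(meta_num(m, "perturb_radius")),
    perturb_orient = as.integer(meta_num(m, "perturb_orient")),
    saturation = meta_num(m, "saturation"),
    local_norm_window = as.integer(meta_num(m, "local_norm_window")),
    dict_meta = list(n_orientations = as.integer(meta_num(m, "n_orientations")),
                     n_scales = as.integer(meta_num(m, "n_scales")),
                     base_size = as.integer(meta_num(m, "base_size")),
                     cycles = meta_num(m, "cycles")),
    background = list(centers = as.numeric(v$bg_centers),
                      q = as.numeric(v$bg_q)),
    image_dim = as.integer(meta_num(m, "image_dim"))),
    class = "active_basis_template")
}

#' Rebuild the dictionary a template was trained with
#'
#' @param template an [ssa_train()] or [read_template()] result.
#' @return A [gabor_dictionary()] with the template's geometry.
#' @export
template_dictionary <- function(template) {
  dm <- template$dict_meta
  gabor_dictionary(dm$n_orientations, dm$n_scales, dm$base_size, dm$cycles)
}
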