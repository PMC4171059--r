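## Action prototypes: per class, five representative form descriptors
## extracted by eigendecomposition (eigenimages) plus clustering, with the
## frame nearest each cluster centre kept as the prototype. This approximates
## the synergetic-network "melting" abstraction with a documented,
## deterministic procedure.

as_descriptor_matrix <- function(frames) {
  if (is.matrix(frames) && is.numeric(frames)) return(frames)
  if (!is.list(frames) || length(frames) == 0L)
    stopf("`frames` must be a list of matrices or a numeric matrix")
  d0 <- dim(frames[[1]])
  X <- t(vapply(frames, function(f) {
    check_matrix(f, "frames[[i]]")
    if (!identical(dim(f), d0)) stopf("all descriptors must share a shape")
    as.numeric(f)
  }, numeric(prod(d0))))
  attr(X, "frame_dim") <- d0
  X
}

unit_norm <- function(x) {
  n <- sqrt(sum(x^2))
  if (n > 0) x / n else x
}

#' Extract k action prototypes from one class's frame descriptors
#'
#' Two-stage reduction: (1) project the descriptors onto the top principal
#' components (eigenimages) capturing at least 95% of the variance;
#' (2) k-means cluster in that space (seeded, multiple restarts) and return
#' the descriptor nearest each cluster centre, unit-normalised. Prototype
#' frame indices are pairwise distinct. With zero-variance input all k
#' prototypes equal the (normalised) first frame.
#'
#' @param frames list of equally shaped numeric matrices (or an N x D
#'   matrix), N >= k.
#' @param k number of prototypes; default 5.
#' @param seed integer seed for the clustering restarts.
#' @param var_explained PCA variance fraction to retain (default 0.95).
#' @return A list with `prototypes` (length-k list of unit-norm matrices or
#'   vectors) and `indices` (selected frame indices).
#' @export
extract_prototypes <- function(frames, k = 5L, seed = 1L,
                               var_explained = 0.95) {
  k <- check_count(k, "k")
  X <- as_descriptor_matrix(frames)
  fd <- attr(X, "frame_dim")
  N <- nrow(X)
  if (N < k) stopf("need at least k = %d frames, got %d", k, N)
  reshape <- function(v) {
    if (is.null(fd)) v else matrix(v, fd[1], fd[2])
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  tv <- sum(Xc^2)
  if (tv < 1e-18) {
    p <- reshape(unit_norm(X[1, ]))
    return(list(prototypes = rep(list(p), k), indices = seq_len(k)))
  }
  sv <- svd(Xc, nu = min(N, 20L), nv = 0)
  varfrac <- cumsum(sv$d^2) / sum(sv$d^2)
  p <- max(1L, which(varfrac >= var_explained)[1])
  p <- min(p, ncol(sv$u))
  scores <- sv$u[, seq_len(p), drop = FALSE] *
    rep(sv$d[seq_len(p)], each = N)
  ncenters <- min(k, nrow(unique(scores)))
  used <- logical(N)
  idx <- integer(0)
  if (ncenters < N) {
    km <- with_seed(seed,
                    stats::kmeans(scores, centers = ncenters,
                                  nstart = 10L, iter.max = 100L))
    # nearest real frame per cluster centre, indices kept distinct
    for (cl in seq_len(nrow(km$centers))) {
      d2 <- colSums((t(scores) - km$centers[cl, ])^2)
      d2[used] <- Inf
      j <- which.min(d2)
      used[j] <- TRUE
      idx <- c(idx, j)
    }
  } else {
    idx <- seq_len(ncenters)        # one frame per cluster, trivially
    used[idx] <- TRUE
  }
  # if clustering collapsed (duplicate frames), fill with unused frames
  while (length(idx) < k) {
    j <- which(!used)[1]
    used[j] <- TRUE
    idx <- c(idx, j)
  }
  list(prototypes = lapply(idx, function(j) reshape(unit_norm(X[j, ]))),
       indices = idx)
}

#' Build a prototype bank over all action classes
#'
#' @param descriptors_by_class named list: per class, a list of frame
#'   descriptors (equally shaped matrices).
#' @param k prototypes per class; default 5.
#' @param seed integer seed.
#' @return An object of class `prototype_bank`.
#' @export
prototype_bank <- function(descriptors_by_class, k = 5L, seed = 1L) {
  if (is.null(names(descriptors_by_class)) ||
      any(names(descriptors_by_class) == ""))
    stopf("`descriptors_by_class` must be a named list (one entry per class)")
  classes <- names(descriptors_by_class)
  protos <- indices <- vector("list", length(classes))
  names(protos) <- names(indices) <- classes
  for (cl in classes) {
    ex <- extract_prototypes(descriptors_by_class[[cl]], k = k,
                             seed = seed + match(cl, classes))
    protos[[cl]] <- ex$prototypes
    indices[[cl]] <- ex$indices
  }
  structure(list(classes = classes, k = as.integer(k), prototypes = protos,
                 indices = indices), class = "prototype_bank")
}

#' @export
print.prototype_bank <- function(x, ...) {
  cat(sprintf("Prototype bank: %d classes x %d prototypes\n",
              length(x$classes), x$k))
  invisible(x)
}

#' Per-class best prototype match of a frame descriptor
#'
#' For each class, the maximum over its prototypes of the normalised
#' cross-correlation `sum((x - mean(x)) (p - mean(p))) / (N sd(x) sd(p))`
#' between the descriptor and the prototype, in `[-1, 1]`. A zero-variance
#' descriptor scores 0 for every class.
#'
#' @param prototypes a [prototype_bank()].
#' @param frame_descriptor numeric matrix with the prototypes' shape.
#' @return Named numeric vector of per-class scores.
#' @export
prototype_score <- function(prototypes, frame_descriptor) {
  if (!inherits(prototypes, "prototype_bank"))
    stopf("`prototypes` must be a prototype_bank")
  x <- as.numeric(frame_descriptor)
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  out <- stats::setNames(numeric(length(prototypes$classes)), prototypes$classes)
  if (sx < 1e-12) return(out)
  for (cl in prototypes$classes) {
    best <- -Inf
    for (p in prototypes$prototypes[[cl]]) {
      pv <- as.numeric(p)
      if (length(pv) != length(x))
        stopf("descriptor shape does not match the prototypes")
      pc <- pv - mean(pv)
      sp <- sqrt(sum(pc^2))
      v <- if (sp < 1e-12) 0 else sum(xc * pc) / (sx * sp)
      if (v > best) best <- v
    }
    out[cl] <- best
  }
  out
}

#' Subject-disjoint train/test split
#'
#' Samples `n_train_subjects` subjects (seeded, reproducible) and splits a
#' labelled video collection into subject-disjoint train and test sets whose
#' union covers every video exactly once.
#'
#' @param videos an `action_dataset` from [make_dataset()] or a list of
#'   `video_stack`s.
#' @param n_train_subjects number of training subjects; default 5.
#' @param seed integer seed.
#' @return A list with `train` and `test` datasets and the chosen
#'   `train_subjects`.
#' @export
train_split <- function(videos, n_train_subjects = 5L, seed = 1L) {
  vids <- if (inherits(videos, "action_dataset")) videos$videos else videos
  n_train_subjects <- check_count(n_train_subjects, "n_train_subjects")
  subjects <- sort(unique(vapply(vids, function(v) v$subject_id, integer(1))))
  if (length(subjects) < n_train_subjects)
    stopf("need at least %d subjects, got %d", n_train_subjects,
          length(subjects))
  train_subj <- with_seed(seed, sort(sample(subjects, n_train_subjects)))
  in_train <- vapply(vids, function(v) v$subject_id %in% train_subj, logical(1))
  subset_ds <- function(keep) {
    out <- vids[keep]
    if (inherits(videos, "action_dataset"))
      structure(list(videos = out, manifest = videos$manifest[keep, , drop = FALSE],
                     actions = videos$actions), class = "action_dataset")
    else out
  }
  list(train = subset_ds(in_train), test = subset_ds(!in_train),
       train_subjects = train_subj)
}

#' Serialise a prototype bank to a text archive
#'
#' @param bank a [prototype_bank()].
#' @param path file path.
#' @export
write_prototypes <- function(bank, path) {
  arrays <- list()
  for (ci in seq_along(bank$classes)) {
    cl <- bank$classes[ci]
    for (j in seq_len(bank$k))
      arrays[[sprintf("p_%d_%d", ci, j)]] <- bank$prototypes[[cl]][[j]]
    arrays[[sprintf("idx_%d", ci)]] <- bank$indices[[cl]]
  }
  write_archive(path, "prototype_bank",
                meta = list(classes = paste(bank$classes, collapse = ","),
                            k = bank$k),
                arrays = arrays)
}

#' @rdname write_prototypes
#' @export
read_prototypes <- function(path) {
  ar <- read_archive(path, "prototype_bank")
  classes <- strsplit(ar$meta$classes, ",", fixed = TRUE)[[1]]
  k <- as.integer(meta_num(ar$meta, "k"))
  protos <- indices <- stats::setNames(vector("list", length(classes)), classes)
  for (ci in seq_along(classes)) {
    protos[[ci]] <- lapply(seq_len(k), function(j)
      ar$arrays[[sprintf("p_%d_%d", ci, j)]])
    indices[[ci]] <- as.integer(ar$arrays[[sprintf("idx_%d", ci)]])
  }
  structure(list(classes = classes, k = k, prototypes = protos,
                 indices = indices), class = "prototype_bank")
}
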