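## Two-pathway pipeline: per-frame feature extraction (form scores from
## prototype matching on motion-guided sketch responses; motion memberships
## from the fuzzy flow cells), frame labelling by limb-group gating or an
## ELM, and video labels by majority voting.

#' Pipeline configuration
#'
#' All numeric defaults of the two pathways in one place. Values can be
#' overridden by name; unknown names are an error.
#'
#' @param ... overrides, e.g. `action_config(elm_L = 80)`.
#' @return An object of class `action_config`.
#' @export
action_config <- function(...) {
  cfg <- list(
    # form pathway
    n_orientations = 8L, n_scales = 1L, base_size = 17L,
    saturation = 6, local_norm_window = 15L,
    perturb_radius = 3L, perturb_orient = 1L,
    template_elements = 30L, template_frames_per_class = 10L,
    descriptor_downsample = 2L, prior_floor = 0.25,
    descriptor_window = 112L,
    # motion pathway
    flow_rho = 0, flow_xi = 0.02, flow_levels = 4L, flow_warps = 2L,
    flow_inner = 6L, flow_epsilon = 1e-3,
    # fuzzy inference
    eta = 0.15, memory_N = 25L, tau = 1 / 25, bbox_frac = 0.1,
    # prototypes & classifier
    prototypes_k = 5L, prototype_var = 0.95, mirror_augment = TRUE,
    elm_L = 60L, elm_node_type = "sigmoid", elm_ridge = 0,
    # orchestration
    n_train_subjects = 5L, seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stopf("unknown config option(s): %s", paste(bad, collapse = ", "))
  structure(modifyList(cfg, dots), class = "action_config")
}

flow_params_from_config <- function(config) {
  flow_params(rho = config$flow_rho, xi = config$flow_xi,
              pyramid_levels = config$flow_levels,
              warps_per_level = config$flow_warps,
              inner_iterations = config$flow_inner,
              epsilon = config$flow_epsilon)
}

## energy-weighted cell division of a combined speed map over a grid
energy_cells <- function(e, grid) {
  vapply(grid$cells, function(cl)
    sum(e[cl$rows[1]:cl$rows[2], cl$cols[1]:cl$cols[2]]), numeric(1))
}

## motion-guided form descriptor of one frame: orientation-summed whitened
## Gabor responses, modulated by the normalised flow-speed prior (floored so
## static body structure is attenuated, not erased), cropped to a fixed
## window centred on the person (translation invariance: a walker is the
## same snapshot wherever it stands in the frame), then downsampled.
form_descriptor <- function(frame, energy_map, dict, config) {
  st <- sigmoid_whiten(convolve_bank(frame, dict, keep_raw = FALSE),
                       config$saturation, config$local_norm_window)
  tr <- st$transformed[[1]]
  d <- dim(tr)
  D <- matrix(rowSums(matrix(tr, d[1] * d[2], d[3])), d[1], d[2])
  half <- dict$half_sizes[1]
  ctr <- NULL
  if (!is.null(energy_map)) {
    mx <- max(energy_map)
    prior <- if (mx > 0) energy_map / mx else energy_map + 1
    pp <- matrix(0, nrow(D), ncol(D))
    pp[half + seq_len(nrow(prior)), half + seq_len(ncol(prior))] <- prior
    D <- D * (config$prior_floor + (1 - config$prior_floor) * pp)
    if (mx > 0) {
      # energy centroid locates the person; shift to response-lattice coords
      tot <- sum(energy_map)
      ctr <- c(sum(row(energy_map) * energy_map),
               sum(col(energy_map) * energy_map)) / tot + half
    }
  }
  win <- config$descriptor_window
  if (!is.null(win) && win > 0L) {
    if (is.null(ctr)) ctr <- (dim(D) + 1) / 2
    r0 <- round(ctr[1]) - win %/% 2L
    c0 <- round(ctr[2]) - win %/% 2L
    out <- matrix(0, win, win)
    rr <- max(1, r0):min(nrow(D), r0 + win - 1L)
    cc <- max(1, c0):min(ncol(D), c0 + win - 1L)
    if (length(rr) > 0L && length(cc) > 0L)
      out[rr - r0 + 1L, cc - c0 + 1L] <- D[rr, cc]
    D <- out
  }
  ds <- config$descriptor_downsample
  if (ds > 1L)
    D <- cpp_resize_bilinear(D, ceiling(nrow(D) / ds), ceiling(ncol(D) / ds))
  D
}

## fuzzy-motion step for one combined energy map; returns updated state and
## the instantaneous memberships
fuzzy_step <- function(e, state, config) {
  bb <- person_bbox(e, config$bbox_frac)
  grid <- cell_grid(dim(e), bb)
  cells <- energy_cells(e, grid)
  if (sum(cells) <= 0) {
    inst <- c(0, 0, 0, 0)
  } else {
    pk <- which(e == max(e), arr.ind = TRUE)[1, ]
    inst <- frame_membership(cells, pk, grid)
  }
  state <- update_membership(state, inst)
  list(state = state, inst = inst)
}

#' Extract the fused feature vector for one frame
#'
#' Runs both pathways around frame `t`: optical flow is computed on the
#' pairs `(t-1, t)` and `(t, t+1)` (frames at the boundary reuse the first
#' or last available pair), the fuzzy membership state is updated from the
#' combined flow-speed map, and the frame's motion-guided sketch descriptor
#' is scored against the action prototypes. The fused feature vector
#' concatenates 6 per-class form scores, 4 aggregated cell memberships and
#' the limb-group confidence (length 11 for six classes).
#'
#' @param frames `T x H x W` array (or a `video_stack`).
#' @param t frame index, 1-based.
#' @param dict a [gabor_dictionary()].
#' @param bank a [prototype_bank()].
#' @param state a [membership_state()]; carried across frames by the caller.
#' @param config an [action_config()].
#' @return A list with `features` (length 11), `form_scores`,
#'   `memberships`, `group`, `confidence` and the updated `state`.
#' @export
extract_frame_features <- function(frames, t, dict, bank, state,
                                   config = action_config()) {
  if (inherits(frames, "video_stack")) frames <- frames$frames
  Tn <- dim(frames)[1]
  if (Tn < 4L) stopf("need at least 4 frames")
  fp <- flow_params_from_config(config)
  i1 <- min(max(t - 1L, 1L), Tn - 1L)
  i2 <- min(max(t, 1L), Tn - 1L)
  f1 <- estimate_flow(frames[i1, , ], frames[i1 + 1L, , ], fp)
  f2 <- if (i2 == i1) f1 else estimate_flow(frames[i2, , ], frames[i2 + 1L, , ], fp)
  e <- (flow_energy(f1$forward) + flow_energy(f2$forward)) / 2
  frame_features_core(frames[t, , ], e, dict, bank, state, config)
}

frame_features_core <- function(frame, e, dict, bank, state, config) {
  fz <- fuzzy_step(e, state, config)
  state <- fz$state
  dfz <- defuzzify(state)
  D <- form_descriptor(frame, e, dict, config)
  fs <- prototype_score(bank, D)
  list(features = c(fs, state$mu, dfz$confidence), form_scores = fs,
       memberships = state$mu, group = dfz$group,
       confidence = dfz$confidence, state = state, descriptor = D)
}

#' Fuse pathway features into a frame label
#'
#' `mode = "gated"`: candidate classes are restricted to the defuzzified
#' limb group (lower: walking/jogging/running; upper: boxing/clapping/
#' waving; all six when the group is unknown) and the best form score among
#' the candidates wins. `mode = "elm"`: the trained ELM labels the fused
#' 11-feature vector.
#'
#' @param features result of [extract_frame_features()] (or a list with
#'   `form_scores`, `features`, `group`).
#' @param mode `"gated"` or `"elm"`.
#' @param elm_model an [elm()] fit (required for `mode = "elm"`).
#' @return The frame label (character).
#' @export
fuse_and_label <- function(features, mode = c("gated", "elm"),
                           elm_model = NULL) {
  mode <- match.arg(mode)
  if (mode == "elm") {
    if (is.null(elm_model)) stopf("mode 'elm' requires a trained elm_model")
    return(as.character(predict(elm_model, features$features)))
  }
  fs <- features$form_scores
  cand <- switch(features$group,
                 lower = intersect(lower_limb_classes, names(fs)),
                 upper = intersect(upper_limb_classes, names(fs)),
                 names(fs))
  if (length(cand) == 0L) cand <- names(fs)
  cand[which.max(fs[cand])]
}

#' Majority vote over frame labels
#'
#' The video label is the most frequent frame label; an exact vote tie is
#' broken by the larger summed per-class score.
#'
#' @param labels character vector of frame labels.
#' @param classes class set.
#' @param score_sums named numeric vector of summed per-class scores.
#' @return A list with `label` and the `votes` table.
#' @export
majority_vote <- function(labels, classes, score_sums) {
  v <- table(factor(labels, levels = classes))
  top <- names(v)[v == max(v)]
  label <- if (length(top) == 1L) top else top[which.max(score_sums[top])]
  list(label = label, votes = v)
}

#' Classify a video frame by frame and vote
#'
#' Per-frame labels via [fuse_and_label()]; the video label is the majority
#' vote over frames, with ties broken by the larger summed per-class score.
#'
#' @param video a `video_stack` (or `T x H x W` array).
#' @param model an [action_model()] bundle.
#' @param mode `"gated"`, `"elm"` or `"both"`.
#' @return An object of class `video_prediction`: per-frame labels, final
#'   label(s), vote counts and the per-frame feature trace.
#' @export
classify_video <- function(video, model, mode = c("gated", "elm", "both")) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("gated", "elm") else mode
  frames <- if (inherits(video, "video_stack")) video$frames else video
  Tn <- dim(frames)[1]
  if (Tn < 4L) stopf("video must have at least 4 frames")
  config <- model$config
  fp <- flow_params_from_config(config)
  dict <- model$dictionary
  state <- membership_state(eta = config$eta, N = config$memory_N,
                            tau = config$tau)
  classes <- model$classes
  prev_flow <- estimate_flow(frames[1, , ], frames[2, , ], fp)
  rows <- vector("list", Tn - 2L)
  scores <- list(gated = numeric(length(classes)), elm = numeric(length(classes)))
  names(scores$gated) <- names(scores$elm) <- classes
  labels <- list(gated = character(0), elm = character(0))
  for (t in 2:(Tn - 1L)) {
    nxt <- estimate_flow(frames[t, , ], frames[t + 1L, , ], fp)
    e <- (flow_energy(prev_flow$forward) + flow_energy(nxt$forward)) / 2
    ff <- frame_features_core(frames[t, , ], e, dict, model$prototypes,
                              state, config)
    state <- ff$state
    for (md in modes) {
      lb <- fuse_and_label(ff, md, model$elm)
      labels[[md]] <- c(labels[[md]], lb)
      sc <- if (md == "elm")
        drop(predict(model$elm, ff$features, type = "score"))
      else ff$form_scores
      scores[[md]][names(sc)] <- scores[[md]][names(sc)] + sc
    }
    rows[[t - 1L]] <- data.frame(frame = t,
                                 t(ff$memberships),
                                 group = ff$group,
                                 confidence = ff$confidence)
    prev_flow <- nxt
  }
  trace <- do.call(rbind, rows)
  names(trace)[2:5] <- c("mu_C1", "mu_C2", "mu_C3", "mu_C4")
  final <- votes <- list()
  for (md in modes) {
    mv <- majority_vote(labels[[md]], classes, scores[[md]])
    final[[md]] <- mv$label
    votes[[md]] <- mv$votes
  }
  structure(list(modes = modes, frame_labels = labels, final = final,
                 votes = votes, score_sums = scores, trace = trace,
                 label = if (inherits(video, "video_stack")) video$label else NA),
            class = "video_prediction")
}

#' @export
print.video_prediction <- function(x, ...) {
  for (md in x$modes)
    cat(sprintf("%s: %s (%d/%d frames)\n", md, x$final[[md]],
                max(x$votes[[md]]), sum(x$votes[[md]])))
  invisible(x)
}

## ---- training --------------------------------------------------------------

## per-video pathway pass: consecutive-pair flows, combined energy maps,
## fuzzy trace and motion-guided descriptors for frames 2..T-1
analyze_video <- function(video, dict, config) {
  frames <- video$frames
  Tn <- dim(frames)[1]
  fp <- flow_params_from_config(config)
  state <- membership_state(eta = config$eta, N = config$memory_N,
                            tau = config$tau)
  prev_flow <- estimate_flow(frames[1, , ], frames[2, , ], fp)
  descriptors <- vector("list", Tn - 2L)
  mus <- matrix(0, Tn - 2L, 4L)
  conf <- numeric(Tn - 2L)
  groups <- character(Tn - 2L)
  energies <- vector("list", Tn - 2L)
  for (t in 2:(Tn - 1L)) {
    nxt <- estimate_flow(frames[t, , ], frames[t + 1L, , ], fp)
    e <- (flow_energy(prev_flow$forward) + flow_energy(nxt$forward)) / 2
    fz <- fuzzy_step(e, state, config)
    state <- fz$state
    dfz <- defuzzify(state)
    i <- t - 1L
    descriptors[[i]] <- form_descriptor(frames[t, , ], e, dict, config)
    energies[[i]] <- e
    mus[i, ] <- state$mu
    conf[i] <- dfz$confidence
    groups[i] <- dfz$group
    prev_flow <- nxt
  }
  list(descriptors = descriptors, mus = mus, conf = conf, groups = groups,
       energies = energies)
}

#' Fit the two-pathway action recognition model
#'
#' Trains every component on a labelled, subject-disjoint training set:
#' per-class active basis templates (shared sketch algorithm with the mean
#' flow-speed prior of the class), five action prototypes per class
#' (eigendecomposition + clustering of motion-guided sketch descriptors,
#' horizontally mirrored copies included), and an ELM classifier on the
#' fused 11-feature frame vectors. All randomness derives from
#' `config$seed`.
#'
#' @param dataset an `action_dataset` (or list of `video_stack`s) used for
#'   training.
#' @param config an [action_config()].
#' @param verbose print per-stage progress.
#' @return An object of class `action_model`.
#' @export
action_model <- function(dataset, config = action_config(), verbose = FALSE) {
  vids <- if (inherits(dataset, "action_dataset")) dataset$videos else dataset
  if (length(vids) == 0L) stopf("empty training set")
  classes <- sort(unique(vapply(vids, function(v) v$label, character(1))))
  dict <- gabor_dictionary(config$n_orientations, config$n_scales,
                           config$base_size)
  say <- function(...) if (verbose) message(sprintf(...))

  say("pathway pass over %d training videos", length(vids))
  t0 <- proc.time()[3]
  analyses <- lapply(vids, analyze_video, dict = dict, config = config)
  say("  done in %.1f s", proc.time()[3] - t0)

  # prototypes: per class, pooled descriptors (+ mirrored copies)
  say("extracting %d prototypes per class", config$prototypes_k)
  desc_by_class <- stats::setNames(vector("list", length(classes)), classes)
  for (i in seq_along(vids)) {
    cl <- vids[[i]]$label
    ds <- analyses[[i]]$descriptors
    keep <- seq(1, length(ds), by = 2)   # every other frame is ample
    ds <- ds[keep]
    if (config$mirror_augment)
      ds <- c(ds, lapply(ds, function(m) m[, ncol(m):1]))
    desc_by_class[[cl]] <- c(desc_by_class[[cl]], ds)
  }
  bank <- prototype_bank(desc_by_class, k = config$prototypes_k,
                         seed = config$seed)

  # per-class active basis templates with the class-mean flow prior
  say("learning active basis templates")
  templates <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    idx <- which(vapply(vids, function(v) v$label, character(1)) == cl)
    imgs <- list(); prior <- NULL
    per_vid <- max(1L, ceiling(config$template_frames_per_class / length(idx)))
    for (i in idx) {
      Tn <- dim(vids[[i]]$frames)[1]
      ts <- unique(round(seq(2, Tn - 1L, length.out = per_vid)))
      for (t in ts) {
        imgs[[length(imgs) + 1L]] <- vids[[i]]$frames[t, , ]
        e <- analyses[[i]]$energies[[t - 1L]]
        prior <- if (is.null(prior)) e else prior + e
      }
    }
    imgs <- imgs[seq_len(min(length(imgs), config$template_frames_per_class))]
    templates[[cl]] <- ssa_train(imgs, dict, config$template_elements,
                                 flow_prior = prior / length(imgs),
                                 saturation = config$saturation,
                                 local_norm_window = config$local_norm_window,
                                 perturb_radius = config$perturb_radius,
                                 perturb_orient = config$perturb_orient)
  }

  # fused frame features for the ELM
  say("training %s ELM (L = %d)", config$elm_node_type, config$elm_L)
  X <- NULL; y <- character(0)
  for (i in seq_along(vids)) {
    an <- analyses[[i]]
    n <- nrow(an$mus)
    fs <- t(vapply(an$descriptors, function(D) prototype_score(bank, D),
                   numeric(length(classes))))
    Xi <- cbind(fs, an$mus, an$conf)
    X <- rbind(X, Xi)
    y <- c(y, rep(vids[[i]]$label, n))
  }
  colnames(X) <- NULL
  fit <- elm(X, y, L = config$elm_L, node_type = config$elm_node_type,
             seed = config$seed + 101L, ridge = config$elm_ridge)

  subj <- sort(unique(vapply(vids, function(v) v$subject_id, integer(1))))
  structure(list(classes = classes, dictionary = dict, templates = templates,
                 prototypes = bank, elm = fit, config = config,
                 train_subjects = subj,
                 n_train_frames = nrow(X)),
            class = "action_model")
}

#' @export
print.action_model <- function(x, ...) {
  cat(sprintf("action_model: %d classes (%s)\n", length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained on subjects {%s}, %d frame samples\n",
              paste(x$train_subjects, collapse = ","), x$n_train_frames))
  cat(sprintf("  form: %d-orientation Gabor bank, %d-element templates, %d prototypes/class\n",
              x$config$n_orientations, x$config$template_elements,
              x$prototypes$k))
  cat(sprintf("  fusion: gated or %s-ELM (L = %d)\n", x$elm$node_type, x$elm$L))
  invisible(x)
}

#' @export
summary.action_model <- function(object, ...) {
  print(object)
  for (cl in object$classes)
    cat(sprintf("  template[%s]: %d elements\n", cl,
                nrow(object$templates[[cl]]$elements)))
  invisible(object)
}

#' Predict video labels with a fitted action model
#'
#' @param object an [action_model()].
#' @param newdata a `video_stack`, a list of them, or an `action_dataset`.
#' @param mode `"gated"`, `"elm"` or `"both"`.
#' @param ... unused.
#' @return A single [classify_video()] prediction, or a list of them.
#' @export
predict.action_model <- function(object, newdata,
                                 mode = c("gated", "elm", "both"), ...) {
  mode <- match.arg(mode)
  if (inherits(newdata, "video_stack"))
    return(classify_video(newdata, object, mode))
  vids <- if (inherits(newdata, "action_dataset")) newdata$videos else newdata
  lapply(vids, classify_video, model = object, mode = mode)
}

#' Evaluate an action model on a test set
#'
#' Requires a subject-disjoint test set (videos from training subjects are
#' an error). Returns per-mode 6 x 6 confusion matrices (rows = predicted
#' class, columns = true class) and overall accuracies.
#'
#' @param model an [action_model()].
#' @param dataset an `action_dataset` or list of `video_stack`s.
#' @param mode `"gated"`, `"elm"` or `"both"`.
#' @return An object of class `action_eval` with `confusion` (per mode),
#'   `accuracy` (per mode) and the per-video predictions.
#' @export
evaluate <- function(model, dataset, mode = c("both", "gated", "elm")) {
  mode <- match.arg(mode)
  vids <- if (inherits(dataset, "action_dataset")) dataset$videos else dataset
  subj <- unique(vapply(vids, function(v) v$subject_id, integer(1)))
  if (any(subj %in% model$train_subjects))
    stopf("test set shares subjects {%s} with the training set",
          paste(intersect(subj, model$train_subjects), collapse = ","))
  preds <- lapply(vids, classify_video, model = model, mode = mode)
  modes <- preds[[1]]$modes
  truth <- vapply(vids, function(v) v$label, character(1))
  confusion <- accuracy <- list()
  for (md in modes) {
    got <- vapply(preds, function(p) p$final[[md]], character(1))
    cm <- table(predicted = factor(got, levels = model$classes),
                true = factor(truth, levels = model$classes))
    confusion[[md]] <- unclass(cm)
    accuracy[[md]] <- mean(got == truth)
  }
  structure(list(confusion = confusion, accuracy = accuracy,
                 predictions = preds, modes = modes),
            class = "action_eval")
}

#' @export
print.action_eval <- function(x, ...) {
  for (md in x$modes) {
    cat(sprintf("mode %s: accuracy %.3f\n", md, x$accuracy[[md]]))
    print(x$confusion[[md]])
  }
  invisible(x)
}
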