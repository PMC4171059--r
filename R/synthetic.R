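## Synthetic KTH-like action videos: an articulated stick figure (head,
## torso, two arms with elbows, two legs with knees) with sinusoidal joint
## angles, rendered with anti-aliased segments on a gray background, plus
## low-level fixtures with analytically known ground truth.

action_classes <- c("boxing", "clapping", "waving", "walking", "jogging",
                    "running")
lower_limb_classes <- c("walking", "jogging", "running")
upper_limb_classes <- c("boxing", "clapping", "waving")

# per-action kinematic defaults: gait speed (px/frame), limb swing frequency
# (cycles/frame), limb amplitude (radians). Running vs jogging differ in both
# speed (4 vs 2) and swing frequency (0.25 vs 0.15) so the three gaits are
# distinguishable yet confusable.
action_defaults <- list(
  boxing   = list(gait_speed = 0, limb_frequency = 0.15, limb_amplitude = 0.9),
  clapping = list(gait_speed = 0, limb_frequency = 0.12, limb_amplitude = 0.8),
  waving   = list(gait_speed = 0, limb_frequency = 0.12, limb_amplitude = 0.9),
  walking  = list(gait_speed = 1, limb_frequency = 0.10, limb_amplitude = 0.55),
  jogging  = list(gait_speed = 2, limb_frequency = 0.15, limb_amplitude = 0.60),
  running  = list(gait_speed = 4, limb_frequency = 0.25, limb_amplitude = 0.65))

#' Specification of one synthetic action video
#'
#' Defaults encode the study conditions: 142 x 200 frames, six action
#' classes, lower-limb actions translating at increasing gait speeds
#' (walking 1 < jogging 2 < running 4 px/frame) with increasing leg-swing
#' frequency, upper-limb actions stationary with arm motion only.
#'
#' @param action one of `boxing, clapping, waving, walking, jogging, running`.
#' @param n_frames number of frames; default 40.
#' @param frame_shape `c(height, width)`; default `c(142, 200)`.
#' @param limb_amplitude joint swing amplitude in radians (action default if
#'   `NULL`).
#' @param limb_frequency joint swing frequency in cycles/frame (action
#'   default if `NULL`).
#' @param gait_speed horizontal translation in px/frame (action default if
#'   `NULL`).
#' @param noise_sigma additive Gaussian noise sd in intensity units;
#'   default 0.02.
#' @param clutter add static background clutter; default `FALSE`.
#' @param seed integer seed; the rendered stack is fully determined by the
#'   spec including this seed.
#' @param subject_id integer subject tag; also perturbs limb proportions
#'   (style variation).
#' @return An object of class `action_spec`.
#' @export
action_spec <- function(action, n_frames = 40L, frame_shape = c(142L, 200L),
                        limb_amplitude = NULL, limb_frequency = NULL,
                        gait_speed = NULL, noise_sigma = 0.02,
                        clutter = FALSE, seed = 1L, subject_id = 1L) {
  if (!is.character(action) || length(action) != 1L ||
      !(action %in% action_classes))
    stopf("unknown action '%s'", paste(action, collapse = ","))
  def <- action_defaults[[action]]
  spec <- list(action = action,
               n_frames = check_count(n_frames, "n_frames", min = 2L),
               frame_shape = as.integer(frame_shape),
               limb_amplitude = if (is.null(limb_amplitude)) def$limb_amplitude
                                else check_number(limb_amplitude, "limb_amplitude", min = 0),
               limb_frequency = if (is.null(limb_frequency)) def$limb_frequency
                                else check_number(limb_frequency, "limb_frequency", min = 0),
               gait_speed = if (is.null(gait_speed)) def$gait_speed
                            else check_number(gait_speed, "gait_speed", min = 0),
               noise_sigma = check_number(noise_sigma, "noise_sigma", min = 0),
               clutter = isTRUE(clutter),
               seed = check_count(seed, "seed", min = 0L),
               subject_id = check_count(subject_id, "subject_id", min = 1L))
  if (action %in% upper_limb_classes && spec$gait_speed != 0)
    stopf("upper-limb actions must have gait_speed = 0")
  if (action %in% lower_limb_classes && spec$gait_speed <= 0)
    stopf("lower-limb actions must have gait_speed > 0")
  structure(spec, class = "action_spec")
}

## anti-aliased thick segment: blend `ink` where the distance to the segment
## is below width/2, with a 1-px linear falloff
draw_segment <- function(img, p0, p1, width = 3, ink = 0.05) {
  H <- nrow(img); W <- ncol(img)
  r0 <- min(p0[1], p1[1]) - width; r1 <- max(p0[1], p1[1]) + width
  c0 <- min(p0[2], p1[2]) - width; c1 <- max(p0[2], p1[2]) + width
  rr <- max(1, floor(r0)):min(H, ceiling(r1))
  cc <- max(1, floor(c0)):min(W, ceiling(c1))
  if (length(rr) == 0L || length(cc) == 0L) return(img)
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 < 1e-12) {
    dist <- sqrt((R - p0[1])^2 + (C - p0[2])^2)
  } else {
    t <- pmin(pmax(((R - p0[1]) * d[1] + (C - p0[2]) * d[2]) / len2, 0), 1)
    dist <- sqrt((R - p0[1] - t * d[1])^2 + (C - p0[2] - t * d[2])^2)
  }
  alpha <- pmin(pmax(width / 2 + 0.5 - dist, 0), 1)
  img[rr, cc] <- img[rr, cc] * (1 - alpha) + ink * alpha
  img
}

draw_disc <- function(img, center, radius, ink = 0.05) {
  draw_segment(img, center, center, width = 2 * radius, ink = ink)
}

## joint skeleton of the figure for one frame; returns a list of segments
## (pairs of (row, col)) plus named joint positions
figure_pose <- function(spec, t, style, x_center) {
  H <- spec$frame_shape[1]
  fh <- 0.6 * H * style$height_scale        # figure height
  foot <- 0.85 * H
  hip <- c(foot - 0.46 * fh, x_center)
  shoulder <- c(hip[1] - 0.32 * fh, x_center)
  head_c <- c(shoulder[1] - 0.11 * fh, x_center)
  head_r <- 0.06 * fh
  thigh <- 0.23 * fh * style$leg_scale
  shin <- 0.23 * fh * style$leg_scale
  uarm <- 0.16 * fh * style$arm_scale
  farm <- 0.15 * fh * style$arm_scale
  # left/right limbs attach slightly apart so crossing limbs never fully
  # coincide (keeps the silhouette area stable through the gait cycle)
  hipL <- hip + c(0, -1.5); hipR <- hip + c(0, 1.5)
  shL <- shoulder + c(0, -1.5); shR <- shoulder + c(0, 1.5)
  ph <- 2 * pi * spec$limb_frequency * t + style$phase0
  A <- spec$limb_amplitude
  dir <- function(a) c(cos(a), sin(a))    # a = 0 points down (row+), a>0 tilts +col
  seg <- list(); joints <- list(hip = hip, shoulder = shoulder, head = head_c)
  lower_action <- spec$action %in% lower_limb_classes

  if (lower_action) {
    a1 <- A * sin(ph); a2 <- A * sin(ph + pi)
    k1 <- max(0, 0.8 * A * sin(ph + pi / 2))
    k2 <- max(0, 0.8 * A * sin(ph + pi + pi / 2))
    knee1 <- hipL + thigh * dir(a1)
    foot1 <- knee1 + shin * dir(a1 - k1)
    knee2 <- hipR + thigh * dir(a2)
    foot2 <- knee2 + shin * dir(a2 - k2)
    b1 <- 0.2 * A * sin(ph + pi); b2 <- 0.2 * A * sin(ph)
    elb1 <- shL + uarm * dir(b1)
    hnd1 <- elb1 + farm * dir(b1 + 0.3)
    elb2 <- shR + uarm * dir(b2)
    hnd2 <- elb2 + farm * dir(b2 + 0.3)
    joints$knee1 <- knee1; joints$knee2 <- knee2
    joints$foot1 <- foot1; joints$foot2 <- foot2
  } else {
    # stance legs, slightly apart
    knee1 <- hipL + thigh * dir(0.12)
    foot1 <- knee1 + shin * dir(0.12)
    knee2 <- hipR + thigh * dir(-0.12)
    foot2 <- knee2 + shin * dir(-0.12)
    joints$knee1 <- knee1; joints$knee2 <- knee2
    joints$foot1 <- foot1; joints$foot2 <- foot2
    if (spec$action == "boxing") {
      # alternating forward extension at shoulder height (+col direction)
      e1 <- (sin(ph) + 1) / 2; e2 <- (sin(ph + pi) + 1) / 2
      elb1 <- shR + uarm * c(0.1, 0.3 + 0.7 * e1)
      hnd1 <- elb1 + farm * c(0, 0.1 + 0.9 * e1)
      elb2 <- shL + uarm * c(0.1, 0.3 + 0.7 * e2)
      hnd2 <- elb2 + farm * c(0, 0.1 + 0.9 * e2)
    } else if (spec$action == "clapping") {
      # both arms periodic, hands meeting at chest height
      s <- (sin(ph) + 1) / 2              # 1 = hands together
      spread <- (1 - s) * 0.9 + 0.1
      chest <- shoulder + c(0.12 * fh, 0)
      elb1 <- shR + uarm * c(0.5, spread)
      hnd1 <- chest + c(0, spread * 0.25 * fh)
      elb2 <- shL + uarm * c(0.5, -spread)
      hnd2 <- chest + c(0, -spread * 0.25 * fh)
    } else {                              # waving: one arm above the head
      wa <- A * sin(ph)
      elb1 <- shR + uarm * c(-0.9, 0.35)               # raised upper arm
      hnd1 <- elb1 + farm * dir(pi + wa)               # forearm oscillates up
      elb2 <- shL + uarm * dir(0.15)                   # other arm hangs
      hnd2 <- elb2 + farm * dir(0.15)
    }
  }
  joints$elbow1 <- elb1; joints$elbow2 <- elb2
  joints$hand1 <- hnd1; joints$hand2 <- hnd2
  seg <- list(
    torso = list(shoulder, hip),
    thigh1 = list(hip, knee1), shin1 = list(knee1, foot1),
    thigh2 = list(hip, knee2), shin2 = list(knee2, foot2),
    uarm1 = list(shoulder, elb1), farm1 = list(elb1, hnd1),
    uarm2 = list(shoulder, elb2), farm2 = list(elb2, hnd2))
  list(segments = seg, joints = joints, head = list(c = head_c, r = head_r))
}

#' Render a synthetic action video
#'
#' Renders the articulated figure frame by frame with additive Gaussian
#' noise (and optional static clutter). Lower-limb actions translate
#' horizontally at `gait_speed`, wrapping around the frame; the figure and
#' noise are fully determined by the spec's seed.
#'
#' @param spec an [action_spec()].
#' @return An object of class `video_stack`: `frames` is a `T x H x W` array
#'   in `[0, 1]`, with `label`, `subject_id`, `fps` and per-frame ground-truth
#'   `joints`.
#' @export
render_action <- function(spec) {
  if (!inherits(spec, "action_spec")) stopf("`spec` must be an action_spec")
  H <- spec$frame_shape[1]; W <- spec$frame_shape[2]
  Tn <- spec$n_frames
  with_seed(spec$seed + 7891L * spec$subject_id, {
    style <- list(height_scale = runif(1, 0.92, 1.08),
                  leg_scale = runif(1, 0.9, 1.1),
                  arm_scale = runif(1, 0.9, 1.1),
                  phase0 = runif(1, 0, 2 * pi))
    bg <- matrix(0.5, H, W)
    if (spec$clutter) {
      for (i in 1:3) {
        p0 <- c(runif(1, 1, H), runif(1, 1, W))
        ang <- runif(1, 0, pi)
        len <- runif(1, 10, 30)
        p1 <- p0 + len * c(cos(ang), sin(ang))
        bg <- draw_segment(bg, p0, p1, width = runif(1, 2, 5), ink = 0.35)
      }
    }
    frames <- array(0, c(Tn, H, W))
    joints <- vector("list", Tn)
    x0 <- if (spec$gait_speed > 0) 0.15 * W else 0.5 * W
    for (t in seq_len(Tn) - 1L) {
      xc <- (x0 + spec$gait_speed * t) %% W
      pose <- figure_pose(spec, t, style, xc)
      img <- bg
      widths <- c(torso = 3, thigh1 = 4.5, shin1 = 4.5, thigh2 = 4.5,
                  shin2 = 4.5, uarm1 = 2.2, farm1 = 2.2, uarm2 = 2.2,
                  farm2 = 2.2)
      for (nm in names(pose$segments)) {
        sg <- pose$segments[[nm]]
        img <- draw_segment(img, sg[[1]], sg[[2]], width = widths[[nm]],
                            ink = 0.05)
      }
      img <- draw_disc(img, pose$head$c, pose$head$r, ink = 0.05)
      if (spec$noise_sigma > 0)
        img <- img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
      frames[t + 1L, , ] <- pmin(pmax(img, 0), 1)
      joints[[t + 1L]] <- pose$joints
    }
    structure(list(frames = frames, label = spec$action,
                   subject_id = spec$subject_id, fps = 25, joints = joints,
                   spec = spec),
              class = "video_stack")
  })
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("video_stack: %s, subject %d, %d frames of %dx%d\n",
              x$label, x$subject_id, d[1], d[2], d[3]))
  invisible(x)
}

#' @export
plot.video_stack <- function(x, frame = 1L, ...) {
  f <- x$frames[frame, , ]
  graphics::image(t(f[nrow(f):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(f) / ncol(f),
                  main = sprintf("%s, frame %d", x$label, frame), ...)
  invisible(x)
}

#' Generate a labelled synthetic dataset
#'
#' One video per subject per action; subject identity perturbs limb lengths
#' and proportions (style variation) and offsets every video's seed, so
#' distinct seeds give distinct pixel content.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param actions character vector of action classes; default all six.
#' @param frames_per_video frames per video; default 40.
#' @param seed integer base seed.
#' @param frame_shape,noise_sigma,clutter passed to [action_spec()].
#' @param subject_offset added to every subject id (so independently
#'   generated datasets can carry disjoint subject identities).
#' @return An object of class `action_dataset` with `videos` (list of
#'   `video_stack`) and a `manifest` data frame (video id, label, subject,
#'   seed).
#' @export
make_dataset <- function(n_subjects, actions = action_classes,
                         frames_per_video = 40L, seed = 1L,
                         frame_shape = c(142L, 200L), noise_sigma = 0.02,
                         clutter = FALSE, subject_offset = 0L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (!all(actions %in% action_classes)) stopf("unknown action in `actions`")
  videos <- list()
  rows <- list()
  vid <- 0L
  for (s in seq_len(n_subjects) + as.integer(subject_offset)) {
    for (ai in seq_along(actions)) {
      vid <- vid + 1L
      vseed <- (seed * 20011L + s * 131L + ai) %% 2147483647L
      spec <- action_spec(actions[ai], n_frames = frames_per_video,
                          frame_shape = frame_shape,
                          noise_sigma = noise_sigma, clutter = clutter,
                          seed = vseed, subject_id = s)
      videos[[vid]] <- render_action(spec)
      rows[[vid]] <- data.frame(video_id = vid, label = actions[ai],
                                subject_id = s, seed = vseed)
    }
  }
  structure(list(videos = videos, manifest = do.call(rbind, rows),
                 actions = actions),
            class = "action_dataset")
}

#' @export
print.action_dataset <- function(x, ...) {
  cat(sprintf("action_dataset: %d videos, %d classes, %d subjects\n",
              length(x$videos), length(unique(x$manifest$label)),
              length(unique(x$manifest$subject_id))))
  invisible(x)
}

#' Oriented-bar test image
#'
#' A single anti-aliased bar on a uniform background whose axis is rotated by
#' `orientation` radians clockwise from the vertical, matching the
#' dictionary's orientation convention (index 0 = vertical). A zero-length
#' bar gives a blank image.
#'
#' @param orientation bar angle in radians.
#' @param length,width bar dimensions in pixels.
#' @param shape image shape `c(height, width)`; default `c(32, 32)`.
#' @param noise additive Gaussian noise sd; default 0.
#' @param seed seed for the noise.
#' @return Numeric matrix in `[0, 1]`.
#' @export
make_bar_image <- function(orientation, length = 16, width = 3,
                           shape = c(32L, 32L), noise = 0, seed = 1L) {
  img <- matrix(0.5, shape[1], shape[2])
  if (length > 0) {
    ctr <- (shape + 1) / 2
    d <- c(cos(orientation), -sin(orientation))   # (row, col) axis direction
    p0 <- ctr - length / 2 * d
    p1 <- ctr + length / 2 * d
    img <- draw_segment(img, p0, p1, width = width, ink = 0.05)
  }
  if (noise > 0)
    img <- with_seed(seed,
                     pmin(pmax(img + matrix(rnorm(prod(shape), 0, noise),
                                            shape[1], shape[2]), 0), 1))
  img
}

#' Translated texture pair with known ground-truth flow
#'
#' A smooth random texture and its circular (wrap-padded) shift by an
#' integer pixel offset, so the true flow is `u = shift[2]`,
#' `v = shift[1]` everywhere away from the wrap seam.
#'
#' @param shift integer `c(row_shift, col_shift)` in pixels.
#' @param shape image shape; default `c(64, 64)`.
#' @param seed texture seed.
#' @return A list with `frame_prev`, `frame_next` and `shift`.
#' @export
make_translation_pair <- function(shift, shape = c(64L, 64L), seed = 1L) {
  if (any(shift != round(shift))) stopf("`shift` must be integer-valued")
  shift <- as.integer(shift)
  tex <- with_seed(seed, matrix(rnorm(prod(shape)), shape[1], shape[2]))
  tex <- cpp_gauss_blur(tex, 2)
  tex <- (tex - min(tex)) / max(max(tex) - min(tex), 1e-12)
  roll <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- ((seq_len(nr) - 1L - dr) %% nr) + 1L
    ci <- ((seq_len(nc) - 1L - dc) %% nc) + 1L
    m[ri, ci]
  }
  list(frame_prev = tex, frame_next = roll(tex, shift[1], shift[2]),
       shift = shift)
}
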