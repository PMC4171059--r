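# synthetic action videos: determinism, geometry, motion separability

test_that("rendering is bit-deterministic in the spec and seed", {
  sp <- action_spec("boxing", n_frames = 6, seed = 17, frame_shape = c(64, 80))
  v1 <- render_action(sp)
  v2 <- render_action(sp)
  expect_identical(v1$frames, v2$frames)
  v3 <- render_action(action_spec("boxing", n_frames = 6, seed = 18,
                                  frame_shape = c(64, 80)))
  expect_false(identical(v1$frames, v3$frames))
  expect_true(all(v1$frames >= 0 & v1$frames <= 1))
  expect_equal(dim(v1$frames), c(6, 64, 80))
})

test_that("action specs validate their kinematic invariants", {
  expect_error(action_spec("moonwalk"), "unknown")
  expect_error(action_spec("waving", gait_speed = 2), "gait_speed = 0")
  expect_error(action_spec("running", gait_speed = 0), "gait_speed > 0")
  # default ordering walking < jogging < running in speed and frequency
  gs <- sapply(c("walking", "jogging", "running"),
               function(a) action_spec(a)$gait_speed)
  expect_true(all(diff(gs) > 0))
  fr <- sapply(c("walking", "jogging", "running"),
               function(a) action_spec(a)$limb_frequency)
  expect_true(all(diff(fr) > 0))
})

test_that("walking leg joints stay in the lower half of the figure box", {
  v <- render_action(action_spec("walking", n_frames = 10, seed = 4))
  for (j in v$joints) {
    ys <- sapply(j, function(p) p[1])
    mid <- (min(ys) + max(ys)) / 2
    expect_gt(j$knee1[1], mid)
    expect_gt(j$knee2[1], mid)
    expect_gt(j$foot1[1], mid)
    expect_gt(j$foot2[1], mid)
  }
})

test_that("figure silhouette area is conserved across frames", {
  for (a in c("running", "clapping")) {
    v <- render_action(action_spec(a, n_frames = 12, seed = 6,
                                   noise_sigma = 0))
    areas <- apply(v$frames, 1, function(f) sum(f < 0.3))
    expect_lt((max(areas) - min(areas)) / mean(areas), 0.15)
  }
})

# halves are taken over the person's silhouette box (intensity threshold),
# the stable reference for where on the body the motion happens
figure_box <- function(frame) {
  idx <- which(frame < 0.35, arr.ind = TRUE)
  c(range(idx[, 1]), range(idx[, 2]))
}

bottom_energy_fraction <- function(action, seed) {
  v <- render_action(action_spec(action, n_frames = 10, seed = seed))
  fr <- numeric(0)
  for (t in 2:9) {
    fl <- estimate_flow(v$frames[t, , ], v$frames[t + 1, , ],
                        flow_params(warps_per_level = 2,
                                    inner_iterations = 6))
    e <- flow_energy(fl$forward)
    bb <- figure_box(v$frames[t, , ])
    mid <- floor((bb[1] + bb[2]) / 2)
    fr <- c(fr, sum(e[(mid + 1):bb[2], bb[3]:bb[4]]) /
                  max(sum(e[bb[1]:bb[2], bb[3]:bb[4]]), 1e-12))
  }
  mean(fr)
}

test_that("flow energy separates upper- from lower-limb classes", {
  expect_gt(bottom_energy_fraction("running", 21), 0.6)
  expect_gt(bottom_energy_fraction("walking", 22), 0.6)
  expect_gt(bottom_energy_fraction("jogging", 25), 0.6)
  expect_lt(bottom_energy_fraction("waving", 23), 0.4)
  expect_lt(bottom_energy_fraction("clapping", 24), 0.4)
  expect_lt(bottom_energy_fraction("boxing", 26), 0.4)
})

test_that("waving concentrates flow in the top half of most frames", {
  v <- render_action(action_spec("waving", n_frames = 12, seed = 31))
  top_wins <- 0
  for (t in 1:11) {
    fl <- estimate_flow(v$frames[t, , ], v$frames[t + 1, , ],
                        flow_params(warps_per_level = 2,
                                    inner_iterations = 6))
    e <- flow_energy(fl$forward)
    bb <- figure_box(v$frames[t, , ])
    mid <- floor((bb[1] + bb[2]) / 2)
    top <- sum(e[bb[1]:mid, bb[3]:bb[4]])
    bot <- sum(e[(mid + 1):bb[2], bb[3]:bb[4]])
    if (top > bot) top_wins <- top_wins + 1
  }
  expect_gte(top_wins / 11, 0.7)
})

test_that("static background pixels carry almost no estimated flow", {
  v <- render_action(action_spec("boxing", n_frames = 4, seed = 41,
                                 noise_sigma = 0.01))
  fl <- estimate_flow(v$frames[2, , ], v$frames[3, , ])
  e <- flow_energy(fl$forward)
  expect_lt(max(e[1:25, 1:50]), 0.2)      # far corner, no figure
})

test_that("datasets are balanced, labelled and hash-distinct", {
  ds <- make_dataset(3, frames_per_video = 4, seed = 9,
                     frame_shape = c(40, 56))
  expect_length(ds$videos, 18)
  expect_equal(as.integer(table(ds$manifest$label)), rep(3L, 6))
  expect_equal(anyDuplicated(sapply(ds$videos, function(v)
    sum(v$frames * seq_along(v$frames)))), 0)
  expect_equal(nrow(ds$manifest), 18)
})

test_that("bar and translation fixtures have their constructed ground truth", {
  b <- make_bar_image(0, length = 0)
  expect_true(all(b == 0.5))              # zero-length bar is blank
  p <- make_translation_pair(c(1, 3), c(32, 32), seed = 2)
  expect_identical(p$frame_next[10, 10], p$frame_prev[9, 7])
  expect_error(make_translation_pair(c(0.5, 1)), "integer")
})

test_that("video stacks round-trip through PNG frame directories", {
  v <- render_action(action_spec("clapping", n_frames = 3, seed = 12,
                                 frame_shape = c(32, 40)))
  dir <- file.path(tempdir(), "vid_roundtrip")
  write_video_stack(v, dir)
  w <- read_video_stack(dir)
  expect_equal(dim(w$frames), dim(v$frames))
  expect_equal(w$label, "clapping")
  expect_lt(max(abs(w$frames - v$frames)), 1 / 255)  # 8-bit quantisation
  unlink(dir, recursive = TRUE)
})
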