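# prototype extraction (eigenimages + clustering) and subject splits

test_that("well-separated clusters map to one prototype each", {
  set.seed(80)
  centers <- lapply(1:5, function(i) matrix(10 * i, 6, 6))
  frames <- list()
  owner <- integer(0)
  for (i in 1:5) for (r in 1:4) {
    frames[[length(frames) + 1L]] <- centers[[i]] + matrix(rnorm(36, 0, 0.05), 6, 6)
    owner <- c(owner, i)
  }
  ex <- extract_prototypes(frames, k = 5, seed = 3)
  expect_length(ex$prototypes, 5)
  # bijection: the 5 selected frames come from 5 different clusters
  expect_setequal(owner[ex$indices], 1:5)
  # indices pairwise distinct
  expect_equal(anyDuplicated(ex$indices), 0)
})

test_that("degenerate and edge cases behave as documented", {
  same <- replicate(8, matrix(2, 4, 4), simplify = FALSE)
  ex <- extract_prototypes(same, k = 5, seed = 1)
  expect_length(ex$prototypes, 5)
  for (p in ex$prototypes) expect_equal(p, matrix(0.25, 4, 4))  # unit-norm
  expect_error(extract_prototypes(same[1:3], k = 5), "at least")
  # every prototype is unit-norm
  set.seed(81)
  frames <- replicate(9, matrix(rnorm(25), 5, 5), simplify = FALSE)
  ex <- extract_prototypes(frames, k = 5, seed = 2)
  for (p in ex$prototypes) expect_equal(sum(p^2), 1, tolerance = 1e-12)
})

test_that("extraction is invariant to frame order up to relabelling", {
  set.seed(82)
  frames <- list()
  for (i in 1:3) for (r in 1:4)
    frames[[length(frames) + 1L]] <- matrix(5 * i, 4, 4) +
      matrix(rnorm(16, 0, 0.05), 4, 4)
  ex1 <- extract_prototypes(frames, k = 3, seed = 9)
  perm <- c(7, 2, 11, 4, 1, 12, 3, 10, 5, 8, 6, 9)
  ex2 <- extract_prototypes(frames[perm], k = 3, seed = 9)
  canon <- function(ex) {
    m <- sapply(ex$prototypes, function(p) round(as.numeric(p), 6))
    m[, order(colSums(m))]
  }
  expect_equal(canon(ex1), canon(ex2))
})

test_that("prototype banks serialise bit-exactly", {
  set.seed(83)
  frames <- replicate(6, matrix(rnorm(16), 4, 4), simplify = FALSE)
  bank <- prototype_bank(list(a = frames, b = frames), k = 3, seed = 1)
  path <- tempfile(fileext = ".txt")
  write_prototypes(bank, path)
  b2 <- read_prototypes(path)
  expect_identical(bank$classes, b2$classes)
  for (cl in bank$classes)
    for (j in seq_len(bank$k))
      expect_identical(bank$prototypes[[cl]][[j]], b2$prototypes[[cl]][[j]])
})

test_that("train_split is subject-disjoint, exhaustive and reproducible", {
  ds <- make_dataset(6, actions = c("walking", "waving"),
                     frames_per_video = 4, seed = 3,
                     frame_shape = c(32, 40))
  sp <- train_split(ds, n_train_subjects = 2, seed = 5)
  tr_subj <- unique(sapply(sp$train$videos, function(v) v$subject_id))
  te_subj <- unique(sapply(sp$test$videos, function(v) v$subject_id))
  expect_length(intersect(tr_subj, te_subj), 0)
  expect_setequal(c(tr_subj, te_subj), 1:6)
  expect_equal(length(sp$train$videos) + length(sp$test$videos), 12)
  sp2 <- train_split(ds, n_train_subjects = 2, seed = 5)
  expect_identical(sp$train_subjects, sp2$train_subjects)
  expect_error(train_split(ds, n_train_subjects = 9, seed = 1), "subjects")
})
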