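# Gabor dictionary, filter bank, whitening, MAX pooling, SSA and scoring

test_that("dictionary geometry follows theta = k*pi/n and m x n counts", {
  d <- gabor_dictionary(8, 1, 17)
  expect_equal(d$thetas, (0:7) * pi / 8)
  expect_length(d$kernels[[1]], 8)
  d2 <- gabor_dictionary(8, 2, 17)
  expect_equal(sum(lengths(d2$kernels)), 16)
  d1 <- gabor_dictionary(1, 1, 5)
  expect_length(d1$kernels[[1]], 1)
  expect_equal(d1$thetas, 0)
  # zero-mean even part, unit norm both parts
  for (k in d$kernels[[1]]) {
    expect_lt(abs(mean(k$even)), 1e-14)
    expect_equal(sum(k$even^2), 1, tolerance = 1e-12)
    expect_equal(sum(k$odd^2), 1, tolerance = 1e-12)
  }
  expect_error(gabor_dictionary(0, 1, 17), "n_orientations")
  expect_error(gabor_dictionary(8, 1, 16), "odd")
})

test_that("convolve_bank is the full zero-padded convolution of the bank", {
  d <- gabor_dictionary(4, 1, 5)
  img <- matrix(0, 10, 10)
  st <- convolve_bank(img, d, normalize = FALSE)
  expect_equal(dim(st$energy[[1]]), c(14L, 14L, 4L))   # 10 + 5 - 1
  expect_true(all(st$energy[[1]] == 0))                # linearity at zero
  set.seed(11)
  img <- matrix(rnorm(100), 10, 10)
  st <- convolve_bank(img, d, normalize = FALSE)
  for (o in c(1L, 3L)) {
    k <- d$kernels[[1]][[o]]
    ref <- brute_convolve(img, k$even, k$odd)
    expect_lt(max(abs(st$raw[[1]][, , o] - ref)), 1e-8)
    expect_lt(max(abs(st$energy[[1]][, , o] - Mod(ref)^2)), 1e-8)
  }
})

test_that("whitening transform is bounded, monotone and constant on flat input", {
  d <- gabor_dictionary(4, 1, 5)
  set.seed(2)
  st <- convolve_bank(matrix(runif(64), 8, 8), d, normalize = FALSE)
  sw <- sigmoid_whiten(st, saturation = 6, local_norm_window = 15)
  tr <- sw$transformed[[1]]
  expect_true(all(tr >= 0 & tr <= 6))
  # monotone in |c|^2 at fixed local energy: same pixel, across orientations
  e <- st$energy[[1]][5, 5, ]
  o <- order(e)
  expect_equal(order(tr[5, 5, ][o]), seq_along(o))
  # uniform energy map -> all transformed values equal the closed form
  st2 <- st
  st2$energy[[1]][] <- 2.5
  sw2 <- sigmoid_whiten(st2, saturation = 6, local_norm_window = 15,
                        epsilon = 0)
  expect_equal(as.numeric(sw2$transformed[[1]]),
               rep(6 * tanh(1), length(sw2$transformed[[1]])),
               tolerance = 1e-12)
  # zero raw response stays zero
  st3 <- st
  st3$energy[[1]][] <- 0
  expect_true(all(sigmoid_whiten(st3)$transformed[[1]] == 0))
})

test_that("local_max_response equals exhaustive enumeration with tie-breaks", {
  d <- gabor_dictionary(4, 1, 5)
  set.seed(3)
  st <- sigmoid_whiten(convolve_bank(matrix(rnorm(81), 9, 9), d,
                                     normalize = FALSE))
  for (i in 1:20) {
    el <- gabor_element(sample(0:12, 1), sample(0:12, 1), sample(0:3, 1),
                        0, d)
    got <- local_max_response(st, el, perturb_radius = 2, perturb_orient = 1)
    ref <- brute_local_max(st$transformed[[1]], el$row, el$col,
                           el$orientation_index, 2, 1)
    expect_identical(got$value, ref$value)
    expect_identical(c(got$row, got$col, got$orientation_index), ref$arg)
  }
  # constant map: the constant, argmax at smallest lexicographic index
  stc <- st
  stc$transformed[[1]][] <- 1.5
  el <- gabor_element(5, 5, 2, 0, d)
  got <- local_max_response(stc, el, 2, 1)
  expect_equal(got$value, 1.5)
  expect_equal(c(got$row, got$col, got$orientation_index), c(3, 3, 1))
  expect_error(local_max_response(st, gabor_element(100, 3, 0, 0, d)),
               "lattice")
})

test_that("SSA recovers bar orientations and respects inhibition", {
  d <- small_dict()
  for (k in c(0L, 2L, 5L)) {
    img <- make_bar_image(k * pi / 8, length = 20, width = 3)
    tpl <- ssa_train(list(img), d, 1)
    expect_equal(tpl$elements$orientation_index, k)
    # element sits on the bar: distance of centre to image centre is small
    half <- d$half_sizes[1]
    expect_lt(abs(tpl$elements$row[1] - half - 15.5), 6)
  }
  # n_elements = 0 -> empty template, score 0
  img <- make_bar_image(0, 20, 3)
  t0 <- ssa_train(list(img), d, 0)
  expect_equal(nrow(t0$elements), 0)
  expect_equal(match_score(t0, sigmoid_whiten(convolve_bank(img, d))), 0)
  # "+" fixture: one vertical and one horizontal element
  plus <- pmin(make_bar_image(0, 20, 3), make_bar_image(pi / 2, 20, 3))
  tpl <- ssa_train(list(plus, plus), d, 2)
  expect_setequal(tpl$elements$orientation_index, c(0L, 4L))
  # inhibition: selected pairs are separated in space or orientation
  tpl8 <- ssa_train(list(plus), d, 8)
  els <- tpl8$elements
  half <- d$half_sizes[1]
  n <- d$n_orientations
  for (i in seq_len(nrow(els) - 1)) for (j in (i + 1):nrow(els)) {
    dist2 <- (els$row[i] - els$row[j])^2 + (els$col[i] - els$col[j])^2
    dori <- abs(els$orientation_index[i] - els$orientation_index[j])
    dori <- min(dori, n - dori)
    expect_true(dist2 >= half^2 || dori > 1)
  }
  expect_error(ssa_train(list(), d, 1), "non-empty")
})

test_that("a uniform flow prior leaves SSA selection unchanged", {
  d <- small_dict()
  plus <- pmin(make_bar_image(0, 20, 3), make_bar_image(pi / 2, 20, 3))
  t1 <- ssa_train(list(plus), d, 4)
  t2 <- ssa_train(list(plus), d, 4, flow_prior = matrix(3.7, 32, 32))
  expect_identical(t1$elements, t2$elements)
  expect_equal(t1$weights, t2$weights)
})

test_that("a concentrated flow prior steers element selection", {
  d <- small_dict()
  b <- make_bar_image(0, 14, 3, shape = c(32, 32))
  two_bars <- matrix(0.5, 32, 64)
  two_bars[, 1:32] <- b               # identical bars left and right
  two_bars[, 33:64] <- b
  prior <- matrix(0, 32, 64)
  prior[, 33:64] <- 1                 # motion only on the right bar
  tpl <- ssa_train(list(two_bars), d, 1, flow_prior = prior)
  half <- d$half_sizes[1]
  expect_gte(tpl$elements$col[1] - half, 32)
})

test_that("match score is additive over elements and shift-invariant", {
  d <- small_dict()
  img <- make_bar_image(0, 20, 3)
  tpl <- ssa_train(list(img), d, 3)
  st <- sigmoid_whiten(convolve_bank(img, d),
                       tpl$saturation, tpl$local_norm_window)
  s <- match_score(tpl, st)
  # term-by-term oracle
  terms <- vapply(seq_len(nrow(tpl$elements)), function(i) {
    el <- list(row = tpl$elements$row[i], col = tpl$elements$col[i],
               orientation_index = tpl$elements$orientation_index[i],
               scale_index = tpl$elements$scale_index[i])
    r <- local_max_response(st, el, tpl$perturb_radius, tpl$perturb_orient)
    tpl$weights[i] * r$value - tpl$log_z[i]
  }, numeric(1))
  expect_equal(s, sum(terms), tolerance = 1e-10)
  # score on the training image >= score on a blank image
  blank <- sigmoid_whiten(convolve_bank(matrix(0, 32, 32), d),
                          tpl$saturation, tpl$local_norm_window)
  expect_gte(s, match_score(tpl, blank))
  # translation within the perturbation radius leaves the score unchanged
  sh <- rbind(img[3:32, ], matrix(0.5, 2, 32))
  st_sh <- sigmoid_whiten(convolve_bank(sh, d),
                          tpl$saturation, tpl$local_norm_window)
  expect_equal(match_score(tpl, st_sh), s, tolerance = 1e-8)
  # dictionary geometry mismatch is an error
  d2 <- gabor_dictionary(4, 1, 17)
  st2 <- sigmoid_whiten(convolve_bank(img, d2))
  expect_error(match_score(tpl, st2), "geometry")
})

test_that("templates round-trip through the text archive bit-exactly", {
  d <- small_dict()
  img <- make_bar_image(pi / 4, 18, 3, noise = 0.05, seed = 2)
  tpl <- ssa_train(list(img), d, 4)
  path <- tempfile(fileext = ".txt")
  write_template(tpl, path)
  t2 <- read_template(path)
  expect_identical(tpl$elements, t2$elements)
  expect_identical(tpl$weights, t2$weights)
  expect_identical(tpl$lambdas, t2$lambdas)
  expect_identical(tpl$log_z, t2$log_z)
  expect_identical(tpl$background$q, t2$background$q)
  # a reloaded template scores identically with its rebuilt dictionary
  st <- sigmoid_whiten(convolve_bank(img, template_dictionary(t2)),
                       t2$saturation, t2$local_norm_window)
  expect_identical(match_score(tpl, st), match_score(t2, st))
})
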