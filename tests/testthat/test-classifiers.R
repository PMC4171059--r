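# ELM: hidden nodes, closed-form training, prediction; prototype matching

test_that("hidden node outputs match scalar closed forms", {
  set.seed(21)
  for (nt in c("sigmoid", "rbf", "wavelet")) {
    m <- elm(matrix(rnorm(20), 5, 4), c("a", "b", "a", "b", "a"), L = 3,
             node_type = nt, seed = 2)
    x <- rnorm(4)
    h <- hidden_output(m, x)
    for (i in 1:3) {
      ref <- switch(nt,
        sigmoid = 1 / (1 + exp(-(sum(m$a[i, ] * x) + m$b[i]))),
        rbf = exp(-m$b[i] * sum((x - m$a[i, ])^2)),
        wavelet = {
          z <- sqrt(sum((x - m$a[i, ])^2)) / m$b[i]
          (1 - z^2) * exp(-z^2 / 2)
        })
      expect_equal(h[i], ref, tolerance = 1e-12)
    }
  }
  # sigmoid node with a = 0, b = 0 gives g(0) = 0.5
  m <- elm(matrix(rnorm(8), 2, 4), c("a", "b"), L = 2, node_type = "sigmoid",
           seed = 3)
  m$a[1, ] <- 0; m$b[1] <- 0
  expect_equal(hidden_output(m, rnorm(4))[1], 0.5)
  # rbf apex: x == a_i gives exp(0) = 1; outputs in (0, 1]
  m <- elm(matrix(rnorm(8), 2, 4), c("a", "b"), L = 2, node_type = "rbf",
           seed = 3)
  expect_equal(hidden_output(m, m$a[1, ])[1], 1)
  expect_true(all(hidden_output(m, rnorm(4)) > 0 &
                  hidden_output(m, rnorm(4)) <= 1))
})

test_that("ELM interpolates distinct samples exactly when L >= N", {
  set.seed(31)
  X <- matrix(rnorm(5 * 3), 5, 3)
  y <- c("p", "q", "p", "q", "q")
  m <- elm(X, y, L = 20, node_type = "sigmoid", seed = 4)
  expect_equal(as.character(predict(m, X)), y)
  H <- actionrec:::elm_hidden_matrix(X, m$a, m$b, "sigmoid")
  Tm <- matrix(0, 5, 2); Tm[cbind(1:5, as.integer(factor(y)))] <- 1
  expect_lt(max(abs(H %*% m$beta_out - Tm)), 1e-6)
  # across 20 seeds (zero-error property holds with probability 1)
  for (s in 1:20) {
    ms <- elm(X, y, L = 20, node_type = "sigmoid", seed = s)
    expect_equal(as.character(predict(ms, X)), y)
  }
})

test_that("ELM solves XOR and degenerate cases", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  m <- elm(X, y, L = 20, node_type = "sigmoid", seed = 1)
  expect_equal(as.character(predict(m, X)), as.character(y))
  # N = 1 predicts its own label
  m1 <- elm(matrix(c(1, 2), 1, 2), "only", L = 5, node_type = "rbf", seed = 2)
  expect_equal(as.character(predict(m1, matrix(c(1, 2), 1, 2))), "only")
  expect_error(elm(X, y, L = 0, node_type = "sigmoid", seed = 1), "L")
  expect_error(predict(m, matrix(0, 2, 5)), "features")
})

test_that("training is deterministic in the seed and linear in the targets", {
  set.seed(44)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(c("u", "w"), 5)
  m1 <- elm(X, y, L = 15, node_type = "rbf", seed = 7)
  m2 <- elm(X, y, L = 15, node_type = "rbf", seed = 7)
  expect_identical(m1$a, m2$a)
  expect_identical(m1$beta_out, m2$beta_out)
  # scale-equivariance of the least-squares solution: solving H beta = 2T
  H <- actionrec:::elm_hidden_matrix(X, m1$a, m1$b, "rbf")
  Tm <- matrix(0, 10, 2); Tm[cbind(1:10, as.integer(factor(y)))] <- 1
  b1 <- actionrec:::pinv_solve(H, Tm)
  b2 <- actionrec:::pinv_solve(H, 2 * Tm)
  expect_equal(b2, 2 * b1, tolerance = 1e-10)
})

test_that("prediction scores equal the explicit H beta product", {
  set.seed(50)
  X <- matrix(rnorm(30), 6, 5)
  y <- rep(c("a", "b", "c"), 2)
  m <- elm(X, y, L = 12, node_type = "wavelet", seed = 9)
  Xt <- matrix(rnorm(20), 4, 5)
  S <- predict(m, Xt, type = "score")
  for (i in 1:4) {
    h <- hidden_output(m, Xt[i, ])
    for (j in 1:3) {
      ref <- sum(vapply(1:12, function(l) m$beta_out[l, j] * h[l], numeric(1)))
      expect_equal(unname(S[i, j]), ref, tolerance = 1e-10)
    }
  }
  # permuting sample order permutes predictions identically
  p <- c(3, 1, 4, 2)
  expect_identical(predict(m, Xt)[p], predict(m, Xt[p, ]))
})

test_that("prototype scores are normalised cross-correlations", {
  set.seed(60)
  frames <- lapply(1:6, function(i) matrix(rnorm(64), 8, 8))
  bank <- prototype_bank(list(go = frames[1:3], stop = frames[4:6]), k = 3,
                         seed = 1)
  p <- bank$prototypes$go[[1]]
  sc <- prototype_score(bank, p)
  expect_equal(unname(sc["go"]), 1, tolerance = 1e-10)   # autocorrelation
  expect_true(all(sc >= -1 & sc <= 1))
  # against a single prototype, a negated descriptor scores exactly -1
  bank1 <- prototype_bank(list(solo = frames[1:4]), k = 1, seed = 2)
  p1 <- bank1$prototypes$solo[[1]]
  expect_equal(unname(prototype_score(bank1, -p1)["solo"]), -1,
               tolerance = 1e-10)
  # direct-formula oracle
  x <- matrix(rnorm(64), 8, 8)
  sc <- prototype_score(bank, x)
  ref <- max(vapply(bank$prototypes$stop, function(pr) {
    xv <- as.numeric(x); pv <- as.numeric(pr)
    sum((xv - mean(xv)) * (pv - mean(pv))) /
      (length(xv) * sd(xv) * sd(pv)) * length(xv) / (length(xv) - 1)
  }, numeric(1)))
  expect_equal(unname(sc["stop"]), ref, tolerance = 1e-10)
  # zero-variance descriptor scores 0 everywhere
  expect_equal(unname(prototype_score(bank, matrix(1, 8, 8))), c(0, 0))
})

test_that("ELM models round-trip through the text archive bit-exactly", {
  set.seed(70)
  m <- elm(matrix(rnorm(40), 10, 4), rep(c("a", "b"), 5), L = 8,
           node_type = "wavelet", seed = 11)
  path <- tempfile(fileext = ".txt")
  write_elm(m, path)
  m2 <- read_elm(path)
  expect_identical(m$a, m2$a)
  expect_identical(m$b, m2$b)
  expect_identical(m$beta_out, m2$beta_out)
  expect_identical(m$classes, m2$classes)
  Xt <- matrix(rnorm(12), 3, 4)
  expect_identical(predict(m, Xt, type = "score"),
                   predict(m2, Xt, type = "score"))
})
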