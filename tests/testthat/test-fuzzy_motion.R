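# fuzzy motion cells: division, triangular memberships, temporal memory,
# winner-takes-all defuzzification

test_that("cell division conserves energy and respects support", {
  g <- cell_grid(c(20, 20))
  z <- flow_field(matrix(0, 20, 20), matrix(0, 20, 20))
  expect_equal(divide_flow(z, g), c(C1 = 0, C2 = 0, C3 = 0, C4 = 0))
  u <- matrix(0, 20, 20)
  u[15:20, ] <- 1                     # motion only in the bottom half
  f <- flow_field(u, matrix(0, 20, 20))
  ce <- divide_flow(f, g)
  expect_equal(unname(ce[1:2]), c(0, 0))
  expect_true(all(ce[3:4] > 0))
  set.seed(4)
  f <- flow_field(matrix(rnorm(400), 20, 20), matrix(rnorm(400), 20, 20))
  expect_equal(sum(divide_flow(f, g)), sum(flow_energy(f)), tolerance = 1e-9)
})

test_that("instantaneous memberships follow the configured triangles", {
  g <- cell_grid(c(20, 20))
  # peak at C3's centre with all energy in C3
  expect_equal(frame_membership(c(0, 0, 5, 0), g$centers[3, ], g),
               c(0, 0, 1, 0))
  expect_equal(frame_membership(c(0, 0, 0, 0), c(10, 10), g), rep(0, 4))
  # peak midway between C1 and C2 centres, equal energy split:
  # row triangle 1, column triangle 0.5, energy share 0.5 each
  mid <- (g$centers[1, ] + g$centers[2, ]) / 2
  mu <- frame_membership(c(3, 3, 0, 0), mid, g)
  expect_equal(mu[1], mu[2])
  expect_equal(mu[1], 0.5 * 0.5)
  expect_equal(unname(mu[3:4]), c(0, 0))
})

test_that("the membership update matches the closed form of its recurrence", {
  st <- membership_state(eta = 0.15, N = 25)
  st$mu <- c(0.5, 0, 0, 0); st$winner <- 1L
  st2 <- update_membership(st, c(0.2, 0, 0, 0))
  expect_equal(st2$mu[1], 0.6)                 # mu + eta (1 - mu)
  st$mu <- c(1, 0, 0, 0)
  expect_equal(update_membership(st, c(0.7, 0, 0, 0))$mu[1], 1) # fixed point
  # eta = 0 everywhere: state unchanged, counter incremented
  st3 <- update_membership(st, c(0, 0, 0, 0))
  expect_equal(st3$mu, st$mu)
  expect_equal(st3$k, st$k + 1L)
  # constant winner: mu(k) = 1 - (1 - eta)^k, and the memory cap stops growth
  st <- membership_state(eta = 0.15, N = 25)
  mus <- numeric(30)
  for (k in 1:30) {
    st <- update_membership(st, c(0.15, 0, 0, 0))
    mus[k] <- st$mu[1]
  }
  expect_equal(mus[1:25], 1 - 0.85^(1:25), tolerance = 1e-12)
  expect_equal(mus[26:30], rep(mus[25], 5))    # k capped at N
  expect_error(update_membership(st, c(0.5, 2, 0, 0)), "0, 1")
})

test_that("memberships stay in [0,1] under random admissible streams", {
  set.seed(99)
  st <- membership_state(eta = 0.3, N = 10)
  for (i in 1:10000) {
    st <- update_membership(st, runif(4))
    if (i %% 500 == 0) {
      expect_true(all(st$mu >= 0 & st$mu <= 1))
      expect_true(st$k >= 0 && st$k <= st$N)
    }
  }
  expect_true(all(st$mu >= 0 & st$mu <= 1))
})

test_that("a single spurious frame cannot displace an established winner", {
  for (eta in c(0.1, 0.2, 0.3)) {
    st <- membership_state(eta = eta)
    st$mu <- c(0, 0, 0.55, 0); st$winner <- 3L; st$k <- 5L
    flipped <- c(eta, 0, 0, 0)       # one frame with flow flipped to the top
    st2 <- update_membership(st, flipped)
    expect_equal(defuzzify(st2)$group, "lower")
  }
})

test_that("defuzzification picks the limb group by winner-takes-all", {
  st <- membership_state()
  st$mu <- c(0.1, 0.1, 0.9, 0.8)
  d <- defuzzify(st)
  expect_equal(d$group, "lower")
  expect_equal(d$confidence, 0.9)
  st$mu <- c(0.7, 0.6, 0.1, 0.0)
  expect_equal(defuzzify(st)$group, "upper")
  st$mu <- c(0, 0, 0, 0)
  d0 <- defuzzify(st)
  expect_equal(d0$group, "unknown")
  expect_equal(d0$confidence, 0)
  st$mu <- c(0.4, 0.1, 0.4, 0.2)
  expect_message(dt <- defuzzify(st), "tie")
  expect_equal(dt$group, "lower")
  expect_equal(dt$confidence, 0.5)
})

test_that("person bounding box tracks the energetic region", {
  e <- matrix(0, 30, 40)
  e[10:20, 5:15] <- 1
  expect_equal(person_bbox(e), c(10L, 20L, 5L, 15L))
  expect_equal(person_bbox(matrix(0, 30, 40)), c(1L, 30L, 1L, 40L))
})
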