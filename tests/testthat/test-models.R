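test_that("seed constructors validate and resolve regions", {
  expect_error(seed_vector(c(0, 0)), "positive")
  expect_error(seed_vector(c(-1, 1)), "nonnegative")
  atlas <- make_atlas(86)
  s <- unit_seed(atlas, "Hippocampus-L")
  expect_equal(sum(s$values), 1)
  expect_equal(which(s$values == 1) - 1L, resolve_regions(atlas, "Hippocampus-L"))
  bt <- bilateral_temporal_seed(atlas)
  expect_equal(sum(bt$values), sum(atlas$lobe == "temporal"))
  expect_true(all(bt$values[atlas$lobe != "temporal"] == 0))
})

test_that("model1 on the 2-node toy matches the hand-derived quarter pattern", {
  eig <- laplacian_eigensystem(toy2())
  est <- model1_atrophy(eig, c(1, 0), K = 2)
  expect_equal(est$values, c(1 / 4, -1 / 4), tolerance = 1e-12)
})

test_that("model1 annihilates the sqrt-degree seed and matches pinv at K = N", {
  conn <- rand_conn(8, 11)
  eig <- laplacian_eigensystem(conn)
  # seed proportional to u1 (sqrt of degree): orthogonal to all i >= 2 modes
  est <- model1_atrophy(eig, sqrt(conn$delta), K = 8)
  expect_lt(max(abs(est$values)), 1e-10)

  set.seed(11)
  x0 <- runif(8)
  est <- model1_atrophy(eig, x0, K = 8)
  expect_equal(est$values, drop(pinv_oracle(eig$L) %*% x0), tolerance = 1e-8)
})

test_that("model1 rejects out-of-range K", {
  eig <- laplacian_eigensystem(rand_conn(8, 1))
  expect_error(model1_atrophy(eig, rep(1, 8), K = 1), "K must be")
  expect_error(model1_atrophy(eig, rep(1, 8), K = 9), "K must be")
})

test_that("model2 closed form: zero at t = 0, 2-node analytic, t -> Inf limit", {
  eig <- laplacian_eigensystem(toy2())
  expect_equal(model2_atrophy(eig, c(1, 0), 0)$values, c(0, 0))
  for (tt in c(0.2, 1, 5)) {
    expect_equal(model2_atrophy(eig, c(1, 0), tt)$values,
                 (1 - exp(-2 * tt)) / 4 * c(1, -1), tolerance = 1e-12)
  }
  conn <- rand_conn(10, 13)
  eig <- laplacian_eigensystem(conn)
  set.seed(13)
  y0 <- runif(10)
  expect_equal(model2_atrophy(eig, y0, 1e4)$values,
               model1_atrophy(eig, y0, K = 10)$values, tolerance = 1e-6)
  expect_error(model2_atrophy(eig, y0, -1), "nonnegative")
})

test_that("model2 first-mode option adds the analytic limit term", {
  eig <- laplacian_eigensystem(toy2())
  y0 <- c(1, 0)
  tt <- 3
  base <- model2_atrophy(eig, y0, tt)$values
  with1 <- model2_atrophy(eig, y0, tt, include_first_mode = TRUE)$values
  u1 <- eig$U[, 1]
  expect_equal(with1 - base, tt * u1 * sum(u1 * y0), tolerance = 1e-12)
})

test_that("model2 trajectory equals pointwise calls and is mode-monotone", {
  conn <- rand_conn(10, 17)
  eig <- laplacian_eigensystem(conn)
  set.seed(17)
  y0 <- runif(10)
  grid <- default_t_grid()
  traj <- model2_trajectory(eig, y0, grid)
  expect_equal(dim(traj), c(10, 1000))
  expect_equal(traj[, 1], rep(0, 10))
  for (k in c(2, 57, 433, 900, 1000)) {
    expect_equal(traj[, k], model2_atrophy(eig, y0, grid[k])$values,
                 tolerance = 1e-12)
  }
  # projection on each non-null mode is nondecreasing along the grid
  for (i in 2:10) {
    proj <- drop(crossprod(eig$U[, i], traj))
    expect_true(all(diff(proj * sign(proj[1000])) >= -1e-12))
  }
  expect_error(model2_trajectory(eig, y0, numeric(0)), "nonempty")
  expect_error(model2_trajectory(eig, y0, c(2, 1)), "ascending")
})

test_that("both models are linear in the seed", {
  conn <- rand_conn(10, 19)
  eig <- laplacian_eigensystem(conn)
  set.seed(19)
  s1 <- runif(10)
  s2 <- runif(10)
  a <- 1.7
  b <- 0.4
  expect_equal(model1_atrophy(eig, a * s1 + b * s2, 6)$values,
               a * model1_atrophy(eig, s1, 6)$values +
                 b * model1_atrophy(eig, s2, 6)$values, tolerance = 1e-10)
  expect_equal(model2_atrophy(eig, a * s1 + b * s2, 2.5)$values,
               a * model2_atrophy(eig, s1, 2.5)$values +
                 b * model2_atrophy(eig, s2, 2.5)$values, tolerance = 1e-10)
})

test_that("small-t law: Phi2(t)/t approaches the mode-1-deflated seed", {
  conn <- rand_conn(10, 23)
  eig <- laplacian_eigensystem(conn)
  set.seed(23)
  y0 <- runif(10)
  u1 <- eig$U[, 1]
  expected <- y0 - u1 * sum(u1 * y0)
  got <- model2_atrophy(eig, y0, 1e-6)$values / 1e-6
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("limit law: corr(Phi2(t), full Phi1) tends to 1", {
  for (seed in c(29, 31)) {
    conn <- rand_conn(12, seed)
    eig <- laplacian_eigensystem(conn)
    set.seed(seed)
    y0 <- runif(12)
    full <- model1_atrophy(eig, y0, 12)$values
    r_small <- cor(model2_atrophy(eig, y0, 1)$values, full)
    r_large <- cor(model2_atrophy(eig, y0, 1e4)$values, full)
    expect_gt(r_large, 1 - 1e-6)
    expect_gt(r_large, r_small)
  }
})
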