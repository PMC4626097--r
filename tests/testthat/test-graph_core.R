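test_that("weighted degree is the row sum and rejects isolated regions", {
  expect_equal(unname(weighted_degree(toy2())), c(1, 1))
  expect_equal(unname(weighted_degree(toy3())), c(2, 3, 1))

  atlas <- toy3()$atlas
  C <- matrix(c(0, 2, 0, 2, 0, 0, 0, 0, 0), 3, byrow = TRUE)
  expect_error(connectome(C, atlas), "isolated region.*Mid")
})

test_that("connectome validation rejects bad matrices", {
  atlas <- toy2()$atlas
  expect_error(connectome(matrix(c(0, 1, 2, 0), 2), atlas), "not symmetric")
  expect_error(connectome(matrix(c(0, -1, -1, 0), 2), atlas), "nonnegative")
  expect_error(connectome(matrix(c(1, 1, 1, 0), 2), atlas), "diagonal")
})

test_that("normalized Laplacian matches hand-derived forms", {
  expect_equal(normalized_laplacian(toy2()),
               matrix(c(1, -1, -1, 1), 2), tolerance = 1e-14)
  # delta = (2, 3, 1): off-diagonals -2/sqrt(6) and -1/sqrt(3)
  L3 <- matrix(c(1, -2 / sqrt(6), 0,
                 -2 / sqrt(6), 1, -1 / sqrt(3),
                 0, -1 / sqrt(3), 1), 3, byrow = TRUE)
  expect_equal(normalized_laplacian(toy3()), L3, tolerance = 1e-14)
})

test_that("eigendecomposition: order, orthonormality, reconstruction, null mode", {
  for (seed in 1:5) {
    conn <- rand_conn(10, seed)
    eig <- laplacian_eigensystem(conn)
    n <- 10
    expect_false(is.unsorted(eig$lambdas))
    expect_equal(eig$lambdas[1], 0)
    expect_true(all(eig$lambdas >= 0 & eig$lambdas <= 2))
    expect_lt(max(abs(crossprod(eig$U) - diag(n))), 1e-10)
    expect_lt(max(abs(eig$U %*% (eig$lambdas * t(eig$U)) - eig$L)), 1e-10)
    # u1 proportional to sqrt(degree)
    u1 <- eig$U[, 1]
    ref <- sqrt(conn$delta) / sqrt(sum(conn$delta))
    expect_lt(max(abs(abs(u1) - ref)), 1e-10)
  }
})

test_that("eigendecompose 2x2 closed form and asymmetry error", {
  eig <- eigendecompose(matrix(c(1, -1, -1, 1), 2))
  expect_equal(eig$lambdas, c(0, 2), tolerance = 1e-14)
  expect_equal(abs(eig$U[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(abs(eig$U[, 2]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(abs(sum(eig$U[, 2] * c(1, -1))), sqrt(2), tolerance = 1e-12)
  expect_error(eigendecompose(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("disconnected graphs are flagged with a component count", {
  atlas <- make_atlas(4)
  C <- matrix(0, 4, 4)
  C[1, 3] <- C[3, 1] <- 1  # L pair
  C[2, 4] <- C[4, 2] <- 1  # R pair: two components
  conn <- connectome(C, atlas)
  expect_warning(laplacian_eigensystem(conn), "disconnected.*2")
})

test_that("diffuse: identity at 0, 2-node closed form, ODE oracle", {
  eig <- laplacian_eigensystem(toy2())
  x0 <- c(1, 0)
  expect_equal(diffuse(eig, x0, 0), x0, tolerance = 1e-14)
  for (tt in c(0.1, 0.5, 1, 3)) {
    expect_equal(diffuse(eig, x0, tt),
                 c((1 + exp(-2 * tt)) / 2, (1 - exp(-2 * tt)) / 2),
                 tolerance = 1e-12)
  }
  # numerical integration oracle on random graphs
  for (seed in 1:5) {
    conn <- rand_conn(10, seed)
    eig <- laplacian_eigensystem(conn)
    set.seed(seed + 100)
    x0 <- runif(10)
    for (tt in c(0.5, 2)) {
      expect_equal(diffuse(eig, x0, tt), ode_oracle(eig$L, x0, tt),
                   tolerance = 1e-8)
    }
  }
})

test_that("diffuse agrees with the matrix exponential", {
  conn <- rand_conn(12, 42)
  eig <- laplacian_eigensystem(conn)
  set.seed(7)
  x0 <- rnorm(12)
  E <- as.matrix(Matrix::expm(-1.7 * Matrix::Matrix(eig$L)))
  expect_equal(diffuse(eig, x0, 1.7), drop(E %*% x0), tolerance = 1e-9)
})

test_that("diffusion conserves the first-mode projection", {
  for (seed in 1:5) {
    conn <- rand_conn(10, seed)
    eig <- laplacian_eigensystem(conn)
    set.seed(seed)
    x0 <- runif(10)
    m0 <- sum(eig$U[, 1] * x0)
    for (tt in c(0.3, 1, 10, 100)) {
      expect_equal(sum(eig$U[, 1] * diffuse(eig, x0, tt)), m0,
                   tolerance = 1e-10)
    }
  }
})

test_that("diffuse is a semigroup", {
  conn <- rand_conn(10, 3)
  eig <- laplacian_eigensystem(conn)
  set.seed(3)
  x0 <- runif(10)
  lhs <- diffuse(eig, diffuse(eig, x0, 0.7), 1.3)
  expect_equal(lhs, diffuse(eig, x0, 2), tolerance = 1e-8)
})

test_that("model outputs are invariant to eigenvector sign flips", {
  conn <- rand_conn(10, 5)
  eig <- laplacian_eigensystem(conn)
  eig2 <- eig
  eig2$U[, c(2, 5, 9)] <- -eig2$U[, c(2, 5, 9)]
  set.seed(5)
  x0 <- runif(10)
  expect_equal(diffuse(eig, x0, 1.2), diffuse(eig2, x0, 1.2),
               tolerance = 1e-12)
  expect_equal(model1_atrophy(eig, x0, 7)$values,
               model1_atrophy(eig2, x0, 7)$values, tolerance = 1e-12)
  expect_equal(model2_atrophy(eig, x0, 4)$values,
               model2_atrophy(eig2, x0, 4)$values, tolerance = 1e-12)
})

test_that("connectome text round-trip preserves the matrix", {
  conn <- rand_conn(8, 9)
  path <- withr::local_tempfile(fileext = ".txt")
  write_connectome(conn, path)
  back <- read_connectome(path, conn$atlas)
  expect_equal(back$C, conn$C, tolerance = 1e-12)
})
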