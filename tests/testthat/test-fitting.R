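test_that("pearson_r matches hand values and cor.test", {
  expect_equal(pearson_r(1:5, 1:5)$R, 1)
  expect_equal(pearson_r(1:5, -(1:5))$R, -1)
  # hand derivation: centered a = (-1,0,1), b = (-4,-1,5)/3;
  # R = 3 / sqrt(2 * 14/3) = sqrt(27/28)
  pr <- pearson_r(c(1, 2, 3), c(1, 2, 4))
  expect_equal(pr$R, sqrt(27 / 28), tolerance = 1e-12)
  set.seed(1)
  a <- rnorm(20)
  b <- rnorm(20)
  ct <- cor.test(a, b)
  pr <- pearson_r(a, b)
  expect_equal(pr$R, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pr$p, ct$p.value, tolerance = 1e-10)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("fit_model1 recovers a planted interior K with R = 1", {
  conn <- rand_conn(12, 31)
  eig <- laplacian_eigensystem(conn)
  seed <- bilateral_temporal_seed(conn$atlas)
  planted <- model1_atrophy(eig, seed, K = 7)$values
  fit <- fit_model1(eig, seed, planted)
  expect_equal(fit$param$K, 7)
  expect_equal(fit$R, 1, tolerance = 1e-10)
  expect_equal(fit$curve$xs, 2:12)
  expect_lt(max(fit$curve$Rs[1:5], na.rm = TRUE), 1)
})

test_that("fit_model1 breaks exact ties toward the smaller K", {
  conn <- rand_conn(10, 37)
  eig <- laplacian_eigensystem(conn)
  # seed with spectral support only on modes 1 and 2: Phi1 identical for
  # every K >= 2, so all K tie at R = 1
  raw <- eig$U[, 1] * 2 + eig$U[, 2] * 0.3
  expect_true(all(raw > 0))
  planted <- model1_atrophy(eig, raw, K = 2)$values
  fit <- fit_model1(eig, seed_vector(raw), planted)
  expect_equal(fit$param$K, 2)
  expect_equal(fit$R, 1, tolerance = 1e-10)
})

test_that("sweep_model2 is exactly self-consistent on planted data", {
  conn <- rand_conn(10, 41)
  eig <- laplacian_eigensystem(conn)
  grid <- seq(0, 20, by = 0.5)
  t_true <- 6
  planted <- model2_atrophy(eig, unit_seed(conn$atlas, 3L), t_true)$values
  curve <- sweep_model2(eig, 3L, planted, grid)
  expect_true(is.na(curve$Rs[1]))  # t = 0 recorded missing
  expect_equal(curve$Rs[grid == t_true], 1, tolerance = 1e-10)
  sel <- select_tcrit(curve)
  expect_equal(sel$t_crit, t_true)
  # single-point grid equals a direct pearson_r
  one <- sweep_model2(eig, 3L, planted, 4)
  est <- model2_atrophy(eig, unit_seed(conn$atlas, 3L), 4)$values
  expect_equal(one$Rs, pearson_r(est, planted)$R, tolerance = 1e-12)
})

test_that("select_tcrit implements the shallow-depth discard rule", {
  # global max at admissible depth
  cv <- rcurve("diffusion_depth", c(1, 3, 5.56, 10, 50),
               c(0.1, 0.3, 0.9, 0.5, 0.2))
  sel <- select_tcrit(cv)
  expect_equal(sel$t_crit, 5.56)
  expect_equal(sel$flag, "global")
  # global max too shallow: highest admissible local maximum wins
  cv <- rcurve("diffusion_depth", c(0.5, 1.2, 2, 10, 40, 100, 200),
               c(0.2, 0.95, 0.3, 0.2, 0.6, 0.3, 0.1))
  sel <- select_tcrit(cv)
  expect_equal(sel$t_crit, 40)
  expect_equal(sel$flag, "local")
  # strictly increasing: last grid point, flagged monotone
  cv <- rcurve("diffusion_depth", c(1, 5, 10, 20), c(0.1, 0.2, 0.3, 0.4))
  sel <- select_tcrit(cv)
  expect_equal(sel$t_crit, 20)
  expect_equal(sel$flag, "monotone")
  # nothing to select
  cv <- rcurve("diffusion_depth", c(0, 1), c(NA, NA))
  expect_error(select_tcrit(cv), "missing")
})

test_that("fit_model2 finds the true seed and depth on noiseless data", {
  conn <- rand_conn(12, 43)
  eig <- laplacian_eigensystem(conn)
  grid <- seq(0, 30, by = 0.25)
  t_true <- 5
  true_seed <- 4L
  planted <- model2_atrophy(eig, unit_seed(conn$atlas, true_seed), t_true)$values
  fit <- fit_model2(eig, planted, t_grid = grid)
  expect_equal(fit$best$param$seed_region, true_seed)
  expect_equal(fit$best$R, 1, tolerance = 1e-8)
  expect_lt(abs(fit$best$param$t_crit - t_true), 0.25 + 1e-12)
  expect_equal(nrow(fit$table), 12)
})

test_that("fit_model2 honours a restricted seed subset", {
  conn <- make_connectome(synthetic_spec(), rng_seed = 5)
  eig <- laplacian_eigensystem(conn)
  atlas <- conn$atlas
  sub <- atlas$name[atlas$lobe == "subcortical" & atlas$hemisphere == "left"]
  expect_length(sub, 9)
  planted <- model2_atrophy(eig, unit_seed(atlas, "Hippocampus-L"), 5)$values
  fit <- fit_model2(eig, planted, t_grid = seq(0, 20, by = 0.5), seeds = sub)
  expect_equal(nrow(fit$table), 9)
  expect_equal(fit$best$param$seed_name, "Hippocampus-L")
})

test_that("true seed is recovered under the stated 25% pattern noise", {
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    conn <- make_connectome(synthetic_spec(), rng_seed = 300 + r)
    eig <- laplacian_eigensystem(conn)
    pat <- planted_pattern(synthetic_spec(), conn)
    set.seed(400 + r)
    measured <- pat + rnorm(length(pat), 0, 0.25 * sd(pat))
    fit <- fit_model2(eig, measured)
    hits <- hits + (fit$best$param$seed_name == "Hippocampus-L")
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("eigenmode_correlations peaks at the planted mode, sign-invariantly", {
  conn <- rand_conn(12, 47)
  eig <- laplacian_eigensystem(conn)
  set.seed(47)
  target <- eig$U[, 6] + rnorm(12, 0, 0.05)
  cv <- eigenmode_correlations(eig, target)
  expect_equal(cv$xs[which.max(cv$Rs)], 6)
  cv_neg <- eigenmode_correlations(eig, -target)
  expect_equal(cv$Rs, cv_neg$Rs, tolerance = 1e-12)
})

test_that("eigenmode correlations of pure noise sit at the null scale", {
  conn <- make_connectome(synthetic_spec(), rng_seed = 53)
  eig <- laplacian_eigensystem(conn)
  set.seed(53)
  for (r in 1:3) {
    cv <- eigenmode_correlations(eig, rnorm(86))
    expect_lt(max(cv$Rs), 0.5)  # null scale ~ 1/sqrt(86) ~ 0.11
  }
})

test_that("classify_curve separates planted shapes and flags flat curves", {
  conn <- rand_conn(12, 59)
  eig <- laplacian_eigensystem(conn)
  grid <- seq(0, 50, by = 0.25)
  p2 <- model2_atrophy(eig, unit_seed(conn$atlas, 2L), 4)$values
  expect_equal(
    as.character(classify_curve(sweep_model2(eig, 2L, p2, grid))),
    "peak_at_intermediate_t")
  p1 <- model1_atrophy(eig, unit_seed(conn$atlas, 2L), 12)$values
  expect_equal(
    as.character(classify_curve(sweep_model2(eig, 2L, p1, grid))),
    "monotone_increasing")
  flat <- rcurve("diffusion_depth", 1:5, rep(0.4, 5))
  cls <- classify_curve(flat)
  expect_equal(as.character(cls), "monotone_increasing")
  expect_true(attr(cls, "degenerate"))
  expect_error(classify_curve(rcurve("diffusion_depth", 1, 0.2)),
               "single-point")
})

test_that("fit R is invariant under positive affine transforms of the estimate", {
  conn <- rand_conn(10, 61)
  eig <- laplacian_eigensystem(conn)
  set.seed(61)
  measured <- rnorm(10)
  est <- model2_atrophy(eig, unit_seed(conn$atlas, 1L), 3)$values
  base <- pearson_r(est, measured)$R
  expect_equal(pearson_r(5 * est + 2, measured)$R, base, tolerance = 1e-12)
})

test_that("log_estimate_correlation handles zeros and rejects degenerate input", {
  conn <- rand_conn(10, 67)
  eig <- laplacian_eigensystem(conn)
  set.seed(67)
  measured <- rnorm(10)
  est <- model2_atrophy(eig, unit_seed(conn$atlas, 0L), 2)
  out <- log_estimate_correlation(est, measured)
  expect_true(is.finite(out$R))
  expect_gte(out$offset, -min(est$values))
  expect_error(log_estimate_correlation(rep(0, 10), measured), "all-zero")
  expect_error(log_estimate_correlation(rep(2, 10), measured), "constant")
})
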