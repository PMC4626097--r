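# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check: RK4 integration instead of the eigen closed form,
# SVD pseudo-inverse instead of the eigen-mode partial sum.

# 2-node unit-edge toy used throughout: L = [[1,-1],[-1,1]]
toy2 <- function() {
  atlas <- region_atlas(c("Temporal01-L", "Temporal01-R"),
                        hemisphere = c("left", "right"),
                        lobe = c("temporal", "temporal"),
                        homotopic = c(1L, 0L))
  connectome(matrix(c(0, 1, 1, 0), 2), atlas)
}

# 3-node path with weights 2 and 1 (hand-derived Laplacian in tests)
toy3 <- function() {
  atlas <- region_atlas(c("A-L", "A-R", "Mid"),
                        hemisphere = c("left", "right", "midline"),
                        lobe = c("temporal", "temporal", "subcortical"),
                        homotopic = c(1L, 0L, NA))
  connectome(matrix(c(0, 2, 0,
                      2, 0, 1,
                      0, 1, 0), 3, byrow = TRUE), atlas)
}

# random connected weighted graph on an even number of nodes (ring plus
# random chords, continuous weights => connected, simple spectrum a.s.)
rand_conn <- function(n = 10L, seed = 1L, chord_p = 0.3) {
  set.seed(seed)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    C[i, j] <- C[j, i] <- runif(1, 0.5, 2)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (C[i, j] == 0 && runif(1) < chord_p) {
        C[i, j] <- C[j, i] <- runif(1, 0.1, 1)
      }
    }
  }
  connectome(C, make_atlas(n))
}

# fixed-step RK4 integration of dx/dt = -L x, independent of eigen code
ode_oracle <- function(L, x0, t_end, n_steps = 4000L) {
  h <- t_end / n_steps
  x <- x0
  f <- function(x) -L %*% x
  for (s in seq_len(n_steps)) {
    k1 <- f(x)
    k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  drop(x)
}

# Moore-Penrose pseudo-inverse via SVD (tolerance-thresholded)
pinv_oracle <- function(L, tol = 1e-10) {
  s <- svd(L)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
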