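#' Structural connectome
#'
#' Wraps a symmetric nonnegative connectivity matrix `C` (e.g. streamline
#' counts between gray-matter regions) together with its region atlas and the
#' weighted degrees \eqn{\delta_i = \sum_j c_{ij}}. Diffusion MRI tractography
#' cannot resolve fiber directionality, so `C` must be symmetric; asymmetric
#' input is rejected rather than silently symmetrized.
#'
#' @param C numeric `N x N` matrix, symmetric, nonnegative, zero diagonal.
#' @param atlas a [region_atlas()] with `N` regions.
#' @param tol relative tolerance for the symmetry check.
#' @return An object of class `connectome`: list with elements `atlas`, `C`,
#'   `delta` (weighted degrees).
#' @export
connectome <- function(C, atlas, tol = 1e-8) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (ncol(C) != n) stop("C must be square")
  if (n != nrow(atlas)) stop("C dimension does not match atlas")
  if (any(!is.finite(C))) stop("C must be finite")
  if (any(C < 0)) stop("C must be nonnegative")
  scale <- max(abs(C), 1)
  if (max(abs(C - t(C))) > tol * scale) {
    stop("C is not symmetric; symmetrize upstream, never silently here")
  }
  C <- (C + t(C)) / 2  # remove float-level asymmetry only
  if (any(diag(C) != 0)) stop("C must have a zero diagonal (no self-loops)")
  delta <- rowSums(C)
  if (any(delta <= 0)) {
    stop("isolated region(s) with zero weighted degree: ",
         paste(atlas$name[delta <= 0], collapse = ", "))
  }
  structure(list(atlas = atlas, C = C, delta = delta), class = "connectome")
}

#' Weighted degree
#'
#' \eqn{\delta_i = \sum_j c_{ij}}, the sum of all connection weights at each
#' region. Strictly positive for every region of a valid connectome.
#'
#' @param conn a `connectome`.
#' @return numeric vector of length `N`, named by region.
#' @export
weighted_degree <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  stats::setNames(conn$delta, conn$atlas$name)
}

#' Symmetric normalized Laplacian
#'
#' \deqn{L = I - \Delta^{-1/2} C \Delta^{-1/2}}
#' with \eqn{\Delta = diag(\delta)}. Symmetric and positive semi-definite,
#' with eigenvalues in `[0, 2]`; its null space is spanned by
#' \eqn{(\sqrt{\delta_1}, \ldots, \sqrt{\delta_N})}.
#'
#' @param conn a `connectome`.
#' @return numeric `N x N` matrix.
#' @export
normalized_laplacian <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  s <- 1 / sqrt(conn$delta)
  L <- diag(nrow(conn$C)) - (s * conn$C) * rep(s, each = nrow(conn$C))
  (L + t(L)) / 2
}

#' Eigendecomposition of a Laplacian
#'
#' Eigenvalues in ascending order with orthonormal eigenvectors. Eigenvector
#' signs are fixed deterministically (first component of magnitude above
#' `1e-8` made positive) purely for reproducibility: every downstream model
#' quantity depends only on the outer products \eqn{u_i u_i'} and is invariant
#' to sign flips. Eigenvalues below `zero_tol` in magnitude are snapped to
#' exactly zero; more than one zero eigenvalue means the graph is
#' disconnected, which is reported as a warning (the eigen-mode formulas stay
#' valid but fits on such graphs should be interpreted with care).
#'
#' @param L symmetric matrix (a normalized Laplacian).
#' @param tol relative tolerance for the symmetry check.
#' @param zero_tol eigenvalues with `|lambda| < zero_tol` are treated as 0.
#' @return An object of class `laplacian_eigensystem`: list with `L`,
#'   `lambdas` (ascending), `U` (columns are eigen-modes), `n_zero_modes`.
#' @export
eigendecompose <- function(L, tol = 1e-8, zero_tol = 1e-10) {
  L <- as.matrix(L)
  if (max(abs(L - t(L))) > tol * max(abs(L), 1)) {
    stop("matrix is not symmetric within tolerance")
  }
  L <- (L + t(L)) / 2
  e <- eigen(L, symmetric = TRUE)
  ord <- rev(seq_along(e$values))  # eigen() returns decreasing order
  lambdas <- e$values[ord]
  U <- e$vectors[, ord, drop = FALSE]
  lambdas[abs(lambdas) < zero_tol] <- 0
  # deterministic sign convention
  for (j in seq_len(ncol(U))) {
    k <- which(abs(U[, j]) > 1e-8)[1]
    if (!is.na(k) && U[k, j] < 0) U[, j] <- -U[, j]
  }
  nz <- sum(lambdas == 0)
  if (nz > 1L) {
    warning(sprintf("graph appears disconnected: %d zero eigenvalues (%d components)",
                    nz, nz))
  }
  structure(list(L = L, lambdas = lambdas, U = U, n_zero_modes = nz),
            class = "laplacian_eigensystem")
}

#' Laplacian eigensystem of a connectome
#'
#' Convenience wrapper: [normalized_laplacian()] followed by
#' [eigendecompose()]; the result additionally carries the degree vector so
#' that the \eqn{u_1 \propto \sqrt{\delta}} invariant can be checked.
#'
#' @param conn a `connectome`.
#' @inheritParams eigendecompose
#' @return a `laplacian_eigensystem` with an extra `delta` element.
#' @export
laplacian_eigensystem <- function(conn, zero_tol = 1e-10) {
  eig <- eigendecompose(normalized_laplacian(conn), zero_tol = zero_tol)
  eig$delta <- conn$delta
  eig$atlas <- conn$atlas
  eig
}

#' Heat-kernel diffusion
#'
#' Evaluates the closed-form solution of the network diffusion equation
#' \eqn{dx/dt = -\beta L x}:
#' \deqn{x(t) = \sum_i e^{-\lambda_i \beta t} u_i (u_i' x_0).}
#' The rate constant is absorbed into the time axis, so `beta_t` is the
#' product \eqn{\beta t} (time in units of \eqn{1/\beta}). The dynamics are
#' mass conserving in the first eigen-mode: \eqn{u_1' x(t)} is constant.
#'
#' @param eig a `laplacian_eigensystem`.
#' @param x0 numeric length-`N` initial configuration.
#' @param beta_t nonnegative scalar diffusion depth.
#' @return numeric length-`N` vector `x(beta_t)`.
#' @export
diffuse <- function(eig, x0, beta_t) {
  stopifnot(inherits(eig, "laplacian_eigensystem"))
  if (length(beta_t) != 1L || !is.finite(beta_t) || beta_t < 0) {
    stop("beta_t must be a single nonnegative number")
  }
  x0 <- as.numeric(x0)
  if (length(x0) != length(eig$lambdas)) stop("x0 has wrong length")
  proj <- drop(crossprod(eig$U, x0))
  drop(eig$U %*% (exp(-eig$lambdas * beta_t) * proj))
}

#' Read / write a connectivity matrix
#'
#' Plain-text delimited `N x N` matrix (whitespace or comma separated), row
#' and column order matching the atlas file.
#'
#' @param path file path.
#' @param atlas a `region_atlas` giving region order.
#' @return `read_connectome` returns a `connectome`.
#' @export
read_connectome <- function(path, atlas) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  C <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(C) <- NULL
  connectome(C, atlas)
}

#' @rdname read_connectome
#' @param conn a `connectome` to write.
#' @export
write_connectome <- function(conn, path) {
  utils::write.table(conn$C, path, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d regions, %d edges, total weight %.4g\n",
              nrow(x$C), sum(x$C[upper.tri(x$C)] > 0), sum(x$C) / 2))
  invisible(x)
}

#' @export
print.laplacian_eigensystem <- function(x, ...) {
  n <- length(x$lambdas)
  cat(sprintf("laplacian_eigensystem: %d modes, lambda in [%.3g, %.3g], %d zero mode(s)\n",
              n, x$lambdas[1], x$lambdas[n], x$n_zero_modes))
  invisible(x)
}
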