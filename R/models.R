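#' Seed vectors
#'
#' A seed is the initial configuration of the diffusion process: where
#' epileptogenic hyperactivity (Model 1) or degeneration (Model 2)
#' originates. Single-node seeds are unit vectors; the canonical Model 1
#' seed puts ones on every temporal-lobe region of both hemispheres.
#'
#' @param values numeric length-`N` nonnegative vector with at least one
#'   strictly positive entry.
#' @param description provenance label, e.g. `"bilateral temporal"` or
#'   `"node: Hippocampus-L"`.
#' @return An object of class `seed_vector`.
#' @export
seed_vector <- function(values, description = "custom") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("seed values must be finite and nonnegative")
  }
  if (!any(values > 0)) stop("seed must have at least one positive entry")
  structure(list(values = values, description = description),
            class = "seed_vector")
}

#' @rdname seed_vector
#' @param atlas a `region_atlas`.
#' @param region a region name or 0-based region id.
#' @export
unit_seed <- function(atlas, region) {
  id <- resolve_regions(atlas, region)
  if (length(id) != 1L) stop("unit_seed takes exactly one region")
  v <- numeric(nrow(atlas))
  v[id + 1L] <- 1
  seed_vector(v, paste0("node: ", atlas$name[id + 1L]))
}

#' @rdname seed_vector
#' @export
bilateral_temporal_seed <- function(atlas) {
  v <- as.numeric(atlas$lobe == "temporal")
  if (!any(v > 0)) stop("atlas has no temporal regions")
  seed_vector(v, "bilateral temporal")
}

as_seed_values <- function(seed, n) {
  v <- if (inherits(seed, "seed_vector")) seed$values else as.numeric(seed)
  if (length(v) != n) stop("seed has wrong length")
  v
}

#' Model 1: time-integrated activity-spread atrophy
#'
#' Predicted atrophy from the excitotoxicity hypothesis: atrophy is
#' proportional to the lifetime integral of diffusing epileptogenic
#' activity, which evaluates to a partial eigen-mode expansion of the
#' Laplacian pseudo-inverse applied to the seed:
#' \deqn{\Phi_1 = \sum_{i=2}^{K} \frac{1}{\lambda_i} u_i (u_i' x_0).}
#' The first eigen-mode (uniform activation of the whole brain) is always
#' excluded: its eigenvalue is zero so its time integral diverges, and it
#' carries no topography. `K` counts the largest included mode index, so
#' `K = 68` means modes \eqn{u_2..u_{68}}. At `K = N` on a connected graph
#' the estimate equals the Moore-Penrose pseudo-inverse of `L` applied to
#' the seed. The overall \eqn{1/\beta} prefactor is a positive scale and is
#' dropped (correlations downstream are scale-invariant).
#'
#' @param eig a `laplacian_eigensystem`.
#' @param x0 a [seed_vector()] or numeric vector.
#' @param K integer in `[2, N]`: largest eigen-mode index included.
#' @param include_first_mode re-include the zero mode with its analytic
#'   divergent-limit surrogate removed; only meaningful for sensitivity
#'   analysis, default `FALSE`.
#' @return An object of class `atrophy_estimate` with elements `values`,
#'   `model = "model1"`, `params = list(K = K)`, `seed`.
#' @export
model1_atrophy <- function(eig, x0, K, include_first_mode = FALSE) {
  stopifnot(inherits(eig, "laplacian_eigensystem"))
  n <- length(eig$lambdas)
  if (length(K) != 1L || K != round(K) || K < 2 || K > n) {
    stop("K must be an integer in [2, N]")
  }
  v <- as_seed_values(x0, n)
  idx <- 2:K
  zero <- eig$lambdas[idx] == 0
  if (any(zero)) {
    warning("disconnected graph: skipping ", sum(zero),
            " additional zero eigen-mode(s) in Model 1 sum")
    idx <- idx[!zero]
  }
  proj <- drop(crossprod(eig$U[, idx, drop = FALSE], v))
  vals <- drop(eig$U[, idx, drop = FALSE] %*% (proj / eig$lambdas[idx]))
  if (include_first_mode) {
    # the i = 1 term's integral diverges; no finite surrogate exists for
    # Model 1, so re-inclusion is a no-op here (kept for interface symmetry)
    warning("Model 1 has no finite first-mode term; ignoring include_first_mode")
  }
  desc <- if (inherits(x0, "seed_vector")) x0$description else "custom"
  structure(list(values = vals, model = "model1", params = list(K = K),
                 seed = desc),
            class = "atrophy_estimate")
}

#' Model 2: time-resolved degenerative-spread atrophy
#'
#' Predicted atrophy from the deafferentation hypothesis: degeneration
#' diffuses from a seed and atrophy accumulates as its running time
#' integral, with closed form
#' \deqn{\Phi_2(t) = \sum_{i=2}^{N} \frac{1 - e^{-\lambda_i t}}{\lambda_i}
#'       u_i (u_i' y_0).}
#' Time is in units of \eqn{1/\gamma} (rate constant absorbed). At `t = 0`
#' the estimate is the zero vector; as \eqn{t \to \infty} it converges to
#' the full Model 1 pattern — the two models differ only in whether the
#' integral is taken to a finite depth or to infinity.
#'
#' The first eigen-mode is excluded by default: its closed-form term is the
#' analytic limit \eqn{t \, u_1 (u_1' y_0)}, which grows without bound and
#' would swamp the pattern, and dropping it preserves the stated
#' equivalence with Model 1 at \eqn{t = \infty}. Set
#' `include_first_mode = TRUE` to add that limit term back for sensitivity
#' analysis.
#'
#' @param eig a `laplacian_eigensystem`.
#' @param y0 a [seed_vector()] or numeric vector.
#' @param t nonnegative scalar diffusion depth.
#' @param include_first_mode add the analytic `t * u1 (u1' y0)` term.
#' @return An `atrophy_estimate` with `params = list(t = t)`.
#' @export
model2_atrophy <- function(eig, y0, t, include_first_mode = FALSE) {
  stopifnot(inherits(eig, "laplacian_eigensystem"))
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a single nonnegative number")
  }
  n <- length(eig$lambdas)
  v <- as_seed_values(y0, n)
  vals <- drop(model2_patterns(eig, v, t,
                               include_first_mode = include_first_mode))
  desc <- if (inherits(y0, "seed_vector")) y0$description else "custom"
  structure(list(values = vals, model = "model2", params = list(t = t),
                 seed = desc),
            class = "atrophy_estimate")
}

# Vectorized workhorse: N x length(t_grid) matrix of Phi_2 patterns.
# Mode 1 and any further numerically-zero modes are excluded (limit term
# t * u_i u_i' y0 optionally re-added for mode 1 only).
model2_patterns <- function(eig, v, t_grid, include_first_mode = FALSE) {
  lam <- eig$lambdas
  n <- length(lam)
  idx <- which(seq_len(n) >= 2L & lam > 0)
  proj <- drop(crossprod(eig$U[, idx, drop = FALSE], v))
  # G[i, k] = (1 - exp(-lambda_i t_k)) / lambda_i
  G <- outer(lam[idx], t_grid, function(l, tt) (1 - exp(-l * tt)) / l)
  out <- eig$U[, idx, drop = FALSE] %*% (G * proj)
  if (include_first_mode) {
    p1 <- sum(eig$U[, 1] * v)
    out <- out + outer(eig$U[, 1] * p1, t_grid)
  }
  out
}

#' Model 2 trajectory over a grid of diffusion depths
#'
#' Evaluates [model2_atrophy()] at every depth of an ascending grid in one
#' vectorized pass. Within each eigen-mode the coefficient
#' \eqn{(1 - e^{-\lambda_i t})/\lambda_i} is nondecreasing in `t`.
#'
#' @inheritParams model2_atrophy
#' @param t_grid ascending nonnegative depths.
#' @return numeric `N x length(t_grid)` matrix; column `k` is
#'   \eqn{\Phi_2(t_k)}. Carries attribute `t_grid`.
#' @export
model2_trajectory <- function(eig, y0, t_grid, include_first_mode = FALSE) {
  stopifnot(inherits(eig, "laplacian_eigensystem"))
  if (length(t_grid) == 0L) stop("t_grid must be nonempty")
  if (any(!is.finite(t_grid)) || any(t_grid < 0)) {
    stop("t_grid must be nonnegative")
  }
  if (is.unsorted(t_grid, strictly = FALSE)) stop("t_grid must be ascending")
  v <- as_seed_values(y0, length(eig$lambdas))
  out <- model2_patterns(eig, v, t_grid,
                         include_first_mode = include_first_mode)
  attr(out, "t_grid") <- t_grid
  out
}

#' Default diffusion-depth grid
#'
#' 900 evenly spaced samples on `[0, 100]` followed by 100 evenly spaced
#' samples on `[100.01, 500]` — dense where the correlation curves peak,
#' sparse in the asymptotic tail.
#'
#' @return numeric vector of 1000 depths.
#' @export
default_t_grid <- function() {
  c(seq(0, 100, length.out = 900), seq(100.01, 500, length.out = 100))
}

#' Export an atrophy estimate as region/value text
#' @param estimate an `atrophy_estimate`.
#' @param atlas a `region_atlas` (region order of the estimate).
#' @param path output file.
#' @export
write_estimate <- function(estimate, atlas, path) {
  df <- data.frame(region = atlas$name, value = estimate$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.atrophy_estimate <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("atrophy_estimate [%s] seed=%s %s; range [%.3g, %.3g]\n",
              x$model, x$seed, p, min(x$values), max(x$values)))
  invisible(x)
}
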