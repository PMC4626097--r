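#' Pearson correlation with two-sided p-value
#'
#' Plain Pearson R between two region patterns, with the two-sided p-value
#' from the t-transform \eqn{t = R\sqrt{(N-2)/(1-R^2)}} on `N - 2` degrees
#' of freedom. Constant inputs are an error (R undefined), never silently
#' `NA`.
#'
#' @param a,b numeric vectors of equal length `N >= 3`.
#' @return list with elements `R` and `p`.
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors must have equal length")
  n <- length(a)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant input vector: correlation undefined")
  }
  R <- stats::cor(a, b)
  if (abs(R) >= 1) {
    p <- 0
  } else {
    tt <- R * sqrt((n - 2) / (1 - R^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(R = R, p = p)
}

#' Correlation curve
#'
#' A sweep of Pearson correlations along one model axis: eigen-mode count
#' `K` (Model 1), diffusion depth `t` (Model 2), eigen-mode index, or seed
#' region.
#'
#' @param axis one of `"eigenmode_count"`, `"diffusion_depth"`,
#'   `"eigenmode_index"`, `"seed_region"`.
#' @param xs ascending axis values (or region ids).
#' @param Rs correlations, `NA` where undefined (e.g. at `t = 0` where the
#'   Model 2 estimate is the zero vector).
#' @return object of class `rcurve`.
#' @export
rcurve <- function(axis, xs, Rs) {
  axis <- match.arg(axis, c("eigenmode_count", "diffusion_depth",
                            "eigenmode_index", "seed_region"))
  if (length(xs) != length(Rs)) stop("xs and Rs must have equal length")
  if (any(!is.na(Rs) & abs(Rs) > 1 + 1e-12)) stop("Rs must lie in [-1, 1]")
  structure(list(axis = axis, xs = as.numeric(xs), Rs = as.numeric(Rs)),
            class = "rcurve")
}

# correlations of each column of M with vector y; columns with zero
# variance yield NA
cor_with_columns <- function(M, y) {
  suppressWarnings(drop(stats::cor(M, y)))
}

#' Fit Model 1 by the eigen-mode-count sweep
#'
#' Evaluates [model1_atrophy()] for every `K` in `[2, N]`, records the
#' Pearson correlation `R(K)` with the measured atrophy, and returns the
#' estimate at the `K` maximizing `R` (ties broken toward the smallest
#' `K`). The canonical seed puts ones on all temporal regions of both
#' hemispheres.
#'
#' @param eig a `laplacian_eigensystem`.
#' @param seed a [seed_vector()].
#' @param measured an `atrophy_vector` or numeric vector.
#' @param K_range integer range of mode counts to sweep (default `2:N`).
#' @return A `fit_result`: list with `model`, `estimate`, `R`, `p`,
#'   `param = list(K = best K)`, `curve` (the `R(K)` sweep).
#' @export
fit_model1 <- function(eig, seed, measured, K_range = NULL) {
  stopifnot(inherits(eig, "laplacian_eigensystem"))
  n <- length(eig$lambdas)
  if (is.null(K_range)) K_range <- 2:n
  if (any(K_range < 2 | K_range > n)) stop("K_range must lie in [2, N]")
  K_range <- sort(unique(as.integer(K_range)))
  y <- as_atrophy_values(measured)
  if (stats::sd(y) == 0) stop("measured atrophy is constant")
  v <- as_seed_values(seed, n)

  idx <- which(seq_len(n) >= 2L & eig$lambdas > 0)
  if (length(idx) < n - 1L) {
    warning("disconnected graph: zero eigen-modes beyond the first are skipped")
  }
  proj <- drop(crossprod(eig$U[, idx, drop = FALSE], v))
  contrib <- sweep(eig$U[, idx, drop = FALSE], 2,
                   proj / eig$lambdas[idx], "*")
  # cumulative partial sums over modes: Phi(K) = sum of contribs with mode <= K
  csum <- contrib %*% upper.tri(diag(length(idx)), diag = TRUE)
  # map each K to the number of included modes
  ninc <- vapply(K_range, function(K) sum(idx <= K), integer(1))
  Phi <- matrix(0, n, length(K_range))
  pos <- ninc > 0
  Phi[, pos] <- csum[, ninc[pos], drop = FALSE]
  Rs <- cor_with_columns(Phi, y)
  curve <- rcurve("eigenmode_count", K_range, Rs)
  best <- which(Rs == max(Rs, na.rm = TRUE))[1]  # smallest K on ties
  est <- model1_atrophy(eig, seed_vector(v, "model1 sweep"), K_range[best])
  pr <- pearson_r(est$values, y)
  structure(list(model = "model1", estimate = est, R = pr$R, p = pr$p,
                 param = list(K = K_range[best]), curve = curve),
            class = "fit_result")
}

#' Sweep Model 2 over diffusion depth for one seed region
#'
#' Places a unit seed at `seed_region`, evaluates \eqn{\Phi_2(t)} on the
#' grid and records `R(t)`. At `t = 0` the estimate is the zero vector and
#' `R` is undefined; it is recorded as `NA` (missing), not 0.
#'
#' @param eig a `laplacian_eigensystem` (must carry an atlas, as produced
#'   by [laplacian_eigensystem()], or pass `atlas`).
#' @param seed_region region name or 0-based id.
#' @param measured an `atrophy_vector` or numeric vector.
#' @param t_grid ascending depths, default [default_t_grid()].
#' @param atlas optional `region_atlas` override.
#' @return an `rcurve` on the diffusion-depth axis.
#' @export
sweep_model2 <- function(eig, seed_region, measured, t_grid = default_t_grid(),
                         atlas = NULL) {
  stopifnot(inherits(eig, "laplacian_eigensystem"))
  atlas <- atlas %||% eig$atlas
  if (is.null(atlas)) stop("an atlas is required to resolve the seed region")
  id <- resolve_regions(atlas, seed_region)
  y <- as_atrophy_values(measured)
  v <- numeric(length(eig$lambdas))
  v[id + 1L] <- 1
  Phi <- model2_patterns(eig, v, t_grid)
  Rs <- cor_with_columns(Phi, y)
  Rs[t_grid == 0] <- NA_real_
  rcurve("diffusion_depth", t_grid, Rs)
}

#' Select the critical diffusion depth from an R-vs-t curve
#'
#' The paper's selection rule: take the global maximum of `R(t)` unless it
#' occurs at too shallow a depth (`t < t_min`, default 3), where the
#' diffusion has not propagated meaningfully into the network; in that
#' case take the highest strict discrete local maximum with `t >= t_min`.
#' If no such local maximum exists (e.g. a monotone nondecreasing curve),
#' the last grid point is returned, flagged `"monotone"`.
#'
#' @param curve an `rcurve` on the diffusion-depth axis.
#' @param t_min threshold on the depth value below which global maxima are
#'   discarded.
#' @return list with `t_crit`, `R`, and `flag` (`"global"`, `"local"`,
#'   `"monotone"` or `"boundary"`).
#' @export
select_tcrit <- function(curve, t_min = 3) {
  stopifnot(inherits(curve, "rcurve"))
  if (curve$axis != "diffusion_depth") {
    stop("select_tcrit expects a diffusion-depth curve")
  }
  xs <- curve$xs
  Rs <- curve$Rs
  ok <- !is.na(Rs)
  if (!any(ok)) stop("all correlations missing: cannot select t_crit")
  gmax <- which(ok & Rs == max(Rs[ok]))[1]
  if (xs[gmax] >= t_min) {
    last <- max(which(ok))
    nondecr <- all(diff(Rs[ok]) >= -1e-15)
    flag <- if (Rs[gmax] == Rs[last] && nondecr) "monotone" else "global"
    return(list(t_crit = if (flag == "monotone") xs[last] else xs[gmax],
                R = Rs[gmax], flag = flag))
  }
  # strict discrete local maxima at admissible depth
  m <- length(Rs)
  loc <- logical(m)
  for (i in seq_len(m)) {
    if (!ok[i] || xs[i] < t_min) next
    left <- if (i > 1 && ok[i - 1]) Rs[i] > Rs[i - 1] else TRUE
    right <- if (i < m && ok[i + 1]) Rs[i] > Rs[i + 1] else TRUE
    loc[i] <- left && right && (i > 1 || i < m)
  }
  # exclude flat interior points masquerading as maxima at the boundary:
  # the last point only counts if the curve rose into it
  if (loc[m] && m >= 2 && ok[m - 1] && Rs[m] <= Rs[m - 1]) loc[m] <- FALSE
  if (any(loc)) {
    cand <- which(loc)
    best <- cand[which.max(Rs[cand])]
    flag <- if (best == m) "monotone" else "local"
    return(list(t_crit = xs[best], R = Rs[best], flag = flag))
  }
  # monotone nondecreasing (or no admissible local max): fall back
  adm <- which(ok & xs >= t_min)
  if (length(adm) == 0L) adm <- which(ok)
  last <- adm[length(adm)]
  best <- adm[which.max(Rs[adm])]
  if (best == last) {
    list(t_crit = xs[last], R = Rs[last], flag = "monotone")
  } else {
    list(t_crit = xs[best], R = Rs[best], flag = "boundary")
  }
}

#' Fit Model 2 by the per-seed sweep
#'
#' Repeats [sweep_model2()] + [select_tcrit()] for every candidate seed
#' region (all `N` by default, or a subset such as the ipsilateral
#' subcortical regions), and returns the per-seed table together with the
#' best fit: the seed maximizing the selected `R`, ties broken toward the
#' lowest region index.
#'
#' @inheritParams sweep_model2
#' @param seeds candidate seed regions (names or 0-based ids); default all.
#' @param t_min passed to [select_tcrit()].
#' @return list with `table` (data frame: `region_id`, `name`, `t_crit`,
#'   `R`, `flag`) and `best` (a `fit_result` with
#'   `param = list(seed_region, t_crit)` and the winning sweep as `curve`).
#' @export
fit_model2 <- function(eig, measured, t_grid = default_t_grid(),
                       seeds = NULL, t_min = 3, atlas = NULL) {
  stopifnot(inherits(eig, "laplacian_eigensystem"))
  atlas <- atlas %||% eig$atlas
  if (is.null(atlas)) stop("an atlas is required")
  ids <- if (is.null(seeds)) atlas$region_id else resolve_regions(atlas, seeds)
  ids <- sort(unique(ids))
  y <- as_atrophy_values(measured)

  rows <- vector("list", length(ids))
  curves <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    cv <- sweep_model2(eig, ids[k], y, t_grid, atlas = atlas)
    sel <- select_tcrit(cv, t_min = t_min)
    rows[[k]] <- data.frame(region_id = ids[k],
                            name = atlas$name[ids[k] + 1L],
                            t_crit = sel$t_crit, R = sel$R,
                            flag = sel$flag, stringsAsFactors = FALSE)
    curves[[k]] <- cv
  }
  tab <- do.call(rbind, rows)
  best_k <- which(tab$R == max(tab$R))[1]  # lowest region index on ties
  best_id <- tab$region_id[best_k]
  est <- model2_atrophy(eig, unit_seed(atlas, best_id), tab$t_crit[best_k])
  pr <- pearson_r(est$values, y)
  best <- structure(list(model = "model2", estimate = est, R = pr$R,
                         p = pr$p,
                         param = list(seed_region = best_id,
                                      seed_name = tab$name[best_k],
                                      t_crit = tab$t_crit[best_k]),
                         curve = curves[[best_k]]),
                    class = "fit_result")
  list(table = tab, best = best)
}

#' Per-eigen-mode correlations with measured atrophy
#'
#' For each eigen-mode index `i` in `[2, N]`, the absolute Pearson
#' correlation \eqn{|R(u_i, s)|}. The absolute value is used because an
#' eigenvector's sign is arbitrary.
#'
#' @inheritParams fit_model1
#' @return an `rcurve` on the eigen-mode-index axis.
#' @export
eigenmode_correlations <- function(eig, measured) {
  stopifnot(inherits(eig, "laplacian_eigensystem"))
  y <- as_atrophy_values(measured)
  n <- length(eig$lambdas)
  Rs <- abs(cor_with_columns(eig$U[, 2:n, drop = FALSE], y))
  rcurve("eigenmode_index", 2:n, Rs)
}

#' Classify an R-vs-t curve: peak or monotone
#'
#' The model-comparison criterion: Model 1 is Model 2 evaluated at
#' \eqn{t = \infty}, so a correlation curve that is monotonically
#' increasing in `t` (peaking at the end) favors Model 1, while a peak at
#' an intermediate depth favors Model 2. The curve is called
#' `monotone_increasing` iff `R(last) >= max(R) - eps` with
#' `eps = 1e-3` of the R range; a flat curve is monotone by convention and
#' flagged degenerate.
#'
#' @param curve an `rcurve` on the diffusion-depth axis with at least two
#'   non-missing points.
#' @param eps_frac tolerance as a fraction of the R range.
#' @return character scalar `"peak_at_intermediate_t"` or
#'   `"monotone_increasing"`, with logical attribute `"degenerate"`.
#' @export
classify_curve <- function(curve, eps_frac = 1e-3) {
  stopifnot(inherits(curve, "rcurve"))
  if (curve$axis != "diffusion_depth") {
    stop("classify_curve expects a diffusion-depth curve")
  }
  ok <- !is.na(curve$Rs)
  Rs <- curve$Rs[ok]
  if (length(Rs) < 2L) stop("cannot classify a single-point curve")
  rng <- max(Rs) - min(Rs)
  if (rng == 0) {
    out <- "monotone_increasing"
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- if (Rs[length(Rs)] >= max(Rs) - eps_frac * rng) {
    "monotone_increasing"
  } else {
    "peak_at_intermediate_t"
  }
  attr(out, "degenerate") <- FALSE
  out
}

#' Correlation of log-transformed estimate with measured atrophy
#'
#' Outlier-robustness check: correlates `log(estimate + offset)` with the
#' measured atrophy. The offset is 0 if all entries are already positive;
#' otherwise the estimate is shifted so its minimum lands at the smallest
#' positive spacing of the shifted values (keeping the log finite without
#' manufacturing an extreme outlier at the minimum).
#'
#' @param estimate an `atrophy_estimate` or numeric vector.
#' @param measured an `atrophy_vector` or numeric vector.
#' @return list with `R`, `p` and the `offset` used.
#' @export
log_estimate_correlation <- function(estimate, measured) {
  e <- if (inherits(estimate, "atrophy_estimate")) estimate$values
       else as.numeric(estimate)
  y <- as_atrophy_values(measured)
  if (all(e == 0)) stop("all-zero estimate: log correlation undefined")
  if (min(e) > 0) {
    offset <- 0
  } else {
    shifted <- e - min(e)
    pos <- shifted[shifted > 0]
    if (length(pos) == 0L) stop("constant estimate: log correlation undefined")
    offset <- -min(e) + min(pos)
  }
  pr <- pearson_r(log(e + offset), y)
  list(R = pr$R, p = pr$p, offset = offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rcurve <- function(x, ...) {
  ok <- !is.na(x$Rs)
  cat(sprintf("rcurve [%s]: %d points, R in [%.3f, %.3f]%s\n",
              x$axis, length(x$xs),
              if (any(ok)) min(x$Rs[ok]) else NA,
              if (any(ok)) max(x$Rs[ok]) else NA,
              if (all(ok)) "" else sprintf(" (%d missing)", sum(!ok))))
  invisible(x)
}

#' @export
print.fit_result <- function(x, ...) {
  p <- paste(names(x$param), unlist(x$param), sep = "=", collapse = ", ")
  cat(sprintf("fit_result [%s]: R = %.4f (p = %.3g), %s\n",
              x$model, x$R, x$p, p))
  invisible(x)
}
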