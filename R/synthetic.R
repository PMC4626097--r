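#' Synthetic-data specification
#'
#' The stated world for end-to-end validation: an 86-region bilateral
#' modular connectome (43 regions per hemisphere with a Desikan-Killiany
#' style lobe split: 11 frontal, 5 parietal, 4 occipital, 9 temporal, 5
#' cingulate, 9 subcortical) and a healthy/patient cohort whose patient
#' group carries atrophy planted by one of the two diffusion models from a
#' known seed.
#'
#' Planting: patient volumes are
#' `baseline_r * (1 - kappa * pattern_r) + measurement noise`, where the
#' pattern is the true model's prediction from the true seed,
#' max-normalized to 1, perturbed per patient by a Gaussian of standard
#' deviation `pattern_noise_frac * sd(pattern)` (subject-level disease
#' heterogeneity), and mirrored for right-focus patients so that
#' [side_flip()] must realign it. Baseline volumes are homotopically
#' symmetric, as real regional volumes nearly are.
#'
#' @param n_regions even region count, default 86.
#' @param n_healthy,n_patient cohort sizes (defaults 61 and 29, echoing a
#'   typical healthy/TLE-MTS cohort split).
#' @param true_model `"model1"` or `"model2"`.
#' @param true_seed region name seeded by the planted process; default the
#'   left hippocampus.
#' @param true_t diffusion depth of the planted Model 2 process (default 5).
#' @param true_K eigen-mode count of a planted Model 1 process (default
#'   `n_regions`, the full pseudo-inverse pattern).
#' @param kappa atrophy effect size: fraction of baseline volume removed per
#'   unit of normalized pattern (default 0.2, i.e. 20% loss at the seed).
#' @param baseline_range region baseline volumes are drawn uniformly from
#'   this range (mm^3).
#' @param baseline_cv per-subject measurement noise as a coefficient of
#'   variation of the region baseline (default 0.05).
#' @param pattern_noise_frac per-patient pattern noise, as a fraction of the
#'   planted pattern's standard deviation (default 0.25).
#' @param frac_right fraction of patients with a right-sided focus
#'   (default 0.5).
#' @param intra_lobe_density,intra_lobe_weight edge probability and weight
#'   scale within a lobe of one hemisphere.
#' @param inter_lobe_density,inter_lobe_weight between lobes, same
#'   hemisphere.
#' @param cross_density,cross_weight non-homotopic inter-hemispheric edges.
#' @param homotopic_weight weight scale of the always-present homotopic
#'   edges.
#' @param subcortical_boost multiplicative degree boost for edges touching
#'   subcortical regions (they are hubs).
#' @param rng_seed integer seed used by the generators when none is given
#'   explicitly.
#' @return object of class `synthetic_spec` (a named list).
#' @export
synthetic_spec <- function(n_regions = 86L,
                           n_healthy = 61L, n_patient = 29L,
                           true_model = c("model2", "model1"),
                           true_seed = NULL,
                           true_t = 5, true_K = NULL,
                           kappa = 0.2,
                           baseline_range = c(3000, 9000),
                           baseline_cv = 0.05,
                           pattern_noise_frac = 0.25,
                           frac_right = 0.5,
                           intra_lobe_density = 0.8, intra_lobe_weight = 1,
                           inter_lobe_density = 0.3, inter_lobe_weight = 0.3,
                           cross_density = 0.1, cross_weight = 0.1,
                           homotopic_weight = 0.8,
                           subcortical_boost = 2,
                           rng_seed = 1L) {
  true_model <- match.arg(true_model)
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L || n_regions %% 2L != 0L) {
    stop("n_regions must be an even integer >= 2")
  }
  if (kappa < 0 || kappa >= 1) stop("kappa must lie in [0, 1)")
  spec <- list(n_regions = n_regions, n_healthy = as.integer(n_healthy),
               n_patient = as.integer(n_patient), true_model = true_model,
               true_seed = true_seed, true_t = true_t,
               true_K = if (is.null(true_K)) n_regions else as.integer(true_K),
               kappa = kappa, baseline_range = baseline_range,
               baseline_cv = baseline_cv,
               pattern_noise_frac = pattern_noise_frac,
               frac_right = frac_right,
               intra_lobe_density = intra_lobe_density,
               intra_lobe_weight = intra_lobe_weight,
               inter_lobe_density = inter_lobe_density,
               inter_lobe_weight = inter_lobe_weight,
               cross_density = cross_density, cross_weight = cross_weight,
               homotopic_weight = homotopic_weight,
               subcortical_boost = subcortical_boost,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "synthetic_spec"
  spec
}

# subcortical region names, hippocampus first so it exists at any size
.subcortical_names <- c("Hippocampus", "Amygdala", "Thalamus", "VDC",
                        "Putamen", "Pallidum", "Caudate", "Accumbens",
                        "Cerebellum")

#' Synthetic bilateral atlas
#'
#' Left hemisphere occupies ids `0..m-1`, right hemisphere `m..2m-1`, with
#' region `i` homotopic to `i + m`. At the default 43 regions per
#' hemisphere the lobe split is 11 frontal / 5 parietal / 4 occipital /
#' 9 temporal / 5 cingulate / 9 subcortical; other sizes are allocated
#' proportionally (always keeping at least one temporal and one
#' subcortical region per hemisphere when there is room).
#'
#' @param n_regions even total region count.
#' @return a `region_atlas`.
#' @export
make_atlas <- function(n_regions = 86L) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L || n_regions %% 2L != 0L) {
    stop("n_regions must be an even integer >= 2")
  }
  m <- n_regions %/% 2L
  ref <- c(frontal = 11, parietal = 5, occipital = 4, temporal = 9,
           cingulate = 5, subcortical = 9)
  if (m == 1L) {
    counts <- c(temporal = 1L)
  } else if (m < 6L) {
    counts <- c(temporal = ceiling(m / 2), subcortical = floor(m / 2))
  } else {
    raw <- ref / sum(ref) * m
    counts <- floor(raw)
    rem <- m - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    counts <- counts[counts > 0]
  }
  lobes <- rep(names(counts), counts)
  nm <- character(m)
  for (lb in unique(lobes)) {
    ix <- which(lobes == lb)
    if (lb == "subcortical") {
      nm[ix] <- .subcortical_names[seq_along(ix)]
    } else {
      cap <- paste0(toupper(substring(lb, 1, 1)), substring(lb, 2))
      nm[ix] <- sprintf("%s%02d", cap, seq_along(ix))
    }
  }
  region_atlas(name = c(paste0(nm, "-L"), paste0(nm, "-R")),
               hemisphere = rep(c("left", "right"), each = m),
               lobe = rep(lobes, 2),
               homotopic = c(seq_len(m) - 1L + m, seq_len(m) - 1L))
}

#' Generate a synthetic connectome
#'
#' Bilateral modular weighted graph: dense strong blocks within each lobe
#' of each hemisphere, sparser weaker edges between lobes, always-present
#' homotopic inter-hemispheric edges, sparse weak non-homotopic crossings,
#' and a multiplicative degree boost for subcortical regions. Weights are
#' drawn from continuous log-normals, so the Laplacian spectrum is simple
#' with probability one. Regenerates (up to `max_tries`) until connected.
#'
#' @param spec a [synthetic_spec()].
#' @param rng_seed integer seed (defaults to `spec$rng_seed`).
#' @param max_tries connectivity retries before giving up.
#' @return a `connectome`.
#' @export
make_connectome <- function(spec, rng_seed = spec$rng_seed, max_tries = 20L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  atlas <- make_atlas(spec$n_regions)
  n <- nrow(atlas)
  m <- n %/% 2L
  set.seed(rng_seed)
  if (n == 2L) {
    return(connectome(matrix(c(0, 1, 1, 0), 2), atlas))
  }
  hemi <- atlas$hemisphere
  lobe <- atlas$lobe
  sub <- lobe == "subcortical"
  hom <- flip_permutation(atlas, strict = FALSE)

  for (try in seq_len(max_tries)) {
    C <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (hom[i] == j) {
          w <- spec$homotopic_weight * stats::rlnorm(1, 0, 0.3)
        } else if (hemi[i] == hemi[j] && lobe[i] == lobe[j]) {
          w <- if (stats::runif(1) < spec$intra_lobe_density) {
            spec$intra_lobe_weight * stats::rlnorm(1, 0, 0.4)
          } else 0
        } else if (hemi[i] == hemi[j]) {
          w <- if (stats::runif(1) < spec$inter_lobe_density) {
            spec$inter_lobe_weight * stats::rlnorm(1, 0, 0.4)
          } else 0
        } else {
          w <- if (stats::runif(1) < spec$cross_density) {
            spec$cross_weight * stats::rlnorm(1, 0, 0.4)
          } else 0
        }
        if (w > 0) {
          w <- w * sqrt(spec$subcortical_boost)^(sub[i] + sub[j])
          C[i, j] <- C[j, i] <- w
        }
      }
    }
    if (all(rowSums(C) > 0) && is_connected(C)) {
      return(connectome(C, atlas))
    }
  }
  stop("failed to generate a connected connectome after ", max_tries,
       " tries")
}

# BFS connectivity on a nonnegative symmetric matrix
is_connected <- function(C) {
  n <- nrow(C)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(C[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Planted atrophy pattern of a synthetic spec
#'
#' The true model's prediction from the true seed, max-normalized to 1,
#' in the canonical (left-focus) orientation.
#'
#' @param spec a [synthetic_spec()].
#' @param conn the `connectome` the cohort lives on.
#' @return numeric length-`N` pattern with `max == 1`.
#' @export
planted_pattern <- function(spec, conn) {
  eig <- laplacian_eigensystem(conn)
  atlas <- conn$atlas
  seed_name <- spec$true_seed %||% default_true_seed(atlas)
  sv <- unit_seed(atlas, seed_name)
  est <- if (spec$true_model == "model2") {
    model2_atrophy(eig, sv, spec$true_t)
  } else {
    model1_atrophy(eig, sv, spec$true_K)
  }
  pat <- est$values
  pat / max(pat)
}

default_true_seed <- function(atlas) {
  hit <- which(atlas$name == "Hippocampus-L")
  if (length(hit) == 1L) return(atlas$name[hit])
  sub <- which(atlas$lobe == "subcortical" & atlas$hemisphere == "left")
  if (length(sub) > 0) return(atlas$name[sub[1]])
  atlas$name[1]
}

#' Generate a synthetic cohort volumetrics table
#'
#' Healthy volumes are `Normal(baseline_r, baseline_cv * baseline_r)` per
#' region. Patient volumes carry the planted pattern (see
#' [synthetic_spec()]); right-focus patients receive the homotopically
#' mirrored pattern, so the raw group t-map is bilaterally diluted until
#' [side_flip()] realigns it.
#'
#' @param spec a [synthetic_spec()].
#' @param conn a `connectome` from [make_connectome()].
#' @param rng_seed integer seed (defaults to `spec$rng_seed`).
#' @return a `volumetrics_table` with attribute `"truth"`: list with
#'   `model`, `seed_name`, `seed_region` (0-based id), `t`, `K`,
#'   `pattern` (noiseless, left-oriented, max-normalized).
#' @export
make_cohort <- function(spec, conn, rng_seed = spec$rng_seed) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(conn, "connectome"))
  atlas <- conn$atlas
  n <- nrow(atlas)
  pat <- planted_pattern(spec, conn)
  seed_name <- spec$true_seed %||% default_true_seed(atlas)

  set.seed(rng_seed)
  p <- flip_permutation(atlas, strict = FALSE)
  pat_sd <- stats::sd(pat)

  # baselines are homotopically symmetric (as real regional volumes nearly
  # are); otherwise side-flipping injects baseline asymmetry into the t-map
  b0 <- stats::runif(n, spec$baseline_range[1], spec$baseline_range[2])
  baseline <- (b0 + b0[p]) / 2
  sd_r <- spec$baseline_cv * baseline

  nh <- spec$n_healthy
  np <- spec$n_patient
  n_right <- round(spec$frac_right * np)
  sides <- c(rep("right", n_right), rep("left", np - n_right))

  vols <- matrix(0, nh + np, n)
  for (s in seq_len(nh)) {
    vols[s, ] <- stats::rnorm(n, baseline, sd_r)
  }
  for (k in seq_len(np)) {
    # per-patient pattern heterogeneity on top of per-region measurement
    # noise; both are subject-level and average out across the group
    pk <- pat + stats::rnorm(n, 0, spec$pattern_noise_frac * pat_sd)
    if (sides[k] == "right") pk <- pk[p]
    vols[nh + k, ] <- baseline * (1 - spec$kappa * pk) +
      stats::rnorm(n, 0, sd_r)
  }
  if (any(vols <= 0)) {
    stop("generated nonpositive volumes: kappa or noise too large")
  }
  tab <- volumetrics_table(
    subject_id = c(sprintf("H%03d", seq_len(nh)), sprintf("P%03d", seq_len(np))),
    group = c(rep("healthy", nh), rep("patient", np)),
    focus_side = c(rep("none", nh), sides),
    volumes = vols
  )
  attr(tab, "truth") <- list(
    model = spec$true_model, seed_name = seed_name,
    seed_region = resolve_regions(atlas, seed_name),
    t = spec$true_t, K = spec$true_K,
    pattern = pat
  )
  tab
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the exact formats the pipeline reads: `connectome.txt` (delimited
#' matrix), `atlas.tsv`, `volumetrics.tsv`, plus `truth.tsv` (a sidecar
#' with the planted parameters and pattern).
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param rng_seed integer seed.
#' @return invisibly, the named list of file paths.
#' @export
write_synthetic_dataset <- function(spec, dir, rng_seed = spec$rng_seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conn <- make_connectome(spec, rng_seed = rng_seed)
  cohort <- make_cohort(spec, conn, rng_seed = rng_seed + 1L)
  truth <- attr(cohort, "truth")
  paths <- list(connectome = file.path(dir, "connectome.txt"),
                atlas = file.path(dir, "atlas.tsv"),
                volumetrics = file.path(dir, "volumetrics.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_connectome(conn, paths$connectome)
  write_atlas(conn$atlas, paths$atlas)
  write_volumetrics(cohort, conn$atlas, paths$volumetrics)
  tdf <- data.frame(region = conn$atlas$name, pattern = truth$pattern)
  con <- file(paths$truth, "w")
  writeLines(sprintf("# true_model=%s true_seed=%s seed_region=%d true_t=%g true_K=%d rng_seed=%d",
                     truth$model, truth$seed_name, truth$seed_region,
                     truth$t, truth$K, rng_seed), con)
  utils::write.table(tdf, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(paths)
}

#' Parameter-recovery experiment
#'
#' The validation harness: for each replicate, generate a connectome and
#' cohort, run the full pipeline (side-flip, t-statistics, both model
#' fits, curve classification, optionally reduced permutation nulls) and
#' record whether the planted truth is recovered.
#'
#' @param spec a [synthetic_spec()].
#' @param n_replicates number of independent replicates.
#' @param rng_seed base seed; replicate `i` uses `rng_seed + 1000 * i`.
#' @param t_grid diffusion-depth grid for Model 2 fitting.
#' @param n_iter_null permutations per null (0 skips the nulls).
#' @return data frame with one row per replicate (recovered seed, t_crit
#'   and relative error, fit correlations, curve class, winning model,
#'   null exceedances) carrying aggregate rates as attribute `"summary"`.
#' @export
run_recovery_experiment <- function(spec, n_replicates = 20L,
                                    rng_seed = spec$rng_seed,
                                    t_grid = default_t_grid(),
                                    n_iter_null = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sr <- rng_seed + 1000L * r
    conn <- make_connectome(spec, rng_seed = sr)
    cohort <- make_cohort(spec, conn, rng_seed = sr + 1L)
    truth <- attr(cohort, "truth")
    eig <- laplacian_eigensystem(conn)

    flipped <- side_flip(cohort, conn$atlas)
    measured <- measure_atrophy(flipped, conn$atlas)

    f1 <- fit_model1(eig, bilateral_temporal_seed(conn$atlas), measured)
    f2 <- fit_model2(eig, measured, t_grid = t_grid)
    cls <- classify_curve(f2$best$curve)
    winner <- if (cls == "peak_at_intermediate_t") "model2" else "model1"

    ex1 <- ex2 <- NA_real_
    if (n_iter_null > 0) {
      ex1 <- permutation_null_model1(eig, bilateral_temporal_seed(conn$atlas),
                                     measured, n_iter = n_iter_null,
                                     rng_seed = sr + 2L)$exceed_fraction
      ex2 <- permutation_null_model2(eig, f2$best$param$seed_region,
                                     measured, t_grid = t_grid,
                                     n_iter = n_iter_null,
                                     rng_seed = sr + 3L)$exceed_fraction
    }
    rows[[r]] <- data.frame(
      replicate = r,
      true_seed = truth$seed_name,
      recovered_seed = f2$best$param$seed_name,
      seed_correct = f2$best$param$seed_region == truth$seed_region,
      t_crit = f2$best$param$t_crit,
      t_rel_error = if (spec$true_model == "model2")
        abs(f2$best$param$t_crit - truth$t) / truth$t else NA_real_,
      R_model1 = f1$R, K_model1 = f1$param$K,
      R_model2 = f2$best$R,
      curve_class = as.character(cls),
      winner = winner,
      null_exceed_model1 = ex1, null_exceed_model2 = ex2,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    seed_recovery_rate = mean(out$seed_correct),
    class_match_rate = mean(out$winner == spec$true_model),
    mean_R_model2 = mean(out$R_model2),
    mean_t_rel_error = mean(out$t_rel_error)
  )
  out
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %d regions, cohorts %d/%d, true %s (seed=%s, t=%g), kappa=%g\n",
    x$n_regions, x$n_healthy, x$n_patient, x$true_model,
    x$true_seed %||% "<default hippocampus-left>", x$true_t, x$kappa))
  invisible(x)
}
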