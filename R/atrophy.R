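#' Cohort volumetrics table
#'
#' Subjects-by-regions gray-matter volumes with group labels. Healthy
#' subjects carry `focus_side = "none"`; patients carry the laterality of
#' their epileptogenic focus (`"left"` or `"right"`).
#'
#' @param subject_id character vector of subject ids (unique).
#' @param group character vector, `"healthy"` or `"patient"`.
#' @param focus_side character vector, `"left"`, `"right"` or `"none"`.
#' @param volumes numeric subjects x `N` matrix of positive region volumes
#'   (mm^3 or ICV-normalized fractions), columns in atlas order.
#' @return An object of class `volumetrics_table`: list with `subjects`
#'   data frame and `volumes` matrix.
#' @export
volumetrics_table <- function(subject_id, group, focus_side, volumes) {
  volumes <- as.matrix(volumes)
  ns <- length(subject_id)
  if (anyDuplicated(subject_id)) stop("subject ids must be unique")
  if (length(group) != ns || length(focus_side) != ns ||
      nrow(volumes) != ns) {
    stop("subject_id, group, focus_side and volumes rows must align")
  }
  group <- match.arg(group, c("healthy", "patient"), several.ok = TRUE)
  focus_side <- match.arg(focus_side, c("left", "right", "none"),
                          several.ok = TRUE)
  if (any(group == "healthy" & focus_side != "none")) {
    stop("healthy subjects must have focus_side = none")
  }
  if (any(group == "patient" & focus_side == "none")) {
    stop("patients must have focus_side left or right")
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("all volumes must be positive and non-missing")
  }
  structure(list(
    subjects = data.frame(subject_id = as.character(subject_id),
                          group = group, focus_side = focus_side,
                          stringsAsFactors = FALSE),
    volumes = volumes
  ), class = "volumetrics_table")
}

#' Side-flip patients to an ipsilateral-left convention
#'
#' Mirrors every right-focus patient by swapping each pair of homotopic
#' region columns, so that after flipping all patients have their focus on
#' the left ("ipsilateral") side. Healthy subjects and midline regions are
#' untouched; applying the flip twice restores the original table.
#'
#' @param table a `volumetrics_table`.
#' @param atlas a `region_atlas` providing the homotopic partner mapping;
#'   a non-midline region without a partner is an error.
#' @return a new `volumetrics_table` with every patient labeled
#'   `focus_side = "left"`.
#' @export
side_flip <- function(table, atlas) {
  stopifnot(inherits(table, "volumetrics_table"))
  if (ncol(table$volumes) != nrow(atlas)) {
    stop("volumetrics columns do not match atlas")
  }
  p <- flip_permutation(atlas, strict = TRUE)
  flip <- table$subjects$group == "patient" &
    table$subjects$focus_side == "right"
  vols <- table$volumes
  vols[flip, ] <- vols[flip, p, drop = FALSE]
  subj <- table$subjects
  subj$focus_side[subj$group == "patient"] <- "left"
  out <- table
  out$volumes <- vols
  out$subjects <- subj
  out
}

#' Optional ICV normalization
#'
#' Divides each subject's row by its intracranial volume, turning absolute
#' volumes into fractions. Off by default in the pipeline.
#'
#' @param table a `volumetrics_table`.
#' @param icv positive numeric vector, one value per subject.
#' @return a normalized `volumetrics_table`.
#' @export
icv_normalize <- function(table, icv) {
  stopifnot(inherits(table, "volumetrics_table"))
  icv <- as.numeric(icv)
  if (length(icv) != nrow(table$volumes) || any(!is.finite(icv)) ||
      any(icv <= 0)) {
    stop("icv must be one positive value per subject")
  }
  table$volumes <- table$volumes / icv
  table
}

#' Two-sample t-statistic atrophy vector
#'
#' Per-region unpooled (Welch-style) two-sample t-statistic
#' \deqn{s = \frac{\bar{x} - \bar{y}}
#'            {\sqrt{\sigma_x^2/n + \sigma_y^2/m}}}
#' with `x` the healthy group (size `n`) and `y` the patient group (size
#' `m`), sample variances with an `n - 1` denominator. Positive `s` means
#' smaller volumes in patients, i.e. atrophy. `s` is used downstream as a
#' spatial pattern, not for inference, so no degrees-of-freedom correction
#' is applied.
#'
#' @param healthy numeric `n x N` matrix of healthy-group volumes.
#' @param patient numeric `m x N` matrix of patient-group volumes.
#' @param region_names optional region labels for error messages.
#' @return An object of class `atrophy_vector`: list with `values`
#'   (length `N`) and `group_sizes = c(n_healthy, n_patient)`.
#' @export
two_sample_tstat <- function(healthy, patient, region_names = NULL) {
  healthy <- as.matrix(healthy)
  patient <- as.matrix(patient)
  if (ncol(healthy) != ncol(patient)) stop("region columns do not match")
  n <- nrow(healthy)
  m <- nrow(patient)
  if (n < 2L || m < 2L) stop("each group needs at least two subjects")
  xbar <- colMeans(healthy)
  ybar <- colMeans(patient)
  vx <- apply(healthy, 2, stats::var)
  vy <- apply(patient, 2, stats::var)
  den <- sqrt(vx / n + vy / m)
  if (any(den == 0)) {
    bad <- which(den == 0)
    lab <- if (is.null(region_names)) paste0("#", bad - 1L)
           else region_names[bad]
    stop("zero variance in both groups for region(s): ",
         paste(lab, collapse = ", "))
  }
  structure(list(values = (xbar - ybar) / den, group_sizes = c(n, m)),
            class = "atrophy_vector")
}

#' Measured atrophy from a cohort table
#'
#' Convenience wrapper: splits a (side-flipped) `volumetrics_table` into
#' healthy and patient groups and computes [two_sample_tstat()].
#'
#' @param table a `volumetrics_table`.
#' @param atlas optional `region_atlas` for region names in errors.
#' @return an `atrophy_vector`.
#' @export
measure_atrophy <- function(table, atlas = NULL) {
  stopifnot(inherits(table, "volumetrics_table"))
  h <- table$subjects$group == "healthy"
  two_sample_tstat(table$volumes[h, , drop = FALSE],
                   table$volumes[!h, , drop = FALSE],
                   region_names = if (!is.null(atlas)) atlas$name)
}

as_atrophy_values <- function(measured) {
  if (inherits(measured, "atrophy_vector")) measured$values
  else as.numeric(measured)
}

#' Read / write a volumetrics table
#'
#' Tab-separated, one row per subject: `subject_id`, `group`,
#' `focus_side`, then `N` region columns ordered as the atlas.
#'
#' @param path file path.
#' @param atlas a `region_atlas` (column order check).
#' @return `read_volumetrics` returns a `volumetrics_table`.
#' @export
read_volumetrics <- function(path, atlas) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("subject_id", "group", "focus_side")
  if (!all(meta %in% names(df))) {
    stop("volumetrics file must have columns subject_id, group, focus_side")
  }
  vols <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  if (ncol(vols) != nrow(atlas)) {
    stop(sprintf("volumetrics has %d region columns, atlas has %d regions",
                 ncol(vols), nrow(atlas)))
  }
  volumetrics_table(df$subject_id, df$group, df$focus_side, vols)
}

#' @rdname read_volumetrics
#' @param table a `volumetrics_table` to write.
#' @export
write_volumetrics <- function(table, atlas, path) {
  df <- cbind(table$subjects,
              as.data.frame(table$volumes))
  names(df)[-(1:3)] <- atlas$name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.volumetrics_table <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("volumetrics_table: %d subjects (%s) x %d regions\n",
              nrow(x$volumes),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              ncol(x$volumes)))
  invisible(x)
}

#' @export
print.atrophy_vector <- function(x, ...) {
  cat(sprintf("atrophy_vector: %d regions, t-stats in [%.3g, %.3g], groups n=%d/m=%d\n",
              length(x$values), min(x$values), max(x$values),
              x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}
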