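#' Region atlas
#'
#' A region atlas names the `N` gray-matter regions of a connectome and
#' carries, for each region, its hemisphere, its lobe, and (where one exists)
#' the index of its homotopic partner in the opposite hemisphere. Region ids
#' are 0-based to match the on-disk atlas format; all functions in this
#' package address regions through the atlas, never by bare column position.
#'
#' @param name character vector of region labels (unique).
#' @param hemisphere character vector, each one of `"left"`, `"right"`,
#'   `"midline"`.
#' @param lobe character vector, each one of `"frontal"`, `"parietal"`,
#'   `"occipital"`, `"temporal"`, `"cingulate"`, `"subcortical"`.
#' @param homotopic integer vector of 0-based partner region ids, `NA` for
#'   regions without a homotopic partner (only allowed on the midline). The
#'   mapping must be an involution: `flip(flip(r)) == r`.
#'
#' @return An object of class `region_atlas`: a data frame with columns
#'   `region_id` (0-based), `name`, `hemisphere`, `lobe`, `homotopic_index`.
#' @export
region_atlas <- function(name, hemisphere, lobe, homotopic = NULL) {
  n <- length(name)
  if (n < 1L) stop("atlas must contain at least one region")
  if (anyDuplicated(name)) stop("region names must be unique")
  hemisphere <- match.arg(hemisphere, c("left", "right", "midline"),
                          several.ok = TRUE)
  if (length(hemisphere) != n) stop("hemisphere must have one entry per region")
  lobe <- match.arg(lobe, c("frontal", "parietal", "occipital", "temporal",
                            "cingulate", "subcortical"), several.ok = TRUE)
  if (length(lobe) != n) stop("lobe must have one entry per region")
  if (is.null(homotopic)) homotopic <- rep(NA_integer_, n)
  homotopic <- as.integer(homotopic)
  if (length(homotopic) != n) stop("homotopic must have one entry per region")

  ok <- !is.na(homotopic)
  if (any(homotopic[ok] < 0L | homotopic[ok] >= n)) {
    stop("homotopic indices must be 0-based region ids")
  }
  # involution check: partner of my partner is me
  idx <- which(ok)
  partner <- homotopic[idx] + 1L
  if (any(is.na(homotopic[partner])) || any(homotopic[partner] != idx - 1L)) {
    stop("homotopic mapping is not an involution")
  }
  lr <- hemisphere[idx] != "midline"
  if (any(hemisphere[idx][lr] == hemisphere[partner][lr])) {
    stop("homotopic partners must lie in opposite hemispheres")
  }

  atlas <- data.frame(
    region_id = seq_len(n) - 1L,
    name = as.character(name),
    hemisphere = hemisphere,
    lobe = lobe,
    homotopic_index = homotopic,
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

#' Number of regions in an atlas
#' @param atlas a `region_atlas`.
#' @return integer region count.
#' @export
n_regions <- function(atlas) nrow(atlas)

#' Homotopic flip permutation
#'
#' Returns the 1-based permutation that maps every region to its homotopic
#' partner (regions without a partner map to themselves). Used by
#' [side_flip()] to mirror right-focus patients.
#'
#' @param atlas a `region_atlas`.
#' @param strict error if a non-midline region has no partner (the pipeline's
#'   default: a cortical region that cannot be mirrored breaks side-flipping).
#' @return integer vector `p` with `p[p] == seq_along(p)`.
#' @export
flip_permutation <- function(atlas, strict = TRUE) {
  h <- atlas$homotopic_index
  missing <- is.na(h) & atlas$hemisphere != "midline"
  if (strict && any(missing)) {
    stop("regions without a homotopic partner that are not midline: ",
         paste(atlas$name[missing], collapse = ", "))
  }
  p <- ifelse(is.na(h), atlas$region_id, h) + 1L
  p
}

#' Resolve region ids from names or ids
#'
#' @param atlas a `region_atlas`.
#' @param regions character region names or 0-based integer region ids.
#' @return 0-based integer region ids.
#' @export
resolve_regions <- function(atlas, regions) {
  if (is.character(regions)) {
    idx <- match(regions, atlas$name)
    if (anyNA(idx)) {
      stop("unknown region name(s): ",
           paste(regions[is.na(idx)], collapse = ", "))
    }
    return(atlas$region_id[idx])
  }
  regions <- as.integer(regions)
  if (any(regions < 0L | regions >= nrow(atlas))) {
    stop("region ids must lie in [0, N-1]")
  }
  regions
}

#' Read / write an atlas table
#'
#' Tab-separated with header `region_id  name  hemisphere  lobe
#' homotopic_index`; indices are 0-based (documented in a leading comment
#' line on write).
#'
#' @param path file path.
#' @return `read_atlas` returns a `region_atlas`.
#' @export
read_atlas <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("region_id", "name", "hemisphere", "lobe", "homotopic_index")
  if (!all(need %in% names(df))) {
    stop("atlas file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[order(df$region_id), ]
  if (!identical(as.integer(df$region_id), seq_len(nrow(df)) - 1L)) {
    stop("atlas region_id column must be 0..N-1")
  }
  region_atlas(df$name, df$hemisphere, df$lobe, df$homotopic_index)
}

#' @rdname read_atlas
#' @param atlas a `region_atlas` to write.
#' @export
write_atlas <- function(atlas, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# region_id and homotopic_index are 0-based", con)
  utils::write.table(as.data.frame(atlas), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("region_atlas: %d regions (%d left / %d right / %d midline)\n",
              nrow(x), sum(x$hemisphere == "left"),
              sum(x$hemisphere == "right"), sum(x$hemisphere == "midline")))
  cat("lobes:", paste(sprintf("%s=%d", names(table(x$lobe)), table(x$lobe)),
                      collapse = " "), "\n")
  invisible(x)
}
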