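#' Construct a parcellation descriptor
#'
#' A parcellation registers each region's system membership, hemisphere,
#' cortical inclusion flag, and centroid in world coordinates. Synthetic
#' parcellations use abstract spatial units; real ones carry millimetres from
#' a NIfTI affine — distances only ever enter correlations and binnings, so
#' the unit is immaterial.
#'
#' @param region_id Character vector of unique region labels.
#' @param system_id System label per region.
#' @param hemisphere One of `"left"`, `"right"`, `"midline"` per region.
#' @param include_flag Logical cortical-membership flag per region.
#' @param centroid Numeric matrix (regions x 3) of centroid coordinates, or
#'   `NULL` if unknown.
#' @return A tibble of class `ratmind_parcellation`.
#' @export
parcellation <- function(region_id, system_id,
                         hemisphere = rep("midline", length(region_id)),
                         include_flag = rep(TRUE, length(region_id)),
                         centroid = NULL) {
  if (anyDuplicated(region_id)) abort_invalid("`region_id` must be unique.")
  if (!all(hemisphere %in% c("left", "right", "midline"))) {
    abort_invalid("`hemisphere` must be 'left', 'right' or 'midline'.")
  }
  if (any(include_flag & (is.na(system_id) | system_id == ""))) {
    abort_invalid("Every included region must have a system.")
  }
  out <- tibble::tibble(
    region_id = as.character(region_id),
    system_id = as.character(system_id),
    hemisphere = hemisphere,
    include_flag = include_flag
  )
  if (!is.null(centroid)) {
    centroid <- as.matrix(centroid)
    stopifnot(nrow(centroid) == nrow(out), ncol(centroid) == 3L)
    out$x <- centroid[, 1L]; out$y <- centroid[, 2L]; out$z <- centroid[, 3L]
  }
  class(out) <- c("ratmind_parcellation", class(out))
  out
}

#' Derive a parcellation from generative region models
#'
#' Hemisphere is assigned by centroid position relative to the median
#' x-coordinate (metadata only; no hemispheric symmetrization is performed
#' anywhere in the pipeline).
#'
#' @param regions Tibble from [generate_parcellation()].
#' @return A [parcellation()] tibble with centroids.
#' @export
as_parcellation <- function(regions) {
  parcellation(
    region_id = regions$region_id,
    system_id = regions$system_id,
    hemisphere = ifelse(regions$x < median(regions$x), "left", "right"),
    include_flag = rep(TRUE, nrow(regions)),
    centroid = cbind(regions$x, regions$y, regions$z)
  )
}

#' Region centroids from a labelled volume
#'
#' Computes the internal center of each region in an integer label volume:
#' the arithmetic centroid of the region's voxel world-coordinates, snapped
#' to the nearest voxel belonging to that region, guaranteeing the reported
#' center lies inside (possibly non-convex) regions.
#'
#' Voxel indices are 0-based; world coordinates are `affine %*% c(i, j, k, 1)`.
#'
#' @param label_volume 3-D integer array of region codes (0 = background), or
#'   a path to a NIfTI file (requires the RNifti package, whose stored xform
#'   is then used as the affine).
#' @param affine 4x4 voxel-to-world affine. Defaults to identity spacing.
#' @param regions Integer region codes to locate. Defaults to all nonzero
#'   codes present.
#' @return Tibble with columns `region` (code), `x`, `y`, `z`.
#' @export
region_centroids <- function(label_volume, affine = NULL, regions = NULL) {
  if (is.character(label_volume)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort_invalid("Reading NIfTI paths requires the RNifti package.")
    }
    img <- RNifti::readNifti(label_volume)
    if (is.null(affine)) affine <- structure(RNifti::xform(img), class = NULL)
    label_volume <- array(as.integer(round(as.array(img))), dim = dim(img))
  }
  stopifnot(length(dim(label_volume)) == 3L)
  if (is.null(affine)) affine <- diag(4)
  affine <- unclass(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  codes <- regions %||% sort(setdiff(unique(as.vector(label_volume)), 0L))
  present <- codes %in% label_volume
  if (any(!present)) {
    abort(sprintf("Region code(s) absent from the volume: %s.",
                  paste(codes[!present], collapse = ", ")),
          class = "ratmind_missing_region")
  }
  rows <- purrr::map(codes, function(code) {
    idx <- which(label_volume == code, arr.ind = TRUE) - 1  # 0-based
    world <- cbind(idx, 1) %*% t(affine)
    world <- world[, 1:3, drop = FALSE]
    ctr <- colMeans(world)
    d2 <- rowSums(sweep(world, 2L, ctr)^2)
    snapped <- world[which.min(d2), ]
    tibble::tibble(region = code, x = snapped[1L], y = snapped[2L],
                   z = snapped[3L])
  })
  dplyr::bind_rows(rows)
}

#' Pairwise Euclidean distances between region centroids
#'
#' @param centroids Either a tibble with a label column (first column or
#'   `region_id`/`region`) plus `x`, `y`, `z`, or a numeric matrix
#'   (regions x 3) with rownames.
#' @return A symmetric, zero-diagonal labelled distance matrix (class
#'   `ratmind_distances`).
#' @examples
#' m <- rbind(a = c(0, 0, 0), b = c(3, 4, 0))
#' edge_distances(m)
#' @export
edge_distances <- function(centroids) {
  if (is.data.frame(centroids)) {
    lab_col <- intersect(c("region_id", "region"), names(centroids))[1L]
    if (is.na(lab_col)) lab_col <- names(centroids)[1L]
    m <- as.matrix(centroids[, c("x", "y", "z")])
    rownames(m) <- as.character(centroids[[lab_col]])
  } else {
    m <- as.matrix(centroids)
  }
  if (nrow(m) < 2L) abort_invalid("Need at least 2 regions.")
  if (any(!is.finite(m))) abort_invalid("All centroids must be finite.")
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(rownames(m), rownames(m))
  class(d) <- c("ratmind_distances", class(d))
  d
}

#' Write / read a parcellation descriptor as JSON
#'
#' @param parc A [parcellation()] tibble.
#' @param path JSON path.
#' @return `path` (write) or the parcellation (read).
#' @export
write_parcellation <- function(parc, path) {
  jsonlite::write_json(as.data.frame(parc), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroid <- if (all(c("x", "y", "z") %in% names(df))) {
    cbind(df$x, df$y, df$z)
  }
  parcellation(df$region_id, df$system_id, df$hemisphere, df$include_flag,
               centroid)
}
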