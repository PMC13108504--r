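new_mind_network <- function(weights, meta = list()) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights),
            !is.null(rownames(weights)))
  structure(list(weights = weights, nodes = rownames(weights), meta = meta),
            class = "mind_network")
}

#' Wrap a symmetric weight matrix as a MIND network
#'
#' For externally computed or synthetic weight matrices. The matrix must be
#' square and symmetric with labelled rows/columns, unit diagonal, and
#' off-diagonal weights in (0, 1].
#'
#' @param weights Labelled symmetric numeric matrix.
#' @param estimator Estimator tag stored in the metadata.
#' @return A `mind_network`.
#' @export
as_mind_network <- function(weights, estimator = "external") {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights))) {
    abort_invalid("`weights` must have row/column labels.")
  }
  if (!isSymmetric(unname(weights))) {
    abort_invalid("`weights` must be symmetric.")
  }
  off <- weights[upper.tri(weights)]
  if (any(off <= 0 | off > 1) || any(diag(weights) != 1)) {
    abort_invalid("Off-diagonal weights must be in (0, 1] with unit diagonal.")
  }
  new_mind_network(weights, meta = list(estimator = estimator))
}

#' Build a MIND similarity network from a voxel table
#'
#' Fits each region's Gaussian MTR distribution, computes the symmetrized KL
#' divergence between every unordered pair of regions, and fills the
#' symmetric edge-weight matrix `w = 1 / (1 + KLsym)` with unit diagonal.
#'
#' Two estimators are available. `"resampled"` (the default, and the
#' region-balancing procedure): draw `n_resamples` points from each fitted
#' Gaussian and estimate KL nonparametrically with a k-nearest-neighbour
#' density estimate, so regions of very different voxel counts contribute
#' equally. `"analytic"`: the closed-form Gaussian KL, an exact fast path
#' under the same Gaussian fit. Per-edge seeds derive deterministically from
#' the scan seed and the sorted region pair, so results do not depend on
#' evaluation order.
#'
#' Regions with fewer than `min_voxels` voxels are dropped and listed in the
#' network metadata; building fails if fewer than 2 usable regions remain.
#'
#' @param voxels Tibble with columns `Label`, `MTR`.
#' @param parcellation Optional [parcellation()]; voxels are first restricted
#'   to its included regions and nodes follow its region order.
#' @param estimator `"resampled"` or `"analytic"`.
#' @param n_resamples Draws per region for the resampled estimator.
#'   Default 5000.
#' @param k Nearest-neighbour order for the resampled estimator. Default 3.
#' @param min_voxels Minimum voxels per region. Default 20.
#' @param sigma_floor See [fit_region_distribution()].
#' @param seed Scan-level seed for the resampled estimator.
#' @return A `mind_network`: edge-weight matrix plus metadata (estimator
#'   settings, seed, dropped regions, per-region fits).
#' @examples
#' regions <- generate_parcellation(6, 2, seed = 1)
#' truth <- generative_truth(regions)
#' net <- build_mind_network(generate_scan(truth, seed = 1),
#'                           estimator = "analytic")
#' net
#' @export
build_mind_network <- function(voxels, parcellation = NULL,
                               estimator = c("resampled", "analytic"),
                               n_resamples = 5000, k = 3L, min_voxels = 20,
                               sigma_floor = NULL, seed = 1) {
  estimator <- match.arg(estimator)
  if (!is.null(parcellation)) {
    voxels <- filter_to_included(voxels, parcellation)
    wanted <- parcellation$region_id[parcellation$include_flag]
  } else {
    wanted <- unique(voxels$Label)
  }
  sigma_floor <- sigma_floor %||% default_sigma_floor(voxels$MTR)
  counts <- table(voxels$Label)
  usable <- wanted[wanted %in% names(counts)[counts >= min_voxels]]
  dropped <- setdiff(wanted, usable)
  if (length(usable) < 2L) {
    abort_pipeline(sprintf(
      "Only %d region(s) meet min_voxels = %d; need at least 2.",
      length(usable), min_voxels))
  }
  fits <- dplyr::bind_rows(purrr::map(
    usable, ~ fit_region_distribution(voxels, .x, min_voxels = min_voxels,
                                      sigma_floor = sigma_floor)))
  n <- nrow(fits)
  if (estimator == "analytic") {
    w <- analytic_similarity(fits$mu, fits$sigma, fits$region_id)
  } else {
    w <- matrix(1, n, n, dimnames = list(fits$region_id, fits$region_id))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pair <- sort(c(fits$region_id[i], fits$region_id[j]))
        es <- derive_seed(seed, "edge", pair[1L], pair[2L])
        kls <- with_preserved_seed(es, {
          x <- rnorm(n_resamples, fits$mu[i], fits$sigma[i])
          y <- rnorm(n_resamples, fits$mu[j], fits$sigma[j])
          c(kl_knn_1d(x, y, k = k), kl_knn_1d(y, x, k = k))
        })
        w[i, j] <- w[j, i] <- edge_weight(kls[1L], kls[2L])
      }
    }
  }
  new_mind_network(w, meta = list(
    estimator = estimator, n_resamples = n_resamples, k = as.integer(k),
    min_voxels = min_voxels, sigma_floor = sigma_floor, seed = seed,
    dropped_regions = dropped, fits = fits
  ))
}

#' Element-wise median network across scans
#'
#' The normative network: for each edge, the median of that edge's weight
#' across the contributing scans' networks. All networks must share the same
#' node labels in the same order.
#'
#' @param networks List of `mind_network` objects.
#' @return A `mind_network` whose metadata records the contributing scan
#'   count.
#' @export
median_network <- function(networks) {
  stopifnot(length(networks) >= 1L,
            all(vapply(networks, inherits, TRUE, "mind_network")))
  nodes <- networks[[1L]]$nodes
  for (net in networks) {
    if (!identical(net$nodes, nodes)) {
      abort_invalid(sprintf(
        "Node label mismatch across networks; symmetric difference: %s.",
        paste(union(setdiff(net$nodes, nodes), setdiff(nodes, net$nodes)),
              collapse = ", ")))
    }
  }
  arr <- vapply(networks, function(net) net$weights,
                matrix(0, length(nodes), length(nodes)))
  med <- apply(arr, c(1L, 2L), median)
  dimnames(med) <- list(nodes, nodes)
  new_mind_network(med, meta = list(estimator = "median",
                                    n_contributing = length(networks)))
}

#' @export
print.mind_network <- function(x, ...) {
  off <- upper_values(x$weights)
  cat(sprintf("<mind_network> %d nodes, %d edges (%s estimator)\n",
              length(x$nodes), length(off),
              x$meta$estimator %||% "unknown"))
  cat(sprintf("  edge weights: min %.3f, median %.3f, max %.3f\n",
              min(off), median(off), max(off)))
  if (length(x$meta$dropped_regions %||% character()) > 0L) {
    cat("  dropped regions:",
        paste(x$meta$dropped_regions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.mind_network <- function(x, ...) x$weights

#' Tidy a MIND network into a long edge table
#'
#' @param x A `mind_network`.
#' @param ... Unused.
#' @return Tibble with one row per unique edge: `region_a`, `region_b`,
#'   `weight`.
#' @method tidy mind_network
#' @export
tidy.mind_network <- function(x, ...) {
  out <- label_pairs(x$nodes)
  out$weight <- upper_values(x$weights)
  out
}

#' One-row summary of a MIND network
#'
#' @param x A `mind_network`.
#' @param ... Unused.
#' @return Tibble: node/edge counts, weight summaries, estimator.
#' @method glance mind_network
#' @export
glance.mind_network <- function(x, ...) {
  off <- upper_values(x$weights)
  tibble::tibble(
    n_nodes = length(x$nodes), n_edges = length(off),
    min_weight = min(off), median_weight = median(off),
    max_weight = max(off),
    estimator = x$meta$estimator %||% NA_character_,
    n_dropped = length(x$meta$dropped_regions %||% character())
  )
}

#' Serialize / deserialize a MIND network as a labelled CSV matrix
#'
#' @param network A `mind_network`.
#' @param path CSV path (labels as header row and first column).
#' @return `path` (write) / a `mind_network` (read).
#' @export
write_mind_network <- function(network, path) {
  df <- as.data.frame(network$weights)
  df <- cbind(region = network$nodes, df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_mind_network
#' @export
read_mind_network <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  new_mind_network(m, meta = list(estimator = "file", source = path))
}
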