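#' Assign unique edges to evenly sized distance bins
#'
#' Sorts the network's unique edges by centroid distance and splits them into
#' `n_bins` bins (proximal to distal) whose sizes differ by at most one;
#' remainder edges go to the proximal-most bins. Ties in distance are broken
#' by the stable sort on (distance, region pair), so the assignment is
#' deterministic.
#'
#' @param distances Labelled symmetric distance matrix
#'   (see [edge_distances()]).
#' @param n_bins Number of bins. Default 3 (proximal, intermediate, distal).
#' @return Tibble with columns `region_a`, `region_b`, `distance`, `bin`.
#' @export
distance_bins <- function(distances, n_bins = 3) {
  n_bins <- check_count(n_bins, "n_bins")
  d <- as.matrix(distances)
  edges <- label_pairs(rownames(d))
  edges$distance <- upper_values(d)
  if (n_bins > nrow(edges)) {
    abort_invalid("`n_bins` exceeds the number of unique edges.")
  }
  ord <- order(edges$distance, edges$region_a, edges$region_b)
  sizes <- rep(nrow(edges) %/% n_bins, n_bins)
  extra <- nrow(edges) %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(nrow(edges))
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  edges$bin <- bin
  edges
}

#' Distance-preserving edge shuffle
#'
#' Produces a null network by permuting edge weights only among edges in the
#' same distance bin, preserving the per-bin weight multiset (hence the
#' distance-weight relationship up to bin coarseness), symmetry, and the
#' unit diagonal.
#'
#' @param network A `mind_network`.
#' @param bins Tibble from [distance_bins()]; must cover exactly the
#'   network's unique edges.
#' @param seed Integer seed.
#' @return A null `mind_network`.
#' @export
shuffle_within_bins <- function(network, bins, seed = 1) {
  w <- as.matrix(network)
  nodes <- colnames(w)
  expected <- label_pairs(nodes)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (!setequal(key(bins$region_a, bins$region_b),
                key(expected$region_a, expected$region_b)) ||
      nrow(bins) != nrow(expected)) {
    abort_invalid("`bins` must cover exactly the network's unique edges.")
  }
  bin_of <- setNames(bins$bin, key(bins$region_a, bins$region_b))
  edge_bins <- unname(bin_of[key(expected$region_a, expected$region_b)])
  weights <- upper_values(w)
  shuffled <- weights
  with_preserved_seed(seed, {
    for (b in sort(unique(edge_bins))) {
      idx <- which(edge_bins == b)
      shuffled[idx] <- weights[idx][sample.int(length(idx))]
    }
  })
  out <- matrix(0, length(nodes), length(nodes),
                dimnames = dimnames(w))
  out[upper.tri(out)] <- shuffled
  out <- out + t(out)
  diag(out) <- diag(w)
  new_mind_network(out, meta = c(network$meta[c("estimator")],
                                 list(null = "distance_binned", seed = seed)))
}

#' Ensemble of distance-preserving null networks
#'
#' Generates `n_nulls` independent within-bin shuffles with per-null seeds
#' derived from `seed`. If `statistic` is supplied, only its value on each
#' null is stored (bounding memory for large ensembles); otherwise the null
#' networks themselves are kept.
#'
#' @param network A `mind_network`.
#' @param distances Labelled distance matrix over the network's nodes.
#' @param n_nulls Number of nulls. Default 10000.
#' @param seed Integer seed.
#' @param n_bins Number of distance bins. Default 3.
#' @param statistic Optional function `mind_network -> numeric(1)`.
#' @return A list of class `null_ensemble`: `bins`, `seed`, and either
#'   `networks` or `values` (plus `statistic_name`).
#' @export
null_ensemble <- function(network, distances, n_nulls = 10000, seed = 1,
                          n_bins = 3, statistic = NULL) {
  n_nulls <- check_count(n_nulls, "n_nulls")
  d <- as.matrix(distances)[network$nodes, network$nodes]
  class(d) <- NULL
  bins <- distance_bins(d, n_bins = n_bins)
  seeds <- vapply(seq_len(n_nulls), function(i) derive_seed(seed, "null", i),
                  integer(1))
  if (is.null(statistic)) {
    nets <- purrr::map(seeds, ~ shuffle_within_bins(network, bins, seed = .x))
    structure(list(networks = nets, bins = bins, seed = seed),
              class = "null_ensemble")
  } else {
    vals <- vapply(seeds, function(s) {
      statistic(shuffle_within_bins(network, bins, seed = s))
    }, numeric(1))
    structure(list(values = vals, bins = bins, seed = seed,
                   statistic_name = deparse(substitute(statistic))),
              class = "null_ensemble")
  }
}

#' @export
print.null_ensemble <- function(x, ...) {
  n <- if (!is.null(x$networks)) length(x$networks) else length(x$values)
  cat(sprintf("<null_ensemble> %d distance-preserving nulls (%d bins)\n",
              n, max(x$bins$bin)))
  invisible(x)
}

#' Permutation z-score and p-value of an observed statistic
#'
#' `z = (observed - mean(nulls)) / sd(nulls)`; the p-value uses the add-one
#' convention `p = (1 + #\{null >= observed\}) / (1 + n_nulls)` for the upper
#' tail, so the smallest attainable p with 10,000 nulls is 1.0e-4. The
#' two-sided variant doubles the smaller tail, capped at 1. With degenerate
#' (zero-SD) nulls, `z` is `NA` with a warning and the p-value is still
#' returned.
#'
#' @param observed Observed scalar statistic.
#' @param nulls Numeric vector of null statistics (length >= 2).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A list of class `permutation_result`: `observed`, `z`, `p`,
#'   `n_nulls`, `null_mean`, `null_sd`, `alternative`.
#' @export
permutation_z_p <- function(observed, nulls,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(nulls) < 2L) abort_invalid("Need at least 2 null values.")
  mu <- mean(nulls); s <- sd(nulls)
  z <- if (s > 0) (observed - mu) / s else {
    warn("Null distribution has zero SD; z is undefined.")
    NA_real_
  }
  n <- length(nulls)
  p_up <- (1 + sum(nulls >= observed)) / (1 + n)
  p_dn <- (1 + sum(nulls <= observed)) / (1 + n)
  p <- switch(alternative,
              greater = p_up,
              two.sided = min(1, 2 * min(p_up, p_dn)))
  structure(list(observed = observed, z = z, p = p, n_nulls = n,
                 null_mean = mu, null_sd = s, alternative = alternative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation> observed = %.4g, z = %.3g, p = %.3g (%d nulls, %s)\n",
              x$observed, x$z, x$p, x$n_nulls, x$alternative))
  invisible(x)
}

#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, z = x$z, p = x$p,
                 n_nulls = x$n_nulls, null_mean = x$null_mean,
                 null_sd = x$null_sd, alternative = x$alternative)
}
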