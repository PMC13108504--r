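#' Correlation between edge weight and interregional distance
#'
#' Pearson correlation over the unique edges between MIND edge weight and
#' Euclidean centroid distance (the primary, approximately linear
#' relationship), with Spearman's rank correlation reported alongside as a
#' sensitivity output.
#'
#' @param network A `mind_network`.
#' @param distances Labelled distance matrix covering the network's nodes.
#' @return One-row tibble: `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n_edges`.
#' @export
distance_weight_correlation <- function(network, distances) {
  d <- as.matrix(distances)
  nodes <- network$nodes
  if (!all(nodes %in% rownames(d))) {
    abort_invalid("`distances` must cover all network nodes.")
  }
  w <- upper_values(as.matrix(network))
  dd <- upper_values(d[nodes, nodes])
  if (length(w) < 3L) abort_invalid("Need at least 3 edges.")
  pe <- suppressWarnings(cor.test(dd, w, method = "pearson"))
  sp <- suppressWarnings(cor.test(dd, w, method = "spearman", exact = FALSE))
  tibble::tibble(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 n_edges = length(w))
}

#' Jaccard similarity of tract-tracing connection profiles
#'
#' For each region pair (i, j), compares their ordinal connection profiles
#' over all third regions k (k not in \{i, j\}): the intersection counts the
#' k with identical *and* nonzero weights (`w_ik == w_jk != 0`), the union
#' counts the k connected to i or j (either weight nonzero), and
#' `J = intersection / union` (0 when the union is empty). `J(i, i) = 1` by
#' convention. Optionally, positions where both profiles are zero can also
#' count as matches (they then also enter the union denominator through
#' neither side, so this only changes results via `count_zero_matches`).
#'
#' Strictly monotone transforms of the ordinal levels (e.g. log10) cannot
#' change equality or nonzero patterns, so they leave J unchanged.
#'
#' @param tract Square ordinal matrix (possibly asymmetric) with region
#'   labels; 0 means no reported connection. The diagonal is ignored.
#' @param count_zero_matches If `TRUE`, positions with `w_ik == w_jk == 0`
#'   count toward the intersection and the denominator becomes all third
#'   regions. Default `FALSE`.
#' @return Symmetric similarity matrix in the unit interval with unit diagonal.
#' @export
jaccard_profile_similarity <- function(tract, count_zero_matches = FALSE) {
  m <- as.matrix(tract)
  n <- nrow(m)
  if (n < 3L) abort_invalid("Need at least 3 regions.")
  labels <- rownames(m) %||% sprintf("R%03d", seq_len(n))
  J <- matrix(1, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- setdiff(seq_len(n), c(i, j))
      a <- m[i, k]; b <- m[j, k]
      if (count_zero_matches) {
        inter <- sum(a == b)
        union <- length(k)
      } else {
        inter <- sum(a == b & a != 0)
        union <- sum(a != 0 | b != 0)
      }
      J[i, j] <- J[j, i] <- if (union == 0) 0 else inter / union
    }
  }
  J
}

# Spearman rho between a reference edge-value matrix and MIND weights over
# shared regions, plus inference against a null ensemble of networks.
alignment_against_nulls <- function(network, reference, nulls,
                                    label = "reference") {
  shared <- intersect(network$nodes, rownames(reference))
  if (length(shared) < 3L) {
    abort_invalid(sprintf("Fewer than 3 regions shared with the %s matrix.",
                          label))
  }
  ref_vals <- upper_values(as.matrix(reference)[shared, shared])
  obs_vals <- upper_values(as.matrix(network)[shared, shared])
  if (length(ref_vals) < 2L || sd(ref_vals) == 0) {
    abort_invalid(sprintf("The %s values are constant; alignment undefined.",
                          label))
  }
  rho <- cor(ref_vals, obs_vals, method = "spearman")
  if (is.null(nulls)) return(list(rho = rho, result = NULL, n = length(shared)))
  stopifnot(inherits(nulls, "null_ensemble"), !is.null(nulls$networks))
  null_rho <- vapply(nulls$networks, function(nn) {
    cor(ref_vals, upper_values(as.matrix(nn)[shared, shared]),
        method = "spearman")
  }, numeric(1))
  list(rho = rho, result = permutation_z_p(rho, null_rho),
       n = length(shared))
}

#' Alignment of MIND weights with tract-tracing profile similarity
#'
#' Spearman correlation between the Jaccard profile-similarity entries of an
#' ordinal tract-tracing matrix and the MIND edge weights over shared
#' regions, assessed against distance-preserving null networks (the same
#' correlation recomputed on every null).
#'
#' @param network A `mind_network`.
#' @param tract Ordinal tract matrix (see [jaccard_profile_similarity()]).
#' @param nulls A [null_ensemble()] holding networks, or `NULL` to skip
#'   inference.
#' @return One-row tibble: `rho`, `z`, `p`, `n_regions`, `n_nulls`.
#' @export
tract_mind_alignment <- function(network, tract, nulls = NULL) {
  J <- jaccard_profile_similarity(tract)
  al <- alignment_against_nulls(network, J, nulls, label = "tract Jaccard")
  tibble::tibble(rho = al$rho,
                 z = al$result$z %||% NA_real_,
                 p = al$result$p %||% NA_real_,
                 n_regions = al$n,
                 n_nulls = al$result$n_nulls %||% 0L)
}

#' Alignment of MIND weights with transcriptomic similarity
#'
#' Builds the pairwise regional correlation matrix of gene-expression
#' profiles, then correlates (Spearman) its entries with MIND edge weights
#' over shared regions, with null-ensemble inference as in
#' [tract_mind_alignment()]. Regions with zero-variance profiles make the
#' profile correlation undefined and raise an error.
#'
#' @param network A `mind_network`.
#' @param expression Numeric matrix, regions x genes, with region rownames.
#' @param nulls A [null_ensemble()] holding networks, or `NULL`.
#' @return One-row tibble: `rho`, `z`, `p`, `n_regions`, `n_nulls`.
#' @export
expression_alignment <- function(network, expression, nulls = NULL) {
  expr <- as.matrix(expression)
  if (is.null(rownames(expr))) abort_invalid("`expression` needs rownames.")
  sds <- apply(expr, 1L, sd)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    abort_invalid("Zero-variance expression profile(s); correlation undefined.")
  }
  sim <- cor(t(expr))
  al <- alignment_against_nulls(network, sim, nulls, label = "expression")
  tibble::tibble(rho = al$rho,
                 z = al$result$z %||% NA_real_,
                 p = al$result$p %||% NA_real_,
                 n_regions = al$n,
                 n_nulls = al$result$n_nulls %||% 0L)
}

# Collapse a cortical-type label to its class: allocortical types -> "allo",
# mesocortical (agranular/dysgranular) -> "meso", anything else verbatim.
type_class <- function(type) {
  dplyr::case_when(
    grepl("allocortex", type, ignore.case = TRUE) ~ "allo",
    grepl("mesocortex", type, ignore.case = TRUE) ~ "meso",
    TRUE ~ type
  )
}

# Class-pair category of each edge given a region -> type mapping.
edge_type_pairs <- function(edges, types) {
  class_of <- setNames(type_class(types$type), types$region_id)
  ca <- unname(class_of[edges$region_a])
  cb <- unname(class_of[edges$region_b])
  cat <- ifelse(is.na(ca) | is.na(cb), NA_character_,
                paste(pmin(ca, cb), pmax(ca, cb), sep = "-"))
  dplyr::mutate(edges, class_a = ca, class_b = cb,
                intraclass = !is.na(ca) & !is.na(cb) & ca == cb,
                class_pair = cat)
}

#' Percentage of intraclass edges across density thresholds
#'
#' Thresholds the network at each density d, keeping the `ceiling(d * E)`
#' top-weighted unique edges (ties at the cut broken by label order), and
#' reports the percentage of kept edges whose two endpoint regions share a
#' cortical type. Regions flagged `excluded` in the type table (and edges
#' touching regions without a type) are removed before thresholding.
#'
#' Because thresholding is rank-based, the curve is invariant to strictly
#' monotone transforms of the edge weights.
#'
#' @param network A `mind_network`.
#' @param types Tibble with `region_id`, `type`, optional logical `excluded`.
#' @param densities Fractions in (0,1), each the proportion of top-weighted edges kept. Default 1%-10% in 1% steps.
#' @return Tibble: `density`, `n_edges`, `pct_intraclass`.
#' @export
intraclass_edge_curve <- function(network, types,
                                  densities = seq(0.01, 0.10, by = 0.01)) {
  if (any(densities <= 0 | densities > 1)) {
    abort_invalid("`densities` must lie in (0, 1].")
  }
  if ("excluded" %in% names(types)) {
    types <- types[!types$excluded, , drop = FALSE]
  }
  edges <- edge_type_pairs(tidy.mind_network(network), types)
  edges <- edges[!is.na(edges$class_pair), , drop = FALSE]
  edges <- edges[order(-edges$weight, edges$region_a, edges$region_b), ,
                 drop = FALSE]
  E <- nrow(edges)
  purrr::map_dfr(densities, function(d) {
    m <- ceiling(d * E)
    if (m < 1L) {
      warn(sprintf("Density %.3g yields no edges; skipped.", d))
      return(NULL)
    }
    top <- edges[seq_len(m), , drop = FALSE]
    tibble::tibble(density = d, n_edges = m,
                   pct_intraclass = 100 * mean(top$intraclass))
  })
}

#' Compare edge weights between cortical class-pair categories
#'
#' Categorizes each edge by its endpoint cortical classes (e.g. allo-allo,
#' allo-meso, meso-meso, after collapsing mesocortical subtypes to their
#' class), pools edges across the supplied network(s), and runs rank-based
#' (Wilcoxon-Mann-Whitney) tests between every pair of categories with
#' Benjamini-Hochberg adjustment. Categories with fewer than 2 edges are
#' excluded with a warning. For class membership, region types containing
#' "allocortex" count as allo and "mesocortex" as meso; other naming schemes
#' are compared verbatim on the leading type token.
#'
#' @param networks A `mind_network` or list of them.
#' @param types Tibble with `region_id`, `type`, optional `excluded`.
#' @return Tibble: `category_a`, `category_b`, `median_a`, `median_b`,
#'   `statistic`, `p_value`, `q_value` (BH).
#' @export
class_pair_weight_test <- function(networks, types) {
  if (inherits(networks, "mind_network")) networks <- list(networks)
  if ("excluded" %in% names(types)) {
    types <- types[!types$excluded, , drop = FALSE]
  }
  edges <- dplyr::bind_rows(purrr::map(networks, tidy.mind_network))
  edges <- edge_type_pairs(edges, types)
  edges <- edges[!is.na(edges$class_pair), , drop = FALSE]
  counts <- table(edges$class_pair)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    warn(sprintf("Excluding class-pair categor%s with < 2 edges: %s.",
                 if (length(small) > 1L) "ies" else "y",
                 paste(small, collapse = ", ")))
    edges <- edges[!edges$class_pair %in% small, , drop = FALSE]
  }
  cats <- sort(unique(edges$class_pair))
  if (length(cats) < 2L) {
    abort_invalid("Need at least 2 class-pair categories with >= 2 edges.")
  }
  combos <- utils::combn(cats, 2L)
  res <- purrr::map_dfr(seq_len(ncol(combos)), function(ci) {
    a <- combos[1L, ci]; b <- combos[2L, ci]
    wa <- edges$weight[edges$class_pair == a]
    wb <- edges$weight[edges$class_pair == b]
    wt <- suppressWarnings(stats::wilcox.test(wa, wb))
    tibble::tibble(category_a = a, category_b = b,
                   median_a = median(wa), median_b = median(wb),
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Aggregate a network into a reference atlas space
#'
#' Maps source regions to reference-atlas labels via the crosswalk and sets
#' each reference-space edge weight to the median over all source-region
#' pairs mapping to that reference pair. Pairs of subdivisions of a single
#' reference region never contribute to off-diagonal entries; the diagonal
#' stays 1. Source regions absent from the crosswalk are dropped with a
#' warning.
#'
#' @param network A `mind_network`.
#' @param crosswalk Tibble with columns `region_id` (source) and
#'   `reference_id`; each source maps to at most one reference region.
#' @return A `mind_network` over the reference regions.
#' @export
crosswalk_aggregate <- function(network, crosswalk) {
  stopifnot(all(c("region_id", "reference_id") %in% names(crosswalk)))
  if (anyDuplicated(crosswalk$region_id)) {
    abort_invalid("Each source region must map to at most one reference region.")
  }
  w <- as.matrix(network)
  unmapped <- setdiff(network$nodes, crosswalk$region_id)
  if (length(unmapped) > 0L) {
    warn(sprintf("Dropping %d source region(s) not in the crosswalk: %s.",
                 length(unmapped), paste(unmapped, collapse = ", ")))
  }
  cw <- crosswalk[crosswalk$region_id %in% network$nodes, , drop = FALSE]
  refs <- unique(cw$reference_id)
  if (length(refs) < 2L) {
    abort_invalid("Crosswalk yields fewer than 2 reference regions.")
  }
  ref_of <- setNames(cw$reference_id, cw$region_id)
  out <- matrix(1, length(refs), length(refs), dimnames = list(refs, refs))
  for (i in seq_along(refs)[-length(refs)]) {
    for (j in (i + 1L):length(refs)) {
      src_i <- names(ref_of)[ref_of == refs[i]]
      src_j <- names(ref_of)[ref_of == refs[j]]
      out[i, j] <- out[j, i] <- median(w[src_i, src_j, drop = FALSE])
    }
  }
  new_mind_network(out, meta = list(estimator = network$meta$estimator,
                                    crosswalk = TRUE,
                                    n_source = nrow(cw)))
}
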