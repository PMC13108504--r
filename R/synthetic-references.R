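#' Generate synthetic external reference assets with planted alignment
#'
#' Builds the four reference inputs the validation module consumes, each
#' coupled to the planted similarity structure so that alignment tests have a
#' known positive truth at `noise = 0` and no truth as `noise` grows large:
#'
#' * an ordinal tract-tracing matrix whose connection profiles are more
#'   concordant for region pairs with high true similarity (levels 0-7,
#'   0 = no reported connection, derived by quantile-cutting a latent
#'   similarity-plus-noise score);
#' * a cortical-type table assigning each system's regions one of three
#'   cortical types (archicortical allocortex, agranular and dysgranular
#'   mesocortex), so within-type edges inherit the within-system similarity
#'   excess;
#' * a gene-expression table whose regional profiles have pairwise
#'   correlations increasing with true similarity (low-rank factor
#'   construction from the similarity matrix's eigenstructure);
#' * a crosswalk mapping each region to a reference-atlas label, with
#'   same-system region pairs occasionally merged many-to-one.
#'
#' @param truth A [generative_truth()] object.
#' @param noise Nonnegative noise level; 0 gives the cleanest planted
#'   alignment, large values destroy it.
#' @param seed Integer seed.
#' @param n_genes Number of genes in the expression table. Default 50.
#' @param n_levels Number of nonzero ordinal tract levels. Default 7.
#' @param zero_frac Fraction of region pairs with no reported connection.
#'   Default 0.4.
#' @return A list with `tract` (ordinal matrix), `types` (tibble `region_id`,
#'   `type`, `excluded`), `expression` (regions x genes matrix), `crosswalk`
#'   (tibble `region_id`, `reference_id`).
#' @export
generate_reference_assets <- function(truth, noise = 0, seed = 1,
                                      n_genes = 50, n_levels = 7,
                                      zero_frac = 0.4) {
  stopifnot(inherits(truth, "generative_truth"))
  check_number(noise, "noise", lower = 0)
  S <- truth$true_similarity
  n <- nrow(S)
  labels <- rownames(S)
  with_preserved_seed(seed, {
    # --- ordinal tract matrix: monotone in latent = scaled similarity + noise
    z <- (S - mean(S[upper.tri(S)])) / stats::sd(S[upper.tri(S)])
    latent <- z + matrix(rnorm(n * n, 0, noise), n, n)
    latent <- (latent + t(latent)) / 2
    vals <- latent[upper.tri(latent)]
    breaks <- quantile(vals, probs = c(zero_frac, zero_frac +
                         (1 - zero_frac) * seq_len(n_levels - 1) / n_levels))
    lev <- findInterval(latent, vec = sort(unique(breaks)))
    tract <- matrix(as.integer(lev), n, n, dimnames = dimnames(S))
    diag(tract) <- 0L

    # --- cortical-type table: systems cycled over three included types
    systems <- unique(truth$regions$system_id)
    type_names <- c("archicortical-allocortex", "agranular-mesocortex",
                    "dysgranular-mesocortex")
    sys_type <- setNames(type_names[(seq_along(systems) - 1L) %% 3L + 1L],
                         systems)
    types <- tibble::tibble(
      region_id = labels,
      type = unname(sys_type[truth$regions$system_id]),
      excluded = FALSE
    )

    # --- expression: low-rank factors reproducing the similarity structure
    k <- min(10L, n - 1L)
    eig <- eigen(S, symmetric = TRUE)
    vpos <- pmax(eig$values[seq_len(k)], 0)
    factors <- eig$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vpos), k)
    loadings <- matrix(rnorm(k * n_genes), k, n_genes)
    expr <- factors %*% loadings +
      matrix(rnorm(n * n_genes, 0, noise), n, n_genes)
    dimnames(expr) <- list(labels, sprintf("gene%03d", seq_len(n_genes)))

    # --- crosswalk: pair up every other same-system region (many-to-one)
    ref <- character(n)
    counter <- 0L
    for (s in systems) {
      idx <- which(truth$regions$system_id == s)
      j <- 1L
      while (j <= length(idx)) {
        counter <- counter + 1L
        take <- if (j + 1L <= length(idx) && j %% 4L == 1L) 2L else 1L
        ref[idx[j:(j + take - 1L)]] <- sprintf("REF%03d", counter)
        j <- j + take
      }
    }
    crosswalk <- tibble::tibble(region_id = labels, reference_id = ref)

    list(tract = tract, types = types, expression = expr,
         crosswalk = crosswalk)
  })
}
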