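# Shared fixtures and independent oracles for the test suite. All fixtures
# are built in code; oracles are deliberately naive (enumeration / double
# loops) and independent of the package's implementation paths.

# A truth whose `target` system is a tight cluster of regional means offset
# from the rest of the cortex, so planted slopes and group offsets have an
# analytically known direction of effect on similarity and strength:
# moving the cluster toward the pack raises its regions' strengths, moving
# it away lowers them.
clustered_truth <- function(n_regions = 20, n_systems = 4, seed = 1,
                            target = "SYS01", cluster_offset = -0.08,
                            ...) {
  regions <- generate_parcellation(n_regions, n_systems, seed = seed,
                                   sigma_range = c(0.05, 0.07))
  sel <- regions$system_id == target
  regions$mu[sel] <- 0.5 + cluster_offset +
    seq(-0.004, 0.004, length.out = sum(sel))
  generative_truth(regions, ...)
}

# Small two-block generative layout: regions within a block share one
# Gaussian, blocks differ strongly.
two_block_voxels <- function(n_per_block = 3, n_voxels = 800, gap = 0.3,
                             sigma = 0.05, seed = 1) {
  withr::with_seed(seed, {
    labels <- sprintf("B%d_R%d", rep(1:2, each = n_per_block),
                      rep(seq_len(n_per_block), 2))
    mu <- rep(c(0.4, 0.4 + gap), each = n_per_block)
    tibble::tibble(
      Label = rep(labels, each = n_voxels),
      MTR = rnorm(n_per_block * 2 * n_voxels, rep(mu, each = n_voxels), sigma)
    )
  })
}

# Random symmetric weight matrix in (0, 1] with unit diagonal.
random_network <- function(n, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2, 0.05, 1)
    w <- w + t(w)
    diag(w) <- 1
    dimnames(w) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
    w
  })
}

as_net <- function(w) as_mind_network(w, estimator = "fixture")

upper_w <- function(net) {
  w <- as.matrix(net)
  w[upper.tri(w)]
}

# Brute-force weighted rich club: enumerate all edges, sort, take sums.
brute_rich_club <- function(w, hubs) {
  n <- nrow(w)
  labels <- rownames(w)
  club <- 0
  all_w <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      all_w <- c(all_w, w[i, j])
      if (labels[i] %in% hubs && labels[j] %in% hubs) club <- club + w[i, j]
    }
  }
  m <- length(hubs) * (length(hubs) - 1) / 2
  club / sum(sort(all_w, decreasing = TRUE)[1:m])
}

# Exhaustive double-loop Jaccard profile similarity.
brute_jaccard <- function(m) {
  n <- nrow(m)
  J <- matrix(1, n, n, dimnames = dimnames(m))
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      inter <- 0; uni <- 0
      for (k in 1:n) {
        if (k == i || k == j) next
        if (m[i, k] != 0 || m[j, k] != 0) uni <- uni + 1
        if (m[i, k] == m[j, k] && m[i, k] != 0) inter <- inter + 1
      }
      J[i, j] <- if (uni == 0) 0 else inter / uni
    }
  }
  J
}

# Invariant bundle asserted for every network the tests construct.
expect_valid_network <- function(net) {
  w <- as.matrix(net)
  expect_true(isSymmetric(unname(w)))
  expect_equal(unname(diag(w)), rep(1, nrow(w)))
  off <- w[upper.tri(w)]
  expect_true(all(off > 0 & off <= 1))
}

# Per-bin sorted weight multisets of a network under a bin assignment.
bin_multisets <- function(net, bins) {
  w <- as.matrix(net)
  vapply(sort(unique(bins$bin)), function(b) {
    rows <- bins[bins$bin == b, ]
    list(sort(w[cbind(rows$region_a, rows$region_b)]))
  }, list(1))
}
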