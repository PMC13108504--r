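test_that("distance-weight correlation recovers exact and null relations", {
  pts <- matrix(rnorm(30), 10, 3, dimnames = list(sprintf("r%02d", 1:10), NULL))
  d <- edge_distances(pts)
  # weights an exact decreasing linear function of distance
  w <- 1 - as.matrix(d) / (2 * max(d))
  diag(w) <- 1
  res <- distance_weight_correlation(as_net(w), d)
  expect_equal(res$pearson_r, -1)

  # permuted weights carry no relation on average
  rs <- vapply(1:50, function(s) {
    wp <- w
    perm <- withr::with_seed(s, sample(45))
    wp[upper.tri(wp)] <- w[upper.tri(w)][perm]
    wp[lower.tri(wp)] <- t(wp)[lower.tri(wp)]
    distance_weight_correlation(as_net(wp), d)$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("estimated networks inherit the planted distance decay", {
  truth <- clustered_truth(20, 4, seed = 21)
  scan <- generate_scan(truth, age = 20, seed = 1)
  net <- build_mind_network(scan, estimator = "analytic")
  dists <- edge_distances(as_parcellation(truth$regions))
  expect_lt(distance_weight_correlation(net, dists)$pearson_r, 0)
})

test_that("jaccard profile similarity handles the canonical cases", {
  # identical nonzero profiles
  m <- rbind(i = c(0, 0, 1, 2, 3), j = c(0, 0, 1, 2, 3),
             k1 = c(1, 1, 0, 1, 1), k2 = c(2, 1, 1, 0, 2),
             k3 = c(3, 1, 1, 2, 0))
  colnames(m) <- rownames(m)
  J <- jaccard_profile_similarity(m)
  expect_equal(J["i", "j"], 1)

  # worked 4-third-region example: profiles (3,0,2,1) vs (3,1,0,1)
  m2 <- matrix(0L, 6, 6,
               dimnames = list(letters[1:6], letters[1:6]))
  m2["a", c("c", "d", "e", "f")] <- c(3, 0, 2, 1)
  m2["b", c("c", "d", "e", "f")] <- c(3, 1, 0, 1)
  J2 <- jaccard_profile_similarity(m2)
  expect_equal(J2["a", "b"], 2 / 4)

  # disjoint support
  m3 <- rbind(i = c(0, 0, 1, 1, 0, 0), j = c(0, 0, 0, 0, 1, 1),
              k1 = rep(1, 6), k2 = rep(1, 6), k3 = rep(1, 6),
              k4 = rep(1, 6))
  colnames(m3) <- rownames(m3)
  expect_equal(jaccard_profile_similarity(m3)["i", "j"], 0)

  expect_error(jaccard_profile_similarity(m[1:2, 1:2]),
               class = "ratmind_invalid_argument")
})

test_that("jaccard matches the exhaustive oracle on random matrices", {
  for (s in 1:100) {
    m <- withr::with_seed(s, {
      mm <- matrix(sample(0:3, 36, replace = TRUE), 6, 6,
                   dimnames = list(letters[1:6], letters[1:6]))
      diag(mm) <- 0L
      mm
    })
    J <- jaccard_profile_similarity(m)
    expect_equal(J, brute_jaccard(m))
    expect_true(isSymmetric(unname(J)))
    expect_true(all(J >= 0 & J <= 1))
    expect_equal(unname(diag(J)), rep(1, 6))
  }
})

test_that("monotone transforms of ordinal levels leave jaccard unchanged", {
  m <- withr::with_seed(9, matrix(sample(0:7, 49, replace = TRUE), 7, 7))
  dimnames(m) <- list(letters[1:7], letters[1:7])
  mt <- m
  mt[mt > 0] <- log10(mt[mt > 0]) + 1   # strictly monotone on nonzero levels
  expect_equal(jaccard_profile_similarity(m), jaccard_profile_similarity(mt))
})

test_that("tract alignment detects planted coupling against nulls", {
  truth <- clustered_truth(14, 3, seed = 31)
  net <- as_net(truth$true_similarity)
  dists <- edge_distances(as_parcellation(truth$regions))
  nulls <- null_ensemble(net, dists, n_nulls = 99, seed = 2)
  refs <- generate_reference_assets(truth, noise = 0, seed = 3)
  res <- tract_mind_alignment(net, refs$tract, nulls)
  expect_gt(res$rho, 0)
  expect_lt(res$p, 0.05)

  # a network that is a monotone transform of the Jaccard matrix: rho = 1
  J <- jaccard_profile_similarity(refs$tract)
  wj <- 0.05 + 0.9 * (J - min(J)) / (max(J) - min(J))
  diag(wj) <- 1
  expect_equal(tract_mind_alignment(as_net(wj), refs$tract)$rho, 1)
})

test_that("expression alignment detects planted coupling and degeneracy", {
  truth <- clustered_truth(14, 3, seed = 33)
  net <- as_net(truth$true_similarity)
  refs <- generate_reference_assets(truth, noise = 0, seed = 5)
  res <- expression_alignment(net, refs$expression)
  expect_gt(res$rho, 0)

  flat <- matrix(1, 5, 30, dimnames = list(net$nodes[1:5], NULL))
  expect_error(expression_alignment(net, flat),
               class = "ratmind_invalid_argument")
})

test_that("intraclass curve is exact in the saturated case", {
  w <- random_network(10, seed = 41)
  types <- tibble::tibble(region_id = rownames(w),
                          type = rep(c("archicortical-allocortex",
                                       "agranular-mesocortex"), each = 5))
  # make every allo-allo edge the strongest
  allo <- types$region_id[1:5]
  w[allo, allo] <- 1
  w[!rownames(w) %in% allo, ] <- w[!rownames(w) %in% allo, ] * 0.9
  w[, !colnames(w) %in% allo] <- w[, !colnames(w) %in% allo] * 0.9
  w <- pmax(w, t(w))
  diag(w) <- 1
  curve <- intraclass_edge_curve(as_net(w), types,
                                 densities = seq(0.02, 0.2, by = 0.02))
  expect_true(all(curve$pct_intraclass == 100))
  expect_equal(curve$n_edges, ceiling(seq(0.02, 0.2, by = 0.02) * 45))
})

test_that("random type labels give chance-level intraclass percentages", {
  w <- random_network(12, seed = 43)
  pct <- vapply(1:100, function(s) {
    types <- withr::with_seed(s, tibble::tibble(
      region_id = sample(rownames(w)),
      type = rep(c("archicortical-allocortex", "agranular-mesocortex"),
                 each = 6)))
    mean(intraclass_edge_curve(as_net(w), types,
                               densities = 0.2)$pct_intraclass)
  }, numeric(1))
  # chance: edges within either of two equal classes of 6 among 12 nodes
  chance <- 100 * 2 * choose(6, 2) / choose(12, 2)
  expect_lt(abs(mean(pct) - chance), 5)
})

test_that("intraclass curve is invariant to monotone weight transforms", {
  w <- random_network(10, seed = 44)
  types <- tibble::tibble(region_id = rownames(w),
                          type = rep(c("archicortical-allocortex",
                                       "dysgranular-mesocortex"), 5))
  w2 <- w ^ 3
  diag(w2) <- 1
  expect_equal(intraclass_edge_curve(as_net(w), types),
               intraclass_edge_curve(as_net(w2), types))
})

test_that("planted intraclass enrichment exceeds distance-matched nulls", {
  truth <- clustered_truth(15, 3, seed = 45, cluster_offset = -0.1)
  net <- as_net(truth$true_similarity)
  refs <- generate_reference_assets(truth, noise = 0, seed = 1)
  dists <- edge_distances(as_parcellation(truth$regions))
  ens <- null_ensemble(net, dists, n_nulls = 30, seed = 7)
  dens <- seq(0.05, 0.10, by = 0.05)
  obs <- intraclass_edge_curve(net, refs$types, densities = dens)
  null_mean <- rowMeans(vapply(ens$networks, function(nn) {
    intraclass_edge_curve(nn, refs$types, densities = dens)$pct_intraclass
  }, numeric(length(dens))))
  expect_true(all(obs$pct_intraclass >= null_mean))
})

test_that("class-pair weight tests flag planted allo-allo excess", {
  w <- random_network(12, seed = 47)
  types <- tibble::tibble(region_id = rownames(w),
                          type = rep(c("archicortical-allocortex",
                                       "agranular-mesocortex"), each = 6))
  allo <- types$region_id[1:6]
  w[allo, allo] <- pmin(w[allo, allo] + 0.6, 0.999)
  diag(w) <- 1
  res <- class_pair_weight_test(as_net(w), types)
  row <- res[res$category_a == "allo-allo" & res$category_b == "allo-meso", ]
  expect_lt(row$q_value, 0.05)
  expect_gt(row$median_a, row$median_b)
  # q-values are BH-monotone in p
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))

  one_class <- tibble::tibble(region_id = rownames(w),
                              type = "archicortical-allocortex")
  expect_error(class_pair_weight_test(as_net(w), one_class),
               class = "ratmind_invalid_argument")
})

test_that("crosswalk aggregation takes medians over subdivision pairs", {
  w <- matrix(1, 3, 3, dimnames = list(c("s1", "s2", "t"), c("s1", "s2", "t")))
  w["s1", "t"] <- w["t", "s1"] <- 0.3
  w["s2", "t"] <- w["t", "s2"] <- 0.5
  w["s1", "s2"] <- w["s2", "s1"] <- 0.9
  cw <- tibble::tibble(region_id = c("s1", "s2", "t"),
                       reference_id = c("REF1", "REF1", "REF2"))
  agg <- crosswalk_aggregate(as_net(w), cw)
  expect_equal(as.matrix(agg)["REF1", "REF2"], 0.4)
  expect_equal(unname(diag(as.matrix(agg))), c(1, 1))

  # all-1:1 crosswalk is the identity up to relabeling
  w5 <- random_network(5, seed = 51)
  cw5 <- tibble::tibble(region_id = rownames(w5),
                        reference_id = paste0("X_", rownames(w5)))
  agg5 <- crosswalk_aggregate(as_net(w5), cw5)
  expect_equal(unname(as.matrix(agg5)), unname(w5))

  # relabeling commutes with aggregation
  perm <- c(3, 1, 2, 5, 4)
  wp <- w5[perm, perm]
  aggp <- crosswalk_aggregate(as_net(wp), cw5)
  expect_equal(as.matrix(aggp)[rownames(as.matrix(agg5)),
                               colnames(as.matrix(agg5))],
               as.matrix(agg5))

  all_one <- tibble::tibble(region_id = rownames(w5), reference_id = "REF1")
  expect_error(crosswalk_aggregate(as_net(w5), all_one),
               class = "ratmind_invalid_argument")
  expect_warning(crosswalk_aggregate(as_net(w5), cw5[-1, ]), "Dropping")
})
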