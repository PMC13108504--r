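test_that("fit_region_distribution returns sample moments with flooring", {
  v <- tibble::tibble(Label = "A", MTR = c(1, 2, 3))
  fit <- fit_region_distribution(v, "A", min_voxels = 3)
  expect_equal(fit$mu, 2)
  expect_equal(fit$sigma, 1)   # n-1 denominator
  expect_equal(fit$n_voxels, 3L)

  const <- tibble::tibble(Label = "A", MTR = rep(0.5, 30))
  fitc <- fit_region_distribution(const, "A", sigma_floor = 1e-4)
  expect_equal(fitc$sigma, 1e-4)

  expect_error(fit_region_distribution(v, "A", min_voxels = 50),
               class = "ratmind_insufficient_data")
})

test_that("kl_gaussian evaluates the closed form", {
  p <- list(mu = 0, sigma = 1)
  expect_equal(kl_gaussian(p, p), 0)
  expect_equal(kl_gaussian(p, list(mu = 1, sigma = 1)), 0.5)
  expect_equal(kl_gaussian(p, list(mu = 0, sigma = 2)), log(2) + 1 / 8 - 1 / 2)
  expect_error(kl_gaussian(p, list(mu = 0, sigma = 0)),
               class = "ratmind_invalid_argument")
})

test_that("kl_resampled tracks the analytic oracle", {
  p <- list(mu = 0, sigma = 1); q <- list(mu = 1, sigma = 1)
  same <- mean(vapply(1:20, function(s) kl_resampled(p, p, 5000, seed = s),
                      numeric(1)))
  expect_lt(abs(same), 0.05)
  shift <- mean(vapply(1:20, function(s) kl_resampled(p, q, 5000, seed = s),
                       numeric(1)))
  expect_lt(abs(shift - 0.5), 0.1)
  expect_identical(kl_resampled(p, q, 1000, seed = 3),
                   kl_resampled(p, q, 1000, seed = 3))
  expect_error(kl_resampled(p, q, 50), class = "ratmind_invalid_argument")
})

test_that("resampling balances region size: fit-count invariance", {
  # the same Gaussian fitted from 100 vs 10,000 draws gives the same
  # resampled KL in expectation - the property the resampling exists for
  q <- list(mu = 0.55, sigma = 0.06)
  diffs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      small <- rnorm(100, 0.5, 0.05)
      big <- rnorm(10000, 0.5, 0.05)
    })
    fs <- list(mu = mean(small), sigma = sd(small))
    fb <- list(mu = mean(big), sigma = sd(big))
    kl_resampled(fs, q, 5000, seed = 100 + s) -
      kl_resampled(fb, q, 5000, seed = 200 + s)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("estimator error shrinks with the number of resamples", {
  p <- list(mu = 0, sigma = 1); q <- list(mu = 1, sigma = 1)
  target <- (kl_gaussian(p, q) + kl_gaussian(q, p)) / 2
  ns <- c(500, 2000, 5000, 20000)
  errs <- vapply(ns, function(n) {
    mean(vapply(1:8, function(s) {
      abs((kl_resampled(p, q, n, seed = s) +
             kl_resampled(q, p, n, seed = 50 + s)) / 2 - target)
    }, numeric(1)))
  }, numeric(1))
  # convergence: |error| grows with 1/sqrt(n), i.e. shrinks as n grows
  expect_gt(coef(lm(errs ~ I(1 / sqrt(ns))))[2], 0)
  expect_lt(errs[4], errs[1])
})

test_that("edge_weight is the symmetrized inverse-divergence transform", {
  expect_equal(edge_weight(0, 0), 1)
  expect_equal(edge_weight(1, 1), 0.5)
  expect_equal(edge_weight(2, 0), edge_weight(0, 2))
  expect_error(edge_weight(-0.1, 0), class = "ratmind_invalid_argument")
})

test_that("networks from one distribution are near-complete similarity", {
  withr::with_seed(11, {
    v <- tibble::tibble(Label = rep(sprintf("R%d", 1:6), each = 1000),
                        MTR = rnorm(6000, 0.5, 0.05))
  })
  net <- build_mind_network(v, n_resamples = 5000, seed = 1)
  expect_valid_network(net)
  expect_true(all(upper_w(net) > 0.9))
})

test_that("planted two-block structure is recovered", {
  v <- two_block_voxels(n_per_block = 3, gap = 0.3, seed = 2)
  net <- build_mind_network(v, n_resamples = 2000, seed = 1)
  expect_valid_network(net)
  w <- as.matrix(net)
  same_block <- outer(substr(net$nodes, 1, 2), substr(net$nodes, 1, 2), "==")
  ut <- upper.tri(w)
  expect_gt(mean(w[ut & same_block]), mean(w[ut & !same_block]))
})

test_that("resampled and analytic estimators agree on the same scan", {
  truth <- clustered_truth(20, 4, seed = 7)
  scan <- generate_scan(truth, age = 20, seed = 3)
  res <- build_mind_network(scan, estimator = "resampled",
                            n_resamples = 5000, seed = 3)
  ana <- build_mind_network(scan, estimator = "analytic")
  dv <- abs(upper_w(res) - upper_w(ana))
  expect_lt(mean(dv), 0.05)
  expect_lt(unname(quantile(dv, 0.95)), 0.05)
  expect_gt(cor(upper_w(res), upper_w(ana)), 0.98)
})

test_that("networks recover the planted similarity structure", {
  truth <- clustered_truth(20, 4, seed = 5)
  truth$regions$n_voxels <- rep(500L, 20)
  truth2 <- generative_truth(truth$regions)
  scan <- generate_scan(truth2, age = 20, seed = 9)
  net <- build_mind_network(scan, estimator = "resampled",
                            n_resamples = 5000, seed = 2)
  expect_gt(cor(upper_w(net), truth2$true_similarity[upper.tri(
    truth2$true_similarity)]), 0.9)
})

test_that("resample count barely changes the network", {
  truth <- clustered_truth(15, 3, seed = 13)
  scan <- generate_scan(truth, age = 20, seed = 4)
  n2 <- build_mind_network(scan, n_resamples = 2000, seed = 5)
  n5 <- build_mind_network(scan, n_resamples = 5000, seed = 6)
  expect_gt(cor(upper_w(n2), upper_w(n5)), 0.99)
})

test_that("regions below min_voxels are dropped with a record", {
  v <- tibble::tibble(Label = c(rep("A", 100), rep("B", 100), rep("C", 5)),
                      MTR = rnorm(205, 0.5, 0.05))
  net <- build_mind_network(v, estimator = "analytic", min_voxels = 20)
  expect_equal(net$meta$dropped_regions, "C")
  expect_equal(net$nodes, c("A", "B"))
  tiny <- tibble::tibble(Label = c("A", "B"), MTR = c(0.1, 0.2))
  expect_error(build_mind_network(tiny, min_voxels = 20),
               class = "ratmind_pipeline_error")
})

test_that("median_network is the element-wise median with matched nodes", {
  w <- random_network(4, seed = 1)
  net <- as_net(w)
  expect_equal(as.matrix(median_network(list(net))), w)

  mk <- function(val) {
    m <- w; m[1, 2] <- m[2, 1] <- val; as_net(m)
  }
  med <- median_network(list(mk(0.2), mk(0.5), mk(0.9)))
  expect_equal(as.matrix(med)[1, 2], 0.5)
  expect_equal(med$meta$n_contributing, 3)

  shuf <- w[c(2, 1, 3, 4), c(2, 1, 3, 4)]
  expect_error(median_network(list(net, as_net(shuf))),
               class = "ratmind_invalid_argument")
})

test_that("networks round-trip through CSV and tidy to edge tables", {
  net <- as_net(random_network(5, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mind_network(net, path)
  back <- read_mind_network(path)
  expect_equal(as.matrix(back), as.matrix(net))
  td <- tidy(net)
  expect_equal(nrow(td), 10)
  expect_equal(td$weight[td$region_a == "N01" & td$region_b == "N02"],
               as.matrix(net)["N01", "N02"])
  gl <- glance(net)
  expect_equal(gl$n_nodes, 5)
  expect_equal(gl$n_edges, 10)
})
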