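#' Fit a region's Gaussian feature distribution
#'
#' Estimates the Gaussian distribution of a region's voxel MTR values: `mu`
#' is the sample mean and `sigma` the sample SD (n-1 denominator), floored at
#' `sigma_floor` so degenerate (near-constant) regions cannot produce
#' infinite divergences.
#'
#' @param voxels Tibble with columns `Label`, `MTR`.
#' @param region Region label to fit.
#' @param min_voxels Minimum voxel count required. Default 20.
#' @param sigma_floor Lower bound on `sigma`. Default `NULL`: 1e-6 times the
#'   global SD of all values in `voxels` (or 1e-12 if that SD is 0/undefined).
#' @return One-row tibble: `region_id`, `mu`, `sigma`, `n_voxels`.
#' @examples
#' v <- tibble::tibble(Label = "A", MTR = c(1, 2, 3))
#' fit_region_distribution(v, "A", min_voxels = 3)
#' @export
fit_region_distribution <- function(voxels, region, min_voxels = 20,
                                    sigma_floor = NULL) {
  vals <- voxels$MTR[voxels$Label == region]
  if (length(vals) < min_voxels) {
    abort(sprintf("Region '%s' has %d voxels; min_voxels = %d.",
                  region, length(vals), min_voxels),
          class = "ratmind_insufficient_data")
  }
  sigma_floor <- sigma_floor %||% default_sigma_floor(voxels$MTR)
  s <- sd(vals)
  if (!is.finite(s)) s <- 0
  tibble::tibble(region_id = region, mu = mean(vals),
                 sigma = max(s, sigma_floor),
                 n_voxels = length(vals))
}

default_sigma_floor <- function(values) {
  g <- sd(values)
  if (!is.finite(g) || g <= 0) 1e-12 else 1e-6 * g
}

#' Closed-form KL divergence between two fitted Gaussians
#'
#' `KL(p || q) = log(sigma_q / sigma_p) +
#'  (sigma_p^2 + (mu_p - mu_q)^2) / (2 sigma_q^2) - 1/2` (nats); asymmetric
#' in its arguments. This is the analytic oracle and fast path for the
#' resampling estimator.
#'
#' @param p,q Fitted distributions (lists or one-row data frames with `mu`,
#'   `sigma`).
#' @return KL divergence in nats.
#' @examples
#' kl_gaussian(list(mu = 0, sigma = 1), list(mu = 1, sigma = 1)) # 0.5
#' @export
kl_gaussian <- function(p, q) {
  if (p$sigma <= 0 || q$sigma <= 0) abort_invalid("Sigmas must be positive.")
  log(q$sigma / p$sigma) + (p$sigma^2 + (p$mu - q$mu)^2) / (2 * q$sigma^2) - 0.5
}

# k-th nearest-neighbour distance of each element of sorted vector `x`
# within x itself (self excluded). The k nearest of a point in a sorted
# vector form a contiguous window adjacent to it, so the k-th NN distance is
# the minimum over window splits of the larger boundary distance.
kth_nn_self <- function(x, k) {
  n <- length(x)
  best <- rep(Inf, n)
  for (j in 0:k) {
    left <- if (j == 0L) rep(0, n) else {
      c(rep(Inf, j), x[(j + 1L):n] - x[seq_len(n - j)])
    }
    r <- k - j
    right <- if (r == 0L) rep(0, n) else {
      c(x[(r + 1L):n] - x[seq_len(n - r)], rep(Inf, r))
    }
    best <- pmin(best, pmax(left, right))
  }
  best
}

# k-th NN distance from each element of `x` to the sorted vector `sy`.
kth_nn_cross <- function(x, sy, k) {
  m <- length(sy)
  pos <- findInterval(x, sy)
  best <- rep(Inf, length(x))
  for (j in 0:k) {
    li <- pos - j + 1L           # left boundary index when taking j from left
    ri <- pos + (k - j)          # right boundary index
    left <- if (j == 0L) 0 else ifelse(li >= 1L, x - sy[pmax(li, 1L)], Inf)
    right <- if (k - j == 0L) 0 else {
      ifelse(ri <= m, sy[pmin(ri, m)] - x, Inf)
    }
    best <- pmin(best, pmax(left, right))
  }
  best
}

# Nonparametric k-NN KL divergence estimate between 1-D samples x ~ P, y ~ Q
# (Wang-Kulkarni-Verdu style): mean log ratio of k-th NN distances plus the
# sample-size correction, truncated below at 0.
kl_knn_1d <- function(x, y, k = 3L) {
  n <- length(x); m <- length(y)
  if (n < k + 1L || m < k) abort_invalid("Samples too small for k-NN KL.")
  sx <- sort(x)
  rho <- pmax(kth_nn_self(sx, k), .Machine$double.eps)
  nu <- pmax(kth_nn_cross(sx, sort(y), k), .Machine$double.eps)
  max(mean(log(nu / rho)) + log(m / (n - 1)), 0)
}

#' Resampling-based KL divergence between two fitted regions
#'
#' The region-balancing estimator: draws `n_resamples` points from each
#' fitted Gaussian so both regions contribute equally many datapoints
#' regardless of region size, then estimates `KL(p || q)` nonparametrically
#' with a k-nearest-neighbour density estimate (k = 3). Negative estimates
#' truncate to 0 so downstream edge weights stay in (0, 1].
#'
#' @inheritParams kl_gaussian
#' @param n_resamples Number of draws per region (>= 100). Default 5000.
#' @param seed Integer seed; same seed, same estimate.
#' @param k Nearest-neighbour order. Default 3.
#' @return Nonnegative KL estimate in nats.
#' @export
kl_resampled <- function(p, q, n_resamples = 5000, seed = 1, k = 3L) {
  if (n_resamples < 100) abort_invalid("`n_resamples` must be >= 100.")
  if (p$sigma <= 0 || q$sigma <= 0) abort_invalid("Sigmas must be positive.")
  with_preserved_seed(seed, {
    x <- rnorm(n_resamples, p$mu, p$sigma)
    y <- rnorm(n_resamples, q$mu, q$sigma)
    kl_knn_1d(x, y, k = k)
  })
}

#' Edge weight from a pair of directed divergences
#'
#' `w = 1 / (1 + KLsym)` with `KLsym = (KL(p||q) + KL(q||p)) / 2`. Averaging
#' the two directions before the transform yields the symmetric weights all
#' downstream analyses require; `w` is strictly decreasing in `KLsym` and
#' lies in (0, 1].
#'
#' @param kl_pq,kl_qp Nonnegative divergences (vectorized).
#' @return Edge weight(s) in (0, 1].
#' @examples
#' edge_weight(1, 1) # 0.5
#' @export
edge_weight <- function(kl_pq, kl_qp) {
  if (any(!is.finite(kl_pq)) || any(!is.finite(kl_qp)) ||
      any(kl_pq < 0) || any(kl_qp < 0)) {
    abort_invalid("Divergences must be finite and nonnegative.")
  }
  1 / (1 + (kl_pq + kl_qp) / 2)
}
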