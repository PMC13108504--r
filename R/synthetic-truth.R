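#' Generate a synthetic cortical parcellation with regional feature models
#'
#' Creates `n_regions` generative region models grouped into `n_systems`
#' contiguous cortical systems. Same-system regions cluster spatially and
#' regional MTR means follow a smooth spatial gradient plus a system offset
#' plus independent regional noise, so that spatially close regions have
#' similar generative distributions — the coupling that gives similarity
#' networks their characteristic negative distance-weight relationship.
#'
#' Each row is one region's generative model: a Gaussian over voxel MTR
#' values with mean `mu`, standard deviation `sigma`, and `n_voxels` voxels.
#'
#' @param n_regions Number of cortical regions (default 53, the size of the
#'   rat cortical parcellation the pipeline targets).
#' @param n_systems Number of coarse-grained cortical systems (default 15).
#' @param seed Integer seed; the same seed reproduces the parcellation.
#' @param mu_base Grand mean MTR (dimensionless ratio). Default 0.5.
#' @param gradient Spatial gradient of `mu` per spatial unit along a random
#'   direction. Default 0.015.
#' @param system_offset_sd SD of per-system `mu` offsets. Default 0.03.
#' @param region_noise_sd SD of independent per-region `mu` noise. Default 0.01.
#' @param sigma_range Range of per-region voxel SDs, drawn uniformly.
#'   Default `c(0.04, 0.08)`.
#' @param n_voxel_range Range of per-region voxel counts, drawn log-uniformly.
#'   Default `c(100, 2000)`.
#'
#' @return A tibble with columns `region_id`, `system_id`, `x`, `y`, `z`
#'   (centroid, abstract spatial units), `mu`, `sigma`, `n_voxels`.
#' @examples
#' regions <- generate_parcellation(12, 4, seed = 1)
#' dplyr::count(regions, system_id)
#' @export
generate_parcellation <- function(n_regions = 53, n_systems = 15, seed = 1,
                                  mu_base = 0.5, gradient = 0.015,
                                  system_offset_sd = 0.03,
                                  region_noise_sd = 0.01,
                                  sigma_range = c(0.04, 0.08),
                                  n_voxel_range = c(100, 2000)) {
  n_regions <- check_count(n_regions, "n_regions")
  n_systems <- check_count(n_systems, "n_systems")
  if (n_systems > n_regions) {
    abort_invalid("`n_systems` must not exceed `n_regions`.")
  }
  with_preserved_seed(seed, {
    # contiguous system blocks, sizes differing by at most one
    sizes <- rep(n_regions %/% n_systems, n_systems)
    extra <- n_regions %% n_systems
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    system_id <- rep(sprintf("SYS%02d", seq_len(n_systems)), times = sizes)

    centers <- matrix(runif(3L * n_systems, 0, 10), ncol = 3L)
    cent <- centers[rep(seq_len(n_systems), times = sizes), , drop = FALSE] +
      matrix(rnorm(3L * n_regions, 0, 0.8), ncol = 3L)

    dir <- rnorm(3L)
    dir <- dir / sqrt(sum(dir^2))
    sys_off <- rnorm(n_systems, 0, system_offset_sd)
    mu <- mu_base + gradient * drop(cent %*% dir) +
      sys_off[rep(seq_len(n_systems), times = sizes)] +
      rnorm(n_regions, 0, region_noise_sd)

    sigma <- runif(n_regions, sigma_range[1L], sigma_range[2L])
    n_vox <- pmax(10L, round(exp(runif(
      n_regions, log(n_voxel_range[1L]), log(n_voxel_range[2L])
    ))))

    tibble::tibble(
      region_id = sprintf("R%03d", seq_len(n_regions)),
      system_id = system_id,
      x = cent[, 1L], y = cent[, 2L], z = cent[, 3L],
      mu = mu, sigma = sigma, n_voxels = as.integer(n_vox)
    )
  })
}

#' Analytic edge weight between two generative region models
#'
#' Ground-truth similarity: `w = 1 / (1 + KLsym)` where `KLsym` is the
#' symmetrized closed-form KL divergence between the two regions' Gaussian
#' voxel-value distributions. Used as the planted truth that estimated
#' networks are checked against.
#'
#' @param model_i,model_j One-row data frames (or lists) with fields `mu` and
#'   `sigma`.
#' @return Edge weight in (0, 1]; 1 for identical models.
#' @examples
#' true_edge_weight(list(mu = 0, sigma = 1), list(mu = 1, sigma = 1)) # 2/3
#' @export
true_edge_weight <- function(model_i, model_j) {
  if (model_i$sigma <= 0 || model_j$sigma <= 0) {
    abort_invalid("Both `sigma` values must be positive.")
  }
  kl_sym <- (kl_gaussian(model_i, model_j) + kl_gaussian(model_j, model_i)) / 2
  1 / (1 + kl_sym)
}

# Symmetric analytic similarity matrix from mu/sigma vectors.
analytic_similarity <- function(mu, sigma, labels) {
  n <- length(mu)
  kl <- matrix(0, n, n)
  for (i in seq_len(n)) {
    kl[i, ] <- log(sigma / sigma[i]) +
      (sigma[i]^2 + (mu[i] - mu)^2) / (2 * sigma^2) - 0.5
  }
  w <- 1 / (1 + (kl + t(kl)) / 2)
  diag(w) <- 1
  dimnames(w) <- list(labels, labels)
  w
}

#' Assemble the generative ground truth for a synthetic cohort
#'
#' Bundles a parcellation's region models with the longitudinal and
#' case-control effect structure used by [generate_scan()] and
#' [generate_cohort()]: per-system developmental and aging slopes on the
#' regional MTR means, a per-system offset applied to stressed animals from
#' `stress_onset_age` onward, a subject random intercept SD, and a total
#' brain volume coefficient. The analytic similarity matrix implied by the
#' baseline region models is stored as `true_similarity`.
#'
#' Age enters piecewise: means change by `dev_slope` per day over PND 20-35,
#' are flat over PND 35-63, and change by `age_slope` per day over PND
#' 63-290. Baseline (`mu`) is anchored at PND 20.
#'
#' @param regions Tibble from [generate_parcellation()].
#' @param dev_slope Per-system named vector (or scalar) of MTR change per
#'   postnatal day during development (PND 20-35). Default 0.
#' @param age_slope As `dev_slope`, for the aging epoch (PND 63-290).
#' @param group_offset Per-system named vector (or scalar) of MTR shift in
#'   stressed animals. Default 0.
#' @param subject_sd SD of subject random intercepts on the feature mean.
#'   Default 0.01 (biological scan-to-scan offsets; a package choice, see the
#'   methods vignette).
#' @param tbv_coef Coefficient linking standardized total brain volume to the
#'   feature mean. Default 0.005.
#' @param stress_onset_age Age (PND) from which `group_offset` applies.
#'   Default 63, the adult case-control timepoint.
#'
#' @return An object of class `generative_truth`.
#' @export
generative_truth <- function(regions, dev_slope = 0, age_slope = 0,
                             group_offset = 0, subject_sd = 0.01,
                             tbv_coef = 0.005, stress_onset_age = 63) {
  stopifnot(is.data.frame(regions),
            all(c("region_id", "system_id", "mu", "sigma", "n_voxels")
                %in% names(regions)))
  if (any(regions$sigma <= 0)) abort_invalid("All region sigmas must be > 0.")
  if (any(regions$n_voxels < 10)) {
    abort_invalid("All regions must have n_voxels >= 10.")
  }
  systems <- unique(regions$system_id)
  expand <- function(x, name) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- setNames(rep(as.numeric(x), length(systems)), systems)
    }
    if (!all(systems %in% names(x))) {
      abort_invalid(sprintf("`%s` must name every system.", name))
    }
    if (any(!is.finite(x))) abort_invalid(sprintf("`%s` must be finite.", name))
    x[systems]
  }
  check_number(subject_sd, "subject_sd", lower = 0)
  check_number(tbv_coef, "tbv_coef", finite = TRUE)
  structure(
    list(
      regions = regions,
      true_similarity = analytic_similarity(regions$mu, regions$sigma,
                                            regions$region_id),
      dev_slope = expand(dev_slope, "dev_slope"),
      age_slope = expand(age_slope, "age_slope"),
      group_offset = expand(group_offset, "group_offset"),
      subject_sd = subject_sd,
      tbv_coef = tbv_coef,
      stress_onset_age = stress_onset_age,
      age_range = c(20, 290)
    ),
    class = "generative_truth"
  )
}

#' @export
print.generative_truth <- function(x, ...) {
  cat(sprintf(
    "<generative_truth> %d regions in %d systems; subject_sd = %g, tbv_coef = %g\n",
    nrow(x$regions), length(unique(x$regions$system_id)),
    x$subject_sd, x$tbv_coef))
  invisible(x)
}

# Piecewise age effect on the regional mean for one system (relative to the
# PND 20 baseline): dev slope over 20-35, plateau 35-63, aging slope 63-290.
age_effect <- function(truth, system, age) {
  dev <- truth$dev_slope[system] * (pmin(age, 35) - 20)
  agn <- truth$age_slope[system] * pmax(age - 63, 0)
  unname(dev + agn)
}

# Regional means at a given age/group (group offset applies from onset age).
region_means_at <- function(truth, age, group = "control") {
  r <- truth$regions
  mu <- r$mu + age_effect(truth, r$system_id, age)
  if (identical(group, "stressed") && age >= truth$stress_onset_age) {
    mu <- mu + unname(truth$group_offset[r$system_id])
  }
  mu
}

#' Analytic similarity matrix at a given age and group
#'
#' Evaluates the planted ground-truth network after applying the epoch slopes
#' (and, for stressed animals, the group offset) to the baseline regional
#' means. Used to compare estimated networks against truth at the age the
#' scan was simulated.
#'
#' @param truth A [generative_truth()] object.
#' @param age Age in postnatal days.
#' @param group `"control"` or `"stressed"`.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
true_similarity_at <- function(truth, age, group = "control") {
  stopifnot(inherits(truth, "generative_truth"))
  mu <- region_means_at(truth, age, group)
  analytic_similarity(mu, truth$regions$sigma, truth$regions$region_id)
}
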