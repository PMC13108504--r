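#' Specify a synthetic cohort design
#'
#' @param n_subjects Number of animals.
#' @param timepoints Strictly increasing ages (postnatal days) at which every
#'   subject is scanned. Default `c(20, 35, 63, 230)`, the longitudinal
#'   design the generator emulates.
#' @param groups Named allocation fractions over group labels, summing to 1.
#'   Default all-control.
#' @param sexes Named allocation fractions over sexes, summing to 1.
#'   Default all-male (the normative cohort design).
#' @param missingness Fraction of scans dropped completely at random.
#'   Default 0.
#' @param seed Integer seed for the cohort.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(8, timepoints = c(20, 35), seed = 1)
#' @export
cohort_spec <- function(n_subjects, timepoints = c(20, 35, 63, 230),
                        groups = c(control = 1), sexes = c(male = 1),
                        missingness = 0, seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (length(timepoints) < 1L || any(diff(timepoints) <= 0)) {
    abort_invalid("`timepoints` must be strictly increasing.")
  }
  check_fracs <- function(x, name) {
    if (is.null(names(x)) || any(x < 0) || abs(sum(x) - 1) > 1e-8) {
      abort_invalid(sprintf("`%s` must be named fractions summing to 1.", name))
    }
  }
  check_fracs(groups, "groups")
  check_fracs(sexes, "sexes")
  check_number(missingness, "missingness", lower = 0)
  structure(
    list(n_subjects = n_subjects, timepoints = timepoints, groups = groups,
         sexes = sexes, missingness = missingness, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate one scan's voxel table from the generative truth
#'
#' For each region, draws `n_voxels` values from a Gaussian whose mean is the
#' region's baseline `mu` shifted by the epoch slope for the scan age, the
#' group offset (stressed animals at or past the onset age, targeted systems
#' only), the TBV effect, and the subject intercept; the SD is the region's
#' `sigma`. The result is a voxel table in the pipeline's `Label,MTR` layout.
#'
#' @param truth A [generative_truth()] object.
#' @param subject_intercept Subject-level shift of all regional means.
#' @param age Scan age in postnatal days (within the supported 20-290 range).
#' @param group Group label, `"control"` or `"stressed"`.
#' @param tbv Standardized total brain volume for this scan.
#' @param seed Integer seed; same arguments and seed give a byte-identical
#'   table.
#' @return A tibble with columns `Label` (region id) and `MTR` (voxel value).
#' @export
generate_scan <- function(truth, subject_intercept = 0, age = 63,
                          group = "control", tbv = 0, seed = 1) {
  stopifnot(inherits(truth, "generative_truth"))
  if (!group %in% c("control", "stressed")) {
    abort_invalid(sprintf("Unknown group label '%s'.", group))
  }
  if (age < truth$age_range[1L] || age > truth$age_range[2L]) {
    abort_invalid(sprintf("`age` %s is outside the supported range [%d, %d].",
                          format(age), truth$age_range[1L], truth$age_range[2L]))
  }
  r <- truth$regions
  mu <- region_means_at(truth, age, group) +
    truth$tbv_coef * tbv + subject_intercept
  with_preserved_seed(seed, {
    values <- rnorm(sum(r$n_voxels),
                    mean = rep(mu, r$n_voxels),
                    sd = rep(r$sigma, r$n_voxels))
    tibble::tibble(Label = rep(r$region_id, r$n_voxels), MTR = values)
  })
}

#' Simulate a full cohort of scans with aligned metadata
#'
#' Draws subject intercepts once per subject (SD `truth$subject_sd`), assigns
#' groups and sexes by the spec's allocation fractions (counts rounded to the
#' nearest integers summing to `n_subjects`, assignment order randomized),
#' gives each subject a standardized TBV with small scan-level jitter, and
#' simulates one voxel table per subject x timepoint. Per-scan seeds derive
#' deterministically from the cohort seed, subject, and timepoint, so any
#' scan can be regenerated independently.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [generative_truth()].
#' @return A list with `scans` (named list of voxel tables, one per scan) and
#'   `cohort` (tibble with `scan_id`, `subject`, `age_pnd`, `sex`, `group`,
#'   `tbv`, rows aligned one-to-one with `scans`).
#' @export
generate_cohort <- function(spec, truth) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "generative_truth"))
  n <- spec$n_subjects
  alloc <- function(fracs) {
    counts <- floor(fracs * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      top <- order(fracs * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1L
    }
    rep(names(fracs), times = counts)
  }
  design <- with_preserved_seed(spec$seed, {
    tibble::tibble(
      subject = sprintf("S%03d", seq_len(n)),
      group = sample(alloc(spec$groups)),
      sex = sample(alloc(spec$sexes)),
      intercept = rnorm(n, 0, truth$subject_sd),
      tbv_base = rnorm(n, 0, 1)
    )
  })
  cohort <- tidyr::expand_grid(design, age_pnd = spec$timepoints)
  cohort$scan_id <- sprintf("%s_PND%03d", cohort$subject, cohort$age_pnd)
  scan_seeds <- purrr::map2_int(cohort$subject, cohort$age_pnd,
                                ~ derive_seed(spec$seed, "scan", .x, .y))
  cohort$tbv <- with_preserved_seed(derive_seed(spec$seed, "tbv"),
                                    cohort$tbv_base + rnorm(nrow(cohort), 0, 0.1))
  if (spec$missingness > 0) {
    keep <- with_preserved_seed(
      derive_seed(spec$seed, "missing"),
      runif(nrow(cohort)) >= spec$missingness
    )
    cohort <- cohort[keep, , drop = FALSE]
    scan_seeds <- scan_seeds[keep]
  }
  scans <- purrr::pmap(
    list(cohort$intercept, cohort$age_pnd, cohort$group, cohort$tbv, scan_seeds),
    function(ic, age, grp, tbv, sd_) {
      generate_scan(truth, subject_intercept = ic, age = age, group = grp,
                    tbv = tbv, seed = sd_)
    }
  )
  names(scans) <- cohort$scan_id
  cohort <- dplyr::select(cohort, "scan_id", "subject", "age_pnd", "sex",
                          "group", "tbv")
  list(scans = scans, cohort = cohort)
}
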