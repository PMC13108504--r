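# Shared small longitudinal cohort with planted, direction-controlled
# effects: SYS01 sits below the pack and converges during development
# (strength rises, t > 0); SYS02 diverges from the pack during aging
# (its strengths fall, t < 0); SYS03 is shifted away in stressed animals.
planted_cohort <- function(seed, n_subjects = 12, groups = c(control = 0.5,
                                                             stressed = 0.5)) {
  regions <- generate_parcellation(20, 4, seed = 17,
                                   sigma_range = c(0.05, 0.07))
  regions$mu[regions$system_id == "SYS01"] <- 0.40 +
    seq(-0.004, 0.004, length.out = sum(regions$system_id == "SYS01"))
  regions$mu[regions$system_id == "SYS02"] <- 0.44 +
    seq(-0.004, 0.004, length.out = sum(regions$system_id == "SYS02"))
  regions$mu[regions$system_id == "SYS03"] <- 0.56 +
    seq(-0.004, 0.004, length.out = sum(regions$system_id == "SYS03"))
  truth <- generative_truth(
    regions,
    dev_slope = c(SYS01 = 0.003, SYS02 = 0, SYS03 = 0, SYS04 = 0),
    age_slope = c(SYS01 = 0, SYS02 = -0.0004, SYS03 = 0, SYS04 = 0),
    group_offset = c(SYS01 = 0, SYS02 = 0, SYS03 = 0.06, SYS04 = 0),
    subject_sd = 0.01)
  spec <- cohort_spec(n_subjects, groups = groups,
                      sexes = c(male = 0.5, female = 0.5), seed = seed)
  sim <- generate_cohort(spec, truth)
  nets <- lapply(sim$scans, build_mind_network, estimator = "analytic",
                 min_voxels = 10)
  list(truth = truth, cohort = sim$cohort, networks = nets,
       regions = regions)
}

test_that("normalize_measure z-scores with the sample SD", {
  expect_equal(normalize_measure(c(1, 2, 3)), c(-1, 0, 1))
  z <- normalize_measure(rnorm(20))
  expect_equal(normalize_measure(z), z, tolerance = 1e-12)
  expect_error(normalize_measure(rep(2, 5)),
               class = "ratmind_invalid_argument")
})

test_that("epochs subset scans at the documented inclusive bounds", {
  cohort <- tibble::tibble(age_pnd = c(20, 35, 63, 230), scan_id = 1:4)
  expect_equal(select_epoch(cohort, "development")$age_pnd, c(20, 35))
  expect_equal(select_epoch(cohort, "aging")$age_pnd, c(63, 230))
  expect_error(select_epoch(tibble::tibble(age_pnd = 50), "development"),
               class = "ratmind_pipeline_error")
})

fixture <- planted_cohort(seed = 101)
sobs <- strength_observations(fixture$networks, fixture$cohort)
sys_regions <- function(fx, sys) {
  fx$regions$region_id[fx$regions$system_id == sys]
}

test_that("node slopes recover the planted development effect", {
  dev <- fit_node_slopes(select_epoch(sobs, "development"),
                         epoch = "development")
  t_target <- dev$t_stat[dev$unit %in% sys_regions(fixture, "SYS01")]
  expect_true(all(t_target > 0))
  expect_true(all(abs(dev$t_stat) < Inf))
  expect_true(all(dev$epoch == "development"))

  single_tp <- sobs[sobs$age_pnd == 63, ]
  expect_error(fit_node_slope(single_tp, single_tp$unit[1]),
               class = "ratmind_invalid_argument")
})

test_that("system-edge slopes recover the planted aging divergence", {
  eobs <- edge_observations(fixture$networks, fixture$cohort,
                            as_parcellation(fixture$regions))
  aging <- select_epoch(eobs, "aging")
  res <- fit_system_edge_slope(aging, c("SYS02", "SYS04"), epoch = "aging")
  expect_lt(res$t_stat, 0)
  expect_gte(res$n_obs, nrow(fixture$cohort[fixture$cohort$age_pnd >= 63, ]))

  # single-ROI-edge unit: random effect degenerate, documented fallback
  one_edge <- aging[aging$roi_edge == aging$roi_edge[1], ]
  one_edge$unit <- one_edge$unit[1]
  res1 <- fit_system_edge_slope(one_edge,
                                strsplit(one_edge$unit[1], "|",
                                         fixed = TRUE)[[1]])
  expect_true(is.finite(res1$t_stat))
})

test_that("slope t statistics are monotone in the planted slope", {
  slopes <- c(-0.003, 0, 0.003)
  mean_t <- vapply(slopes, function(sl) {
    regions <- fixture$regions
    truth <- generative_truth(regions,
                              dev_slope = c(SYS01 = sl, SYS02 = 0,
                                            SYS03 = 0, SYS04 = 0),
                              subject_sd = 0.01)
    mean(vapply(1:3, function(cs) {
      sim <- generate_cohort(cohort_spec(8, timepoints = c(20, 35),
                                         seed = 300 + cs), truth)
      nets <- lapply(sim$scans, build_mind_network, estimator = "analytic",
                     min_voxels = 10)
      so <- strength_observations(nets, sim$cohort)
      dev <- fit_node_slopes(so, epoch = "development")
      mean(dev$t_stat[dev$unit %in% sys_regions(fixture, "SYS01")])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_t) > 0))
})

test_that("development and aging effects couple as planted", {
  dev <- fit_node_slopes(select_epoch(sobs, "development"))
  agn <- fit_node_slopes(select_epoch(sobs, "aging"))
  expect_equal(epoch_coupling(dev, dev)$r, 1)
  res <- epoch_coupling(dev, agn)
  expect_equal(res$n_units, 20)
  expect_error(epoch_coupling(dev, agn[-1, ]),
               class = "ratmind_invalid_argument")

  # planted anti-correlation between constructed slope tables
  base <- tibble::tibble(unit = letters[1:15],
                         t_stat = rnorm(15))
  anti <- tibble::tibble(unit = base$unit,
                         t_stat = -2 * base$t_stat +
                           withr::with_seed(1, rnorm(15, 0, 0.3)))
  expect_lt(epoch_coupling(base, anti)$r, 0)
})

test_that("group effects recover the planted stress offset", {
  cc <- sobs[sobs$age_pnd == 63, ]
  targets <- sys_regions(fixture, "SYS03")
  effs <- purrr::map_dfr(targets, ~ fit_group_effect(cc, .x))
  # the shifted system diverges from the pack: strength falls in stressed
  expect_true(all(effs$effect < 0))
  expect_error(fit_group_effect(cc[cc$group == "control", ], targets[1]),
               class = "ratmind_invalid_argument")

  cc_na <- cc
  cc_na$tbv[1] <- NA
  expect_warning(fit_group_effect(cc_na, cc_na$unit[1]), "TBV")
})

test_that("the residualized group effect equals the lm coefficient", {
  cc <- sobs[sobs$age_pnd == 63, ]
  u <- cc$unit[5]
  df <- cc[cc$unit == u, ]
  eff <- fit_group_effect(cc, u)$effect
  lm_eff <- unname(coef(lm(normalize_measure(value) ~
                             I(group == "stressed") + sex + tbv,
                           data = df))[2])
  expect_equal(eff, lm_eff)
})

test_that("subject-level permutation nulls flag planted units", {
  cc <- sobs[sobs$age_pnd == 63, ]
  res <- permuted_group_null(cc, n_perm = 200, seed = 4)
  targets <- sys_regions(fixture, "SYS03")
  expect_true(all(res$significant[res$unit %in% targets]))
  expect_identical(res, permuted_group_null(cc, n_perm = 200, seed = 4))
  expect_error(permuted_group_null(cc, n_perm = 50),
               class = "ratmind_invalid_argument")

  expect_true(all(c("degenerate", "z_perm") %in% names(res)))
  expect_false(any(res$degenerate))
})

test_that("stress-development coupling has identity and planted cases", {
  slopes <- tibble::tibble(unit = sprintf("u%02d", 1:40),
                           t_stat = withr::with_seed(2, rnorm(40)))
  ident <- tibble::tibble(unit = slopes$unit, effect = slopes$t_stat)
  res <- stress_development_coupling(ident, slopes, n_perm = 999, seed = 1)
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1 / 1000)

  noisy <- tibble::tibble(unit = slopes$unit,
                          effect = slopes$t_stat +
                            withr::with_seed(3, rnorm(40, 0, 0.5)))
  res2 <- stress_development_coupling(noisy, slopes, n_perm = 499, seed = 2)
  expect_gt(res2$observed, 0)
  expect_lt(res2$p, 0.05)
  expect_error(stress_development_coupling(ident[-1, ], slopes, 100, 1),
               class = "ratmind_invalid_argument")
})

test_that("subject-level permutation preserves scan multiplicity", {
  cc <- sobs[sobs$unit == sobs$unit[1], ]
  tab_before <- table(cc$subject)
  # permuting group labels at subject level never changes each subject's
  # number of scans entering the model
  res <- permuted_group_null(sobs[sobs$age_pnd == 63, ], n_perm = 100,
                             seed = 9)
  expect_true(all(res$n_perm == 100))
  expect_identical(table(cc$subject), tab_before)
})

test_that("with no subject variance, mixed and OLS slopes agree", {
  regions <- fixture$regions
  truth0 <- generative_truth(regions,
                             dev_slope = c(SYS01 = 0.003, SYS02 = 0,
                                           SYS03 = 0, SYS04 = 0),
                             subject_sd = 0)
  sim <- generate_cohort(cohort_spec(16, timepoints = c(20, 35), seed = 77),
                         truth0)
  nets <- lapply(sim$scans, build_mind_network, estimator = "analytic",
                 min_voxels = 10)
  so <- strength_observations(nets, sim$cohort)
  rel <- vapply(unique(so$unit), function(u) {
    mixed <- fit_node_slope(so, u)
    df <- so[so$unit == u, ]
    ols <- summary(lm(normalize_measure(value) ~ age_pnd + tbv, data = df))
    t_ols <- ols$coefficients["age_pnd", "t value"]
    abs(mixed$t_stat - t_ols) / abs(t_ols)
  }, numeric(1))
  expect_lt(median(rel), 0.10)
})

test_that("strength distributions across timepoints: omnibus and Dunn", {
  strengths <- sobs[sobs$group == "control",
                    c("age_pnd", "unit", "value")]
  res <- strength_distribution_tests(strengths)
  expect_true(res$omnibus$p_value >= 0 && res$omnibus$p_value <= 1)
  expect_equal(nrow(res$pairwise), choose(4, 2))
  ord <- order(res$pairwise$p_value)
  expect_true(all(diff(res$pairwise$q_value[ord]) >= -1e-12))

  # planted location shift at one timepoint is detected
  shifted <- strengths
  shifted$value[shifted$age_pnd == 20] <-
    shifted$value[shifted$age_pnd == 20] - 10
  res2 <- strength_distribution_tests(shifted)
  expect_lt(res2$omnibus$p_value, 0.01)
  hit <- res2$pairwise[res2$pairwise$timepoint_a == "20" |
                         res2$pairwise$timepoint_b == "20", ]
  expect_true(all(hit$q_value < 0.05))

  expect_error(strength_distribution_tests(
    strengths[strengths$age_pnd == 63, ]),
    class = "ratmind_invalid_argument")
})
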