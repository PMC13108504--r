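# Covariate design matrix for the case-control models: intercept plus sex,
# age and TBV, with constant columns dropped (e.g. age at a single
# timepoint, sex in an all-male cohort).
group_design <- function(df) {
  X <- cbind(`(Intercept)` = 1,
             sex = as.numeric(factor(df$sex)) - 1,
             age_pnd = df$age_pnd,
             tbv = df$tbv)
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, function(c) sd(c) > 0))
  X[, keep, drop = FALSE]
}

# Group coefficient via Frisch-Waugh residualization; identical to the lm
# coefficient for group in norm ~ group + covariates. `g` may be a matrix of
# permuted group indicators (one column per permutation). Indicators that
# are (numerically) collinear with the covariates have no identifiable
# group effect and yield NA.
group_coef_fw <- function(qr_X, y, g) {
  yres <- qr.resid(qr_X, y)
  gres <- qr.resid(qr_X, g)
  if (is.matrix(gres)) {
    denom <- colSums(gres^2)
    out <- colSums(gres * yres) / denom
    out[denom < 1e-8] <- NA_real_
    out
  } else {
    denom <- sum(gres^2)
    if (denom < 1e-8) NA_real_ else sum(gres * yres) / denom
  }
}

#' Case-control group effect for one unit
#'
#' Fits `normalized value ~ group + sex + age + TBV` for a region's strength
#' (or, with `random_edges = TRUE`, adds an ROI-edge random intercept for
#' system-level edge weights) and returns the group coefficient — the
#' case-control effect size — at the adult timepoint. Rows with missing TBV
#' are dropped with a warning. Constant covariates (age at a single
#' timepoint, sex in a single-sex design) are dropped from the design.
#'
#' @param observations Observation tibble ([strength_observations()] or
#'   [edge_observations()]), typically restricted to one timepoint.
#' @param unit Unit label (`unit` column) to fit.
#' @param random_edges Add `(1 | roi_edge)` (system-level edge models).
#' @return One-row tibble: `unit`, `effect` (group coefficient on the
#'   normalized scale), `n_obs`, `n_stressed`, `model`.
#' @export
fit_group_effect <- function(observations, unit, random_edges = FALSE) {
  df <- observations[observations$unit == unit, , drop = FALSE]
  if (nrow(df) == 0L) abort_invalid(sprintf("Unit '%s' not found.", unit))
  if (length(unique(df$group)) < 2L) {
    abort_invalid("Both groups must be present.")
  }
  if (any(!is.finite(df$tbv))) {
    warn(sprintf("Dropping %d observation(s) with missing TBV.",
                 sum(!is.finite(df$tbv))))
    df <- df[is.finite(df$tbv), , drop = FALSE]
  }
  df$norm <- normalize_measure(df$value)
  g <- as.numeric(df$group == "stressed")
  model <- "lm"
  if (random_edges && length(unique(df$roi_edge)) >= 2L) {
    df$g <- g
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(norm ~ g + sex + age_pnd + tbv + (1 | roi_edge),
                   data = droplevels_constants(df), REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
      )),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
      model <- "lmer"
      eff <- lme4::fixef(fit)[["g"]]
      return(tibble::tibble(unit = unit, effect = eff, n_obs = nrow(df),
                            n_stressed = sum(g), model = model))
    }
  }
  X <- group_design(df)
  eff <- group_coef_fw(qr(X), df$norm, g)
  tibble::tibble(unit = unit, effect = eff, n_obs = nrow(df),
                 n_stressed = sum(g), model = model)
}

# Rewrite constant sex/age columns so lmer formulas stay full rank.
droplevels_constants <- function(df) {
  if (length(unique(df$sex)) < 2L) df$sex <- NULL
  if (length(unique(df$age_pnd)) < 2L) df$age_pnd <- NULL
  miss <- setdiff(c("sex", "age_pnd"), names(df))
  for (m in miss) df[[m]] <- 0
  df
}

#' Permutation null for case-control effects, all units at once
#'
#' For every unit in `observations`, computes the observed group effect
#' ([fit_group_effect()]'s region model) and a permutation distribution in
#' which group labels are reassigned at the *subject* level (all scans of a
#' subject move together), the model refit, and the effect recorded. The
#' z score of the observed effect within its permutation distribution is
#' returned; units with |z| > 1.96 are flagged significant. Degenerate
#' (zero-SD) permutation distributions yield `NA` z with a flag.
#'
#' Because the subject-level permutation is identical across units, the
#' permuted designs are shared and effects are computed by residualized
#' least squares in a single matrix operation per unit.
#'
#' @param observations Observation tibble restricted to the case-control
#'   timepoint, with both groups present.
#' @param n_perm Number of permutations (>= 100). Default 1000.
#' @param seed Integer seed.
#' @param z_threshold Significance threshold on |z|. Default 1.96.
#' @return Tibble: `unit`, `effect`, `z_perm`, `null_sd`, `significant`,
#'   `degenerate`, `n_perm`.
#' @export
permuted_group_null <- function(observations, n_perm = 1000, seed = 1,
                                z_threshold = 1.96) {
  if (n_perm < 100) abort_invalid("`n_perm` must be >= 100.")
  if (length(unique(observations$group)) < 2L) {
    abort_invalid("Both groups must be present.")
  }
  observations <- observations[is.finite(observations$tbv), , drop = FALSE]
  subjects <- dplyr::distinct(observations,
                              .data$subject, .data$group)
  if (anyDuplicated(subjects$subject)) {
    abort_invalid("Each subject must belong to exactly one group.")
  }
  perm_labels <- with_preserved_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sample(subjects$group),
           character(nrow(subjects)))
  })
  rownames(perm_labels) <- NULL
  subj_idx <- match(observations$subject, subjects$subject)
  units <- unique(observations$unit)
  purrr::map_dfr(units, function(u) {
    df <- observations[observations$unit == u, , drop = FALSE]
    y <- normalize_measure(df$value)
    X <- group_design(df)
    qr_X <- qr(X)
    g_obs <- as.numeric(df$group == "stressed")
    eff <- group_coef_fw(qr_X, y, g_obs)
    G <- (perm_labels[subj_idx[observations$unit == u], , drop = FALSE]
          == "stressed") * 1
    null_eff <- group_coef_fw(qr_X, y, G)
    # permutations whose labels are collinear with the covariates (e.g. an
    # exact sex match) carry no information about the group effect
    null_eff <- null_eff[is.finite(null_eff)]
    s <- sd(null_eff)
    degenerate <- !is.finite(s) || s == 0
    z <- if (degenerate) NA_real_ else (eff - mean(null_eff)) / s
    tibble::tibble(unit = u, effect = eff, z_perm = z, null_sd = s,
                   significant = !degenerate && abs(z) > z_threshold,
                   degenerate = degenerate, n_perm = n_perm)
  })
}

#' Coupling between developmental change and stress effects
#'
#' Pearson correlation between edge-level (or node-level) case-control
#' effect sizes and the corresponding developmental (or aging) t statistics,
#' with permutation inference: the unit assignment of the effect vector is
#' resampled `n_perm` times and the observed correlation's z score and
#' add-one p-value in that null distribution are reported.
#'
#' @param group_effects Tibble with columns `unit` and `effect` (e.g. from
#'   [permuted_group_null()] or [fit_group_effect()]).
#' @param slopes Tibble with columns `unit` and `t_stat` over the same units.
#' @param n_perm Number of permutations. Default 10000.
#' @param seed Integer seed.
#' @param alternative Passed to [permutation_z_p()]. Default `"greater"`.
#' @return A `permutation_result` with the observed r, z, and p.
#' @export
stress_development_coupling <- function(group_effects, slopes,
                                        n_perm = 10000, seed = 1,
                                        alternative = "greater") {
  if (!setequal(group_effects$unit, slopes$unit)) {
    abort_invalid("`group_effects` and `slopes` must cover the same units.")
  }
  j <- dplyr::inner_join(group_effects[, c("unit", "effect")],
                         slopes[, c("unit", "t_stat")], by = "unit")
  x <- j$t_stat
  y <- j$effect
  r_obs <- cor(x, y)
  xs <- (x - mean(x)) / sd(x)
  n <- length(x)
  null_r <- with_preserved_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- y[sample.int(n)]
      sum(xs * (yp - mean(yp))) / ((n - 1) * sd(yp))
    }, numeric(1))
  })
  permutation_z_p(r_obs, null_r, alternative = alternative)
}

#' Compare normative strength distributions across timepoints
#'
#' Reduces strengths to one value per region and timepoint (the median
#' across scans), runs a Kruskal-Wallis omnibus test of the per-region
#' strength distributions across timepoints, and follows up with Dunn's
#' pairwise rank comparisons (tie-corrected z statistics on the pooled
#' ranks) with Benjamini-Hochberg adjustment.
#'
#' @param strengths Tibble with columns `age_pnd`, `region` (or `unit`), and
#'   `strength` (or `value`); multiple scans per timepoint are medianed per
#'   region first.
#' @return List with `omnibus` (one-row tibble: `statistic`, `df`,
#'   `p_value`) and `pairwise` (tibble: `timepoint_a`, `timepoint_b`, `z`,
#'   `p_value`, `q_value`).
#' @export
strength_distribution_tests <- function(strengths) {
  names(strengths)[names(strengths) == "unit"] <- "region"
  names(strengths)[names(strengths) == "value"] <- "strength"
  stopifnot(all(c("age_pnd", "region", "strength") %in% names(strengths)))
  med <- dplyr::summarise(
    dplyr::group_by(strengths, .data$age_pnd, .data$region),
    strength = median(.data$strength), .groups = "drop")
  counts <- table(med$age_pnd)
  if (length(counts) < 2L || any(counts < 3L)) {
    abort_invalid("Need >= 2 timepoints with >= 3 regions each.")
  }
  kw <- stats::kruskal.test(med$strength, factor(med$age_pnd))
  # Dunn's test on the pooled ranks with tie correction
  g <- factor(med$age_pnd)
  r <- rank(med$strength)
  N <- length(r)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  combos <- utils::combn(levels(g), 2L)
  pw <- purrr::map_dfr(seq_len(ncol(combos)), function(ci) {
    a <- combos[1L, ci]; b <- combos[2L, ci]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    tibble::tibble(timepoint_a = a, timepoint_b = b, z = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
  })
  pw$q_value <- stats::p.adjust(pw$p_value, method = "BH")
  list(omnibus = tibble::tibble(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p_value = kw$p.value),
       pairwise = pw)
}
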