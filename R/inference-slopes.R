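# Shared mixed-model slope fit: normalized value ~ age + tbv with subject
# (and optionally ROI-edge) random intercepts; OLS fallback on singular or
# non-converged fits, flagged in the result.
fit_slope_engine <- function(df, random_edges = FALSE) {
  if (length(unique(df$age_pnd)) < 2L) {
    abort_invalid("Need at least 2 distinct ages to estimate a slope.")
  }
  df <- df[is.finite(df$tbv), , drop = FALSE]
  df$norm <- normalize_measure(df$value)
  n_subj <- length(unique(df$subject))
  terms <- "norm ~ age_pnd + tbv"
  re <- character()
  if (n_subj >= 2L && any(table(df$subject) >= 2L)) re <- "(1 | subject)"
  if (random_edges && length(unique(df$roi_edge)) >= 2L) {
    re <- c(re, "(1 | roi_edge)")
  }
  model <- "lm"; singular <- FALSE
  fit <- NULL
  if (length(re) > 0L) {
    form <- stats::as.formula(paste(c(terms, re), collapse = " + "))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = df, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
      )),
      error = function(e) NULL)
    if (!is.null(fit)) {
      singular <- lme4::isSingular(fit, tol = 1e-5)
      conv <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0L
      if (singular || !conv) fit <- NULL else model <- "lmer"
    }
  }
  if (is.null(fit)) {
    fit <- stats::lm(stats::as.formula(terms), data = df)
  }
  co <- if (model == "lmer") summary(fit)$coefficients else {
    summary(fit)$coefficients
  }
  est <- co["age_pnd", "Estimate"]
  se <- co["age_pnd", "Std. Error"]
  tibble::tibble(beta_age = est, t_stat = est / se,
                 n_obs = nrow(df), n_subjects = n_subj,
                 model = model, singular = singular)
}

#' Developmental / aging slope of nodal strength for one region
#'
#' Fits `normalized strength ~ age + TBV + (1 | subject)` over the scans
#' supplied (typically one epoch, see [select_epoch()]). The age
#' coefficient's t statistic is the standardized age effect for the region;
#' a node is conventionally called significantly changing when |t| > 2.
#'
#' @param observations Tibble from [strength_observations()], already
#'   restricted to the epoch of interest.
#' @param region Region label (`unit`) to fit.
#' @param epoch Optional epoch label stored in the result.
#' @return One-row tibble: `unit`, `epoch`, `beta_age`, `t_stat`, `n_obs`,
#'   `n_subjects`, `model` (`"lmer"` or `"lm"` fallback), `singular`.
#' @export
fit_node_slope <- function(observations, region, epoch = NA_character_) {
  df <- observations[observations$unit == region, , drop = FALSE]
  if (nrow(df) == 0L) abort_invalid(sprintf("Region '%s' not found.", region))
  out <- fit_slope_engine(df, random_edges = FALSE)
  tibble::tibble(unit = region, epoch = epoch, out)
}

#' @rdname fit_node_slope
#' @param t_threshold Significance threshold on |t|. Default 2 for nodes.
#' @export
fit_node_slopes <- function(observations, epoch = NA_character_,
                            t_threshold = 2) {
  res <- purrr::map_dfr(unique(observations$unit),
                        ~ fit_node_slope(observations, .x, epoch = epoch))
  res$significant <- abs(res$t_stat) > t_threshold
  res
}

#' Developmental / aging slope of system-level edge weight
#'
#' Pools all ROI-level edges between two cortical systems and fits
#' `normalized weight ~ age + TBV + (1 | subject) + (1 | ROI edge)`. The age
#' t statistic is the system-pair's standardized edge change; edges are
#' conventionally called significantly changing when |t| > 3.3.
#'
#' @param observations Tibble from [edge_observations()], restricted to the
#'   epoch of interest.
#' @param system_pair Length-2 character vector of system labels.
#' @param epoch Optional epoch label stored in the result.
#' @return One-row tibble as [fit_node_slope()], with `unit` the system pair.
#' @export
fit_system_edge_slope <- function(observations, system_pair,
                                  epoch = NA_character_) {
  key <- paste(sort(system_pair), collapse = "|")
  df <- observations[observations$unit == key, , drop = FALSE]
  if (nrow(df) == 0L) {
    abort_invalid(sprintf("System pair '%s' has no edges.", key))
  }
  out <- fit_slope_engine(df, random_edges = TRUE)
  tibble::tibble(unit = key, epoch = epoch, out)
}

#' @rdname fit_system_edge_slope
#' @param t_threshold Significance threshold on |t|. Default 3.3 for edges.
#' @export
fit_system_edge_slopes <- function(observations, epoch = NA_character_,
                                   t_threshold = 3.3) {
  res <- purrr::map_dfr(unique(observations$unit), function(u) {
    fit_system_edge_slope(observations, strsplit(u, "|", fixed = TRUE)[[1L]],
                          epoch = epoch)
  })
  res$significant <- abs(res$t_stat) > t_threshold
  res
}

#' Correlation between developmental and aging standardized effects
#'
#' Pearson correlation (two-sided test) between the per-unit t statistics of
#' the development and aging epochs, quantifying whether units that change
#' most in early life also change (or reverse) most in aging.
#'
#' @param dev,age Slope tables (from [fit_node_slopes()] or
#'   [fit_system_edge_slopes()]) with columns `unit`, `t_stat`, over the same
#'   units.
#' @return One-row tibble: `r`, `p_value`, `n_units`.
#' @export
epoch_coupling <- function(dev, age) {
  if (!setequal(dev$unit, age$unit)) {
    abort_invalid("`dev` and `age` must cover the same units.")
  }
  j <- dplyr::inner_join(dev[, c("unit", "t_stat")],
                         age[, c("unit", "t_stat")],
                         by = "unit", suffix = c("_dev", "_age"))
  ct <- cor.test(j$t_stat_dev, j$t_stat_age, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n_units = nrow(j))
}
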