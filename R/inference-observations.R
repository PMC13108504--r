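#' Z-score a measure across the observations entering a model fit
#'
#' The "normalized" response used by all slope and group models: mean 0, SD 1
#' (sample SD), computed across all observations that enter a given fit so
#' that t statistics are comparable across units.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Z-scored vector.
#' @examples
#' normalize_measure(c(1, 2, 3))
#' @export
normalize_measure <- function(values) {
  if (length(values) < 2L || sd(values) == 0 || !all(is.finite(values))) {
    abort_invalid("`values` must contain >= 2 distinct finite values.")
  }
  (values - mean(values)) / sd(values)
}

#' Restrict a cohort (or observation) table to a developmental epoch
#'
#' Development keeps scans with 20 <= age <= 35 postnatal days; aging keeps
#' 63 <= age <= 230 (inclusive bounds). Custom epoch bounds can be supplied.
#'
#' @param cohort Tibble with an `age_pnd` column.
#' @param epoch `"development"` or `"aging"`.
#' @param bounds Named list of `c(min, max)` age bounds per epoch.
#' @return The subset tibble; errors if it is empty.
#' @export
select_epoch <- function(cohort, epoch = c("development", "aging"),
                         bounds = list(development = c(20, 35),
                                       aging = c(63, 230))) {
  epoch <- match.arg(epoch, names(bounds))
  b <- bounds[[epoch]]
  out <- cohort[cohort$age_pnd >= b[1L] & cohort$age_pnd <= b[2L], ,
                drop = FALSE]
  if (nrow(out) == 0L) {
    abort_pipeline(sprintf("No scans fall in the %s epoch [%g, %g].",
                           epoch, b[1L], b[2L]))
  }
  out
}

#' Long observation tables from per-scan networks and cohort metadata
#'
#' `strength_observations()` yields one row per scan x region with the
#' region's nodal strength as `value`; `edge_observations()` yields one row
#' per scan x unique ROI-edge with the edge weight as `value`, plus the
#' edge's system pair (taken from the parcellation) for system-level
#' pooling. Both join the cohort columns (`subject`, `age_pnd`, `sex`,
#' `group`, `tbv`) by `scan_id`.
#'
#' @param networks Named list of `mind_network`s keyed by `scan_id`.
#' @param cohort Cohort tibble with `scan_id`, `subject`, `age_pnd`, `sex`,
#'   `group`, `tbv`.
#' @return A tibble of scan-level observations.
#' @export
strength_observations <- function(networks, cohort) {
  stopifnot(!is.null(names(networks)), all(names(networks) %in% cohort$scan_id))
  obs <- purrr::map_dfr(names(networks), function(id) {
    s <- nodal_strength(networks[[id]])
    tibble::tibble(scan_id = id, unit = s$region, value = s$strength)
  })
  dplyr::inner_join(obs, cohort, by = "scan_id")
}

#' @rdname strength_observations
#' @param parcellation A [parcellation()] giving each region's system.
#' @export
edge_observations <- function(networks, cohort, parcellation) {
  stopifnot(!is.null(names(networks)), all(names(networks) %in% cohort$scan_id))
  sys_of <- setNames(parcellation$system_id, parcellation$region_id)
  obs <- purrr::map_dfr(names(networks), function(id) {
    e <- tidy.mind_network(networks[[id]])
    sa <- unname(sys_of[e$region_a]); sb <- unname(sys_of[e$region_b])
    tibble::tibble(
      scan_id = id,
      roi_edge = paste(e$region_a, e$region_b, sep = "|"),
      system_a = pmin(sa, sb), system_b = pmax(sa, sb),
      value = e$weight
    )
  })
  obs$unit <- paste(obs$system_a, obs$system_b, sep = "|")
  dplyr::inner_join(obs, cohort, by = "scan_id")
}
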