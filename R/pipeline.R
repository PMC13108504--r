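#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline with the defaults the
#' method prescribes: 5,000 resamples for the KL estimator, top-10 hubs,
#' 3 distance bins, 10,000 distance-preserving nulls, 1,000 group
#' permutations, 10,000 coupling permutations, a 1%-10% density grid, and
#' the |t| thresholds 2 (nodes) and 3.3 (edges). Any element can be
#' overridden; stage seeds derive from the single global `seed`.
#'
#' @param n_regions,n_systems Synthetic parcellation size. Defaults 53 / 15.
#' @param n_subjects Synthetic cohort size. Default 47.
#' @param timepoints Scan ages (PND). Default `c(20, 35, 63, 230)`.
#' @param estimator,n_resamples,k,min_voxels,sigma_floor Network estimator
#'   settings (see [build_mind_network()]).
#' @param hub_k,n_bins,n_nulls,n_perm_group,n_perm_coupling,densities,
#'   t_node,t_edge Analysis settings.
#' @param seed Global seed.
#' @param ... Further overrides stored verbatim.
#' @return A list of class `mind_config`.
#' @export
mind_config <- function(n_regions = 53, n_systems = 15, n_subjects = 47,
                        timepoints = c(20, 35, 63, 230),
                        estimator = "resampled", n_resamples = 5000, k = 3,
                        min_voxels = 20, sigma_floor = NULL,
                        hub_k = 10, n_bins = 3, n_nulls = 10000,
                        n_perm_group = 1000, n_perm_coupling = 10000,
                        densities = seq(0.01, 0.10, by = 0.01),
                        t_node = 2, t_edge = 3.3, seed = 1, ...) {
  cfg <- c(as.list(environment()), list(...))
  for (nm in c("n_regions", "n_systems", "n_subjects", "n_resamples",
               "hub_k", "n_bins", "n_nulls", "n_perm_group",
               "n_perm_coupling")) {
    check_count(cfg[[nm]], nm)
  }
  if (any(cfg$densities <= 0 | cfg$densities > 1)) {
    abort_invalid("`densities` must lie in (0, 1].")
  }
  structure(cfg, class = "mind_config")
}

manifest_add <- function(manifest, path) {
  manifest[[basename(path)]] <- unname(tools::md5sum(path))
  manifest
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic parcellation, ground truth, cohort and reference
#' assets under `dir`: one `Label,MTR` CSV per scan, the cohort table, the
#' parcellation JSON, the truth (JSON), reference assets (CSVs), and a
#' manifest recording seeds and md5 checksums of every file written.
#'
#' @param config A [mind_config()].
#' @param dir Output directory (created if needed).
#' @param truth Optional pre-built [generative_truth()]; by default one is
#'   created from the config's parcellation settings.
#' @return The manifest (named list), invisibly; files on disk.
#' @export
run_simulate <- function(config, dir, truth = NULL) {
  stopifnot(inherits(config, "mind_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort("Cannot create output directory.",
                              class = "ratmind_io_error")
  if (is.null(truth)) {
    regions <- generate_parcellation(config$n_regions, config$n_systems,
                                     seed = derive_seed(config$seed, "parc"))
    truth <- generative_truth(regions)
  }
  spec <- cohort_spec(config$n_subjects, timepoints = config$timepoints,
                      seed = derive_seed(config$seed, "cohort"))
  sim <- generate_cohort(spec, truth)
  refs <- generate_reference_assets(truth,
                                    seed = derive_seed(config$seed, "refs"))
  manifest <- list(seed = config$seed)
  scan_dir <- file.path(dir, "scans")
  dir.create(scan_dir, showWarnings = FALSE)
  for (id in names(sim$scans)) {
    p <- file.path(scan_dir, paste0(id, ".csv"))
    write_voxel_table(sim$scans[[id]], p)
    manifest <- manifest_add(manifest, p)
  }
  p <- file.path(dir, "cohort.csv")
  readr::write_csv(sim$cohort, p, progress = FALSE)
  manifest <- manifest_add(manifest, p)
  p <- file.path(dir, "parcellation.json")
  write_parcellation(as_parcellation(truth$regions), p)
  manifest <- manifest_add(manifest, p)
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(regions = as.data.frame(truth$regions),
         dev_slope = as.list(truth$dev_slope),
         age_slope = as.list(truth$age_slope),
         group_offset = as.list(truth$group_offset),
         subject_sd = truth$subject_sd, tbv_coef = truth$tbv_coef,
         stress_onset_age = truth$stress_onset_age),
    p, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  manifest <- manifest_add(manifest, p)
  ref_paths <- list(
    tract = refs$tract, expression = refs$expression
  )
  for (nm in names(ref_paths)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    df <- as.data.frame(ref_paths[[nm]])
    readr::write_csv(cbind(region = rownames(ref_paths[[nm]]), df), p,
                     progress = FALSE)
    manifest <- manifest_add(manifest, p)
  }
  p <- file.path(dir, "types.csv")
  readr::write_csv(refs$types, p, progress = FALSE)
  manifest <- manifest_add(manifest, p)
  p <- file.path(dir, "crosswalk.csv")
  readr::write_csv(refs$crosswalk, p, progress = FALSE)
  manifest <- manifest_add(manifest, p)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Build per-scan and median networks from simulated (or real) inputs
#'
#' Reads every scan CSV under `dir/scans`, builds one MIND network per scan,
#' writes them as labelled CSV matrices under `dir/networks`, and writes the
#' per-timepoint (and, when groups are present, per-group) median networks.
#' A QC report lists dropped regions and estimator settings per scan.
#'
#' @param config A [mind_config()].
#' @param dir Directory produced by [run_simulate()] (or laid out like one).
#' @return Invisibly, a list with `networks` (named list) and `medians`.
#' @export
run_networks <- function(config, dir) {
  stopifnot(inherits(config, "mind_config"))
  cohort_path <- file.path(dir, "cohort.csv")
  if (!file.exists(cohort_path)) abort_pipeline("cohort.csv not found.")
  cohort <- readr::read_csv(cohort_path, show_col_types = FALSE,
                            progress = FALSE)
  parc <- read_parcellation(file.path(dir, "parcellation.json"))
  net_dir <- file.path(dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  qc <- list()
  networks <- list()
  for (id in cohort$scan_id) {
    p <- file.path(dir, "scans", paste0(id, ".csv"))
    if (!file.exists(p)) abort_pipeline(sprintf("Missing scan input: %s", p))
    net <- build_mind_network(
      read_voxel_table(p), parcellation = parc,
      estimator = config$estimator, n_resamples = config$n_resamples,
      k = config$k, min_voxels = config$min_voxels,
      sigma_floor = config$sigma_floor,
      seed = derive_seed(config$seed, "net", id))
    networks[[id]] <- net
    write_mind_network(net, file.path(net_dir, paste0(id, ".csv")))
    qc[[id]] <- list(dropped = net$meta$dropped_regions,
                     estimator = config$estimator,
                     n_resamples = config$n_resamples)
  }
  medians <- list()
  for (tp in sort(unique(cohort$age_pnd))) {
    for (grp in unique(cohort$group)) {
      ids <- cohort$scan_id[cohort$age_pnd == tp & cohort$group == grp]
      if (length(ids) == 0L) next
      key <- sprintf("median_PND%03d_%s", tp, grp)
      medians[[key]] <- median_network(networks[ids])
      write_mind_network(medians[[key]],
                         file.path(net_dir, paste0(key, ".csv")))
    }
  }
  jsonlite::write_json(qc, file.path(dir, "networks_qc.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(networks = networks, medians = medians))
}

#' Run the full analysis suite over built networks
#'
#' Sequences topology (strength, hubs, rich club with distance-preserving
#' null inference), validation (distance-weight correlation, cortical-type
#' curve, tract and expression alignment), epoch slopes, and — when two
#' groups are present — case-control contrasts with permutation nulls and
#' the stress-development coupling. Stages whose inputs are absent are
#' skipped with a logged reason. Results are written as CSV/JSON under
#' `dir/report` and returned.
#'
#' @param config A [mind_config()].
#' @param dir Directory holding `run_simulate()` + `run_networks()` outputs.
#' @param built Optional result of [run_networks()] to avoid re-reading.
#' @return Invisibly, a named list of stage results (with `skipped` notes).
#' @export
run_analysis <- function(config, dir, built = NULL) {
  stopifnot(inherits(config, "mind_config"))
  cohort <- readr::read_csv(file.path(dir, "cohort.csv"),
                            show_col_types = FALSE, progress = FALSE)
  parc <- read_parcellation(file.path(dir, "parcellation.json"))
  if (is.null(built)) {
    net_dir <- file.path(dir, "networks")
    networks <- purrr::map(
      setNames(cohort$scan_id, cohort$scan_id),
      ~ read_mind_network(file.path(net_dir, paste0(.x, ".csv"))))
  } else {
    networks <- built$networks
  }
  report_dir <- file.path(dir, "report")
  dir.create(report_dir, showWarnings = FALSE)
  out <- list(skipped = list(),
              provenance = list(seed = config$seed,
                                estimator = config$estimator,
                                n_resamples = config$n_resamples,
                                n_nulls = config$n_nulls,
                                n_perm_group = config$n_perm_group,
                                n_perm_coupling = config$n_perm_coupling))

  # normative network: median across adult (first age >= 63) control scans
  adult_ages <- cohort$age_pnd[cohort$age_pnd >= 63]
  adult_age <- if (length(adult_ages)) min(adult_ages) else max(cohort$age_pnd)
  ref_group <- if ("control" %in% cohort$group) "control" else cohort$group[1L]
  norm_ids <- cohort$scan_id[cohort$age_pnd == adult_age &
                               cohort$group == ref_group]
  normative <- median_network(networks[norm_ids])
  distances <- edge_distances(parc)

  strengths <- nodal_strength(normative)
  hubs <- top_hubs(strengths, k = min(config$hub_k, nrow(strengths)))
  rc <- rich_club(normative, hubs)
  out$topology <- list(strengths = strengths, hubs = hubs, rich_club = rc)
  readr::write_csv(strengths, file.path(report_dir, "strength.csv"),
                   progress = FALSE)
  if (config$n_nulls > 0) {
    nulls <- null_ensemble(normative, distances, n_nulls = config$n_nulls,
                           seed = derive_seed(config$seed, "nulls"),
                           n_bins = config$n_bins)
    # hubs are re-derived within each null so the hub-selection step is
    # applied symmetrically to observed and null networks
    phi_nulls <- vapply(nulls$networks, function(nn) {
      rich_club(nn, top_hubs(nodal_strength(nn), length(hubs)))$phi
    }, numeric(1))
    out$topology$rich_club_test <- permutation_z_p(rc$phi, phi_nulls)
  } else {
    nulls <- NULL
    out$skipped$rich_club_test <- "nulls disabled (n_nulls = 0)"
  }
  rc_json <- c(tidy.rich_club_result(rc),
               if (!is.null(out$topology$rich_club_test)) {
                 list(z = out$topology$rich_club_test$z,
                      p = out$topology$rich_club_test$p)
               })
  jsonlite::write_json(rc_json, file.path(report_dir, "rich_club.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out$distance <- distance_weight_correlation(normative, distances)
  readr::write_csv(out$distance, file.path(report_dir, "distance.csv"),
                   progress = FALSE)

  read_ref <- function(name) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(p)) return(NULL)
    df <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  tract <- read_ref("tract")
  if (!is.null(tract) && !is.null(nulls)) {
    out$tract <- tract_mind_alignment(normative, tract, nulls)
    readr::write_csv(out$tract, file.path(report_dir, "tract.csv"),
                     progress = FALSE)
  } else out$skipped$tract <- "tract matrix or nulls unavailable"
  expr <- read_ref("expression")
  if (!is.null(expr) && !is.null(nulls)) {
    out$expression <- expression_alignment(normative, expr, nulls)
    readr::write_csv(out$expression, file.path(report_dir, "expression.csv"),
                     progress = FALSE)
  } else out$skipped$expression <- "expression table or nulls unavailable"
  types_path <- file.path(dir, "types.csv")
  if (file.exists(types_path)) {
    types <- readr::read_csv(types_path, show_col_types = FALSE,
                             progress = FALSE)
    out$intraclass <- intraclass_edge_curve(normative, types,
                                            densities = config$densities)
    readr::write_csv(out$intraclass, file.path(report_dir, "intraclass.csv"),
                     progress = FALSE)
  } else out$skipped$intraclass <- "types.csv unavailable"

  sobs <- strength_observations(networks, cohort)
  slopes <- list()
  for (ep in c("development", "aging")) {
    sub <- tryCatch(select_epoch(sobs, ep), error = function(e) NULL)
    if (is.null(sub) || length(unique(sub$age_pnd)) < 2L) {
      out$skipped[[paste0("slopes_", ep)]] <- "fewer than 2 ages in epoch"
      next
    }
    slopes[[ep]] <- fit_node_slopes(sub, epoch = ep,
                                    t_threshold = config$t_node)
  }
  out$slopes <- slopes
  if (length(slopes) > 0L) {
    readr::write_csv(dplyr::bind_rows(slopes),
                     file.path(report_dir, "slopes.csv"), progress = FALSE)
  }
  if (length(slopes) == 2L) out$epoch_coupling <-
      epoch_coupling(slopes$development, slopes$aging)

  if (length(unique(cohort$group)) >= 2L) {
    cc <- sobs[sobs$age_pnd == adult_age, , drop = FALSE]
    out$group <- permuted_group_null(cc, n_perm = config$n_perm_group,
                                     seed = derive_seed(config$seed, "group"))
    readr::write_csv(out$group, file.path(report_dir, "group_effects.csv"),
                     progress = FALSE)
    if (!is.null(slopes$development)) {
      out$coupling <- tidy.permutation_result(stress_development_coupling(
        out$group, slopes$development, n_perm = config$n_perm_coupling,
        seed = derive_seed(config$seed, "coupling")))
      jsonlite::write_json(out$coupling, file.path(report_dir,
                                                   "coupling.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  } else out$skipped$group <- "single group; case-control stage not run"

  jsonlite::write_json(out$provenance, file.path(report_dir,
                                                 "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
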