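#' Read a per-scan voxel table
#'
#' Reads the pipeline's two-column CSV input: a `Label` column naming the
#' region of interest of each voxel and an `MTR` column holding that voxel's
#' feature value. Extra columns are dropped with a warning; missing required
#' columns or non-numeric feature values are format errors.
#'
#' @param path Path to a CSV file with columns `Label` and `MTR`.
#' @return A tibble with columns `Label` (character) and `MTR` (double).
#' @seealso [write_voxel_table()]
#' @export
read_voxel_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File '%s' does not exist.", path))
  tbl <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort_format(sprintf("Cannot parse '%s': %s", path,
                                             conditionMessage(e)))
  )
  if (nrow(tbl) == 0L || ncol(tbl) == 0L) {
    abort_format(sprintf("'%s' contains no voxel rows.", path))
  }
  missing_cols <- setdiff(c("Label", "MTR"), names(tbl))
  if (length(missing_cols) > 0L) {
    abort_format(sprintf("'%s' is missing required column(s): %s.", path,
                         paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(tbl), c("Label", "MTR"))
  if (length(extra) > 0L) {
    warn(sprintf("Ignoring extra column(s) in '%s': %s.", path,
                 paste(extra, collapse = ", ")))
  }
  values <- suppressWarnings(as.numeric(tbl$MTR))
  bad <- which(is.na(values) & !is.na(tbl$MTR))
  if (length(bad) > 0L) {
    abort_format(sprintf("Non-numeric MTR value in '%s' at data row %d ('%s').",
                         path, bad[1L], tbl$MTR[bad[1L]]))
  }
  if (any(is.na(tbl$Label)) || any(tbl$Label == "")) {
    abort_format(sprintf("Empty region label in '%s'.", path))
  }
  tibble::tibble(Label = as.character(tbl$Label), MTR = values)
}

#' Write a voxel table to the pipeline's CSV layout
#'
#' @param voxels Tibble with columns `Label` and `MTR`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_voxel_table <- function(voxels, path) {
  stopifnot(all(c("Label", "MTR") %in% names(voxels)))
  readr::write_csv(voxels[, c("Label", "MTR")], path, progress = FALSE)
  invisible(path)
}

#' Compute the magnetization transfer ratio per voxel
#'
#' `MTR = (PD - MT) / PD`, element-wise, where `PD` is the proton-density
#' scan value and `MT` the magnetization-transfer scan value (both already
#' scaled by receiver gain upstream). Voxels with `PD <= 0` yield `NA` and
#' are counted in the `n_invalid` attribute of the result.
#'
#' @param pd_values,mt_values Equal-length numeric vectors.
#' @return Numeric vector of MTR values with attribute `n_invalid`, the count
#'   of non-positive-PD voxels set to `NA`.
#' @examples
#' compute_mtr(c(1, 2), c(0.6, 1)) # 0.4, 0.5
#' @export
compute_mtr <- function(pd_values, mt_values) {
  if (length(pd_values) != length(mt_values)) {
    abort_invalid("`pd_values` and `mt_values` must have equal length.")
  }
  bad <- !is.na(pd_values) & pd_values <= 0
  mtr <- (pd_values - mt_values) / pd_values
  mtr[bad] <- NA_real_
  structure(mtr, n_invalid = sum(bad))
}

#' Restrict a voxel table to a parcellation's included regions
#'
#' Keeps only voxels whose label is flagged as included (cortical membership)
#' in the parcellation; labels absent from the parcellation are dropped like
#' excluded ones. The per-label drop counts are attached as the `dropped`
#' attribute (a tibble `Label`, `n`).
#'
#' @param voxels Tibble with columns `Label`, `MTR`.
#' @param parcellation A [parcellation()] tibble with `region_id` and
#'   `include_flag`.
#' @return Filtered voxel tibble with attribute `dropped`.
#' @export
filter_to_included <- function(voxels, parcellation) {
  stopifnot(all(c("Label", "MTR") %in% names(voxels)),
            all(c("region_id", "include_flag") %in% names(parcellation)))
  included <- parcellation$region_id[parcellation$include_flag]
  keep <- voxels$Label %in% included
  dropped <- dplyr::count(voxels[!keep, , drop = FALSE], .data$Label, name = "n")
  out <- voxels[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
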