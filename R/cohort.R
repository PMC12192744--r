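#' Construct a stimulation-test cohort
#'
#' A cohort bundles one hemisphere's stimulation tests: the shared voxel
#' grid, one record per retained stimulation (patient, tract, depth,
#' current amplitude, improvement score) and the matching electric-field
#' (EF) norm volume for each record. All volumes must live on the same grid
#' and every record must resolve to exactly one volume.
#'
#' @param grid shared `voxel_grid`.
#' @param records data.frame with columns `patient_id`, `lead_id`,
#'   `tract_id` (`"central"` or `"parallel"`), `depth_mm`, `amplitude_mA`,
#'   `improvement_pct` and `ef_volume_ref`.
#' @param ef_volumes named list of `ef_volume` objects, names matching
#'   `records$ef_volume_ref`.
#' @param hemisphere `"left"` or `"right"`; a cohort carries one hemisphere.
#' @param ground_truth optional binary array marking a known effective
#'   region (synthetic cohorts only).
#' @param provenance free-form list stored alongside the data.
#' @return validated object of class `dbs_cohort`.
#' @export
new_cohort <- function(grid, records, ef_volumes, hemisphere = "left",
                       ground_truth = NULL, provenance = list()) {
  cohort <- structure(
    list(grid = grid, records = as.data.frame(records),
         ef_volumes = ef_volumes, hemisphere = hemisphere,
         ground_truth = ground_truth, provenance = provenance),
    class = "dbs_cohort"
  )
  validate_cohort(cohort)
  cohort
}

#' Validate a cohort's cross-references and value ranges
#'
#' Checks the invariants the analysis relies on: required record columns,
#' improvement scores inside \[0, 100\], positive amplitudes, a one-to-one
#' record/volume mapping, identical grids across volumes, and at least two
#' distinct patients.
#'
#' @param cohort a `dbs_cohort`.
#' @return the cohort, invisibly; stops with a specific error otherwise.
#' @export
validate_cohort <- function(cohort) {
  rec <- cohort$records
  needed <- c("patient_id", "tract_id", "depth_mm", "amplitude_mA",
              "improvement_pct", "ef_volume_ref")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols))
    stop("records table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(rec) == 0L) stop("cohort has no stimulation records")
  bad <- which(!is.finite(rec$improvement_pct) |
                 rec$improvement_pct < 0 | rec$improvement_pct > 100)
  if (length(bad))
    stop(sprintf("record '%s': improvement_pct outside [0, 100]",
                 rec$ef_volume_ref[bad[1]]))
  bad <- which(!is.finite(rec$amplitude_mA) | rec$amplitude_mA <= 0)
  if (length(bad))
    stop(sprintf("record '%s': amplitude_mA must be > 0",
                 rec$ef_volume_ref[bad[1]]))
  if (anyDuplicated(rec$ef_volume_ref))
    stop("duplicated ef_volume_ref in records table")
  missing_vol <- setdiff(rec$ef_volume_ref, names(cohort$ef_volumes))
  if (length(missing_vol))
    stop(sprintf("record '%s' references a missing EF volume", missing_vol[1]))
  for (ref in rec$ef_volume_ref) {
    v <- cohort$ef_volumes[[ref]]
    if (!grids_equal(v$grid, cohort$grid))
      stop_grid_mismatch(cohort$grid, v$grid,
                         sprintf("cohort grid and volume '%s'", ref))
  }
  if (length(unique(rec$patient_id)) < 2L)
    stop("cohort must contain at least 2 distinct patients")
  invisible(cohort)
}

#' @export
print.dbs_cohort <- function(x, ...) {
  cat(sprintf("dbs_cohort: %d records, %d patients, %s hemisphere\n",
              nrow(x$records), length(unique(x$records$patient_id)),
              x$hemisphere))
  print(x$grid)
  invisible(x)
}

#' Patients of a cohort
#' @param cohort a `dbs_cohort`.
#' @return character vector of distinct patient ids, sorted.
#' @export
cohort_patients <- function(cohort) sort(unique(cohort$records$patient_id))
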