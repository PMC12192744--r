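#' Threshold an EF volume into a VTA mask
#'
#' The volume of tissue activated is the set of voxels whose EF norm
#' reaches the activation threshold; the comparison is inclusive
#' (values exactly at the threshold are kept, only values strictly lower
#' are discarded).
#'
#' @param ef an `ef_volume`.
#' @param threshold activation threshold in V/mm (default 0.2).
#' @return object of class `vta_mask` with fields `grid`, `mask`,
#'   `record_ref`, `threshold_used`.
#' @export
vta_from_ef <- function(ef, threshold = 0.2) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (!is.null(ef$values)) {
    mask <- ef$values >= threshold
  } else {
    mask <- array(FALSE, dim = ef$grid$shape)
    mask[ef$sparse$idx[ef$sparse$val >= threshold]] <- TRUE
  }
  structure(list(grid = ef$grid, mask = mask, record_ref = ef$record_ref,
                 threshold_used = threshold),
            class = "vta_mask")
}

#' Build the per-voxel observation stack of a cohort
#'
#' Stacks all EF volumes along a fourth dimension: each voxel collects one
#' (EF norm, improvement, patient, record, amplitude) observation per
#' record whose EF at that voxel reaches `threshold`. Also derives the
#' stimulation frequency map `n_map`, the patient frequency map
#' `npat_map`, and the auxiliary amplitude-weighted mean improvement
#' `wimp_map` (weights EF / amplitude; computed for reporting, not used by
#' the masking rules).
#'
#' @param cohort a validated `dbs_cohort`.
#' @param threshold activation threshold in V/mm.
#' @return object of class `voxel_stack`: `obs` (data.table with columns
#'   `voxel`, `ef`, `improvement`, `patient`, `record`, `amplitude`),
#'   `n_map`, `npat_map`, `wimp_map` (3D arrays), `grid`, `threshold`,
#'   `patients`, `n_patients`.
#' @export
build_stack <- function(cohort, threshold = 0.2) {
  validate_cohort(cohort)
  rec <- cohort$records
  parts <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    v <- cohort$ef_volumes[[rec$ef_volume_ref[i]]]
    if (!is.null(v$values)) {
      idx <- which(v$values >= threshold)
      val <- v$values[idx]
    } else {
      keep <- v$sparse$val >= threshold
      idx <- v$sparse$idx[keep]
      val <- v$sparse$val[keep]
    }
    if (length(idx))
      parts[[i]] <- data.table::data.table(
        voxel = idx, ef = val,
        improvement = rec$improvement_pct[i],
        patient = rec$patient_id[i],
        record = rec$ef_volume_ref[i],
        amplitude = rec$amplitude_mA[i])
  }
  obs <- data.table::rbindlist(parts)
  if (nrow(obs) == 0L)
    stop("no voxel reaches the activation threshold in any record")
  data.table::setkey(obs, voxel)
  finish_stack(obs, cohort$grid, threshold,
               patients = cohort_patients(cohort))
}

finish_stack <- function(obs, grid, threshold, patients) {
  nvox <- prod(grid$shape)
  n_map <- array(tabulate(obs$voxel, nbins = nvox), dim = grid$shape)
  upairs <- unique(obs[, c("voxel", "patient")])
  npat_map <- array(tabulate(upairs$voxel, nbins = nvox), dim = grid$shape)
  w <- obs$ef / obs$amplitude
  sw <- rowsum(cbind(w, w * obs$improvement), obs$voxel)
  wimp_map <- array(NA_real_, dim = grid$shape)
  wimp_map[as.integer(rownames(sw))] <- sw[, 2] / sw[, 1]
  structure(list(obs = obs, grid = grid, threshold = threshold,
                 n_map = n_map, npat_map = npat_map, wimp_map = wimp_map,
                 patients = patients, n_patients = length(patients)),
            class = "voxel_stack")
}

#' Restrict a stack to a subset of patients or records
#'
#' Re-derives all frequency maps from the retained observations; used by
#' the leave-one-out cross-validation without re-reading any volume.
#'
#' @param stack a `voxel_stack`.
#' @param patients patient ids to keep (default all).
#' @param records record ids to keep (default all).
#' @return a `voxel_stack` over the subset.
#' @export
stack_subset <- function(stack, patients = NULL, records = NULL) {
  obs <- stack$obs
  keep_pat <- if (is.null(patients)) stack$patients else patients
  obs <- obs[obs$patient %in% keep_pat, ]
  if (!is.null(records)) obs <- obs[obs$record %in% records, ]
  if (nrow(obs) == 0L) stop("stack subset is empty")
  finish_stack(obs, stack$grid, stack$threshold, patients = sort(keep_pat))
}

#' @export
print.voxel_stack <- function(x, ...) {
  cat(sprintf(
    "voxel_stack: %d observations over %d voxels, %d records, %d patients\n",
    nrow(x$obs), sum(x$n_map > 0), length(unique(x$obs$record)),
    x$n_patients))
  invisible(x)
}
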