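#' Write a scalar or binary field to a NIfTI-1 file
#'
#' The grid's affine is stored as both sform and qform; binary masks are
#' written as integers so the round trip is exact, scalar fields as
#' doubles.
#'
#' @param field 3D numeric or logical array matching `grid$shape`.
#' @param grid the `voxel_grid` the field lives on.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(field, grid, path) {
  if (is.logical(field)) field <- array(as.integer(field), dim = dim(field))
  if (!identical(dim(field), as.integer(grid$shape)))
    stop(sprintf("field shape (%s) does not match grid shape (%s)",
                 paste(dim(field), collapse = ","),
                 paste(grid$shape, collapse = ",")))
  img <- RNifti::asNifti(field)
  aff <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [save_volume()]
#'
#' @param path NIfTI file.
#' @return list with `values` (3D array), `grid` (`voxel_grid` rebuilt from
#'   the stored affine) and `affine`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  vs <- abs(diag(aff)[1:3])
  grid <- voxel_grid(dim(img), voxel_size_mm = vs, origin_mm = aff[1:3, 4])
  off <- aff[1:3, 1:3] - diag(vs)
  if (max(abs(off)) > 1e-4)
    stop("only axis-aligned volumes are supported: ", path)
  values <- as.array(img)
  attributes(values) <- list(dim = dim(values))
  list(values = values, grid = grid, affine = aff)
}

grid_to_list <- function(grid) {
  list(shape = grid$shape, voxel_size_mm = grid$voxel_size_mm,
       origin_mm = grid$origin_mm)
}

grid_from_list <- function(x) {
  voxel_grid(x$shape, voxel_size_mm = x$voxel_size_mm, origin_mm = x$origin_mm)
}

#' Save a cohort to a directory
#'
#' Layout: `table.csv` (stimulation records), `volumes/<ref>.nii.gz` (one EF
#' volume per record), `meta.json` (grid, hemisphere, provenance) and
#' optionally `ground_truth.nii.gz`.
#'
#' @param cohort a `dbs_cohort`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  vol_dir <- file.path(dir, "volumes")
  dir.create(vol_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$records, file.path(dir, "table.csv"),
                   row.names = FALSE)
  for (ref in cohort$records$ef_volume_ref) {
    save_volume(ef_values(cohort$ef_volumes[[ref]]), cohort$grid,
                file.path(vol_dir, paste0(ref, ".nii.gz")))
  }
  if (!is.null(cohort$ground_truth))
    save_volume(cohort$ground_truth, cohort$grid,
                file.path(dir, "ground_truth.nii.gz"))
  meta <- list(grid = grid_to_list(cohort$grid),
               hemisphere = cohort$hemisphere,
               provenance = cohort$provenance)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a cohort from disk
#'
#' @param volume_dir directory containing one NIfTI volume per record
#'   (`<ef_volume_ref>.nii` or `.nii.gz`).
#' @param table path to the stimulation-record CSV.
#' @param meta optional path to the JSON sidecar written by
#'   [save_cohort()]; defaults to `meta.json` next to `volume_dir` when
#'   present.
#' @return a validated `dbs_cohort`.
#' @export
load_cohort <- function(volume_dir, table, meta = NULL) {
  records <- utils::read.csv(table, stringsAsFactors = FALSE)
  if (!"ef_volume_ref" %in% names(records))
    stop("records table lacks an ef_volume_ref column")
  if (is.null(meta)) {
    cand <- file.path(dirname(volume_dir), "meta.json")
    if (file.exists(cand)) meta <- cand
  }
  grid <- NULL
  hemisphere <- "left"
  provenance <- list()
  if (!is.null(meta)) {
    m <- jsonlite::read_json(meta, simplifyVector = TRUE)
    grid <- grid_from_list(m$grid)
    if (!is.null(m$hemisphere)) hemisphere <- m$hemisphere
    if (!is.null(m$provenance)) provenance <- m$provenance
  }
  vols <- list()
  for (i in seq_len(nrow(records))) {
    ref <- records$ef_volume_ref[i]
    path <- file.path(volume_dir, paste0(ref, ".nii.gz"))
    if (!file.exists(path)) path <- file.path(volume_dir, paste0(ref, ".nii"))
    if (!file.exists(path))
      stop(sprintf("record '%s': EF volume file not found in %s",
                   ref, volume_dir))
    v <- read_volume(path)
    if (is.null(grid)) grid <- v$grid
    if (!grids_equal(grid, v$grid))
      stop_grid_mismatch(grid, v$grid, sprintf("cohort and volume '%s'", ref))
    vols[[ref]] <- new_ef_volume(v$values, grid, ref)
  }
  gt <- NULL
  gt_path <- file.path(dirname(volume_dir), "ground_truth.nii.gz")
  if (file.exists(gt_path)) gt <- read_volume(gt_path)$values > 0.5
  new_cohort(grid, records, vols, hemisphere = hemisphere,
             ground_truth = gt, provenance = provenance)
}
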