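# Sweet-spot extraction: significance thresholding, frequency masking and
# cluster-size filtering, in that order.

#' Significance thresholding of a map
#'
#' Uncorrected p-maps: p < 0.05 (strict). Permutation/FDR corrected maps:
#' the correction's own rule (corrected p < 0.05, resp. BH-adjusted
#' p <= q). BF maps: BF10 >= 10 (inclusive). LMM maps: p < 0.05 and
#' slope > 0.
#'
#' @param map a `ps_map` or `corrected_map`.
#' @param alpha significance level for p-based maps.
#' @param bf_threshold BF10 cutoff for Bayesian maps.
#' @return logical 3D array.
#' @export
significant_voxels <- function(map, alpha = 0.05, bf_threshold = 10) {
  if (inherits(map, "corrected_map")) return(map$significant)
  if (!inherits(map, "ps_map")) stop("unknown map type")
  sig <- switch(map$stat_type,
                p = !is.na(map$p) & map$p < alpha,
                bf = !is.na(map$bf) & map$bf >= bf_threshold,
                lmm = !is.na(map$p) & map$p < alpha &
                  !is.na(map$slope) & map$slope > 0,
                stop("unknown statistic kind: ", map$stat_type))
  sig & map$valid
}

#' Frequency masking of significant voxels
#'
#' Discards voxels activated in less than `pat_frac` of the patients, or
#' covered by fewer VTAs than `nmap_frac` of the maximum stimulation
#' frequency. Both comparisons discard on strict less-than, on exact
#' fractions.
#'
#' @param sig logical array of significant voxels.
#' @param stack the `voxel_stack` providing `npat_map` and `n_map`.
#' @param n_patients cohort size (default: from the stack).
#' @param pat_frac minimum patient fraction (default 0.25).
#' @param nmap_frac minimum fraction of the maximum `n_map` (default 0.10).
#' @return logical array.
#' @export
apply_frequency_masks <- function(sig, stack, n_patients = stack$n_patients,
                                  pat_frac = 0.25, nmap_frac = 0.10) {
  keep_pat <- stack$npat_map / n_patients >= pat_frac
  keep_n <- stack$n_map >= nmap_frac * max(stack$n_map)
  sig & keep_pat & keep_n
}

cc_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nrm <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nrm == 1, , drop = FALSE],
                 "18" = offs[nrm >= 1 & nrm <= 2, , drop = FALSE],
                 "26" = offs[nrm >= 1, , drop = FALSE],
                 stop("connectivity must be 6, 18 or 26"))
  # half set: lexicographically positive offsets (each edge visited once)
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs[keep, , drop = FALSE]
}

#' Label connected components of a binary 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  lab <- array(0L, dim = dim(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  sh <- dim(mask)
  coords <- arrayInd(idx, sh)
  offs <- cc_offsets(connectivity)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[k, ], nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= sh[1] &
      nb[, 2] >= 1 & nb[, 2] <= sh[2] &
      nb[, 3] >= 1 & nb[, 3] <= sh[3]
    if (!any(ok)) next
    nidx <- (nb[ok, 3] - 1L) * sh[1] * sh[2] + (nb[ok, 2] - 1L) * sh[1] +
      nb[ok, 1]
    j <- match(nidx, idx)
    src <- which(ok)[!is.na(j)]
    dst <- j[!is.na(j)]
    for (e in seq_along(src)) {
      a <- find(src[e]); b <- find(dst[e])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Remove small connected components
#'
#' @param mask logical 3D array.
#' @param min_cluster minimum component size in voxels (default 8, i.e.
#'   1 mm^3 on a 0.5 mm grid); components with fewer voxels are removed.
#' @param connectivity 6, 18 or 26.
#' @return logical array.
#' @export
filter_clusters <- function(mask, min_cluster = 8L, connectivity = 26L) {
  if (min_cluster < 1L) stop("min_cluster must be >= 1")
  lab <- label_components(mask, connectivity)
  if (!any(lab > 0L)) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_cluster)
  array(lab %in% keep, dim = dim(mask))
}

#' Sweet-spot extraction parameters
#'
#' Bundles every threshold of the extraction pipeline with its default:
#' improvement threshold 75 %, alpha 0.05, BF10 cutoff 10, EF activation
#' threshold 0.2 V/mm, patient fraction 25 %, stimulation-frequency
#' fraction 10 %, minimum cluster 8 voxels, 26-connectivity, 200
#' permutations.
#'
#' @param mu0,alpha,bf_threshold,min_n test parameters.
#' @param ef_threshold VTA activation threshold (V/mm).
#' @param pat_frac,nmap_frac frequency-mask fractions.
#' @param min_cluster,connectivity cluster filter.
#' @param n_perm permutation count for the permutation correction.
#' @param prior Bayesian prior, see [prior_spec()].
#' @param min_patients LMM minimum patients per voxel.
#' @export
pss_params <- function(mu0 = 75, alpha = 0.05, bf_threshold = 10,
                       min_n = 3L, ef_threshold = 0.2, pat_frac = 0.25,
                       nmap_frac = 0.10, min_cluster = 8L,
                       connectivity = 26L, n_perm = 200L,
                       prior = prior_spec(), min_patients = 3L) {
  list(mu0 = mu0, alpha = alpha, bf_threshold = bf_threshold,
       min_n = min_n, ef_threshold = ef_threshold, pat_frac = pat_frac,
       nmap_frac = nmap_frac, min_cluster = min_cluster,
       connectivity = connectivity, n_perm = n_perm, prior = prior,
       min_patients = min_patients)
}

#' Extract the probabilistic sweet spot from a thresholded map
#'
#' Composition significance -> frequency masks -> cluster filter, with
#' per-stage voxel counts and full provenance. An empty sweet spot is a
#' legal result.
#'
#' @param map a `ps_map` or `corrected_map`.
#' @param stack the `voxel_stack` the map was computed from.
#' @param params a [pss_params()] list.
#' @return object of class `sweet_spot`: `mask`, `grid`, `stage_counts`
#'   (significant / masked / clustered) and `provenance`.
#' @export
extract_pss <- function(map, stack, params = pss_params()) {
  if (!grids_equal(map$grid, stack$grid))
    stop_grid_mismatch(map$grid, stack$grid, "map and stack")
  sig <- significant_voxels(map, alpha = params$alpha,
                            bf_threshold = params$bf_threshold)
  masked <- apply_frequency_masks(sig, stack, pat_frac = params$pat_frac,
                                  nmap_frac = params$nmap_frac)
  final <- filter_clusters(masked, min_cluster = params$min_cluster,
                           connectivity = params$connectivity)
  structure(
    list(grid = map$grid, mask = final,
         stage_counts = c(significant = sum(sig), masked = sum(masked),
                          clustered = sum(final)),
         provenance = list(
           method = map$method,
           correction = if (inherits(map, "corrected_map")) map$kind
                        else "none",
           map_params = map$params,
           pss_params = params[setdiff(names(params), "prior")],
           prior = unclass(params$prior))),
    class = "sweet_spot"
  )
}

#' @export
print.sweet_spot <- function(x, ...) {
  cat(sprintf("sweet_spot (%s/%s): %d voxels (%.2f mm^3)\n",
              x$provenance$method, x$provenance$correction, sum(x$mask),
              sum(x$mask) * voxel_volume_mm3(x$grid)))
  invisible(x)
}

#' Save a sweet spot (NIfTI mask + JSON provenance)
#' @param pss a `sweet_spot`.
#' @param path output NIfTI path.
#' @export
save_pss <- function(pss, path) {
  save_volume(pss$mask, pss$grid, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    c(pss$provenance, list(stage_counts = as.list(pss$stage_counts))),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
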