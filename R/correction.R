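# Type-I error corrections for the t and Wilcoxon maps.

new_corrected_map <- function(grid, method, kind, corrected_p, significant,
                              valid, params = list()) {
  structure(list(grid = grid, method = method, stat_type = "corrected",
                 kind = kind, corrected_p = corrected_p,
                 significant = significant, valid = valid, params = params),
            class = "corrected_map")
}

#' @export
print.corrected_map <- function(x, ...) {
  cat(sprintf("corrected_map (%s, %s): %d significant / %d valid voxels\n",
              x$method, x$kind, sum(x$significant), sum(x$valid)))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction of a p-value map
#'
#' Applies the BH step-up procedure over the valid voxels only (invalid
#' voxels carry no test). A voxel is significant iff its BH-adjusted
#' p-value is at most `q`, equivalent to the literal step-up rule
#' p <= p(k), k = max\{i : p(i) <= i q / m\}.
#'
#' @param pmap a `ps_map` carrying p-values (t or Wilcoxon; BF maps are
#'   rejected).
#' @param q target false discovery rate (default 0.05).
#' @return a `corrected_map`; `corrected_p` holds BH-adjusted p-values.
#' @export
fdr_bh <- function(pmap, q = 0.05) {
  if (!inherits(pmap, "ps_map") || pmap$stat_type == "bf")
    stop("FDR applies to p-value maps only")
  idx <- which(pmap$valid)
  adj <- array(NA_real_, dim = pmap$grid$shape)
  sig <- array(FALSE, dim = pmap$grid$shape)
  if (length(idx)) {
    adj[idx] <- stats::p.adjust(pmap$p[idx], method = "BH")
    sig[idx] <- adj[idx] <= q
  }
  new_corrected_map(pmap$grid, pmap$method, "fdr", adj, sig, pmap$valid,
                    params = c(pmap$params, list(q = q)))
}

# The permutation correction prunes the already-significant voxels of the
# true map: a voxel belongs to the corrected significant set iff its true
# p-value is below alpha AND fewer than alpha * n_perm permuted maps give
# it a p-value at or below the true one. The corrected_p channel stores
# the plain permutation percentage.

# recompute the chosen test's p-map values for (possibly permuted)
# improvement scores; returns p over the fixed set of valid voxels
perm_test_p <- function(test, voxel, imp, mu0, min_n, cache) {
  if (test == "t") {
    mom <- voxel_moments(voxel, imp)
    list(voxel = mom$voxel, n = mom$n,
         p = t_p_from_moments(mom$n, mom$mean, mom$ss, mu0))
  } else {
    res <- grouped_signed_rank_p(voxel, imp, mu0 = mu0, min_n = min_n,
                                 cache = cache)
    list(voxel = res$voxel, n = res$n, p = res$p)
  }
}

#' Voxel-wise nonparametric permutation correction
#'
#' Improvement scores are permuted across the cohort's records (the
#' default unrestricted shuffle exchanges labels both between and within
#' leads; `stratify_by_lead = TRUE` restricts exchanges to within each
#' lead) while the EF geometry stays fixed. The chosen test is recomputed
#' on each of the `n_perm` permuted datasets, and the corrected p-value of
#' a voxel is the fraction of permuted maps in which its p-value is lower
#' than or equal to its true p-value. Voxels with corrected p >= 0.05 are
#' discarded from the map's significant set (the boundary is discarded),
#' so a corrected map's significant voxels are those significant in the
#' true map whose corrected p-value is also below `alpha`.
#'
#' @param stack a `voxel_stack`.
#' @param test `"t"` or `"wilcoxon"`.
#' @param n_perm number of permutations (default 200).
#' @param seed mandatory RNG seed; permutations are reproducible given
#'   (seed, replicate).
#' @param mu0,min_n test parameters, as in [tmap()].
#' @param alpha significance cutoff on the corrected p-value.
#' @param stratify_by_lead permute within leads only.
#' @param add_one use the (count + 1) / (n_perm + 1) convention instead of
#'   the plain percentage (default off).
#' @return a `corrected_map` with the empirical corrected p-values.
#' @export
permutation_correct <- function(stack, test = c("t", "wilcoxon"),
                                n_perm = 200L, seed, mu0 = 75, min_n = 3L,
                                alpha = 0.05, stratify_by_lead = FALSE,
                                add_one = FALSE) {
  test <- match.arg(test)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  obs <- stack$obs
  recs <- unique(data.frame(record = obs$record, patient = obs$patient,
                            improvement = obs$improvement,
                            stringsAsFactors = FALSE))
  # lead = patient here (one lead per patient and hemisphere)
  rec_of_obs <- match(obs$record, recs$record)
  cache <- new.env(parent = emptyenv())
  true_res <- perm_test_p(test, obs$voxel, obs$improvement, mu0, min_n,
                          cache)
  keep <- true_res$n >= min_n
  vox <- true_res$voxel[keep]
  p_true <- true_res$p[keep]
  count <- numeric(length(vox))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- if (stratify_by_lead) {
        idx <- seq_len(nrow(recs))
        for (g in split(idx, recs$patient)) idx[g] <- g[sample.int(length(g))]
        idx
      } else sample.int(nrow(recs))
      imp_b <- recs$improvement[perm][rec_of_obs]
      res_b <- perm_test_p(test, obs$voxel, imp_b, mu0, min_n, cache)
      # permuted stacks share the voxel support, so rows align
      count <- count + (res_b$p[keep] <= p_true)
    }
  })
  denom <- if (add_one) n_perm + 1 else n_perm
  numer <- if (add_one) count + 1 else count
  cp <- array(NA_real_, dim = stack$grid$shape)
  cp[vox] <- numer / denom
  sig <- array(FALSE, dim = stack$grid$shape)
  sig[vox] <- cp[vox] < alpha & p_true < alpha
  valid <- array(FALSE, dim = stack$grid$shape)
  valid[vox] <- TRUE
  new_corrected_map(stack$grid, test, "perm", cp, sig, valid,
                    params = list(mu0 = mu0, min_n = min_n, alpha = alpha,
                                  n_perm = n_perm, seed = seed,
                                  stratify_by_lead = stratify_by_lead,
                                  add_one = add_one))
}

#' Stability of the sweet spot across permutation counts
#'
#' Reruns the permutation correction (and downstream masking/clustering)
#' for each requested permutation count and reports surviving-voxel
#' counts, pairwise Dice coefficients and centroid distances of the
#' resulting sweet spots.
#'
#' @param stack a `voxel_stack`.
#' @param test `"t"` or `"wilcoxon"`.
#' @param counts integer vector of permutation counts.
#' @param seed RNG seed (one independent correction per count).
#' @param params sweet-spot extraction parameters, see [pss_params()].
#' @return list with `n_voxels` (per count), `dice` and `centroid_dist_mm`
#'   (pairwise matrices) and the extracted sweet spots.
#' @export
permutation_count_stability <- function(stack, test = "t", counts,
                                        seed, params = pss_params()) {
  if (!length(counts)) stop("counts must be non-empty")
  sspots <- lapply(counts, function(np) {
    cm <- permutation_correct(stack, test, n_perm = np, seed = seed,
                              mu0 = params$mu0, min_n = params$min_n,
                              alpha = params$alpha)
    extract_pss(cm, stack, params)
  })
  k <- length(counts)
  dice_m <- matrix(1, k, k)
  dist_m <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    dice_m[i, j] <- dice_m[j, i] <- dice(sspots[[i]]$mask, sspots[[j]]$mask)
    ci <- if (sum(sspots[[i]]$mask)) centroid_mm(sspots[[i]]$mask, stack$grid)
    cj <- if (sum(sspots[[j]]$mask)) centroid_mm(sspots[[j]]$mask, stack$grid)
    d <- if (is.null(ci) || is.null(cj)) NA_real_ else sqrt(sum((ci - cj)^2))
    dist_m[i, j] <- dist_m[j, i] <- d
  }
  dimnames(dice_m) <- dimnames(dist_m) <- list(counts, counts)
  list(counts = counts,
       n_voxels = vapply(sspots, function(s) sum(s$mask), 0),
       dice = dice_m, centroid_dist_mm = dist_m, sweet_spots = sspots)
}
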