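# Comparison metrics: volumetrics, overlap, cross-validated correlation
# with improvement, and consistency statistics.

#' Dice overlap coefficient
#'
#' 2|A n B| / (|A| + |B|); defined as 0 when both masks are empty.
#' @param a,b logical arrays on the same grid.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimension mismatch: (%s) vs (%s)",
                 paste(dim(a), collapse = ","),
                 paste(dim(b), collapse = ",")))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(0)
  2 * sum(a & b) / (sa + sb)
}

# Dice between two sets of voxel indices (used by the LOOCV fast path)
dice_idx <- function(ia, ib) {
  if (length(ia) + length(ib) == 0L) return(0)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

#' Centroid of a mask in world coordinates (mm)
#' @param mask logical 3D array.
#' @param grid the `voxel_grid`.
#' @return length-3 numeric vector.
#' @export
centroid_mm <- function(mask, grid) {
  idx <- which(mask)
  if (!length(idx)) stop("centroid of an empty mask is undefined")
  colMeans(voxel_centers_mm(grid, idx))
}

#' Volume of a mask in mm^3
#' @inheritParams centroid_mm
#' @export
volume_mm3 <- function(mask, grid) sum(mask) * voxel_volume_mm3(grid)

#' Volume coefficient of variation (percent)
#'
#' 100 * sd(volumes) / mean(volumes), with the sample (n - 1) standard
#' deviation.
#' @param volumes numeric vector (>= 2 values, positive mean).
#' @export
volume_cv <- function(volumes) {
  if (length(volumes) < 2L) stop("need at least 2 volumes")
  m <- mean(volumes)
  if (m <= 0) stop("volume CV undefined for non-positive mean")
  100 * stats::sd(volumes) / m
}

# equivalent-sphere diameter of a volume in mm^3
sphere_diameter <- function(v) (6 * v / pi)^(1 / 3)

#' Consistency metrics over a set of sweet spots
#'
#' For the sweet spots of (say) leave-one-out folds: volume CV, all
#' pairwise Dice coefficients, and all pairwise centroid distances, each
#' normalized by the larger equivalent-sphere diameter of the pair and
#' reported in percent. Empty sweet spots are excluded with a warning.
#'
#' @param pss_list list of `sweet_spot` objects (or logical masks).
#' @param grid grid (needed when plain masks are passed).
#' @return list with `volume_cv_pct`, `dice` (vector), `norm_dist_pct`
#'   (vector), `n_used`, `n_empty`.
#' @export
consistency_metrics <- function(pss_list, grid = NULL) {
  masks <- lapply(pss_list, function(p)
    if (inherits(p, "sweet_spot")) p$mask else p)
  if (is.null(grid)) {
    g <- Filter(function(p) inherits(p, "sweet_spot"), pss_list)
    if (!length(g)) stop("supply `grid` when passing plain masks")
    grid <- g[[1]]$grid
  }
  empty <- vapply(masks, function(m) sum(m) == 0, TRUE)
  if (any(empty))
    warning(sum(empty), " empty sweet spot(s) excluded from consistency")
  masks <- masks[!empty]
  if (length(masks) < 2L) stop("need at least 2 non-empty sweet spots")
  vols <- vapply(masks, volume_mm3, 0, grid = grid)
  cents <- t(vapply(masks, centroid_mm, numeric(3), grid = grid))
  k <- length(masks)
  dd <- c(); nd <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    dd <- c(dd, dice(masks[[i]], masks[[j]]))
    dmax <- max(sphere_diameter(vols[i]), sphere_diameter(vols[j]))
    nd <- c(nd, 100 * sqrt(sum((cents[i, ] - cents[j, ])^2)) / dmax)
  }
  list(volume_cv_pct = volume_cv(vols), dice = dd, norm_dist_pct = nd,
       n_used = k, n_empty = sum(empty))
}

#' Leave-one-out cross-validated overlap-improvement correlation
#'
#' One fold per patient: the sweet spot is extracted from the remaining
#' patients, each left-out VTA is overlapped with it (Dice), and the
#' overlap is paired with the VTA's improvement score. Pairs are pooled
#' over folds; pairs at or above the pooled `trim_pct` percentile of
#' overlap are excluded; Spearman's rho and its p-value are computed on
#' the remainder. Folds with an empty sweet spot contribute zero-overlap
#' pairs by default (`empty_fold = "drop"` removes them instead).
#'
#' @param x a `dbs_cohort` or `voxel_stack`.
#' @param method `"t"`, `"wilcoxon"`, `"bayes"` or `"lmm"`.
#' @param correction `"none"`, `"fdr"` or `"perm"` (t / wilcoxon only).
#' @param params a [pss_params()].
#' @param seed seed for per-fold permutation corrections.
#' @param trim_pct overlap trimming percentile (default 95).
#' @param empty_fold `"zero"` or `"drop"`.
#' @return list with `rho`, `p_value`, `pairs` (data.frame overlap /
#'   improvement / patient / used), `folds` (per-fold sweet-spot voxel
#'   counts), `trim_cutoff`.
#' @export
loocv_overlap_correlation <- function(x, method = "t",
                                      correction = c("none", "fdr", "perm"),
                                      params = pss_params(), seed = 1L,
                                      trim_pct = 95,
                                      empty_fold = c("zero", "drop")) {
  correction <- match.arg(correction)
  empty_fold <- match.arg(empty_fold)
  stack <- if (inherits(x, "dbs_cohort"))
    build_stack(x, threshold = params$ef_threshold) else x
  pats <- stack$patients
  if (length(pats) < 3L) stop("LOOCV needs at least 3 patients")
  fold_sizes <- integer(length(pats))
  pairs <- list()
  for (k in seq_along(pats)) {
    train <- stack_subset(stack, patients = setdiff(pats, pats[k]))
    pss <- pss_from_stack(train, method, correction, params,
                          seed = seed + k)
    fold_sizes[k] <- sum(pss$mask)
    pss_idx <- which(pss$mask)
    held <- stack$obs[stack$obs$patient == pats[k], ]
    held_split <- split(held$voxel, held$record)
    ov <- numeric(length(held_split))
    imp <- numeric(length(held_split))
    for (r in seq_along(held_split)) {
      rec_id <- names(held_split)[r]
      ov[r] <- if (fold_sizes[k] == 0 && empty_fold == "zero") 0
               else dice_idx(held_split[[r]], pss_idx)
      imp[r] <- held$improvement[match(rec_id, held$record)]
    }
    if (fold_sizes[k] == 0 && empty_fold == "drop") next
    pairs[[length(pairs) + 1L]] <- data.frame(
      overlap = ov, improvement = imp, patient = pats[k],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) < 3L)
    stop("too few LOOCV pairs to correlate")
  cutoff <- stats::quantile(pairs$overlap, trim_pct / 100, names = FALSE)
  # trimming targets high-overlap outliers; when the percentile collapses
  # onto the minimum (e.g. most folds empty) there is nothing to trim
  pairs$used <- if (cutoff > min(pairs$overlap)) pairs$overlap < cutoff
               else rep(TRUE, nrow(pairs))
  kept <- pairs[pairs$used, ]
  ct <- if (stats::sd(kept$overlap) == 0 || stats::sd(kept$improvement) == 0)
    list(estimate = NA_real_, p.value = NA_real_) # no rankable variation
  else suppressWarnings(
    stats::cor.test(kept$overlap, kept$improvement, method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, pairs = pairs,
       folds = fold_sizes, trim_cutoff = cutoff,
       method = method, correction = correction)
}

#' Between-method comparison of variability scores
#'
#' Checks ANOVA assumptions (Shapiro-Wilk on residuals, Levene's test for
#' homoscedasticity, both at 0.05); if both pass, runs one-way ANOVA with
#' Tukey post-hoc when significant; otherwise Kruskal-Wallis (no post-hoc
#' by default; the omission is noted in the result).
#'
#' @param metric_samples named list of numeric vectors, one per method.
#' @return list with `test` (`"anova"`, `"kruskal"` or `"none"`),
#'   `statistic`, `p_value`, `posthoc` (Tukey table or NULL), and the
#'   assumption-check trail.
#' @export
compare_methods <- function(metric_samples) {
  if (length(metric_samples) < 2L)
    stop("need at least 2 methods")
  if (any(vapply(metric_samples, length, 0L) < 2L))
    stop("each method needs at least 2 values")
  df <- data.frame(
    value = unlist(metric_samples, use.names = FALSE),
    group = factor(rep(names(metric_samples),
                       vapply(metric_samples, length, 0L))))
  if (stats::var(df$value) == 0)
    return(list(test = "none", statistic = NA_real_, p_value = NA_real_,
                posthoc = NULL,
                assumptions = list(note = "all values identical"),
                note = "degenerate input: no differences to test"))
  fit <- stats::aov(value ~ group, data = df)
  res <- stats::residuals(fit)
  sw_p <- if (stats::sd(res) > 0 && length(res) >= 3 && length(res) <= 5000)
    stats::shapiro.test(res)$p.value else NA_real_
  lev_p <- tryCatch(car::leveneTest(value ~ group, data = df)[1, "Pr(>F)"],
                    error = function(e) NA_real_)
  normal_ok <- !is.na(sw_p) && sw_p > 0.05
  homosc_ok <- !is.na(lev_p) && lev_p > 0.05
  assumptions <- list(shapiro_p = sw_p, levene_p = lev_p,
                      normal_ok = normal_ok, homoscedastic_ok = homosc_ok)
  if (normal_ok && homosc_ok) {
    an <- stats::anova(fit)
    pval <- an[1, "Pr(>F)"]
    posthoc <- if (pval < 0.05)
      as.data.frame(stats::TukeyHSD(fit)$group) else NULL
    list(test = "anova", statistic = an[1, "F value"], p_value = pval,
         posthoc = posthoc, assumptions = assumptions)
  } else {
    kw <- stats::kruskal.test(value ~ group, data = df)
    list(test = "kruskal", statistic = unname(kw$statistic),
         p_value = kw$p.value, posthoc = NULL, assumptions = assumptions,
         note = "no post-hoc after Kruskal-Wallis (none specified)")
  }
}
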