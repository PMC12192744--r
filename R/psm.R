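# Probabilistic stimulation maps (PSMs): per-voxel statistics computed
# along the fourth (observation) dimension of the stack.

new_ps_map <- function(grid, method, stat_type, valid,
                       p = NULL, bf = NULL, slope = NULL, params = list()) {
  structure(list(grid = grid, method = method, stat_type = stat_type,
                 valid = valid, p = p, bf = bf, slope = slope,
                 params = params),
            class = "ps_map")
}

#' @export
print.ps_map <- function(x, ...) {
  cat(sprintf("ps_map (%s): %d valid voxels\n", x$method, sum(x$valid)))
  invisible(x)
}

# per-voxel n, mean and centred sum of squares from the stack
voxel_moments <- function(voxel, imp) {
  s <- rowsum(cbind(n = rep(1, length(imp)), sx = imp, sx2 = imp^2), voxel)
  vox <- as.integer(rownames(s))
  n <- s[, 1]
  m <- s[, 2] / n
  ss <- pmax(0, s[, 3] - n * m^2)
  list(voxel = vox, n = n, mean = m, ss = ss)
}

# one-sided upper-tail t-test p-values from grouped moments; the
# zero-variance convention keeps all-equal samples (common on a discrete
# rating scale): p = 0 if the mean exceeds mu0, else p = 1
t_p_from_moments <- function(n, m, ss, mu0) {
  s2 <- ss / (n - 1)
  p <- ifelse(m > mu0, 0, 1)
  pos <- n >= 2 & !is.na(s2) & s2 > 0
  tstat <- (m[pos] - mu0) / sqrt(s2[pos] / n[pos])
  p[pos] <- stats::pt(tstat, n[pos] - 1, lower.tail = FALSE)
  p
}

#' Voxel-wise one-sided one-sample t-test map
#'
#' Tests H0: improvement < `mu0` against H1: improvement >= `mu0` at every
#' voxel with at least `min_n` observations; other voxels are marked
#' invalid (no statistic, excluded from corrections).
#'
#' @param stack a `voxel_stack`.
#' @param mu0 improvement threshold in percent (default 75, the "good
#'   improvement" level of the rating scale).
#' @param min_n minimum observations per voxel.
#' @return a `ps_map` carrying one-sided p-values.
#' @export
tmap <- function(stack, mu0 = 75, min_n = 3L) {
  mom <- voxel_moments(stack$obs$voxel, stack$obs$improvement)
  keep <- mom$n >= min_n
  p <- array(NA_real_, dim = stack$grid$shape)
  p[mom$voxel[keep]] <- t_p_from_moments(mom$n[keep], mom$mean[keep],
                                         mom$ss[keep], mu0)
  valid <- array(FALSE, dim = stack$grid$shape)
  valid[mom$voxel[keep]] <- TRUE
  new_ps_map(stack$grid, "t", "p", valid, p = p,
             params = list(mu0 = mu0, min_n = min_n, alpha = 0.05))
}

#' Voxel-wise one-sided Wilcoxon signed-rank map
#'
#' Same hypotheses as [tmap()]; zero differences follow the Pratt rule and
#' the null distribution is exact for up to 25 non-zero differences
#' (ties handled exactly), normal approximation with continuity
#' correction beyond. See [signed_rank_p()].
#'
#' @inheritParams tmap
#' @param cache internal memo environment (shared by the permutation
#'   correction); leave at default otherwise.
#' @return a `ps_map` carrying one-sided p-values.
#' @export
wmap <- function(stack, mu0 = 75, min_n = 3L,
                 cache = new.env(parent = emptyenv())) {
  res <- grouped_signed_rank_p(stack$obs$voxel, stack$obs$improvement,
                               mu0 = mu0, min_n = min_n, cache = cache)
  keep <- res$n >= min_n
  p <- array(NA_real_, dim = stack$grid$shape)
  p[res$voxel[keep]] <- res$p[keep]
  valid <- array(FALSE, dim = stack$grid$shape)
  valid[res$voxel[keep]] <- TRUE
  new_ps_map(stack$grid, "wilcoxon", "p", valid, p = p,
             params = list(mu0 = mu0, min_n = min_n, alpha = 0.05))
}

#' Export a map statistic as NIfTI
#'
#' @param map a `ps_map` or `corrected_map`.
#' @param path output NIfTI path; a JSON sidecar with the map parameters
#'   is written next to it.
#' @param channel which statistic to write (default: the map's primary
#'   one).
#' @export
save_map <- function(map, path, channel = NULL) {
  if (is.null(channel))
    channel <- switch(map$stat_type, p = "p", bf = "bf", lmm = "p",
                      corrected = "corrected_p")
  vals <- map[[channel]]
  if (is.null(vals)) stop("map has no channel '", channel, "'")
  vals[is.na(vals)] <- -1 # sentinel for invalid voxels
  save_volume(vals, map$grid, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(method = map$method, stat_type = map$stat_type, channel = channel,
         invalid_value = -1, params = map$params),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
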