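# One-sided one-sample Wilcoxon signed-rank test with Pratt zero handling.
#
# Zeros are ranked together with the non-zero differences (midranks over
# the full sample) and then dropped from the statistic; the null
# distribution is taken over sign assignments of the non-zero differences
# only, holding their Pratt ranks fixed. For up to `exact_max_n` non-zero
# differences the null distribution of W+ is computed exactly by dynamic
# programming over (doubled, hence integer) midranks, which also handles
# ties exactly; above that a normal approximation with continuity
# correction is used, with tie handling inherited from the midranks.

#' One-sided signed-rank p-value (H1: location >= mu0)
#'
#' @param x numeric sample.
#' @param mu0 tested location.
#' @param exact_max_n exact enumeration is used while the number of
#'   non-zero differences is at most this (default 25).
#' @return one-sided p-value; 1 when every difference is zero.
#' @export
signed_rank_p <- function(x, mu0 = 75, exact_max_n = 25L) {
  d <- x - mu0
  if (any(!is.finite(d))) stop("non-finite values in sample")
  r <- rank(abs(d)) # midranks over the full sample, zeros included (Pratt)
  nz <- d != 0
  m <- sum(nz)
  if (m == 0L) return(1)
  r_nz <- r[nz]
  w_obs <- sum(r_nz[d[nz] > 0])
  if (m <= exact_max_n) {
    r2 <- as.integer(round(2 * r_nz)) # doubled midranks are integers
    total <- sum(r2)
    # counts[s + 1] = number of sign assignments with doubled W+ == s
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(total + 1L - rk)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w_obs))
    sum(counts[(w2 + 1L):(total + 1L)]) / 2^m
  } else {
    e_w <- sum(r_nz) / 2
    v_w <- sum(r_nz^2) / 4
    stats::pnorm((w_obs - 0.5 - e_w) / sqrt(v_w), lower.tail = FALSE)
  }
}

# p-values for many voxels sharing a small improvement alphabet.
# voxel: integer ids; imp: improvement per observation. Exploits that the
# p-value depends only on the multiset of differences: per-voxel level
# counts index a memo cache (an environment, shared across permutation
# replicates when supplied).
grouped_signed_rank_p <- function(voxel, imp, mu0 = 75, min_n = 3L,
                                  cache = new.env(parent = emptyenv()),
                                  exact_max_n = 25L) {
  uvals <- sort(unique(imp))
  if (length(uvals) > 24L) {
    # continuous data: no useful key, compute per voxel directly
    dt <- data.table::data.table(voxel = voxel, imp = imp)
    res <- dt[, list(n = .N,
                     p = if (.N >= min_n)
                       signed_rank_p(imp, mu0, exact_max_n)
                     else NA_real_),
              by = "voxel"]
    return(res)
  }
  ind <- matrix(0L, length(imp), length(uvals))
  ind[cbind(seq_along(imp), match(imp, uvals))] <- 1L
  cnt <- rowsum(ind, voxel)
  vox_ids <- as.integer(rownames(cnt))
  n <- as.integer(rowSums(cnt))
  keys <- do.call(paste, c(as.data.frame(cnt), sep = ","))
  p <- rep(NA_real_, length(keys))
  valid <- n >= min_n
  ukeys <- unique(keys[valid])
  pk <- vapply(ukeys, function(k) {
    hit <- cache[[k]]
    if (!is.null(hit)) return(hit)
    counts <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    val <- signed_rank_p(rep(uvals, counts), mu0, exact_max_n)
    assign(k, val, envir = cache)
    val
  }, 0)
  p[valid] <- pk[match(keys[valid], ukeys)]
  data.table::data.table(voxel = vox_ids, n = n, p = p)
}
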