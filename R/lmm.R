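#' Voxel-wise linear mixed model map
#'
#' At each candidate voxel fits improvement ~ EF norm with per-patient
#' random intercepts and slopes (`improvement ~ ef + (1 + ef | patient)`).
#' The reported statistic is the fixed-effect slope and its two-sided
#' p-value (Satterthwaite degrees of freedom). When the random-slope fit
#' fails to converge or is singular, the model falls back to random
#' intercepts only; if that also fails the voxel is marked invalid.
#' Selection into a sweet spot additionally requires a positive slope
#' (see [significant_voxels()]).
#'
#' @param stack a `voxel_stack`.
#' @param candidate_mask logical array of voxels to fit (default: all
#'   voxels with data). Restricting candidates to the frequency-mask
#'   support keeps the per-voxel fits tractable.
#' @param min_patients minimum distinct patients per voxel.
#' @param min_n minimum observations per voxel.
#' @return a `ps_map` with channels `p` (two-sided), `slope`, and metadata
#'   recording per-voxel fallbacks (`params$n_fallback`, `params$n_failed`).
#' @export
lmm_map <- function(stack, candidate_mask = NULL, min_patients = 3L,
                    min_n = 5L) {
  obs <- stack$obs
  if (!is.null(candidate_mask)) {
    cand <- which(candidate_mask)
    obs <- obs[obs$voxel %in% cand, ]
  }
  p <- array(NA_real_, dim = stack$grid$shape)
  slope <- array(NA_real_, dim = stack$grid$shape)
  valid <- array(FALSE, dim = stack$grid$shape)
  n_fallback <- 0L; n_failed <- 0L
  if (nrow(obs)) {
    groups <- split(seq_len(nrow(obs)), obs$voxel)
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                              calc.derivs = FALSE)
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      vox <- obs$voxel[rows[1]]
      df <- data.frame(imp = obs$improvement[rows], ef = obs$ef[rows],
                       patient = obs$patient[rows])
      if (length(rows) < min_n ||
          length(unique(df$patient)) < min_patients) next
      fit <- fit_voxel_lmm(df, ctrl)
      if (is.null(fit$coef)) { n_failed <- n_failed + 1L; next }
      if (fit$fallback) n_fallback <- n_fallback + 1L
      p[vox] <- fit$coef["p"]
      slope[vox] <- fit$coef["slope"]
      valid[vox] <- TRUE
    }
  }
  new_ps_map(stack$grid, "lmm", "lmm", valid, p = p, slope = slope,
             params = list(min_patients = min_patients, min_n = min_n,
                           alpha = 0.05, n_fallback = n_fallback,
                           n_failed = n_failed))
}

fit_voxel_lmm <- function(df, ctrl) {
  extract <- function(fit) {
    cf <- stats::coef(summary(fit))
    c(slope = unname(cf["ef", "Estimate"]),
      p = unname(cf["ef", "Pr(>|t|)"]))
  }
  full <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(imp ~ ef + (1 + ef | patient), data = df,
                     control = ctrl))),
    error = function(e) NULL)
  if (!is.null(full) && !lme4::isSingular(full, tol = 1e-5)) {
    cf <- tryCatch(extract(full), error = function(e) NULL)
    if (!is.null(cf) && all(is.finite(cf)))
      return(list(coef = cf, fallback = FALSE))
  }
  reduced <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(imp ~ ef + (1 | patient), data = df,
                     control = ctrl))),
    error = function(e) NULL)
  if (!is.null(reduced)) {
    cf <- tryCatch(extract(reduced), error = function(e) NULL)
    if (!is.null(cf) && all(is.finite(cf)))
      return(list(coef = cf, fallback = TRUE))
  }
  list(coef = NULL, fallback = TRUE)
}
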