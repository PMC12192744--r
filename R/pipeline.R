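# End-to-end orchestration: stack -> map -> correction -> sweet spot for
# every requested method x correction combination.

#' Compute one probabilistic stimulation map
#'
#' @param stack a `voxel_stack`.
#' @param method `"t"`, `"wilcoxon"`, `"bayes"` or `"lmm"`.
#' @param params a [pss_params()].
#' @return a `ps_map`.
#' @export
compute_psm <- function(stack, method, params = pss_params()) {
  switch(method,
         t = tmap(stack, mu0 = params$mu0, min_n = params$min_n),
         wilcoxon = wmap(stack, mu0 = params$mu0, min_n = params$min_n),
         bayes = bmap(stack, mu0 = params$mu0, prior = params$prior,
                      min_n = params$min_n),
         lmm = {
           support <- stack$n_map > 0
           cand <- apply_frequency_masks(support, stack,
                                         pat_frac = params$pat_frac,
                                         nmap_frac = params$nmap_frac)
           lmm_map(stack, candidate_mask = cand,
                   min_patients = params$min_patients)
         },
         stop("unknown method: ", method))
}

#' Extract a sweet spot directly from a stack
#'
#' Computes the requested map, applies the requested correction and runs
#' the extraction pipeline. Only the t and Wilcoxon maps accept a
#' correction; the Bayesian and LMM maps are used uncorrected.
#'
#' @inheritParams compute_psm
#' @param correction `"none"`, `"fdr"` or `"perm"`.
#' @param seed seed for the permutation correction.
#' @return a `sweet_spot`.
#' @export
pss_from_stack <- function(stack, method, correction = "none",
                           params = pss_params(), seed = 1L) {
  if (correction != "none" && !method %in% c("t", "wilcoxon"))
    stop("only the t and Wilcoxon maps accept a type-I error correction")
  map <- if (correction == "perm") {
    permutation_correct(stack, test = method, n_perm = params$n_perm,
                        seed = seed, mu0 = params$mu0,
                        min_n = params$min_n, alpha = params$alpha)
  } else if (correction == "fdr") {
    fdr_bh(compute_psm(stack, method, params), q = params$alpha)
  } else {
    compute_psm(stack, method, params)
  }
  extract_pss(map, stack, params)
}

default_variants <- function() {
  data.frame(method = c("t", "t", "wilcoxon", "wilcoxon", "bayes", "lmm"),
             correction = c("fdr", "perm", "fdr", "perm", "none", "none"),
             stringsAsFactors = FALSE)
}

#' Run the full sweet-spot pipeline over method x correction variants
#'
#' The default variant set reproduces the six-map study design: TFDR,
#' TPerm, WFDR, WPerm, B (uncorrected Bayesian) and LMM (uncorrected).
#' Per-stage voxel counts (significant, after frequency masks, after
#' cluster filter) are recorded per variant, so outcomes like "no voxel
#' passed the FDR correction" stay auditable.
#'
#' @param x a `dbs_cohort` or a prebuilt `voxel_stack`.
#' @param variants data.frame with columns `method`, `correction`
#'   (default: the six study variants).
#' @param params a [pss_params()].
#' @param seed base seed; variant i uses `seed + i` for its permutations.
#' @return list of class `pss_run`: `sweet_spots` (named list),
#'   `stage_counts` (data.frame), `params`, `seed`.
#' @export
run_pss_pipeline <- function(x, variants = default_variants(),
                             params = pss_params(), seed = 1L) {
  bad <- variants$correction != "none" &
    !variants$method %in% c("t", "wilcoxon")
  if (any(bad))
    stop("corrections apply to the t and Wilcoxon maps only: ",
         paste(variants$method[bad], variants$correction[bad],
               collapse = ", "))
  if (!all(variants$method %in% c("t", "wilcoxon", "bayes", "lmm")))
    stop("unknown method name in variants")
  if (!all(variants$correction %in% c("none", "fdr", "perm")))
    stop("unknown correction name in variants")
  stack <- if (inherits(x, "dbs_cohort"))
    build_stack(x, threshold = params$ef_threshold) else x
  sspots <- list()
  for (i in seq_len(nrow(variants))) {
    nm <- variant_name(variants$method[i], variants$correction[i])
    sspots[[nm]] <- pss_from_stack(stack, variants$method[i],
                                   variants$correction[i], params,
                                   seed = seed + i)
  }
  counts <- do.call(rbind, lapply(names(sspots), function(nm) {
    data.frame(variant = nm, t(sspots[[nm]]$stage_counts))
  }))
  structure(list(sweet_spots = sspots, stage_counts = counts,
                 params = params[setdiff(names(params), "prior")],
                 seed = seed),
            class = "pss_run")
}

variant_name <- function(method, correction) {
  base <- c(t = "T", wilcoxon = "W", bayes = "B", lmm = "LMM")[[method]]
  suffix <- c(none = "", fdr = "FDR", perm = "Perm")[[correction]]
  paste0(base, suffix)
}

#' @export
print.pss_run <- function(x, ...) {
  cat("pss_run with", length(x$sweet_spots), "variants\n")
  print(x$stage_counts, row.names = FALSE)
  invisible(x)
}
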