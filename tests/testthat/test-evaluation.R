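# Evaluation metrics against hand-computed fixtures.

test_that("Dice coefficient matches set counting", {
  g <- tiny_grid(4L)
  a <- array(FALSE, dim = g$shape); b <- a
  a[1:10] <- TRUE
  b[7:12] <- TRUE # |a| = 10, |b| = 6, |intersection| = 4
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, array(FALSE, g$shape)), 0)
  expect_equal(dice(array(FALSE, g$shape), array(FALSE, g$shape)), 0)
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "mismatch")
})

test_that("centroid and volume use voxel-centre world coordinates", {
  g <- voxel_grid(c(8L, 8L, 8L), 0.5)
  m <- array(FALSE, dim = g$shape)
  m[1, 1, 1] <- TRUE
  expect_equal(centroid_mm(m, g), voxel_centers_mm(g, 1L)[1, ])
  m[2, 1, 1] <- TRUE # symmetric pair: midpoint
  expect_equal(centroid_mm(m, g)[1],
               mean(voxel_centers_mm(g, 1:2)[, 1]))
  m8 <- array(FALSE, dim = g$shape); m8[1:2, 1:2, 1:2] <- TRUE
  expect_equal(volume_mm3(m8, g), 1.0) # 8 voxels at 0.5 mm = 1 mm^3
  expect_error(centroid_mm(array(FALSE, g$shape), g), "empty")
})

test_that("volume CV uses the sample standard deviation", {
  expect_equal(volume_cv(c(10, 10, 10)), 0)
  expect_equal(volume_cv(c(20, 30)), 100 * sd(c(20, 30)) / 25)
  expect_equal(round(volume_cv(c(20, 30)), 2), 28.28)
  expect_equal(volume_cv(c(20, 30) * 7), volume_cv(c(20, 30)))
  expect_error(volume_cv(c(5)), "at least 2")
  expect_error(volume_cv(c(0, 0)), "non-positive")
})

test_that("consistency metrics: identity, combinatorics, geometry", {
  g <- voxel_grid(c(24L, 24L, 24L), 0.5)
  sphere <- function(center, r) {
    d2 <- pssmap:::grid_dist2(g, center)
    d2 <= r^2
  }
  s1 <- sphere(c(0, 0, 0), 2)
  same <- consistency_metrics(list(s1, s1, s1), grid = g)
  expect_equal(same$volume_cv_pct, 0)
  expect_equal(same$dice, rep(1, 3)) # 3 choose 2 pairs
  expect_equal(same$norm_dist_pct, rep(0, 3))

  # two identical spheres offset by 1 mm: normalized distance =
  # offset / equivalent-sphere diameter
  s2 <- sphere(c(1, 0, 0), 2)
  cm <- consistency_metrics(list(s1, s2), grid = g)
  dvol <- volume_mm3(s1, g)
  expected <- 100 * 1 / (6 * dvol / pi)^(1 / 3)
  expect_equal(cm$norm_dist_pct, expected, tolerance = 1e-6)

  expect_warning(
    cme <- consistency_metrics(list(s1, s2, array(FALSE, g$shape)),
                               grid = g),
    "empty")
  expect_equal(cme$n_used, 2)
})

test_that("Spearman fixture and monotone case", {
  # rank-difference formula: x=(1,2,3), y=(3,1,2) -> rho = -0.5
  expect_equal(unname(cor(1:3, c(3, 1, 2), method = "spearman")), -0.5)
  expect_equal(unname(cor(1:10, (1:10)^3, method = "spearman")), 1)
})

test_that("method comparison picks ANOVA or Kruskal-Wallis correctly", {
  set.seed(11)
  a <- rnorm(30, 10, 1); b <- rnorm(30, 10, 1); c <- rnorm(30, 10, 1)
  same <- compare_methods(list(A = a, B = b, C = c))
  expect_equal(same$test, "anova")
  expect_gt(same$p_value, 0.05)
  expect_null(same$posthoc)

  shifted <- compare_methods(list(A = a, B = b, C = c + 10))
  expect_equal(shifted$test, "anova")
  expect_lt(shifted$p_value, 0.05)
  expect_true(any(grepl("C", rownames(shifted$posthoc))))
  expect_true(all(shifted$posthoc[grepl("C", rownames(shifted$posthoc)),
                                  "p adj"] < 0.05))

  heavy <- compare_methods(list(A = rcauchy(40), B = rcauchy(40)))
  expect_equal(heavy$test, "kruskal")

  degen <- compare_methods(list(A = c(1, 1), B = c(1, 1)))
  expect_equal(degen$test, "none")

  expect_error(compare_methods(list(A = 1:3)), "at least 2")
})

test_that("LOOCV builds one fold per patient and pools trimmed pairs", {
  fx <- small_signal_stack()
  res <- loocv_overlap_correlation(fx$stack, method = "t",
                                   correction = "none",
                                   trim_pct = 95)
  expect_length(res$folds, fx$stack$n_patients)
  expect_equal(nrow(res$pairs), nrow(fx$cohort$records))
  expect_true(all(res$pairs$overlap >= 0 & res$pairs$overlap <= 1))
  # trimming excludes pairs at or above the pooled 95th percentile
  expect_true(all(res$pairs$overlap[res$pairs$used] < res$trim_cutoff))
  expect_true(is.finite(res$rho) && abs(res$rho) <= 1)
  # every held-out patient contributes its own records exactly once
  tab <- table(res$pairs$patient)
  rec_tab <- table(fx$cohort$records$patient_id)
  expect_equal(as.integer(tab[names(rec_tab)]), as.integer(rec_tab))
})

test_that("LOOCV correlation is near zero under shuffled labels", {
  fx <- small_signal_stack()
  st <- fx$stack
  set.seed(4)
  # shuffle improvements at the record level
  recs <- unique(data.frame(record = st$obs$record,
                            improvement = st$obs$improvement))
  shuffled <- recs$improvement[sample.int(nrow(recs))]
  st$obs$improvement <- shuffled[match(st$obs$record, recs$record)]
  res <- loocv_overlap_correlation(st, method = "t", correction = "none")
  # either no sweet spot survives anywhere (no correlation to speak of)
  # or the pooled correlation is consistent with zero
  expect_true(is.na(res$rho) || abs(res$rho) < 0.35)
})
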