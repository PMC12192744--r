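test_that("point-source EF follows the calibrated inverse-square law", {
  # odd-sized grid puts a voxel centre exactly at the origin
  grid <- voxel_grid(c(17L, 17L, 17L), 0.5)
  ef <- ef_point_source(c(0, 0, 0), 1, grid)
  at <- function(dx) ef$values[9L + dx, 9L, 9L]
  # calibration identity: EF(2 mm, 1 mA) = 0.2 V/mm
  expect_equal(at(4L), 0.2, tolerance = 1e-12)
  # inverse square: EF(1 mm) = 4 x EF(2 mm)
  expect_equal(at(2L), 4 * at(4L), tolerance = 1e-12)
  # linear in amplitude
  ef2 <- ef_point_source(c(0, 0, 0), 2, grid)
  expect_equal(ef2$values, 2 * ef$values, tolerance = 1e-12)
  # zero amplitude: no field, empty VTA
  ef0 <- ef_point_source(c(0, 0, 0), 0, grid)
  expect_true(all(ef0$values == 0))
  expect_equal(sum(vta_from_ef(ef0)$mask), 0)
  expect_error(ef_point_source(c(50, 0, 0), 1, grid), "outside")
})

test_that("latent scores snap to the rating scale, midpoints up", {
  expect_equal(snap_to_scale(c(62, 63, 12.5, 37.5, 110, -5, 75)),
               c(50, 75, 25, 50, 100, 0, 75))
  # enumeration of all breakpoints
  lat <- seq(-10, 110, by = 0.5)
  snapped <- snap_to_scale(lat)
  expect_true(all(snapped %in% improvement_scale))
  clamped <- pmin(100, pmax(0, lat))
  expect_true(all(abs(snapped - clamped) <= 12.5))
})

test_that("improvement response interpolates background to max by coverage", {
  gt <- ground_truth()
  grid <- tiny_grid()
  gtm <- gt_mask(gt, grid)
  expect_equal(improvement_response(gtm, gt, grid), 100)
  expect_equal(improvement_response(gtm & FALSE, gt, grid), 25)
})

test_that("generated cohorts are reproducible and match the protocol", {
  cfg <- small_cfg()
  co1 <- generate_cohort(cfg, ground_truth(), seed = 11)
  co2 <- generate_cohort(cfg, ground_truth(), seed = 11)
  expect_identical(co1$records, co2$records)
  expect_identical(lapply(co1$ef_volumes, ef_values),
                   lapply(co2$ef_volumes, ef_values))
  expect_false(identical(
    co1$records,
    generate_cohort(cfg, ground_truth(), seed = 12)$records))

  r <- co1$records
  expect_equal(length(unique(r$patient_id)), 8L)
  expect_true(all(r$improvement_pct %in% improvement_scale))
  expect_true(all(abs(r$amplitude_mA / 0.2 -
                        round(r$amplitude_mA / 0.2)) < 1e-9))
  expect_true(all(r$depth_mm >= -10 & r$depth_mm <= 4))
  expect_true(all(r$tract_id %in% c("central", "parallel")))
  # one record per explored position
  expect_false(any(duplicated(r[c("patient_id", "tract_id", "depth_mm")])))
  expect_error(generate_cohort(cfg, ground_truth()), "seed")
  expect_error(sim_config(n_patients = 0), "positive")
})

test_that("records near the ground truth improve more than distal ones", {
  co <- generate_cohort(sim_config(n_patients = 23L),
                        recovery_ground_truth(), seed = 21)
  r <- co$records
  gt_depth <- -2
  near <- r$improvement_pct[abs(r$depth_mm - gt_depth) <= 2]
  far <- r$improvement_pct[abs(r$depth_mm - gt_depth) >= 7]
  expect_gt(length(near), 20)
  expect_gt(length(far), 20)
  wt <- stats::wilcox.test(near, far, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("null mode makes improvement independent of position", {
  co <- generate_cohort(null_sim_config(n_patients = 23L),
                        null_ground_truth(75), seed = 31)
  r <- co$records
  # no depth trend: Kruskal-Wallis across depth bins
  bins <- cut(r$depth_mm, c(-11, -6, -1, 5))
  kw <- stats::kruskal.test(r$improvement_pct, bins)
  expect_gt(kw$p.value, 0.01)
  expect_gt(stats::sd(r$improvement_pct), 5) # boundary null has spread
  expect_equal(mean(r$improvement_pct), 75, tolerance = 5)
})

test_that("default cohorts reproduce the clinical score summary", {
  ms <- c(); ss <- c()
  for (seed in c(101, 202)) {
    co <- generate_cohort(sim_config(), ground_truth(), seed = seed)
    ms <- c(ms, mean(co$records$improvement_pct))
    ss <- c(ss, stats::sd(co$records$improvement_pct))
  }
  expect_true(all(ms >= 45 & ms <= 65))
  expect_true(all(ss >= 25 & ss <= 40))
})
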