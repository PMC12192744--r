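# Significance thresholding, frequency masking, cluster filtering and
# their composition.

test_that("significance rules follow each statistic's convention", {
  grid <- tiny_grid(4L)
  mk <- function(stat_type, ...) {
    fields <- list(...)
    valid <- array(TRUE, dim = grid$shape)
    do.call(pssmap:::new_ps_map,
            c(list(grid, "m", stat_type, valid), fields))
  }
  p <- array(1, dim = grid$shape); p[1:3] <- c(0.049, 0.05, 0.051)
  sig <- significant_voxels(mk("p", p = p))
  expect_equal(unname(sig[1:3]), c(TRUE, FALSE, FALSE)) # strict <

  bf <- array(0.1, dim = grid$shape); bf[1:3] <- c(9.99, 10, 11)
  sig <- significant_voxels(mk("bf", bf = bf))
  expect_equal(unname(sig[1:3]), c(FALSE, TRUE, TRUE)) # inclusive >=

  pl <- array(1, dim = grid$shape); pl[1:2] <- c(0.01, 0.01)
  sl <- array(0, dim = grid$shape); sl[1:2] <- c(-2, 2)
  sig <- significant_voxels(mk("lmm", p = pl, slope = sl))
  expect_equal(unname(sig[1:2]), c(FALSE, TRUE)) # sign rule
})

test_that("frequency masks discard on strict fractions", {
  grid <- tiny_grid(4L)
  st <- manual_stack(data.frame(voxel = 1L, improvement = 100,
                                patient = "A"), grid)
  st$n_patients <- 23L
  npat <- array(0L, dim = grid$shape)
  nmap <- array(0L, dim = grid$shape)
  npat[1:4] <- c(5L, 6L, 23L, 23L)
  nmap[1:4] <- c(100L, 100L, 9L, 10L)
  nmap[5] <- 100L # sets the maximum
  st$npat_map <- npat; st$n_map <- nmap
  sig <- array(TRUE, dim = grid$shape)
  out <- apply_frequency_masks(sig, st, n_patients = 23L)
  # 5/23 < 25% discarded; 6/23 kept; 9 < 10% of 100 discarded; 10 kept
  expect_equal(unname(out[1:4]), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(sum(apply_frequency_masks(sig & FALSE, st, 23L)), 0)
})

test_that("connected components respect the connectivity scheme", {
  m <- array(FALSE, dim = c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE # diagonal in-plane touch
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(max(label_components(m, 18)), 1)
  expect_equal(max(label_components(m, 6)), 2)
  m2 <- array(FALSE, dim = c(3, 3, 3))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE # full-diagonal touch
  expect_equal(max(label_components(m2, 26)), 1)
  expect_equal(max(label_components(m2, 18)), 2)
})

test_that("cluster filter removes components below 8 voxels", {
  grid <- tiny_grid(12L)
  m <- array(FALSE, dim = grid$shape)
  m[1:7, 1, 1] <- TRUE # 7-voxel line
  m[1:8, 5, 5] <- TRUE # 8-voxel line
  out <- filter_clusters(m)
  expect_equal(sum(out[, 1, 1]), 0)
  expect_equal(sum(out[, 5, 5]), 8)
  expect_equal(sum(filter_clusters(m & FALSE)), 0)
  # under 6-connectivity a diagonal pair splits and both halves vanish
  d <- array(FALSE, dim = grid$shape)
  d[cbind(1:8, 1:8, 1)] <- TRUE
  expect_equal(sum(filter_clusters(d, min_cluster = 8, connectivity = 26)), 8)
  expect_equal(sum(filter_clusters(d, min_cluster = 2, connectivity = 6)), 0)
})

test_that("extraction order is threshold -> mask -> cluster", {
  # a 9-voxel significant component that loses 2 voxels to the frequency
  # mask must then fall below the 8-voxel cluster minimum
  grid <- tiny_grid(12L)
  st <- manual_stack(data.frame(voxel = 1L, improvement = 100,
                                patient = "A"), grid)
  st$n_patients <- 4L
  nmap <- array(100L, dim = grid$shape)
  npat <- array(4L, dim = grid$shape)
  npat[cbind(1:2, 1, 1)] <- 0L # masked out
  st$n_map <- nmap; st$npat_map <- npat
  p <- array(1, dim = grid$shape)
  p[cbind(1:9, 1, 1)] <- 0.001
  valid <- array(TRUE, dim = grid$shape)
  pm <- pssmap:::new_ps_map(grid, "t", "p", valid, p = p)
  pss <- extract_pss(pm, st)
  expect_equal(unname(pss$stage_counts),
               c(9, 7, 0))
  expect_equal(sum(pss$mask), 0)
})

test_that("extraction is deterministic and provenance round-trips", {
  fx <- small_signal_stack()
  st <- fx$stack
  pm <- tmap(st)
  p1 <- extract_pss(pm, st)
  p2 <- extract_pss(pm, st)
  expect_identical(p1$mask, p2$mask)
  expect_equal(p1$provenance$method, "t")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  save_pss(p1, path)
  back <- read_volume(path)
  expect_equal(sum(back$values), sum(p1$mask))
  prov <- jsonlite::read_json(sub("\\.nii\\.gz$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(prov$method, "t")
  expect_equal(prov$stage_counts$clustered, sum(p1$mask))
})
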