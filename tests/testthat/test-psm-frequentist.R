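# t and Wilcoxon probabilistic stimulation maps against independent
# oracles.

stack_of_samples <- function(samples) {
  obs <- do.call(rbind, lapply(seq_along(samples), function(i) {
    data.frame(voxel = i, improvement = samples[[i]],
               patient = paste0("P", seq_along(samples[[i]])),
               record = sprintf("r%d_%d", i, seq_along(samples[[i]])))
  }))
  manual_stack(obs)
}

test_that("t-map matches the closed-form t distribution", {
  samples <- list(c(100, 100, 50, 75, 100), c(50, 75, 100, 25),
                  c(80, 85, 90), c(0, 25, 50, 25, 0, 75))
  st <- stack_of_samples(samples)
  tm <- tmap(st)
  for (i in seq_along(samples)) {
    x <- samples[[i]]
    expected <- stats::t.test(x, mu = 75,
                              alternative = "greater")$p.value
    expect_equal(tm$p[i], expected, tolerance = 1e-12)
  }
})

test_that("t-map degenerate zero-variance convention", {
  st <- stack_of_samples(list(c(75, 75, 75), c(100, 100, 100),
                              c(50, 50, 50), c(75, 75)))
  tm <- tmap(st)
  expect_equal(tm$p[1], 1) # mean == mu0, s = 0
  expect_equal(tm$p[2], 0) # mean > mu0, s = 0
  expect_equal(tm$p[3], 1)
  expect_false(tm$valid[4]) # below min_n
  expect_true(is.na(tm$p[4]))
})

test_that("signed-rank p matches exhaustive sign enumeration (n <= 10)", {
  # independent oracle: enumerate all 2^m sign assignments with Pratt
  # midranks and compare the rank-sum tail directly
  enum_p <- function(x, mu0) {
    d <- x - mu0
    r <- rank(abs(d))
    nz <- which(d != 0)
    if (!length(nz)) return(1)
    w_obs <- sum(r[nz][d[nz] > 0])
    signs <- expand.grid(rep(list(c(FALSE, TRUE)), length(nz)))
    w_all <- as.matrix(signs) %*% r[nz]
    mean(w_all >= w_obs - 1e-9)
  }
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:10, 1)
    x <- sample(improvement_scale, n, replace = TRUE)
    expect_equal(signed_rank_p(x, 75), enum_p(x, 75), tolerance = 1e-12)
  }
  # continuous data too (no ties, no zeros)
  for (rep in 1:50) {
    x <- runif(sample(3:10, 1), 0, 100)
    expect_equal(signed_rank_p(x, 75), enum_p(x, 75), tolerance = 1e-12)
  }
})

test_that("signed-rank spec anchors hold", {
  expect_equal(signed_rank_p(c(100, 100, 100), 75), 1 / 8)
  expect_gte(signed_rank_p(c(50, 50, 50), 75), 0.5)
  expect_equal(signed_rank_p(c(75, 75, 75), 75), 1)
  # matches stats::wilcox.test when no zeros/ties are involved
  x <- c(81.2, 93.7, 62.1, 99.0, 77.3, 88.8, 70.2)
  expect_equal(signed_rank_p(x, 75),
               stats::wilcox.test(x, mu = 75, alternative = "greater",
                                  exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("normal approximation branch is close to exact near n = 25", {
  set.seed(7)
  x <- sample(improvement_scale, 26, replace = TRUE)
  p_apx <- signed_rank_p(x, 75) # 26 non-zero at most -> approx branch
  p_ex <- signed_rank_p(x, 75, exact_max_n = 40L)
  expect_equal(p_apx, p_ex, tolerance = 0.02)
})

test_that("w-map agrees with per-voxel signed_rank_p", {
  st <- small_signal_stack()$stack
  wm <- wmap(st)
  idx <- which(wm$valid)
  set.seed(1)
  for (v in sample(idx, 25)) {
    x <- st$obs$improvement[st$obs$voxel == v]
    expect_equal(wm$p[v], signed_rank_p(x, 75), tolerance = 1e-12)
  }
})

test_that("maps ignore observation order within voxels", {
  st <- small_signal_stack()$stack
  st2 <- st
  set.seed(2)
  perm <- sample(nrow(st2$obs))
  st2$obs <- st2$obs[perm, ]
  expect_equal(tmap(st)$p, tmap(st2)$p)
  expect_equal(wmap(st)$p, wmap(st2)$p)
})
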