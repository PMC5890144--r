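test_that("median split yields 16/15 at n = 31 with the documented directions", {
  set.seed(1)
  v <- rnorm(31)
  g <- median_split(v, "higher")
  expect_equal(sum(g == "high"), 16)
  expect_equal(sum(g == "low"), 15)
  expect_true(min(v[g == "high"]) > max(v[g == "low"]))
  # values 1..10, higher better: high = 6..10
  g10 <- median_split(1:10, "higher")
  expect_equal(which(g10 == "high"), 6:10)
  # lower-better direction (alpha): the smallest values land in "high"
  a <- runif(31)
  ga <- median_split(a, "lower")
  expect_lt(mean(a[ga == "high"]), mean(a[ga == "low"]))
  expect_error(median_split(rep(1, 10), "higher"), "tied")
})

test_that("summary t-tests reproduce Welch and pooled forms", {
  # identical groups: t = 0
  r0 <- group_ttest_summary(1, 1, 10, 1, 1, 10)
  expect_equal(r0$t, 0)
  # hand-checked Welch against t.test on raw data with matching summaries
  set.seed(2)
  x <- rnorm(16, 10, 2); y <- rnorm(15, 8, 3)
  ref <- t.test(x, y)
  rw <- group_ttest_summary(mean(x), sd(x), 16, mean(y), sd(y), 15)
  expect_equal(rw$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(rw$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(rw$p, ref$p.value, tolerance = 1e-10)
  refp <- t.test(x, y, var.equal = TRUE)
  rp <- group_ttest_summary(mean(x), sd(x), 16, mean(y), sd(y), 15,
                            variant = "pooled")
  expect_equal(rp$t, unname(refp$statistic), tolerance = 1e-10)
  expect_equal(rp$df, 29)
})

test_that("voxelwise GLM equals the two-sample t-test without covariates and has df = n - 7", {
  set.seed(4)
  n <- 31
  V <- 50
  Y <- matrix(rnorm(n * V), n, V)
  groups <- rep(c("high", "low"), c(16, 15))
  fit <- voxelwise_glm(Y, groups)
  ref <- apply(Y, 2, function(y)
    t.test(y[groups == "high"], y[groups == "low"],
           var.equal = TRUE)$statistic)
  expect_equal(unname(fit$tmap), unname(ref), tolerance = 1e-10)
  expect_equal(fit$df, n - 2)
  covs <- matrix(rnorm(n * 5), n, 5)
  fit7 <- voxelwise_glm(Y, groups, covariates = covs)
  expect_equal(fit7$df, 24)
  expect_equal(ncol(fit7$design), 7)
})

test_that("median-split groups differ on the split parameter but not on the others", {
  reps <- 30
  p_split <- numeric(reps)
  p_other <- numeric(reps)
  for (r in seq_len(reps)) {
    pop <- sample_population(population_spec(n_subjects = 31, seed = 500 + r))
    g <- median_split(pop$C, "higher", ids = pop$subject_id)
    p_split[r] <- t.test(pop$C[g == "high"], pop$C[g == "low"])$p.value
    p_other[r] <- t.test(pop$K[g == "high"], pop$K[g == "low"])$p.value
  }
  expect_true(all(p_split < 1e-4))
  # unrelated parameter rejected at roughly the nominal rate
  expect_lte(sum(p_other < 0.05), qbinom(0.999, reps, 0.05) + 2)
})

test_that("cluster labelling respects connectivity and cluster inference finds a planted blob", {
  a <- array(FALSE, c(6, 6, 3))
  a[1:2, 1:2, 1] <- TRUE          # one 4-voxel cluster
  a[5, 5, 3] <- TRUE              # isolated voxel
  lab <- label_clusters(a, 26)
  expect_equal(sort(attr(lab, "sizes")), c(1, 4))
  # diagonal touch: joined under 26, separate under 6
  b <- array(FALSE, c(4, 4, 2))
  b[1, 1, 1] <- TRUE
  b[2, 2, 2] <- TRUE
  expect_equal(length(attr(label_clusters(b, 26), "sizes")), 1)
  expect_equal(length(attr(label_clusters(b, 6), "sizes")), 2)
  # all-zero t-map: no clusters
  n <- 20
  Y0 <- matrix(0, n, prod(c(6, 6, 3)))
  Y0 <- Y0 + rnorm(length(Y0), sd = 1e-6)
  groups <- rep(c("high", "low"), 10)
  ci0 <- suppressWarnings(cluster_inference(Y0, groups, grid = c(6, 6, 3),
                                            n_perm = 120, seed = 1))
  # pure-noise map at this size: typically nothing survives
  expect_true(nrow(ci0$clusters) == 0 || !any(ci0$clusters$significant))
  # planted blob: exactly one surviving cluster containing the peak
  set.seed(7)
  grid <- c(8, 8, 4)
  V <- prod(grid)
  blob <- array(FALSE, grid)
  blob[3:5, 3:5, 2:3] <- TRUE
  Y <- matrix(rnorm(n * V), n, V)
  Y[groups == "high", as.vector(blob)] <-
    Y[groups == "high", as.vector(blob)] + 2.5
  ci <- cluster_inference(Y, groups, grid = grid, n_perm = 300, seed = 2)
  expect_true(any(ci$clusters$significant))
  top <- ci$clusters[1, ]
  expect_true(as.vector(blob)[top$peak_index])
})

test_that("Bonferroni across networks uses 0.05/6 = 0.0083", {
  b <- bonferroni_networks(c(0.001, 0.038, 0.008), n_networks = 6)
  expect_equal(b$threshold, 0.0083)
  expect_equal(unname(b$survives), c(TRUE, FALSE, TRUE))
})

test_that("inter-network group test is a one-tailed pooled t with df = n - 2", {
  groups <- rep(c("high", "low"), c(16, 15))
  set.seed(5)
  z <- rnorm(31, 0.2, 0.1)
  res <- internetwork_group_test(z, groups)
  expect_equal(res$df, 29)
  ref <- t.test(z[groups == "high"], z[groups == "low"], var.equal = TRUE,
                alternative = "greater")
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  # identical groups: t = 0, one-tailed p = 0.5 exactly
  res_eq <- internetwork_group_test(rep(c(1, 2, 3, 4), 2),
                                    rep(c("high", "low"), each = 4))
  expect_equal(res_eq$t, 0)
  expect_equal(res_eq$p, 0.5)
  expect_equal(res_eq$bonferroni_threshold, 0.01)
})

test_that("network scalars: mean and eigenvariate behave as documented", {
  grid <- c(5, 5, 2)
  mask <- array(FALSE, grid); mask[1:3, 1:3, 1] <- TRUE
  n <- 10
  Z <- matrix(rnorm(n * prod(grid)), n)
  Z[, as.vector(mask)] <- 4.2
  expect_equal(intra_network_scalar(Z, mask, "mean"), rep(4.2, n))
  # rank-1 structure: eigenvariate recovers subject scores up to scale
  set.seed(6)
  scores <- rnorm(n)
  pattern <- runif(sum(mask))
  Z2 <- matrix(rnorm(n * prod(grid), sd = 1e-8), n)
  Z2[, as.vector(mask)] <- outer(scores, pattern)
  ev <- intra_network_scalar(Z2, mask, "eigenvariate")
  expect_gt(abs(cor(ev, scores)), 0.9999)
  # sign convention: positively correlated with the mean scalar
  expect_gt(cor(ev, intra_network_scalar(Z2, mask, "mean")), 0)
  expect_error(intra_network_scalar(Z, array(FALSE, grid)), "empty")
})

test_that("partial correlation matches its closed-form oracle", {
  set.seed(9)
  n <- 1000
  # trivariate normal with known partial correlation
  ctrl <- rnorm(n)
  x <- 0.5 * ctrl + rnorm(n)
  y <- 0.5 * ctrl + rnorm(n)
  pc <- partial_correlation(x, y, ctrl)
  expect_lt(abs(pc$r), 3 / sqrt(n))   # partial r is 0 by construction
  # known nonzero partial correlation: x and y share an extra source
  s <- rnorm(n)
  x2 <- 0.5 * ctrl + sqrt(0.4) * s + sqrt(0.6) * rnorm(n)
  y2 <- 0.5 * ctrl + sqrt(0.4) * s + sqrt(0.6) * rnorm(n)
  pc2 <- partial_correlation(x2, y2, ctrl)
  expect_lt(abs(pc2$r - 0.4), 3 * (1 - 0.4^2) / sqrt(n))
  # control uncorrelated with both: partial ~ simple r
  u <- rnorm(n)
  pc3 <- partial_correlation(x2, y2, u)
  expect_equal(pc3$r, cor(x2, y2), tolerance = 0.02)
  # y equal to the control: partial r ~ 0
  pc4 <- partial_correlation(x2, ctrl + 1e-8 * rnorm(n), ctrl)
  expect_lt(abs(pc4$r), 0.1)
  expect_equal(pc$df, n - 3)
})

test_that("Welch df values recomputed from the published group summaries", {
  # processing-speed split: df ~ 18.8; capacity split: df rounds to 17
  rC <- group_ttest_summary(30.76, 7.05, 16, 20.70, 2.45, 15)
  expect_equal(rC$df, 18.8, tolerance = 0.1)
  rK <- group_ttest_summary(3.37, 0.41, 16, 2.66, 0.10, 15)
  expect_equal(round(rK$df), 17)
})
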