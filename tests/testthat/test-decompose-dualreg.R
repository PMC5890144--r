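test_that("group decomposition recovers planted orthogonal maps in a noise-free scene", {
  grid <- c(12, 12, 6)
  V <- prod(grid)
  G <- 3
  set.seed(4)
  # spatially disjoint (hence orthogonal) maps
  tpl <- matrix(0, V, G)
  blocks <- split(seq_len(V), cut(seq_len(V), G, labels = FALSE))
  for (g in seq_len(G)) {
    tpl[sample(blocks[[g]], 80), g] <- runif(80, 0.5, 1)
  }
  templates <- array(tpl, c(grid, G))
  imgs <- lapply(1:3, function(s) {
    tc <- matrix(rnorm(60 * G), 60, G)
    array(tpl %*% t(tc), c(grid, 60))   # voxels vary fastest
  })
  comp <- suppressWarnings(group_decompose(imgs, G = G, seed = 2))
  m <- match_templates(comp, templates)
  expect_true(all(abs(m$r) > 0.95))
  # determinism
  comp2 <- suppressWarnings(group_decompose(imgs, G = G, seed = 2))
  expect_identical(comp$maps, comp2$maps)
  # subject order changes nothing about the recovered subspace
  comp3 <- suppressWarnings(group_decompose(imgs[c(2, 3, 1)], G = G, seed = 2))
  m3 <- match_templates(comp3, templates)
  expect_true(all(abs(m3$r) > 0.95))
})

test_that("template matching returns perfect and near-zero correlations where expected", {
  tpl <- make_network_templates(grid = c(12, 12, 6), G = 3, seed = 6)
  m <- match_templates(tpl, tpl)
  expect_equal(m$component, m$template)
  expect_equal(m$r, rep(1, 3), tolerance = 1e-12)
  # independent random maps: small |r|
  set.seed(8)
  noise <- array(rnorm(prod(c(12, 12, 6, 3))), c(12, 12, 6, 3))
  m2 <- match_templates(noise, tpl)
  expect_true(all(abs(m2$r) < 0.15))
  expect_error(
    match_templates(tpl, make_network_templates(grid = c(10, 10, 5), G = 3,
                                                seed = 1)),
    "grid")
})

test_that("dual regression exactly recovers a one-component construction", {
  grid <- c(10, 10, 5)
  V <- prod(grid)
  Tn <- 40
  set.seed(5)
  map1 <- array(0, grid); map1[2:5, 2:5, 2:3] <- runif(32, 0.5, 1)
  map2 <- array(0, grid); map2[7:9, 6:9, 3:5] <- runif(36, 0.5, 1)
  maps <- array(c(map1, map2), c(grid, 2))
  tc_true <- matrix(rnorm(Tn * 2), Tn, 2)
  Y <- cbind(as.vector(map1), as.vector(map2)) %*% t(tc_true)
  img <- array(Y, c(grid, Tn))
  dr <- dual_regression(img, maps)
  expect_gt(cor(dr$timecourses[, 1], tc_true[, 1]), 0.9999)
  expect_gt(cor(dr$timecourses[, 2], tc_true[, 2]), 0.9999)
  # stage-2 support: Z-magnitudes inside the map dwarf those outside
  z1 <- abs(as.vector(dr$zmaps[, , , 1]))
  expect_gt(min(z1[as.vector(map1) > 0]), max(z1[as.vector(map1) == 0]))
  # adding a temporally orthogonal component leaves coefficients stable
  tc3 <- residuals(lm(rnorm(Tn) ~ tc_true))
  map3 <- array(0, grid); map3[1, 1, 1] <- 1
  Y3 <- Y + as.vector(map3) %*% t(tc3)
  maps3 <- array(c(map1, map2, map3), c(grid, 3))
  dr3 <- dual_regression(array(Y3, c(grid, Tn)), maps3)
  b_old <- as.vector(dr$betas[, , , 1])
  b_new <- as.vector(dr3$betas[, , , 1])
  expect_equal(b_new[as.vector(map1) > 0], b_old[as.vector(map1) > 0],
               tolerance = 1e-6)
  # collinear maps rejected
  bad <- array(c(map1, map1), c(grid, 2))
  expect_error(dual_regression(img, bad), "collinear")
})

test_that("dual-regression stage-2 coefficients are proportional to planted gains", {
  scene <- test_scene(G = 3, noise_sd = 0.05, drift_amplitude = 0,
                      motion_amplitude = 0, gain_sd = 0.4)
  n <- 12
  subj <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     group = rep(c("high", "low"), n / 2))
  sim <- simulate_fmri(subj, scene, seed = 30)
  peak <- which.max(as.vector(scene$templates[, , , 2]))
  b <- vapply(subj$subject_id, function(s) {
    dr <- dual_regression(sim$images[[s]], scene$templates)
    as.vector(dr$betas[, , , 2])[peak]
  }, 0)
  g <- sim$truth$gains[, 2]
  expect_gt(summary(lm(b ~ g))$r.squared, 0.99)
})

test_that("inter-network FC matrix is symmetric Fisher z with capped boundaries", {
  set.seed(3)
  tcs <- matrix(rnorm(250 * 3), 250, 3)
  z <- internetwork_fc(tcs)
  expect_true(is.na(z[1, 1]))
  expect_equal(z[1, 2], z[2, 1])
  expect_equal(z[1, 2], atanh(cor(tcs[, 1], tcs[, 2])))
  # independent white noise: z within 3/sqrt(t-3) of zero
  expect_lt(abs(z[1, 3]), 3 / sqrt(250 - 3))
  # odd symmetry
  tcs2 <- cbind(tcs[, 1], -tcs[, 1] + rnorm(250, sd = 0.5))
  z2 <- internetwork_fc(tcs2)
  tcs3 <- cbind(tcs2[, 1], -tcs2[, 2])
  z3 <- internetwork_fc(tcs3)
  expect_equal(z3[1, 2], -z2[1, 2], tolerance = 1e-12)
  # identical pair: capped at atanh(1 - 1e-15), flagged
  dup <- cbind(tcs[, 1], tcs[, 1])
  zd <- internetwork_fc(dup)
  expect_equal(zd[1, 2], atanh(1 - 1e-15))
  expect_true(attr(zd, "capped")[1, 2])
  expect_error(internetwork_fc(cbind(tcs[, 1], rep(1, 250))), "constant")
})
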