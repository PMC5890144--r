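test_that("effective exposure subtracts t0, adds mu when unmasked, clamps at zero", {
  expect_equal(effective_exposure(80, 20, masked = TRUE), 0.060)
  expect_equal(effective_exposure(80, 20, mu = 150, masked = FALSE), 0.210)
  expect_equal(effective_exposure(10, 20, masked = TRUE), 0)
  expect_error(effective_exposure(-5, 0), "nonnegative")
})

test_that("whole-report score distribution matches the censored-binomial closed form", {
  # equal weights, n = 4, C = 20/s, tau = 0.1 s, capacity fixed at 2
  p <- tva_params(C = 20, K_mean = 2)
  cond <- display_condition(rep("left", 4), rep("target", 4),
                            exposure_ms = 100, masked = TRUE)
  pmf <- report_distribution(cond, p, capacity = 2)
  penc <- 1 - exp(-0.5)
  expect_equal(unname(pmf[1]), dbinom(0, 4, penc), tolerance = 1e-12)
  expect_equal(unname(pmf[2]), dbinom(1, 4, penc), tolerance = 1e-12)
  expect_equal(unname(pmf[3]), 1 - dbinom(0, 4, penc) - dbinom(1, 4, penc),
               tolerance = 1e-12)
  expect_equal(round(unname(pmf[1:3]), 4), c(0.1353, 0.3512, 0.5135))
})

test_that("score distribution asymptotes at capacity and vanishes at tau = 0", {
  p <- tva_params(C = 30, K_mean = 3)
  long <- display_condition(rep("left", 6), rep("target", 6),
                            exposure_ms = 1e6, masked = TRUE)
  expect_equal(unname(report_distribution(long, p, capacity = 3)[4]), 1,
               tolerance = 1e-9)
  zero <- display_condition(rep("left", 6), rep("target", 6),
                            exposure_ms = 0, masked = TRUE)
  expect_equal(unname(report_distribution(zero, p)[1]), 1)
})

test_that("every score distribution sums to one and E[score] is monotone in tau, C, K", {
  set.seed(42)
  for (rep_i in 1:20) {
    p <- tva_params(C = runif(1, 5, 60), K_mean = runif(1, 1, 5),
                    t0 = runif(1, 0, 30), mu = runif(1, 0, 300),
                    w_target_left = runif(1, 0.3, 2))
    cond <- display_condition(rep(sample(c("left", "right"), 1), 6),
                              rep("target", 6),
                              exposure_ms = runif(1, 10, 300),
                              masked = sample(c(TRUE, FALSE), 1))
    pmf <- report_distribution(cond, p)
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
    expect_true(all(pmf >= 0))
  }
  base <- tva_params(C = 25, K_mean = 3.2, t0 = 10)
  es <- function(t, prm) expected_score(
    display_condition(rep("left", 6), rep("target", 6), t, TRUE), prm)
  taus <- seq(20, 300, by = 40)
  expect_true(all(diff(sapply(taus, es, prm = base)) > 0))
  Cs <- seq(10, 60, by = 10)
  expect_true(all(diff(sapply(Cs, function(C) es(
    100, tva_params(C = C, K_mean = 3.2, t0 = 10)))) > 0))
  Ks <- seq(1, 5, by = 0.5)
  expect_true(all(diff(sapply(Ks, function(K) es(
    100, tva_params(C = 25, K_mean = K, t0 = 10)))) >= 0))
})

test_that("the slope of E[score] at tau = 0+ equals the total rate C", {
  p <- tva_params(C = 37, K_mean = 4)
  h_ms <- 1e-3   # 1e-6 s
  cond <- function(t) display_condition(rep("left", 6), rep("target", 6),
                                        t, masked = TRUE)
  slope <- (expected_score(cond(2 * h_ms), p) -
              expected_score(cond(h_ms), p)) / (h_ms / 1000)
  expect_equal(slope, 37, tolerance = 1e-2)
})

test_that("weights are scale invariant", {
  p1 <- tva_params(C = 28, K_mean = 3.2, t0 = 12, mu = 140,
                   w_target_left = 1.3, w_target_right = 1,
                   w_distractor_left = 0.7, w_distractor_right = 0.5)
  p2 <- tva_params(C = 28, K_mean = 3.2, t0 = 12, mu = 140,
                   w_target_left = 1.3 * 7.3, w_target_right = 7.3,
                   w_distractor_left = 0.7 * 7.3, w_distractor_right = 0.5 * 7.3)
  cond <- display_condition(c("left", "right"), c("target", "distractor"),
                            90, TRUE)
  expect_equal(partial_report_prob(cond, p1), partial_report_prob(cond, p2),
               tolerance = 1e-12)
  wcond <- display_condition(rep("right", 6), rep("target", 6), 80, FALSE)
  expect_equal(report_distribution(wcond, p1), report_distribution(wcond, p2),
               tolerance = 1e-12)
  expect_equal(p1$alpha, p2$alpha, tolerance = 1e-12)
  expect_equal(p1$w_lat, p2$w_lat, tolerance = 1e-12)
})

test_that("partial-report closed forms match the known special cases", {
  C <- 24; tau_ms <- 100
  # single target, capacity >= 1: whole rate goes to the sole item
  p <- tva_params(C = C, K_mean = 2)
  single <- display_condition("left", "target", tau_ms, TRUE)
  expect_equal(partial_report_prob(single, p), 1 - exp(-C * tau_ms / 1000),
               tolerance = 1e-12)
  # target + distractor, equal weights, capacity 1: competing exponentials
  pe <- tva_params(C = C, K_mean = 1, w_target_left = 1,
                   w_distractor_right = 1)
  td <- display_condition(c("left", "right"), c("target", "distractor"),
                          tau_ms, TRUE)
  expect_equal(partial_report_prob(td, pe, capacity = 1),
               0.5 * (1 - exp(-C * tau_ms / 1000)), tolerance = 1e-12)
  # zero distractor weight: perfect selectivity, same as single target
  ps <- tva_params(C = C, K_mean = 2, w_target_left = 1,
                   w_distractor_right = 0)
  expect_equal(partial_report_prob(td, ps), 1 - exp(-C * tau_ms / 1000),
               tolerance = 1e-12)
  expect_equal(ps$alpha, 0)
})

test_that("exact probabilities agree with the Monte-Carlo race oracle", {
  p <- test_params()
  cap <- capacity_pmf(p$K_mean, 3L)
  n_mc <- 200000
  conds <- list(
    display_condition(c("left", "right"), c("target", "target"), 90, TRUE),
    display_condition(c("left", "right", "left"),
                      c("target", "target", "distractor"), 70, TRUE),
    display_condition(c("right", "right"), c("target", "distractor"), 120, TRUE))
  for (ci in seq_along(conds)) {
    cond <- conds[[ci]]
    rates <- tvanet:::display_rates(cond, p)
    tau <- tvanet:::display_tau(cond, p)
    targets <- which(cond$role == "target")
    exact <- partial_report_prob(cond, p)
    mc <- mc_partial_prob(rates, tau, targets, cap$k, cap$p, n_mc, seed = ci)
    se <- sqrt(exact * (1 - exact) / n_mc)
    expect_true(all(abs(exact - mc) < 3.5 * se))
  }
  # whole report, 6 items
  wcond <- display_condition(rep("left", 6), rep("target", 6), 85, FALSE)
  rates <- tvanet:::display_rates(wcond, p)
  tau <- tvanet:::display_tau(wcond, p)
  cap6 <- capacity_pmf(p$K_mean, 6L)
  exact <- report_distribution(wcond, p)
  mc <- mc_whole_pmf(rates, tau, cap6$k, cap6$p, n_mc, seed = 99)
  se <- sqrt(pmax(exact * (1 - exact), 1e-12) / n_mc)
  expect_true(all(abs(exact - mc) < 3.5 * se + 1e-9))
})

test_that("alpha and w_lat derivations and guards", {
  expect_equal(alpha_from_weights(1, 1), 1)
  expect_equal(alpha_from_weights(1, 0), 0)
  expect_equal(alpha_from_weights(2, 1), 0.5)
  expect_error(alpha_from_weights(0, 1), "positive")
  expect_equal(w_lat_from_weights(1, 1), 0.5)
  expect_equal(w_lat_from_weights(3, 2), 0.6)
  expect_equal(w_lat_from_weights(0, 1), 0)
  expect_error(w_lat_from_weights(0, 0), "zero")
})

test_that("capacity mixture has the requested mean", {
  for (K in c(1, 2.5, 3.03, 4.999)) {
    cp <- capacity_pmf(K, 8L)
    expect_equal(sum(cp$p), 1, tolerance = 1e-12)
    expect_equal(sum(cp$k * cp$p), K, tolerance = 1e-9)
  }
  # capacities above the display size collapse onto n_items
  cp <- capacity_pmf(5.5, 3L)
  expect_true(all(cp$k <= 3))
})

test_that("displays beyond the enumeration limit are rejected", {
  p <- tva_params(C = 20, K_mean = 3)
  big <- display_condition(rep("left", 9), rep("target", 9), 100, TRUE)
  expect_error(report_distribution(big, p), "Monte Carlo")
})
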