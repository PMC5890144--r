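test_that("log-likelihood is additive and matches single-outcome probabilities", {
  p <- test_params()
  pop <- data.frame(subject_id = "s1", C = p$C, K = p$K_mean, t0 = p$t0,
                    mu = p$mu, w_target_left = p$w_target_left,
                    w_target_right = p$w_target_right,
                    w_distractor_left = p$w_distractor_left,
                    w_distractor_right = p$w_distractor_right)
  trials <- simulate_behavior(pop, seed = 3, tasks = "whole")
  ll1 <- tva_loglik(trials, p)
  doubled <- rbind(trials, trials)
  expect_equal(as.numeric(tva_loglik(doubled, p)), 2 * as.numeric(ll1),
               tolerance = 1e-10)
  # a single trial with known outcome probability
  one <- trials[1, ]
  cond <- display_condition(rep(one$hemifield, one$n_targets),
                            rep("target", one$n_targets),
                            one$exposure_ms, one$masked)
  expect_equal(as.numeric(tva_loglik(one, p)),
               log(report_distribution(cond, p)[[as.character(one$score)]]),
               tolerance = 1e-10)
})

test_that("fast likelihood paths equal the general model functions", {
  p <- test_params()
  for (masked in c(TRUE, FALSE)) {
    cond <- display_condition(rep("right", 6), rep("target", 6), 95, masked)
    expect_equal(unname(report_distribution(cond, p)),
                 tvanet:::whole_pmf_fast(6, p$C, p$K_mean, p$t0, p$mu, 95,
                                         masked),
                 tolerance = 1e-12)
  }
  # partial fast path (via nll) against the API probabilities
  pop <- data.frame(subject_id = "s1", C = p$C, K = p$K_mean, t0 = p$t0,
                    mu = p$mu, w_target_left = p$w_target_left,
                    w_target_right = p$w_target_right,
                    w_distractor_left = p$w_distractor_left,
                    w_distractor_right = p$w_distractor_right)
  trials <- simulate_behavior(pop, seed = 5)
  ps <- tvanet:::partial_report_stats(trials)
  plan <- tvanet:::partial_fit_plan(ps)
  theta <- c(p$C, p$t0, p$w_target_left, p$w_distractor_left,
             p$w_distractor_right)
  nll_fast <- tvanet:::nll_partial(theta, plan, p$K_mean)
  # recompute with the general API route
  nll_api <- 0
  for (i in seq_len(nrow(ps$design))) {
    st <- ps$stats[[i]]
    pr <- partial_report_prob(
      tvanet:::condition_display(ps$design[i, ], "partial"),
      tva_params(C = p$C, K_mean = p$K_mean, t0 = p$t0, mu = 0,
                 w_target_left = p$w_target_left, w_target_right = 1,
                 w_distractor_left = p$w_distractor_left,
                 w_distractor_right = p$w_distractor_right))
    nll_api <- nll_api - sum(st$reported * log(pr) +
                               (st$n - st$reported) * log(1 - pr))
  }
  expect_equal(nll_fast, nll_api, tolerance = 1e-9)
})

test_that("fit recovers no-selectivity and balanced-laterality cases", {
  # all weights equal: alpha = 1, w_lat = 0.5; averaged over replicate
  # data sets because a single 288-trial session estimates alpha with
  # appreciable sampling noise
  pop <- data.frame(subject_id = "flat", C = 26, K = 3, t0 = 10, mu = 150,
                    w_target_left = 1, w_target_right = 1,
                    w_distractor_left = 1, w_distractor_right = 1)
  ests <- sapply(1:4, function(sd) {
    trials <- simulate_behavior(pop, seed = sd)
    fit <- suppressWarnings(fit_tva(trials, seed = 2))
    c(alpha = fit$params$alpha, w_lat = fit$params$w_lat)
  })
  expect_equal(mean(ests["alpha", ]), 1, tolerance = 0.2)
  expect_equal(mean(ests["w_lat", ]), 0.5, tolerance = 0.05)
})

test_that("fit returns diagnostics and a best start index", {
  pop <- sample_population(population_spec(n_subjects = 1, seed = 8))
  trials <- simulate_behavior(pop, seed = 8)
  fit <- suppressWarnings(fit_tva(trials, seed = 1))
  expect_true(is.finite(fit$loglik_whole))
  expect_true(is.finite(fit$loglik_partial))
  expect_true(fit$start_index_whole %in% 1:10)
  expect_s3_class(fit$params, "tva_params")
  expect_true(fit$params$C > 1 && fit$params$C < 100)
})

test_that("calibrated exposures are fixed points of their criteria", {
  p <- test_params()
  expo <- calibrate_exposures(p, "whole")
  cond <- display_condition(rep("left", 6), rep("target", 6),
                            expo["middle"], masked = TRUE)
  expect_equal(expected_score(cond, p), 1, tolerance = 1e-3)
  expect_equal(unname(expo["short"] / expo["middle"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(expo["long"] / expo["middle"]), 2, tolerance = 1e-9)
  t_star <- calibrate_exposures(p, "partial")
  acc <- partial_report_prob(
    display_condition("left", "target", t_star, TRUE), p)
  expect_equal(acc, 0.8, tolerance = 1e-3)
  # unreachable criterion: capacity below one letter
  weak <- tva_params(C = 20, K_mean = 0.8)
  expect_error(calibrate_exposures(weak, "whole"), "calibration failure")
})
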