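# Independent Monte-Carlo race oracle: simulates the fixed-capacity
# exponential race directly (exponential encoding times, finishers before
# tau, first-K retained), with no reliance on the package's probability
# calculations. Used to validate the exact enumeration routes.

# MC pmf of the whole-report score under a capacity mixture (vectorised).
mc_whole_pmf <- function(rates, tau, cap_k, cap_p, n_samples, seed) {
  set.seed(seed)
  n <- length(rates)
  ks <- if (length(cap_k) == 1) rep(cap_k, n_samples)
        else sample(cap_k, n_samples, replace = TRUE, prob = cap_p)
  times <- matrix(stats::rexp(n_samples * n, rate = rep(rates, each = n_samples)),
                  n_samples, n)
  n_fin <- rowSums(times <= tau)
  score <- pmin(n_fin, ks)
  tabulate(score + 1L, nbins = n + 1L) / n_samples
}

# MC per-target report probability under a capacity mixture (vectorised):
# a target is reported iff it finished within tau and its finishing rank
# (1 + number of items finishing earlier) does not exceed the capacity draw.
mc_partial_prob <- function(rates, tau, targets, cap_k, cap_p, n_samples, seed) {
  set.seed(seed)
  n <- length(rates)
  ks <- if (length(cap_k) == 1) rep(cap_k, n_samples)
        else sample(cap_k, n_samples, replace = TRUE, prob = cap_p)
  times <- matrix(stats::rexp(n_samples * n, rate = rep(rates, each = n_samples)),
                  n_samples, n)
  vapply(targets, function(j) {
    fin_j <- times[, j] <= tau
    rank_j <- rowSums(times < times[, j]) + 1L
    mean(fin_j & rank_j <= ks)
  }, 0)
}

# Small default test parameter set with unequal weights.
test_params <- function() {
  tva_params(C = 28, K_mean = 3.2, t0 = 12, mu = 140,
             w_target_left = 1.3, w_target_right = 1,
             w_distractor_left = 0.7, w_distractor_right = 0.5)
}

# Small fmri scene shared by imaging tests.
test_scene <- function(..., grid = c(14, 14, 7), n_volumes = 80, G = 3,
                       template_seed = 11) {
  fmri_scene(grid = grid, n_volumes = n_volumes, G = G,
             template_seed = template_seed, ...)
}

# Preprocess one simulated subject the way the study driver does.
preprocess_subject <- function(sim, sid, fwhm = 4) {
  img <- sim$images[[sid]]
  gs <- colMeans(matrix(img, ncol = dim(img)[4]))  # per-volume global mean
  conf <- cbind(as.matrix(sim$motion[[sid]]), global = gs)
  smooth_image(nuisance_regress(img, conf), fwhm, 2)
}
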