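#' Population specification for synthetic subjects
#'
#' Defaults reproduce the study conditions of the source sample: 31 healthy
#' young adults whose TVA parameters are (independently) distributed as
#' C 25.89 +/- 7.34 items/s, K 3.03 +/- 0.47 items, alpha 0.52 +/- 0.21,
#' w_lat 0.49 +/- 0.06, education 9-13 years (integer), balanced gender.
#' t0 and mu population distributions are not part of the published summary
#' table; the generator uses 10 +/- 5 ms and 150 +/- 50 ms.
#'
#' @param n_subjects number of subjects (default 31).
#' @param C,K,alpha,w_lat,t0,mu length-2 numeric vectors c(mean, sd).
#' @param bounds named list of truncation ranges per parameter.
#' @param seed integer seed.
#' @return object of class \code{population_spec}.
#' @export
population_spec <- function(n_subjects = 31L,
                            C = c(25.89, 7.34), K = c(3.03, 0.47),
                            alpha = c(0.52, 0.21), w_lat = c(0.49, 0.06),
                            t0 = c(10, 5), mu = c(150, 50),
                            bounds = list(), seed = 1L) {
  stopifnot(n_subjects >= 1, C[2] >= 0, K[2] >= 0, alpha[2] >= 0,
            w_lat[2] >= 0, t0[2] >= 0, mu[2] >= 0)
  b <- utils::modifyList(
    list(C = c(5, 80), K = c(1.2, 5.8), alpha = c(0.02, 1.4),
         w_lat = c(0.15, 0.85), t0 = c(0, 40), mu = c(20, 400)),
    bounds)
  structure(list(n_subjects = as.integer(n_subjects), C = C, K = K,
                 alpha = alpha, w_lat = w_lat, t0 = t0, mu = mu,
                 bounds = b, seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a synthetic subject population
#'
#' Draws per-subject TVA parameters independently (the parameters are
#' empirically uncorrelated) from truncated normals, reconstructs the four
#' attentional weights from the sampled alpha and w_lat (right target weight
#' pinned to 1; distractor weights share the target laterality so that both
#' the target-based and the all-weight-based laterality equal w_lat), and
#' attaches demographic covariates.
#'
#' @param spec a \code{population_spec}.
#' @return data.frame, one row per subject: subject_id, C, K, t0, mu, alpha,
#'   w_lat, the four weights, education (years), gender (0/1).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_subjects
  b <- spec$bounds
  with_seed(spec$seed, {
    draws <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      C = rtruncnorm(n, spec$C[1], spec$C[2], b$C[1], b$C[2]),
      K = rtruncnorm(n, spec$K[1], spec$K[2], b$K[1], b$K[2]),
      t0 = rtruncnorm(n, spec$t0[1], spec$t0[2], b$t0[1], b$t0[2]),
      mu = rtruncnorm(n, spec$mu[1], spec$mu[2], b$mu[1], b$mu[2]),
      alpha = rtruncnorm(n, spec$alpha[1], spec$alpha[2],
                         b$alpha[1], b$alpha[2]),
      w_lat = rtruncnorm(n, spec$w_lat[1], spec$w_lat[2],
                         b$w_lat[1], b$w_lat[2]),
      stringsAsFactors = FALSE)
    draws$education <- sample(9:13, n, replace = TRUE)
    draws$gender <- sample(rep(0:1, length.out = n))
    draws
  }) -> pop
  # weights: pin w_target_right = 1
  pop$w_target_right <- 1
  pop$w_target_left <- pop$w_lat / (1 - pop$w_lat)
  pop$w_distractor_left <- pop$alpha * pop$w_target_left
  pop$w_distractor_right <- pop$alpha * pop$w_target_right
  pop
}

# tva_params for one population row.
subject_params <- function(row) {
  tva_params(C = row$C, K_mean = row$K, t0 = row$t0, mu = row$mu,
             w_target_left = row$w_target_left,
             w_target_right = row$w_target_right,
             w_distractor_left = row$w_distractor_left,
             w_distractor_right = row$w_distractor_right)
}
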