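# Sufficient statistics: whole-report trials collapse to score counts per
# unique (exposure, masking) cell; partial-report trials collapse to
# per-condition, per-target report counts. The likelihood only touches these.
whole_report_stats <- function(trials) {
  w <- trials[trials$task == "whole", ]
  if (!nrow(w)) return(NULL)
  n_items <- max(w$n_targets)
  key <- paste(w$exposure_ms, w$masked)
  cells <- unique(data.frame(exposure_ms = w$exposure_ms, masked = w$masked,
                             key = key, stringsAsFactors = FALSE))
  counts <- lapply(cells$key, function(k) {
    tabulate(w$score[key == k] + 1L, nbins = n_items + 1L)
  })
  list(cells = cells, counts = counts, n_items = n_items)
}

partial_report_stats <- function(trials) {
  p <- trials[trials$task == "partial", ]
  if (!nrow(p)) return(NULL)
  design <- partial_report_design(exposure_ms = p$exposure_ms[1])
  design <- design[match(unique(p$layout_id), design$layout_id), ]
  if (anyNA(design$condition_id))
    stop("partial-report trials contain layout_id values not in the 16-condition design")
  design$exposure_ms <- p$exposure_ms[match(design$layout_id, p$layout_id)]
  stats <- lapply(seq_len(nrow(design)), function(i) {
    rows <- p[p$layout_id == design$layout_id[i], ]
    n_t <- rows$n_targets[1]
    r <- c(sum(rows$target1_reported),
           if (n_t == 2) sum(rows$target2_reported) else NA)
    list(n = nrow(rows), n_targets = n_t, reported = r[!is.na(r)])
  })
  list(design = design, stats = stats)
}

# Censored-binomial whole-report pmf: with a single hemifield per display all
# items share one weight, so the number encoded is Binomial(n, 1-exp(-C
# tau/n)), censored at the capacity draw and marginalised over the two-point
# capacity mixture. Fast path used inside the optimiser; agrees with
# report_distribution() exactly (asserted in the tests).
whole_pmf_fast <- function(n, C, K, t0, mu, t, masked) {
  tau <- max(0, t - t0 + if (masked) 0 else mu) / 1000
  pmf <- stats::dbinom(0:n, n, 1 - exp(-C * tau / n))
  lo <- min(floor(K), n); hi <- min(ceiling(K), n)
  censor <- function(k) {
    out <- pmf
    if (k < n) {
      out[k + 1] <- sum(pmf[(k + 1):(n + 1)])
      out[(k + 2):(n + 1)] <- 0
    }
    out
  }
  if (lo == hi) censor(lo)
  else (1 - (K - floor(K))) * censor(lo) + (K - floor(K)) * censor(hi)
}

# Negative log-likelihood of whole-report score counts under (C, K, t0, mu).
nll_whole <- function(theta, stats, eps = 1e-12) {
  nll <- 0
  for (i in seq_len(nrow(stats$cells))) {
    pmf <- whole_pmf_fast(stats$n_items, theta[1], theta[2], theta[3],
                          theta[4], stats$cells$exposure_ms[i],
                          stats$cells$masked[i])
    nll <- nll - sum(stats$counts[[i]] * log(pmax(pmf, eps)))
  }
  nll
}

# P(target with rate vj is encoded within tau and ranks among the first k
# finishers), closed forms for at most two competitors (the partial-report
# displays have at most 3 items). g(a) integrates the conditioning on T_j.
fast_rank_prob <- function(vj, u, tau, k) {
  if (tau <= 0 || k <= 0) return(0)
  m <- length(u)
  if (k > m) return(1 - exp(-vj * tau))
  g <- function(a) vj * (1 - exp(-(vj + a) * tau)) / (vj + a)
  if (k == 1) return(g(sum(u)))
  # k == 2, m == 2: P(rank <= 2) = g(u1) + g(u2) - g(u1 + u2)
  g(u[1]) + g(u[2]) - g(u[1] + u[2])
}

# Precompute per-condition structures for the fast partial-report nll:
# weight indices into c(wTL, wTR, wDL, wDR), target item positions, counts.
partial_fit_plan <- function(pstats) {
  widx_of <- function(hemi, role)
    ifelse(role == "target", ifelse(hemi == "left", 1L, 2L),
           ifelse(hemi == "left", 3L, 4L))
  lapply(seq_len(nrow(pstats$design)), function(i) {
    row <- pstats$design[i, ]
    hemi <- strsplit(row$hemifields, ",")[[1]]
    role <- strsplit(row$roles, ",")[[1]]
    st <- pstats$stats[[i]]
    list(widx = widx_of(hemi, role), tpos = which(role == "target"),
         exposure_ms = row$exposure_ms, n = st$n, reported = st$reported)
  })
}

# Negative log-likelihood of per-target report indicators under
# (C_p, t0_p, w_target_left, w_distractor_left, w_distractor_right) with the
# right target weight pinned to 1 and capacity fixed from the whole fit.
nll_partial <- function(theta, plan, K_mean, eps = 1e-12) {
  w <- c(theta[3], 1, theta[4], theta[5])
  lo <- floor(K_mean); p_hi <- K_mean - lo
  nll <- 0
  for (cn in plan) {
    wi <- w[cn$widx]
    rates <- theta[1] * wi / sum(wi)
    tau <- max(0, cn$exposure_ms - theta[2]) / 1000
    pr <- vapply(seq_along(cn$tpos), function(ti) {
      j <- cn$tpos[ti]
      p_lo_k <- fast_rank_prob(rates[j], rates[-j], tau, lo)
      if (p_hi > 0)
        (1 - p_hi) * p_lo_k + p_hi * fast_rank_prob(rates[j], rates[-j], tau, lo + 1)
      else p_lo_k
    }, 0)
    pr <- pmin(pmax(pr, eps), 1 - eps)
    nll <- nll - sum(cn$reported * log(pr) + (cn$n - cn$reported) * log(1 - pr))
  }
  nll
}

#' Log-likelihood of a trial table
#'
#' Sum over trials of the log probability of the observed outcome: the score
#' count for whole-report trials, the per-target report indicators for
#' partial-report trials. Zero-probability outcomes are floored at
#' \code{eps}; the number of floored terms is attached as attribute
#' \code{"n_floored"}.
#'
#' @param trials trial table (see \code{\link{validate_trial_table}}).
#' @param params a \code{tva_params} object used for both tasks.
#' @param partial_params optional separate \code{tva_params} for
#'   partial-report trials (the fit estimates a task-specific sensory rate
#'   and t0 for partial report).
#' @param eps probability floor, default 1e-12.
#' @return scalar log-likelihood.
#' @export
tva_loglik <- function(trials, params, partial_params = NULL, eps = 1e-12) {
  validate_trial_table(trials, check_quotas = FALSE)
  if (is.null(partial_params)) partial_params <- params
  ll <- 0
  n_floored <- 0L
  ws <- whole_report_stats(trials)
  if (!is.null(ws)) {
    for (i in seq_len(nrow(ws$cells))) {
      cond <- display_condition(
        hemifield = rep("left", ws$n_items),
        role = rep("target", ws$n_items),
        exposure_ms = ws$cells$exposure_ms[i],
        masked = ws$cells$masked[i])
      pmf <- report_distribution(cond, params)
      n_floored <- n_floored + sum(ws$counts[[i]] > 0 & pmf < eps)
      ll <- ll + sum(ws$counts[[i]] * log(pmax(pmf, eps)))
    }
  }
  ps <- partial_report_stats(trials)
  if (!is.null(ps)) {
    for (i in seq_len(nrow(ps$design))) {
      st <- ps$stats[[i]]
      pr <- partial_report_prob(condition_display(ps$design[i, ], "partial"),
                                partial_params)
      n_floored <- n_floored + sum(pr < eps & st$reported > 0) +
        sum(1 - pr < eps & st$n - st$reported > 0)
      pr <- pmin(pmax(pr, eps), 1 - eps)
      ll <- ll + sum(st$reported * log(pr) + (st$n - st$reported) * log(1 - pr))
    }
  }
  if (n_floored > 0)
    warning(n_floored, " outcome term(s) floored at eps")
  attr(ll, "n_floored") <- n_floored
  ll
}

# Deterministic integer seed from a subject identifier.
subject_seed <- function(subject_id, base_seed = 0L) {
  h <- sum(utf8ToInt(as.character(subject_id)) * seq_along(utf8ToInt(as.character(subject_id))))
  (as.integer(base_seed) + as.integer(h %% 1000003L)) %% .Machine$integer.max
}

# Latin-hypercube multistart bounded minimisation.
multistart_optim <- function(nll, lower, upper, n_starts, seed, parscale) {
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, length(lower))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(parscale = parscale, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$start_index <- s
    }
  }
  if (is.null(best)) stop("all optimisation starts failed")
  best
}

#' Fit the TVA model to one subject's report data
#'
#' Maximum-likelihood estimation in two stages mirroring the two tasks:
#' whole report yields the capacity parameters (C, K, t0, mu); partial
#' report, with capacity fixed from the whole-report fit and its own sensory
#' rate and minimum effective exposure, yields the attentional weights and
#' hence alpha and w_lat. Each stage uses bounded quasi-Newton (L-BFGS-B)
#' from a deterministic Latin-hypercube of starting points seeded by the
#' subject id.
#'
#' @param trials trial table for one subject containing whole- and/or
#'   partial-report rows.
#' @param n_starts multistart count per stage (default 10 for whole report,
#'   6 for partial report -- the partial likelihood surface is smoother).
#' @param seed base seed combined with the subject id.
#' @param bounds optional named list overriding the default box bounds
#'   (C [1,100] items/s, K [0.5,6], t0 [0,60] ms, mu [0,500] ms,
#'   weights [1e-3, 30] relative to the pinned right-target weight).
#' @return list with \code{params} (a \code{tva_params}),
#'   \code{partial_params}, \code{loglik_whole}, \code{loglik_partial},
#'   \code{converged}, \code{start_index} per stage.
#' @export
fit_tva <- function(trials, n_starts = 10L, seed = 0L, bounds = list()) {
  validate_trial_table(trials, check_quotas = FALSE)
  sid <- unique(trials$subject_id)
  if (length(sid) != 1) stop("fit_tva expects a single subject's trials")
  b <- utils::modifyList(list(C = c(1, 100), K = c(0.5, 6), t0 = c(0, 60),
                              mu = c(0, 500), w = c(1e-3, 30)), bounds)
  ws <- whole_report_stats(trials)
  if (is.null(ws)) stop("whole-report trials are required")
  fw <- multistart_optim(
    function(th) nll_whole(th, ws),
    lower = c(b$C[1], b$K[1], b$t0[1], b$mu[1]),
    upper = c(b$C[2], b$K[2], b$t0[2], b$mu[2]),
    n_starts = n_starts, seed = subject_seed(sid, seed),
    parscale = c(10, 1, 10, 50))
  out <- list(
    loglik_whole = -fw$value,
    converged_whole = fw$convergence == 0,
    start_index_whole = fw$start_index)
  ps <- partial_report_stats(trials)
  if (!is.null(ps)) {
    plan <- partial_fit_plan(ps)
    fp <- multistart_optim(
      function(th) nll_partial(th, plan, K_mean = fw$par[2]),
      lower = c(b$C[1], b$t0[1], rep(b$w[1], 3)),
      upper = c(b$C[2], b$t0[2], rep(b$w[2], 3)),
      n_starts = max(6L, ceiling(n_starts * 0.6)),
      seed = subject_seed(sid, seed) + 1L,
      parscale = c(10, 10, 1, 1, 1))
    out$params <- tva_params(
      C = fw$par[1], K_mean = fw$par[2], t0 = fw$par[3], mu = fw$par[4],
      w_target_left = fp$par[3], w_target_right = 1,
      w_distractor_left = fp$par[4], w_distractor_right = fp$par[5])
    out$partial_params <- tva_params(
      C = fp$par[1], K_mean = fw$par[2], t0 = fp$par[2], mu = 0,
      w_target_left = fp$par[3], w_target_right = 1,
      w_distractor_left = fp$par[4], w_distractor_right = fp$par[5])
    out$loglik_partial <- -fp$value
    out$converged_partial <- fp$convergence == 0
    out$start_index_partial <- fp$start_index
  } else {
    out$params <- tva_params(C = fw$par[1], K_mean = fw$par[2],
                             t0 = fw$par[3], mu = fw$par[4])
  }
  out$converged <- out$converged_whole &&
    (is.null(ps) || out$converged_partial)
  if (!out$converged)
    warning("optimiser did not report convergence; best solution returned")
  out
}
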