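# Truncated-normal draws by inverse-CDF: exact, vectorised, no rejection.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal: mean outside truncation region")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12)
    stop("infeasible truncation region: mass below 1e-12")
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Nearest symmetric positive-definite check.
is_pos_def <- function(S, tol = 1e-10) {
  if (!isSymmetric(unname(S), tol = 1e-8)) return(FALSE)
  min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > tol
}

# with_seed: evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
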