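#' Effective exposure duration
#'
#' Converts a nominal exposure duration to the effective processing time of
#' the race model. Below the minimum effective exposure \code{t0} nothing is
#' encoded; unmasked displays gain an additional \code{mu} ms because iconic
#' memory prolongs processing after stimulus offset.
#'
#' @param t nominal exposure duration, ms, >= 0.
#' @param t0 minimum effective exposure duration, ms, >= 0.
#' @param mu additional effective exposure for unmasked displays, ms, >= 0.
#' @param masked logical; was the display followed by pattern masks?
#' @return effective exposure tau in seconds (vectorised over \code{t} and
#'   \code{masked}).
#' @export
effective_exposure <- function(t, t0, mu = 0, masked = TRUE) {
  if (any(t < 0) || any(t0 < 0) || any(mu < 0))
    stop("t, t0 and mu must be nonnegative")
  pmax(0, t - t0 + ifelse(masked, 0, mu)) / 1000
}

#' Display condition
#'
#' A single display layout of the report tasks: item positions with
#' hemifield and role, a nominal exposure duration and a masking flag.
#'
#' @param hemifield character vector over items, "left"/"right".
#' @param role character vector over items, "target"/"distractor".
#' @param exposure_ms nominal exposure, ms.
#' @param masked logical.
#' @param position optional integer positions (unique); default seq_along.
#' @return object of class \code{display_condition}.
#' @export
display_condition <- function(hemifield, role, exposure_ms, masked,
                              position = seq_along(hemifield)) {
  stopifnot(length(hemifield) == length(role),
            length(position) == length(role),
            all(hemifield %in% c("left", "right")),
            all(role %in% c("target", "distractor")),
            exposure_ms >= 0, is.logical(masked))
  if (!any(role == "target")) stop("display must contain at least one target")
  if (anyDuplicated(position)) stop("positions must be unique")
  structure(list(hemifield = hemifield, role = role,
                 position = position,
                 exposure_ms = exposure_ms, masked = masked),
            class = "display_condition")
}

# Per-item attentional weights of a display under a parameter set.
display_weights <- function(cond, params) {
  w <- numeric(length(cond$role))
  for (i in seq_along(w)) {
    w[i] <- if (cond$role[i] == "target") {
      if (cond$hemifield[i] == "left") params$w_target_left else params$w_target_right
    } else {
      if (cond$hemifield[i] == "left") params$w_distractor_left else params$w_distractor_right
    }
  }
  w
}

# Per-item race rates v_i = C w_i / sum(w): the total rate C is divided among
# the items of the display in proportion to their attentional weights.
display_rates <- function(cond, params) {
  w <- display_weights(cond, params)
  if (sum(w) <= 0) stop("total attentional weight of display is zero")
  params$C * w / sum(w)
}

# tau (seconds) for a display under a parameter set.
display_tau <- function(cond, params) {
  effective_exposure(cond$exposure_ms, params$t0, params$mu, cond$masked)
}

#' Whole-report score distribution
#'
#' Exact distribution of the number of correctly reported items for a
#' whole-report display. Each item's encoding time is exponential with rate
#' \code{v_i = C w_i / sum(w)}; an item is encoded if its time is at most
#' tau, and at most K items are retained in short-term memory. The score is
#' \code{min(number encoded, K)}, so its distribution is the Poisson-binomial
#' distribution of the encoding indicators, censored at K and marginalised
#' over the capacity mixture. (Finishing order determines *which* items are
#' retained, not how many, so no order enumeration is required for the
#' score.)
#'
#' @param cond a \code{display_condition} with all-target items.
#' @param params a \code{tva_params} object.
#' @param capacity optional fixed integer capacity overriding the two-point
#'   mixture implied by \code{params$K_mean} (used by oracles and
#'   calibration).
#' @return numeric vector \code{p} with \code{names 0:n}; \code{sum(p) == 1}.
#' @export
report_distribution <- function(cond, params, capacity = NULL) {
  n <- length(cond$role)
  if (n > 8) stop("n_items > 8: exact enumeration regime exceeded, use a Monte Carlo oracle")
  v <- display_rates(cond, params)
  tau <- display_tau(cond, params)
  p_enc <- 1 - exp(-v * tau)
  # Poisson-binomial pmf of the number encoded, by sequential convolution
  pmf <- c(1, numeric(n))
  for (i in seq_len(n)) {
    pmf <- c(pmf[seq_len(n)] * (1 - p_enc[i]), 0) +
      c(0, pmf[seq_len(n)] * p_enc[i])
    length(pmf) <- n + 1
  }
  cap <- if (is.null(capacity)) capacity_pmf(params$K_mean, n)
         else data.frame(k = min(capacity, n), p = 1)
  out <- numeric(n + 1)
  for (j in seq_len(nrow(cap))) {
    k <- cap$k[j]
    censored <- pmf
    if (k < n) {
      censored[k + 1] <- sum(pmf[(k + 1):(n + 1)])
      censored[(k + 2):(n + 1)] <- 0
    }
    out <- out + cap$p[j] * censored
  }
  names(out) <- 0:n
  out
}

#' Expected whole-report score
#'
#' @inheritParams report_distribution
#' @return expected number of correctly reported items.
#' @export
expected_score <- function(cond, params, capacity = NULL) {
  p <- report_distribution(cond, params, capacity)
  sum(p * (seq_along(p) - 1))
}

# P(item j is encoded before tau AND at most k-1 of the other items finish
# before it), i.e. j lands among the first k finishers. Exact
# inclusion-exclusion over subsets of the other items: conditioning on
# T_j = t, the others are independent, and every term integrates to a
# hypoexponential expression v_j (1 - exp(-R tau)) / R.
race_rank_prob <- function(j, rates, tau, k) {
  n <- length(rates)
  vj <- rates[j]
  if (vj <= 0) return(0)
  if (tau <= 0) return(0)
  others <- rates[-j]
  m <- length(others)
  if (k >= n || m == 0) return(1 - exp(-vj * tau))
  if (k <= 0) return(0)
  total <- 0
  # S = set of others finishing before T_j; need |S| <= k - 1
  for (mask in 0:(2^m - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(S) > k - 1) next
    comp <- setdiff(seq_len(m), S)
    base <- sum(others[comp])   # others that must finish after T_j
    # expand prod_{i in S} (1 - e^{-u_i t}) by inclusion-exclusion
    s <- length(S)
    for (amask in 0:(2^s - 1)) {
      A <- S[which(bitwAnd(amask, 2^(seq_len(s) - 1)) > 0)]
      sgn <- (-1)^length(A)
      R <- vj + base + sum(others[A])
      total <- total + sgn * vj * (1 - exp(-R * tau)) / R
    }
  }
  total
}

#' Partial-report target report probabilities
#'
#' Probability that each target of a partial-report display is reported:
#' the target's encoding time must not exceed tau and the target must be
#' among the first K finishers of the race (distractors consume capacity but
#' their report is never scored). Computed exactly by inclusion-exclusion
#' over the subsets of competing items, marginalised over the capacity
#' mixture.
#'
#' @param cond a \code{display_condition} with 1-2 targets and 0-1
#'   distractors.
#' @param params a \code{tva_params} object.
#' @param capacity optional fixed integer capacity (see
#'   \code{\link{report_distribution}}).
#' @return numeric vector of report probabilities, one per target, in display
#'   order.
#' @export
partial_report_prob <- function(cond, params, capacity = NULL) {
  rates <- display_rates(cond, params)
  tau <- display_tau(cond, params)
  n <- length(rates)
  targets <- which(cond$role == "target")
  cap <- if (is.null(capacity)) capacity_pmf(params$K_mean, n)
         else data.frame(k = min(capacity, n), p = 1)
  sapply(targets, function(j) {
    sum(cap$p * sapply(cap$k, function(k) race_rank_prob(j, rates, tau, k)))
  })
}
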