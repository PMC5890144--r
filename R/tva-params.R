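#' TVA parameter set
#'
#' Container for the parameters of the fixed-capacity exponential race model
#' of visual attention (TVA): the capacity parameters estimated from whole
#' report (processing speed \code{C}, short-term memory capacity
#' \code{K_mean}, minimum effective exposure \code{t0}, iconic-memory
#' prolongation \code{mu}) and the weighting parameters estimated from
#' partial report (attentional weights per role and hemifield, from which
#' top-down control \code{alpha} and spatial laterality \code{w_lat} are
#' derived).
#'
#' Attentional weights are scale invariant: multiplying all four weights by a
#' positive constant changes no model prediction. \code{alpha} is the
#' distractor-to-target weight ratio (lower = more efficient selection);
#' \code{w_lat} is the left-hemifield share of the attentional weight
#' (0.5 = balanced).
#'
#' @param C processing rate, items/second, > 0.
#' @param K_mean mean visual short-term memory capacity, items, > 0. Realised
#'   internally as a two-point mixture on \code{floor(K)} and
#'   \code{ceiling(K)} with mean \code{K_mean}.
#' @param t0 minimum effective exposure duration, ms, >= 0.
#' @param mu additional effective exposure for unmasked displays, ms, >= 0.
#' @param w_target_left,w_target_right,w_distractor_left,w_distractor_right
#'   nonnegative attentional weights.
#' @return An object of class \code{tva_params}: a list with the weights and
#'   the derived \code{alpha} and \code{w_lat} (target-weight based).
#' @export
tva_params <- function(C, K_mean, t0 = 0, mu = 0,
                       w_target_left = 1, w_target_right = 1,
                       w_distractor_left = 0, w_distractor_right = 0) {
  stopifnot(is.numeric(C), C > 0, is.numeric(K_mean), K_mean > 0,
            t0 >= 0, mu >= 0,
            w_target_left >= 0, w_target_right >= 0,
            w_distractor_left >= 0, w_distractor_right >= 0)
  if (w_target_left + w_target_right <= 0)
    stop("target weights must not both be zero")
  p <- list(C = C, K_mean = K_mean, t0 = t0, mu = mu,
            w_target_left = w_target_left,
            w_target_right = w_target_right,
            w_distractor_left = w_distractor_left,
            w_distractor_right = w_distractor_right)
  p$alpha <- alpha_from_weights(c(w_target_left, w_target_right),
                                c(w_distractor_left, w_distractor_right))
  p$w_lat <- w_lat_from_weights(w_target_left, w_target_right)
  class(p) <- "tva_params"
  p
}

#' @export
print.tva_params <- function(x, ...) {
  cat("TVA parameters\n")
  cat(sprintf("  C      %8.2f items/s\n", x$C))
  cat(sprintf("  K      %8.2f items\n", x$K_mean))
  cat(sprintf("  t0     %8.1f ms\n", x$t0))
  cat(sprintf("  mu     %8.1f ms\n", x$mu))
  cat(sprintf("  alpha  %8.3f\n", x$alpha))
  cat(sprintf("  w_lat  %8.3f\n", x$w_lat))
  invisible(x)
}

#' Top-down control from attentional weights
#'
#' \code{alpha = sum(w_distractors) / sum(w_targets)}: the distractor-to-
#' target attentional weight ratio. Lower values indicate more efficient
#' selection (distractors attract little weight); 1 means no selectivity.
#'
#' @param w_targets nonnegative target weights (sum > 0).
#' @param w_distractors nonnegative distractor weights.
#' @return scalar alpha >= 0.
#' @export
alpha_from_weights <- function(w_targets, w_distractors) {
  st <- sum(w_targets)
  sd_ <- sum(w_distractors)
  if (any(w_targets < 0) || any(w_distractors < 0))
    stop("weights must be nonnegative")
  if (st <= 0) stop("target weight sum must be positive")
  sd_ / st
}

#' Spatial laterality from hemifield weights
#'
#' \code{w_lat = w_left / (w_left + w_right)}. 0.5 indicates balanced
#' weighting; values above/below 0.5 indicate left-/right-ward bias.
#'
#' @param w_left,w_right nonnegative hemifield weights, not both zero.
#' @return scalar in [0, 1].
#' @export
w_lat_from_weights <- function(w_left, w_right) {
  if (w_left < 0 || w_right < 0) stop("weights must be nonnegative")
  if (w_left + w_right <= 0) stop("hemifield weights must not both be zero")
  w_left / (w_left + w_right)
}

#' Capacity probability mass function
#'
#' Real-valued mean capacities are realised as the two-point mixture on
#' \code{floor(K)} and \code{ceiling(K)} whose mean equals \code{K_mean} --
#' the simplest integer-capacity mixture consistent with non-integer
#' whole-report asymptotes.
#'
#' @param K_mean mean capacity, > 0.
#' @param n_items number of display items; support is truncated to
#'   \code{0:n_items} (probability renormalised onto attainable scores is not
#'   needed: capacities above \code{n_items} behave identically, so they are
#'   collapsed onto \code{n_items}).
#' @return data.frame with columns \code{k} (integer capacity) and \code{p}.
#' @export
capacity_pmf <- function(K_mean, n_items = 8L) {
  stopifnot(K_mean > 0)
  lo <- floor(K_mean)
  hi <- ceiling(K_mean)
  if (lo == hi) {
    out <- data.frame(k = lo, p = 1)
  } else {
    p_hi <- K_mean - lo
    out <- data.frame(k = c(lo, hi), p = c(1 - p_hi, p_hi))
  }
  # capacities above the display size are equivalent to n_items
  out$k <- pmin(out$k, n_items)
  out <- stats::aggregate(p ~ k, out, sum)
  out
}
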