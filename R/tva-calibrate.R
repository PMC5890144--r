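#' Individualised exposure durations
#'
#' Mirrors the pretest procedure of the report tasks. Whole report: the
#' anchor duration t* is the masked exposure at which the expected score is
#' exactly 1.0 letters; the task then uses {short, middle, long} =
#' {factor_short * t*, t*, factor_long * t*}. Partial report: t* is the
#' masked exposure at which a single target is reported with 80% accuracy.
#' Both are solved by bisection to 0.1 ms.
#'
#' @param params a \code{tva_params} object.
#' @param task "whole" or "partial".
#' @param n_items letters per whole-report display (default 6).
#' @param target_score expected-score criterion for whole report (default 1).
#' @param target_accuracy single-target accuracy criterion for partial
#'   report (default 0.80).
#' @param factor_short,factor_long multipliers for the short and long
#'   whole-report durations (defaults 0.5 and 2).
#' @param t_max search upper bound, ms.
#' @return whole report: named numeric vector (short, middle, long), ms;
#'   partial report: scalar t*, ms.
#' @export
calibrate_exposures <- function(params, task = c("whole", "partial"),
                                n_items = 6L, target_score = 1,
                                target_accuracy = 0.80,
                                factor_short = 0.5, factor_long = 2,
                                t_max = 5000) {
  task <- match.arg(task)
  if (task == "whole") {
    if (params$K_mean < target_score)
      stop("calibration failure: expected score cannot reach ", target_score,
           " (asymptote K_mean = ", params$K_mean, ")")
    f <- function(t) {
      cond <- display_condition(rep("left", n_items), rep("target", n_items),
                                exposure_ms = t, masked = TRUE)
      expected_score(cond, params) - target_score
    }
    if (f(t_max) < 0) stop("calibration failure: criterion unreachable below t_max")
    t_star <- stats::uniroot(f, c(params$t0 + 1e-6, t_max), tol = 0.05)$root
    c(short = factor_short * t_star, middle = t_star,
      long = factor_long * t_star)
  } else {
    f <- function(t) {
      cond <- display_condition("left", "target", exposure_ms = t,
                                masked = TRUE)
      partial_report_prob(cond, params) - target_accuracy
    }
    if (f(t_max) < 0) stop("calibration failure: criterion unreachable below t_max")
    stats::uniroot(f, c(params$t0 + 1e-6, t_max), tol = 0.05)$root
  }
}
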