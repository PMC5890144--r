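# Simulate one race trial: exponential encoding times, capacity draw,
# first-K finishers retained. Returns logical vector "reported" per item.
simulate_race_trial <- function(rates, tau, cap) {
  k <- if (nrow(cap) == 1) cap$k else sample(cap$k, 1, prob = cap$p)
  times <- stats::rexp(length(rates), rates)
  finished <- which(times <= tau)
  if (length(finished) > k)
    finished <- if (k > 0) finished[order(times[finished])][seq_len(k)] else integer()
  out <- logical(length(rates))
  out[finished] <- TRUE
  out
}

#' Simulate whole- and partial-report trial data
#'
#' Generates the full behavioral data set of the study design for a table of
#' synthetic subjects: per subject, exposure durations are individually
#' calibrated (expected masked score of 1 letter for whole report, 80%
#' single-target accuracy for partial report), then 192 whole-report trials
#' (12 conditions, 4 blocks of 48, balanced within block) and 288
#' partial-report trials (16 conditions, 6 blocks of 48, balanced within
#' block) are drawn from the exact race-model outcome distributions.
#'
#' @param population data.frame from \code{\link{sample_population}} (or any
#'   table with the same parameter columns).
#' @param seed integer seed; the whole table is a pure function of
#'   (population, seed).
#' @param tasks character subset of c("whole", "partial").
#' @param n_items letters per whole-report display.
#' @return trial table data.frame (see \code{\link{validate_trial_table}})
#'   with an attribute \code{"exposures"}: per-subject calibrated durations.
#' @export
simulate_behavior <- function(population, seed = 1L,
                              tasks = c("whole", "partial"), n_items = 6L) {
  stopifnot(all(c("subject_id", "C", "K", "t0", "mu") %in% names(population)))
  all_dfs <- list()
  exposures <- list()
  for (i in seq_len(nrow(population))) {
    row <- population[i, ]
    params <- subject_params(row)
    sid <- row$subject_id
    with_seed(subject_seed(sid, seed), {
      if ("whole" %in% tasks) {
        expo <- calibrate_exposures(params, "whole", n_items = n_items)
        exposures[[sid]] <- list(whole = expo)
        des <- whole_report_design(expo, n_items = n_items)
        des$layout_id <- paste0(des$exposure_label,
                                ifelse(des$masked, "-m", "-u"),
                                "-", substr(des$hemifield, 1, 1))
        pmfs <- lapply(seq_len(nrow(des)), function(ci)
          report_distribution(condition_display(des[ci, ], "whole"), params))
        order_ci <- unlist(lapply(seq_len(des$n_blocks[1]), function(b)
          sample(rep(des$condition_id, des$trials_per_block[1]))))
        scores <- vapply(order_ci, function(ci)
          sample.int(n_items + 1L, 1, prob = pmfs[[ci]]) - 1L, 0L)
        all_dfs[[length(all_dfs) + 1L]] <- data.frame(
          subject_id = sid, task = "whole",
          block = rep(seq_len(des$n_blocks[1]), each = 48L),
          trial = seq_along(order_ci),
          exposure_ms = des$exposure_ms[order_ci],
          masked = des$masked[order_ci],
          hemifield = des$hemifield[order_ci],
          n_targets = n_items, n_distractors = 0L,
          layout_id = des$layout_id[order_ci],
          score = scores, target1_reported = NA, target2_reported = NA,
          stringsAsFactors = FALSE)
      }
      if ("partial" %in% tasks) {
        t_star <- calibrate_exposures(params, "partial")
        exposures[[sid]] <- c(exposures[[sid]], list(partial = t_star))
        des <- partial_report_design(t_star)
        conds <- lapply(seq_len(nrow(des)), function(ci)
          condition_display(des[ci, ], "partial"))
        rates_list <- lapply(conds, display_rates, params = params)
        tau <- display_tau(conds[[1]], params)
        cap <- capacity_pmf(params$K_mean, 3L)
        order_ci <- unlist(lapply(seq_len(des$n_blocks[1]), function(b)
          sample(rep(des$condition_id, des$trials_per_block[1]))))
        t1 <- logical(length(order_ci)); t2 <- rep(NA, length(order_ci))
        for (tr in seq_along(order_ci)) {
          ci <- order_ci[tr]
          rep_items <- simulate_race_trial(rates_list[[ci]], tau, cap)
          targ <- which(conds[[ci]]$role == "target")
          t1[tr] <- rep_items[targ[1]]
          if (length(targ) == 2) t2[tr] <- rep_items[targ[2]]
        }
        n_targ <- vapply(conds, function(cd) sum(cd$role == "target"), 0L)
        all_dfs[[length(all_dfs) + 1L]] <- data.frame(
          subject_id = sid, task = "partial",
          block = rep(seq_len(des$n_blocks[1]), each = 48L),
          trial = seq_along(order_ci),
          exposure_ms = t_star, masked = TRUE,
          hemifield = vapply(order_ci, function(ci) {
            cd <- conds[[ci]]; cd$hemifield[which(cd$role == "target")[1]]
          }, ""),
          n_targets = n_targ[order_ci],
          n_distractors = vapply(conds, function(cd)
            sum(cd$role == "distractor"), 0L)[order_ci],
          layout_id = des$layout_id[order_ci],
          score = NA, target1_reported = t1, target2_reported = t2,
          stringsAsFactors = FALSE)
      }
    })
  }
  trials <- do.call(rbind, all_dfs)
  rownames(trials) <- NULL
  attr(trials, "exposures") <- exposures
  validate_trial_table(trials)
}
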