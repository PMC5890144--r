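#' Whole-report design
#'
#' The 12 whole-report conditions: 2 masking conditions (masked, unmasked) x
#' 3 exposure durations (short, middle, long) x 2 hemifields (a single column
#' of letters shown left or right of fixation). 192 trials in 4 blocks of 48,
#' every condition appearing equally often (4 times) within each block.
#'
#' @param exposures named numeric vector of length 3 (ms), names
#'   \code{short}, \code{middle}, \code{long} -- normally the individually
#'   calibrated durations from \code{\link{calibrate_exposures}}.
#' @param n_items letters per display column (default 6).
#' @return data.frame of 12 condition rows: \code{condition_id},
#'   \code{exposure_label}, \code{exposure_ms}, \code{masked},
#'   \code{hemifield}, \code{n_items}, \code{trials_per_block},
#'   \code{n_blocks}.
#' @export
whole_report_design <- function(exposures, n_items = 6L) {
  stopifnot(length(exposures) == 3, all(exposures > 0))
  if (is.null(names(exposures))) names(exposures) <- c("short", "middle", "long")
  g <- expand.grid(exposure_label = names(exposures),
                   masked = c(TRUE, FALSE),
                   hemifield = c("left", "right"),
                   stringsAsFactors = FALSE)
  g$exposure_ms <- as.numeric(exposures[g$exposure_label])
  g$condition_id <- seq_len(nrow(g))
  g$n_items <- n_items
  g$trials_per_block <- 4L   # 48 trials/block over 12 conditions
  g$n_blocks <- 4L
  g[, c("condition_id", "exposure_label", "exposure_ms", "masked",
        "hemifield", "n_items", "trials_per_block", "n_blocks")]
}

#' Partial-report design
#'
#' The 16 partial-report conditions on the corners of an imaginary square
#' (positions UL, LL, UR, LR; hemifield by column): 4 single-target
#' conditions, 8 target-plus-distractor conditions (distractor horizontally
#' or vertically adjacent to the target) and 4 dual-target conditions
#' (horizontal or vertical pairs). All displays masked. 288 trials in 6
#' blocks of 48, every condition 3 times per block.
#'
#' @param exposure_ms the individually calibrated exposure duration, ms.
#' @return data.frame of 16 rows: \code{condition_id}, \code{layout_id},
#'   \code{kind} ("T", "TD", "TT"), positions/hemifields/roles packed as
#'   comma strings, \code{exposure_ms}, \code{masked},
#'   \code{trials_per_block}, \code{n_blocks}.
#' @export
partial_report_design <- function(exposure_ms) {
  stopifnot(exposure_ms > 0)
  corners <- c(UL = "left", LL = "left", UR = "right", LR = "right")
  pos <- names(corners)
  horiz <- list(UL = "UR", UR = "UL", LL = "LR", LR = "LL")
  vert  <- list(UL = "LL", LL = "UL", UR = "LR", LR = "UR")
  rows <- list()
  for (p in pos)  # 4 single target
    rows[[length(rows) + 1]] <- list(kind = "T", pos = p, roles = "target")
  for (p in pos) {  # 8 target + distractor
    rows[[length(rows) + 1]] <- list(kind = "TD", pos = c(p, horiz[[p]]),
                                     roles = c("target", "distractor"))
    rows[[length(rows) + 1]] <- list(kind = "TD", pos = c(p, vert[[p]]),
                                     roles = c("target", "distractor"))
  }
  for (pair in list(c("UL", "UR"), c("LL", "LR"), c("UL", "LL"), c("UR", "LR")))
    rows[[length(rows) + 1]] <- list(kind = "TT", pos = pair,
                                     roles = c("target", "target"))
  out <- data.frame(
    condition_id = seq_along(rows),
    layout_id = vapply(rows, function(r)
      paste(paste0(substr(r$roles, 1, 1), r$pos), collapse = "+"), ""),
    kind = vapply(rows, function(r) r$kind, ""),
    positions = vapply(rows, function(r) paste(r$pos, collapse = ","), ""),
    hemifields = vapply(rows, function(r)
      paste(corners[r$pos], collapse = ","), ""),
    roles = vapply(rows, function(r) paste(r$roles, collapse = ","), ""),
    exposure_ms = exposure_ms,
    masked = TRUE,
    trials_per_block = 3L,   # 48 trials/block over 16 conditions
    n_blocks = 6L,
    stringsAsFactors = FALSE)
  out
}

# Build the display_condition for one design row.
condition_display <- function(row, task) {
  if (task == "whole") {
    n <- row$n_items
    display_condition(hemifield = rep(row$hemifield, n),
                      role = rep("target", n),
                      exposure_ms = row$exposure_ms,
                      masked = row$masked)
  } else {
    display_condition(hemifield = strsplit(row$hemifields, ",")[[1]],
                      role = strsplit(row$roles, ",")[[1]],
                      exposure_ms = row$exposure_ms,
                      masked = TRUE)
  }
}

trial_table_columns <- c("subject_id", "task", "block", "trial",
                         "exposure_ms", "masked", "hemifield", "n_targets",
                         "n_distractors", "layout_id", "score",
                         "target1_reported", "target2_reported")

#' Validate a trial table
#'
#' Checks the trial-table schema (column presence and types) and the design
#' quotas: 192 whole-report trials in 12 conditions per subject, 288
#' partial-report trials in 16 conditions per subject, balanced within
#' blocks.
#'
#' @param trials data.frame in the trial-table schema.
#' @param check_quotas verify per-subject condition counts (default TRUE).
#' @return invisibly, \code{trials}; errors name the offending column.
#' @export
validate_trial_table <- function(trials, check_quotas = TRUE) {
  missing_cols <- setdiff(trial_table_columns, names(trials))
  if (length(missing_cols))
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(trials$task %in% c("whole", "partial")))
    stop("column 'task' must be 'whole' or 'partial'")
  if (check_quotas) {
    for (s in unique(trials$subject_id)) {
      w <- trials[trials$subject_id == s & trials$task == "whole", ]
      p <- trials[trials$subject_id == s & trials$task == "partial", ]
      if (nrow(w) && (nrow(w) != 192 || length(unique(w$layout_id)) != 12))
        stop("subject ", s, ": whole report must have 192 trials in 12 conditions")
      if (nrow(p) && (nrow(p) != 288 || length(unique(p$layout_id)) != 16))
        stop("subject ", s, ": partial report must have 288 trials in 16 conditions")
    }
  }
  invisible(trials)
}
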