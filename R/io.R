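#' Write / read a 4D image or 3D map as NIfTI-1
#'
#' Thin wrappers around RNifti with the package's conventions for synthetic
#' data: identity affine in voxel-index space, TR stored in the time pixdim.
#'
#' @param img 3D/4D array (optionally with a "tr" attribute, seconds).
#' @param path file path (".nii").
#' @return \code{write_nifti}: the path, invisibly. \code{read_nifti}: the
#'   array with the "tr" attribute restored (4D input).
#' @export
write_nifti <- function(img, path) {
  tr <- attr(img, "tr")
  nim <- RNifti::asNifti(unclass(img))
  if (!is.null(tr) && length(dim(img)) == 4)
    RNifti::pixdim(nim) <- c(1, 1, 1, tr)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  arr <- array(as.numeric(nim), dim = dim(nim))
  if (length(dim(arr)) == 4) {
    pd <- RNifti::pixdim(nim)
    if (length(pd) >= 4) attr(arr, "tr") <- pd[4]
  }
  arr
}

#' Trial-table TSV I/O
#'
#' Tab-separated serialisation of the behavioral trial table, with schema
#' validation on read (missing required columns are named).
#'
#' @param trials trial table data.frame.
#' @param path file path (".tsv").
#' @param check_quotas passed to \code{\link{validate_trial_table}} on read.
#' @return \code{write_trial_table}: the path, invisibly;
#'   \code{read_trial_table}: the validated data.frame.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials, check_quotas = FALSE)
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path, check_quotas = FALSE) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_trial_table(tr, check_quotas = check_quotas)
}

#' Fitted-parameter table I/O
#'
#' One row per subject (C, K, t0, mu, alpha, w_lat plus the four weights),
#' as TSV; fit diagnostics go to JSON alongside when provided.
#'
#' @param fits named list of \code{fit_tva} results (names = subject ids).
#' @param path TSV path.
#' @param diagnostics_path optional JSON path for the diagnostics.
#' @return the parameter data.frame, invisibly.
#' @export
write_params <- function(fits, path, diagnostics_path = NULL) {
  tab <- do.call(rbind, lapply(names(fits), function(sid) {
    p <- fits[[sid]]$params
    data.frame(subject_id = sid, C = p$C, K = p$K_mean, t0 = p$t0,
               mu = p$mu, alpha = p$alpha, w_lat = p$w_lat,
               w_target_left = p$w_target_left,
               w_target_right = p$w_target_right,
               w_distractor_left = p$w_distractor_left,
               w_distractor_right = p$w_distractor_right,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(diagnostics_path)) {
    diag_list <- lapply(fits, function(f)
      f[grep("^(loglik|converged|start_index)", names(f))])
    jsonlite::write_json(diag_list, diagnostics_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(tab)
}

#' Motion-parameter TSV I/O
#'
#' @param motion t x 6 data.frame (translations mm, rotations degrees).
#' @param path file path.
#' @return \code{write_motion}: path invisibly; \code{read_motion}: the
#'   data.frame (6 columns enforced).
#' @export
write_motion <- function(motion, path) {
  stopifnot(ncol(motion) == 6)
  utils::write.table(motion, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- utils::read.delim(path)
  if (ncol(m) != 6) stop("motion table must have 6 columns, found ", ncol(m))
  m
}

#' Study configuration YAML round-trip
#'
#' @param config a \code{study_config} (or plain list).
#' @param path YAML file path.
#' @return \code{write_study_config}: path invisibly;
#'   \code{read_study_config}: the restored \code{study_config}.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(study_config, cfg)
}
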