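#' Study configuration
#'
#' Bundles every setting of the synthetic end-to-end study -- population,
#' behavioral design, scene, preprocessing and statistical thresholds --
#' into one serialisable object; a run is reproducible from (config, seed)
#' alone.
#'
#' @param seed master seed.
#' @param n_subjects subjects in the cohort (default 31).
#' @param fit_tva estimate TVA parameters from the simulated trials (TRUE,
#'   default) or use the generating values directly (FALSE, faster).
#' @param n_starts optimiser multistarts for the whole-report fit.
#' @param grid,n_volumes,tr,G_networks scene geometry (defaults 24 x 24 x
#'   12, 250 volumes, TR 2.608 s, 6 planted networks).
#' @param G_decompose group-decomposition dimensionality (default 12 on the
#'   scaled-down grid).
#' @param use_planted_maps skip the group decomposition and dual-regress
#'   against the planted templates (deterministic; default FALSE).
#' @param intra_d,intra_network Cohen's d and network index of the planted
#'   intra-network group effect (split on C; d = 1.2, ventral-attention-like
#'   network 5 by default; direction: high performers lower).
#' @param inter_z_high,inter_z_low,inter_pair planted inter-network
#'   Fisher-z means per group and the affected pair (defaults 0.269 /
#'   0.116 for the ventral-attention / right-frontoparietal pair c(5, 3)).
#' @param fwhm_mm,voxel_mm smoothing kernel and voxel size (4 mm FWHM, 2 mm
#'   voxels).
#' @param height_p,fwe_p,n_perm,connectivity cluster inference settings.
#' @param n_networks,n_pairs Bonferroni counts (6 networks, 5 pairs).
#' @param noise_sd,gain_sd scene noise and gain variability.
#' @return object of class \code{study_config}.
#' @export
study_config <- function(seed = 1L, n_subjects = 31L, fit_tva = TRUE,
                         n_starts = 10L, grid = c(24L, 24L, 12L),
                         n_volumes = 250L, tr = 2.608, G_networks = 6L,
                         G_decompose = 12L, use_planted_maps = FALSE,
                         intra_d = 1.2, intra_network = 5L,
                         inter_z_high = 0.269, inter_z_low = 0.116,
                         inter_pair = c(5L, 3L), fwhm_mm = 4, voxel_mm = 2,
                         height_p = 0.001, fwe_p = 0.05, n_perm = 1000L,
                         connectivity = 26, n_networks = 6L, n_pairs = 5L,
                         noise_sd = 1, gain_sd = 0.25) {
  cfg <- as.list(environment())
  cfg$grid <- as.integer(grid)
  structure(cfg, class = "study_config")
}

# Median-split directions per TVA parameter: better performance is faster
# processing, larger storage, lower distractor weighting; for laterality
# the "high" label marks right-preference (values below the median).
split_direction <- function(param)
  switch(param, C = "higher", K = "higher", alpha = "lower",
         w_lat = "lower", stop("unknown parameter ", param))

#' Run the full synthetic study
#'
#' Executes the complete analysis chain on synthetic data with known ground
#' truth: sample a population, simulate and (optionally) fit the report
#' tasks, simulate resting-state images with planted group effects, run
#' motion/tSNR QC, nuisance regression and smoothing, group decomposition
#' and template matching (or planted maps), dual regression, and the
#' intra-/inter-network group statistics for each TVA parameter.
#'
#' @param config a \code{study_config}.
#' @param out_dir optional directory; when given, parameter tables, the
#'   config and a JSON report are written there.
#' @param params_of_interest TVA parameters to run group statistics for
#'   (default c("C", "alpha")), each tested on its matched network.
#' @return a report list: \code{population}, \code{params} (fitted or
#'   generating), \code{split} per parameter, \code{qc}, \code{match},
#'   \code{intra} (cluster inference per parameter), \code{inter}
#'   (inter-network group tests), \code{partial_cor}, \code{truth},
#'   \code{seeds}.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      params_of_interest = c("C", "alpha")) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("study stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ## behavior ----
  pop <- stage("population", sample_population(
    population_spec(n_subjects = config$n_subjects, seed = config$seed)))
  if (config$fit_tva) {
    trials <- stage("behavior",
                    simulate_behavior(pop, seed = config$seed + 1L))
    fits <- stage("fit", {
      out <- lapply(pop$subject_id, function(s)
        fit_tva(trials[trials$subject_id == s, ], n_starts = config$n_starts,
                seed = config$seed + 2L))
      names(out) <- pop$subject_id
      out
    })
    params <- do.call(rbind, lapply(names(fits), function(sid) {
      p <- fits[[sid]]$params
      data.frame(subject_id = sid, C = p$C, K = p$K_mean, t0 = p$t0,
                 mu = p$mu, alpha = p$alpha, w_lat = p$w_lat)
    }))
  } else {
    fits <- NULL
    params <- pop[, c("subject_id", "C", "K", "t0", "mu", "alpha", "w_lat")]
  }
  params$education <- pop$education
  params$gender <- pop$gender
  ## splits (one per TVA parameter, from the estimated parameters) ----
  split <- lapply(c(C = "C", K = "K", alpha = "alpha", w_lat = "w_lat"),
                  function(pm) median_split(params[[pm]], split_direction(pm),
                                            ids = params$subject_id))
  ## scene: biology follows the generating parameters ----
  true_split_C <- median_split(pop$C, "higher", ids = pop$subject_id)
  scene <- stage("scene", fmri_scene(
    grid = config$grid, n_volumes = config$n_volumes, tr = config$tr,
    G = config$G_networks, noise_sd = config$noise_sd,
    gain_sd = config$gain_sd,
    intra_effect = list(network = config$intra_network, d = config$intra_d,
                        direction = -1),
    inter_effect = list(pair = config$inter_pair,
                        z_high = config$inter_z_high,
                        z_low = config$inter_z_low),
    template_seed = config$seed + 100L))
  subjects <- data.frame(subject_id = pop$subject_id,
                         group = as.character(true_split_C),
                         stringsAsFactors = FALSE)
  sim <- stage("fmri", simulate_fmri(subjects, scene, seed = config$seed + 3L))
  ## QC ----
  qc <- stage("qc", {
    recs <- lapply(sim$motion, motion_qc)
    tsnrs <- vapply(sim$images, function(im) tsnr(im)$scalar, 0)
    mean_step <- vapply(recs, function(r) r$mean_trans, 0)
    data.frame(subject_id = names(recs),
               tsnr = tsnrs, mean_trans = mean_step,
               exclude_motion = vapply(recs, function(r) r$exclude, TRUE),
               extreme_tsnr = flag_extremes(tsnrs, "lower"),
               extreme_motion = flag_extremes(mean_step, "upper"))
  })
  ## preprocessing: nuisance regression then smoothing ----
  pre <- stage("preprocess", lapply(pop$subject_id, function(sid) {
    img <- sim$images[[sid]]
    gs <- rowMeans(img_to_matrix(img))   # global signal: one value per volume
    conf <- cbind(as.matrix(sim$motion[[sid]]), global = gs)
    smooth_image(nuisance_regress(img, conf), config$fwhm_mm, config$voxel_mm)
  }))
  names(pre) <- pop$subject_id
  ## decomposition + matching ----
  if (config$use_planted_maps) {
    maps <- scene$templates
    match <- data.frame(template = seq_len(config$G_networks),
                        component = seq_len(config$G_networks), r = 1)
  } else {
    comp <- stage("decompose", group_decompose(pre, G = config$G_decompose,
                                               seed = config$seed + 4L))
    match <- stage("match", match_templates(comp, scene$templates))
    maps <- comp$maps
  }
  selected <- match$component   # component index per planted network
  ## dual regression ----
  dr <- stage("dualreg", lapply(pre, dual_regression, group_maps = maps))
  zmaps <- lapply(seq_len(config$G_networks), function(net)
    do.call(rbind, lapply(dr, function(d)
      as.vector(d$zmaps[, , , selected[net]]))))
  fc <- lapply(dr, function(d) internetwork_fc(d$timecourses, selected))
  ## group statistics ----
  other <- list(C = c("K", "alpha", "w_lat"), K = c("C", "alpha", "w_lat"),
                alpha = c("C", "K", "w_lat"), w_lat = c("C", "K", "alpha"))
  network_of <- c(C = config$intra_network, alpha = 4L, K = 2L, w_lat = 3L)
  intra <- list()
  for (pm in params_of_interest) {
    covs <- cbind(as.matrix(params[, other[[pm]]]),
                  education = params$education, gender = params$gender)
    net <- network_of[[pm]]
    intra[[pm]] <- stage(paste0("glm-", pm), cluster_inference(
      zmaps[[net]], split[[pm]], covariates = covs, grid = config$grid,
      height_p = config$height_p, fwe_p = config$fwe_p,
      n_perm = config$n_perm, seed = config$seed + 5L,
      connectivity = config$connectivity, negate = TRUE))
    intra[[pm]]$network <- net
    if (nrow(intra[[pm]]$clusters))
      intra[[pm]]$clusters$survives_bonferroni <- bonferroni_networks(
        intra[[pm]]$clusters$p_fwe, config$n_networks)$survives
  }
  ## inter-network: planted pair, high > low, one-tailed ----
  pair <- config$inter_pair
  z_pair <- vapply(fc, function(m) m[pair[1], pair[2]], 0)
  inter <- stage("internetwork", internetwork_group_test(
    z_pair, split[["C"]], tail = "high_greater", n_pairs = config$n_pairs))
  ## intra- vs inter-network partial correlation ----
  net_mask <- scene$templates[, , , config$intra_network] > 0.2
  ctrl_mask <- scene$templates[, , , pair[2]] > 0.2
  intra_scalar <- intra_network_scalar(zmaps[[config$intra_network]], net_mask)
  ctrl_scalar <- intra_network_scalar(zmaps[[pair[2]]], ctrl_mask)
  pcor <- stage("partialcor",
                partial_correlation(intra_scalar, z_pair, ctrl_scalar))
  report <- list(population = pop, params = params, fits = fits,
                 split = split, qc = qc, match = match, intra = intra,
                 inter = inter, partial_cor = pcor,
                 fc = fc, zmaps = zmaps,
                 truth = sim$truth,
                 seeds = list(master = config$seed),
                 config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(params, file.path(out_dir, "params.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_study_config(config, file.path(out_dir, "config.yaml"))
    summary_report <- list(
      qc = qc, match = match,
      intra = lapply(intra, function(g)
        list(network = g$network, df = g$df, clusters = g$clusters)),
      inter = inter, partial_cor = pcor, seed = config$seed)
    jsonlite::write_json(summary_report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
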