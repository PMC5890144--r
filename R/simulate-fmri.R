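#' Synthetic resting-state scene specification
#'
#' Describes how a set of small 4D resting-state images is generated: G
#' planted network spatial maps, network time courses with a specified
#' inter-network correlation structure, per-subject coupling gains, optional
#' group effects on one network's coupling (intra-network connectivity) and
#' on one network pair's correlation (inter-network connectivity), plus
#' drift, motion-locked artifact and Gaussian noise. The grid is scaled
#' down from an MNI-resolution acquisition so that a 31-subject scene
#' simulates in seconds; acquisition constants default to the study's
#' 250 volumes at TR = 2.608 s.
#'
#' @param grid voxel grid dimensions, default c(24, 24, 12).
#' @param n_volumes volumes per subject, default 250.
#' @param tr repetition time in seconds, default 2.608.
#' @param G number of planted networks, default 6.
#' @param templates optional array c(grid, G); generated from
#'   \code{template_seed} when NULL.
#' @param base_r baseline inter-network correlation of the generating time
#'   courses (all pairs), default 0.15.
#' @param gain_mean,gain_sd mean and between-subject SD of the network
#'   coupling gain, defaults 1 and 0.25.
#' @param signal_sd amplitude of the network signal in image units, default 2.
#' @param noise_sd Gaussian voxel noise SD, default 1.
#' @param drift_amplitude linear + slow-cosine drift amplitude, default 1.
#' @param motion_amplitude amplitude of the motion-locked global intensity
#'   artifact, default 0.5; motion traces are random walks with
#'   \code{motion_step} mm (or degrees) per volume.
#' @param motion_step default 0.01.
#' @param intra_effect NULL or list(network =, d =, direction =): a
#'   between-group mean shift of the coupling gain of one network, of size
#'   \code{d * gain_sd}; \code{direction = -1} (default) plants *lower*
#'   gain in the "high" group, matching the observed
#'   higher-speed/lower-intra-FC pattern.
#' @param inter_effect NULL or list(pair = c(i, j), z_high =, z_low =,
#'   z_sd =): generating Fisher-z correlation of the pair per group, with
#'   between-subject SD \code{z_sd} (default 0.15).
#' @param template_seed seed used when generating templates, default 100.
#' @return object of class \code{fmri_scene}.
#' @export
fmri_scene <- function(grid = c(24L, 24L, 12L), n_volumes = 250L,
                       tr = 2.608, G = 6L, templates = NULL,
                       base_r = 0.15, gain_mean = 1, gain_sd = 0.25,
                       signal_sd = 2, noise_sd = 1, drift_amplitude = 1,
                       motion_amplitude = 0.5, motion_step = 0.01,
                       intra_effect = list(network = 5L, d = 0, direction = -1),
                       inter_effect = NULL, template_seed = 100L) {
  if (is.null(templates))
    templates <- make_network_templates(grid, G, seed = template_seed)
  stopifnot(all(dim(templates) == c(grid, G)), all(templates >= 0),
            n_volumes >= 10)
  structure(list(grid = grid, n_volumes = as.integer(n_volumes), tr = tr,
                 G = as.integer(G), templates = templates, base_r = base_r,
                 gain_mean = gain_mean, gain_sd = gain_sd,
                 signal_sd = signal_sd, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 motion_amplitude = motion_amplitude,
                 motion_step = motion_step,
                 intra_effect = intra_effect, inter_effect = inter_effect),
            class = "fmri_scene")
}

# Correlation matrix of the generating time courses for one subject.
subject_cov <- function(scene, z_pair = NULL) {
  G <- scene$G
  S <- matrix(scene$base_r, G, G)
  diag(S) <- 1
  if (!is.null(z_pair)) {
    ij <- scene$inter_effect$pair
    S[ij[1], ij[2]] <- S[ij[2], ij[1]] <- tanh(z_pair)
  }
  if (!is_pos_def(S))
    stop("generating covariance is not positive definite after group shift")
  S
}

#' Simulate a group of 4D resting-state images with planted ground truth
#'
#' Each subject's voxel time series is
#' sum_g template_g(voxel) * gain_{s,g} * timecourse_{s,g}(t) + drift +
#' motion-locked artifact + Gaussian noise. Time courses are drawn from the
#' scene's inter-network correlation structure (mildly AR(1)-smoothed, which
#' preserves contemporaneous correlations); group-dependent effects shift
#' the coupling gain of one network (intra-network effect) and/or the
#' generating correlation of one network pair (inter-network effect).
#'
#' @param subjects data.frame with columns \code{subject_id} and
#'   \code{group} ("high"/"low"); typically a sampled population joined
#'   with \code{\link{median_split}} labels.
#' @param scene an \code{fmri_scene}.
#' @param seed integer seed; output is a pure function of
#'   (subjects, scene, seed).
#' @return list with \code{images} (named list of 4D arrays, TR attached as
#'   attribute "tr"), \code{motion} (named list of t x 6 data.frames,
#'   translations mm then rotations degrees), and \code{truth} (templates,
#'   per-subject gains, generating z per pair, group labels, scene
#'   settings).
#' @export
simulate_fmri <- function(subjects, scene, seed = 1L) {
  stopifnot(inherits(scene, "fmri_scene"),
            all(c("subject_id", "group") %in% names(subjects)))
  G <- scene$G
  Tn <- scene$n_volumes
  V <- prod(scene$grid)
  tmpl <- matrix(scene$templates, nrow = V, ncol = G)
  images <- list()
  motion <- list()
  tcs_all <- list()
  gains <- matrix(NA_real_, nrow(subjects), G,
                  dimnames = list(subjects$subject_id, NULL))
  z_gen <- rep(NA_real_, nrow(subjects))
  drift_lin <- seq(-1, 1, length.out = Tn)
  drift_cos <- cos(seq(0, 2 * pi, length.out = Tn))
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    grp <- subjects$group[i]
    with_seed(subject_seed(sid, seed + 31L), {
      # generating inter-network correlation, possibly group-shifted
      z_pair <- NULL
      if (!is.null(scene$inter_effect)) {
        ie <- scene$inter_effect
        z_sd <- if (is.null(ie$z_sd)) 0.15 else ie$z_sd
        z_pair <- stats::rnorm(1, if (grp == "high") ie$z_high else ie$z_low,
                               z_sd)
        z_gen[i] <- z_pair
      }
      S <- subject_cov(scene, z_pair)
      L <- chol(S)
      tc <- matrix(stats::rnorm(Tn * G), Tn, G) %*% L
      # AR(1) smoothing with a common coefficient: preserves correlations
      tc <- apply(tc, 2, function(x) as.numeric(stats::filter(x, 0.4, "recursive")))
      tc <- scale(tc)
      # coupling gains, group shift on the intra-effect network
      g_mean <- rep(scene$gain_mean, G)
      if (!is.null(scene$intra_effect) && scene$intra_effect$d != 0) {
        net <- scene$intra_effect$network
        dirn <- if (is.null(scene$intra_effect$direction)) -1 else scene$intra_effect$direction
        shift <- scene$intra_effect$d * scene$gain_sd / 2
        g_mean[net] <- g_mean[net] +
          dirn * (if (grp == "high") shift else -shift)
      }
      g <- stats::rnorm(G, g_mean, scene$gain_sd)
      g <- pmax(g, 0.05)
      gains[i, ] <- g
      # motion: random-walk traces; artifact locked to displacement speed
      mot <- matrix(cumsum(stats::rnorm(Tn * 6, 0, scene$motion_step)),
                    Tn, 6)
      speed <- c(0, sqrt(rowSums(diff(mot[, 1:3, drop = FALSE])^2)))
      art <- if (stats::sd(speed) > 0) as.numeric(scale(speed)) else speed
      Y <- tmpl %*% (t(tc) * g) * scene$signal_sd
      Y <- Y + scene$drift_amplitude *
        outer(rep(1, V), 0.7 * drift_lin + 0.3 * drift_cos)
      Y <- Y + scene$motion_amplitude * outer(rep(1, V), art)
      Y <- Y + 100 + stats::rnorm(length(Y), 0, scene$noise_sd)
      img <- array(Y, dim = c(scene$grid, Tn))
      attr(img, "tr") <- scene$tr
      images[[sid]] <- img
      tcs_all[[sid]] <- tc
      colnames(mot) <- c("trans_x", "trans_y", "trans_z",
                         "rot_x", "rot_y", "rot_z")
      motion[[sid]] <- as.data.frame(mot)
    })
  }
  list(images = images, motion = motion,
       truth = list(templates = scene$templates, gains = gains,
                    timecourses = tcs_all,
                    z_gen = z_gen, group = stats::setNames(
                      as.character(subjects$group), subjects$subject_id),
                    scene = scene[setdiff(names(scene), "templates")],
                    seed = seed))
}
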