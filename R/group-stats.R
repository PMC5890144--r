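#' Median split into performance groups
#'
#' Ranks subjects on a parameter (in the direction in which larger means
#' better performance) and labels the top ceiling(n/2) as "high", the rest
#' as "low". For processing speed C and capacity K better is higher; for
#' top-down control alpha better is lower; for spatial laterality the split
#' separates right- from left-preference around the median (direction
#' "lower" labels right-preference subjects "high"). Ties are broken
#' deterministically by subject id.
#'
#' @param values numeric vector of parameter estimates.
#' @param better_direction "higher" or "lower".
#' @param ids optional subject identifiers used for deterministic
#'   tie-breaking (default: element order).
#' @return factor of labels "high"/"low", same length as \code{values};
#'   attribute \code{"median"} holds the group median.
#' @export
median_split <- function(values, better_direction = c("higher", "lower"),
                         ids = seq_along(values)) {
  better_direction <- match.arg(better_direction)
  n <- length(values)
  if (n < 4) stop("median split needs at least 4 subjects")
  if (length(unique(values)) == 1)
    stop("all values tied: split impossible")
  perf <- if (better_direction == "higher") values else -values
  ord <- order(perf, ids, decreasing = TRUE)
  labels <- rep("low", n)
  labels[ord[seq_len(ceiling(n / 2))]] <- "high"
  out <- factor(labels, levels = c("high", "low"))
  attr(out, "median") <- stats::median(values)
  out
}

#' Two-sample t-test from group summaries
#'
#' Recomputes a two-sample t statistic from per-group mean, SD and n, as
#' needed to verify printed group contrasts from summary tables. Welch's
#' variant uses the Welch-Satterthwaite df; the pooled variant uses
#' Student's t with df = n1 + n2 - 2.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param variant "welch" or "pooled".
#' @return list: \code{t}, \code{df}, \code{p} (two-sided).
#' @export
group_ttest_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  if (variant == "welch") {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t_stat <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

# Build the 7-column group design matrix: two cell-mean columns (high, low)
# plus mean-centred covariates. Residual df = n - 7 at the default 5
# covariates, matching a 31-subject sample with 24 df.
group_design <- function(groups, covariates = NULL) {
  groups <- factor(groups, levels = c("high", "low"))
  X <- cbind(high = as.numeric(groups == "high"),
             low = as.numeric(groups == "low"))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    Cv <- scale(as.matrix(covariates), center = TRUE, scale = FALSE)
    colnames(Cv) <- colnames(as.matrix(covariates))
    X <- cbind(X, Cv)
  }
  if (qr(X)$rank < ncol(X)) stop("group design matrix is rank deficient")
  X
}

#' Voxelwise group GLM with a high-minus-low contrast
#'
#' Fits, at every voxel, an ordinary least squares model of the subjects'
#' connectivity values on the two group cell means plus mean-centred
#' covariates, and returns the t-map of the high - low contrast with
#' df = n - ncol(design).
#'
#' @param zmaps subjects x voxels matrix, or list of 3D arrays (one per
#'   subject).
#' @param groups factor/character of "high"/"low" per subject.
#' @param covariates optional subjects x k matrix/data.frame of covariates
#'   of no interest (remaining TVA parameters, education, gender, ...).
#' @param mask optional logical 3D array (required when zmaps is a matrix
#'   only to reshape the output; default all voxels).
#' @return list: \code{tmap} (3D array or vector matching input),
#'   \code{df}, \code{contrast_estimate}, \code{design}.
#' @export
voxelwise_glm <- function(zmaps, groups, covariates = NULL, mask = NULL) {
  if (is.list(zmaps))
    zmaps <- do.call(rbind, lapply(zmaps, as.vector))
  X <- group_design(groups, covariates)
  n <- nrow(zmaps)
  if (nrow(X) != n) stop("groups/covariates do not match number of subjects")
  if (n <= ncol(X)) stop("need more subjects than design columns")
  fit <- glm_contrast_t(zmaps, X, c(1, -1, rep(0, ncol(X) - 2)))
  list(tmap = fit$t, df = fit$df, contrast_estimate = fit$est, design = X)
}

# Contrast t-statistics for Y (n x V) on design X; vectorised across voxels.
glm_contrast_t <- function(Y, X, contrast) {
  qx <- qr(X)
  B <- qr.coef(qx, Y)
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  est <- drop(t(contrast) %*% B)
  list(t = est / sqrt(sigma2 * cvar), est = est, df = df)
}

#' Label suprathreshold clusters
#'
#' Connected-component labelling of a logical 3D array under 26- (default),
#' 18- or 6-neighbourhood connectivity.
#'
#' @param above logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer 3D array of cluster labels (0 = background); attribute
#'   \code{"sizes"} holds voxel counts per label.
#' @export
label_clusters <- function(above, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(above)
  lab <- array(0L, d)
  idx <- which(above)
  if (!length(idx)) { attr(lab, "sizes") <- integer(0); return(lab) }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(offs != 0)
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  coord <- arrayInd(idx, d)
  key <- function(m) (m[, 3] - 1) * d[1] * d[2] + (m[, 2] - 1) * d[1] + m[, 1]
  inset <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = inset)
  visited <- logical(length(idx))
  current <- 0L
  sizes <- integer(0)
  for (start in seq_along(idx)) {
    if (visited[start]) next
    current <- current + 1L
    queue <- start
    visited[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      lab[idx[i]] <- current
      nb <- sweep(offs, 2, coord[i, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      for (k in key(nb[ok, , drop = FALSE])) {
        j <- get0(as.character(k), envir = inset)
        if (!is.null(j) && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  attr(lab, "sizes") <- sizes
  lab
}

#' Permutation cluster-extent inference for a group contrast
#'
#' One-sided cluster-level family-wise-error control: voxels exceeding the
#' height threshold t at p < height_p (df = n - 7) are grouped into
#' connected clusters, and each observed cluster's corrected p-value is the
#' (add-one smoothed) proportion of group-label permutations whose maximal
#' suprathreshold cluster is at least as large. Covariates are held fixed
#' under permutation; only the group labels are exchanged.
#'
#' @param zmaps subjects x voxels matrix or list of 3D arrays.
#' @param groups "high"/"low" labels per subject.
#' @param covariates optional covariates of no interest.
#' @param grid 3D grid dimensions (taken from array input if omitted).
#' @param height_p voxelwise height threshold (default 0.001, one-sided).
#' @param fwe_p cluster-level threshold (default 0.05).
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed integer seed; permutations are deterministic given it.
#' @param connectivity cluster connectivity, default 26.
#' @param negate test the low > high direction instead (default FALSE:
#'   high > low).
#' @return list of class \code{group_result}: \code{tmap} (3D array),
#'   \code{df}, \code{height_threshold}, \code{clusters} data.frame (size,
#'   peak index, peak t, corrected p, significant flag), \code{max_null}
#'   (permutation distribution of the maximal cluster size).
#' @export
cluster_inference <- function(zmaps, groups, covariates = NULL, grid = NULL,
                              height_p = 0.001, fwe_p = 0.05,
                              n_perm = 1000L, seed = 1L, connectivity = 26,
                              negate = FALSE) {
  if (is.list(zmaps)) {
    grid <- dim(zmaps[[1]])
    zmaps <- do.call(rbind, lapply(zmaps, as.vector))
  }
  if (is.null(grid)) stop("grid dimensions are required with matrix input")
  if (n_perm < 100) warning("fewer than 100 permutations: corrected p-values are coarse")
  X <- group_design(groups, covariates)
  n <- nrow(zmaps)
  contrast <- c(1, -1, rep(0, ncol(X) - 2)) * (if (negate) -1 else 1)
  obs <- glm_contrast_t(zmaps, X, contrast)
  df <- obs$df
  thr <- stats::qt(1 - height_p, df)
  max_cluster <- function(tvals) {
    above <- array(tvals > thr, grid)
    sizes <- attr(label_clusters(above, connectivity), "sizes")
    if (length(sizes)) max(sizes) else 0L
  }
  lab <- label_clusters(array(obs$t > thr, grid), connectivity)
  sizes <- attr(lab, "sizes")
  null_max <- integer(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(n)
      Xp <- X
      Xp[, 1:2] <- X[perm, 1:2]
      null_max[b] <- max_cluster(glm_contrast_t(zmaps, Xp, contrast)$t)
    }
  })
  clusters <- data.frame(label = integer(), size = integer(),
                         peak_index = integer(), peak_t = numeric(),
                         p_fwe = numeric(), significant = logical())
  if (length(sizes)) {
    for (cl in seq_along(sizes)) {
      vox <- which(lab == cl)
      peak <- vox[which.max(obs$t[vox])]
      p_fwe <- (1 + sum(null_max >= sizes[cl])) / (1 + n_perm)
      clusters <- rbind(clusters, data.frame(
        label = cl, size = sizes[cl], peak_index = peak,
        peak_t = obs$t[peak], p_fwe = p_fwe,
        significant = p_fwe < fwe_p))
    }
    clusters <- clusters[order(-clusters$size), ]
    rownames(clusters) <- NULL
  }
  structure(list(tmap = array(obs$t, grid), df = df,
                 height_threshold = thr, clusters = clusters,
                 max_null = null_max, fwe_p = fwe_p,
                 any_significant = any(clusters$significant)),
            class = "group_result")
}

#' Bonferroni correction across networks
#'
#' @param p cluster-level corrected p-value(s) in [0, 1].
#' @param n_networks number of networks tested (default 6, threshold
#'   0.05 / 6 = 0.0083).
#' @param alpha family alpha, default 0.05.
#' @return list: \code{threshold} (rounded to 4 decimals for reporting),
#'   \code{survives} logical vector.
#' @export
bonferroni_networks <- function(p, n_networks = 6L, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  thr <- alpha / n_networks
  list(threshold = round(thr, 4), survives = p < thr)
}

#' Group test on an inter-network connectivity value
#'
#' One-tailed pooled-variance two-sample t-test of subjects' Fisher-z
#' connectivity for one network pair, high vs low performers
#' (df = n1 + n2 - 2). A Bonferroni threshold across the tested pairs is
#' reported alongside.
#'
#' @param z numeric vector of per-subject Fisher-z values.
#' @param groups "high"/"low" per subject.
#' @param tail "high_greater" (default) or "low_greater".
#' @param n_pairs number of pairs tested for the Bonferroni threshold
#'   (default 5, threshold 0.01).
#' @param alpha family alpha, default 0.05.
#' @return list: \code{t}, \code{df}, \code{p} (one-tailed),
#'   \code{mean_high}, \code{mean_low}, \code{bonferroni_threshold},
#'   \code{survives_bonferroni}.
#' @export
internetwork_group_test <- function(z, groups,
                                    tail = c("high_greater", "low_greater"),
                                    n_pairs = 5L, alpha = 0.05) {
  tail <- match.arg(tail)
  groups <- factor(groups, levels = c("high", "low"))
  z1 <- z[groups == "high"]
  z2 <- z[groups == "low"]
  if (length(z1) < 2 || length(z2) < 2) stop("both groups need >= 2 subjects")
  n1 <- length(z1); n2 <- length(z2)
  sp2 <- ((n1 - 1) * stats::var(z1) + (n2 - 1) * stats::var(z2)) / (n1 + n2 - 2)
  t_stat <- (mean(z1) - mean(z2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- if (tail == "high_greater") stats::pt(t_stat, df, lower.tail = FALSE)
       else stats::pt(t_stat, df)
  thr <- alpha / n_pairs
  list(t = t_stat, df = df, p = p, mean_high = mean(z1), mean_low = mean(z2),
       bonferroni_threshold = thr, survives_bonferroni = p < thr)
}

#' Network connectivity summary scalar per subject
#'
#' Reduces each subject's Z-map to one number over a network mask: either
#' the in-mask average or the eigenvariate (first principal-component score
#' of the subjects x voxels matrix, sign-aligned with the mean scalar).
#'
#' @param zmaps subjects x voxels matrix or list of 3D arrays.
#' @param mask logical 3D array (or vector) selecting the network voxels.
#' @param method "mean" or "eigenvariate".
#' @return numeric vector, one value per subject.
#' @export
intra_network_scalar <- function(zmaps, mask,
                                 method = c("mean", "eigenvariate")) {
  method <- match.arg(method)
  if (is.list(zmaps)) zmaps <- do.call(rbind, lapply(zmaps, as.vector))
  mvec <- as.logical(mask)
  if (!any(mvec)) stop("empty network mask")
  Z <- zmaps[, mvec, drop = FALSE]
  m <- rowMeans(Z)
  if (method == "mean") return(m)
  s <- svd(scale(Z, scale = FALSE), nu = 1, nv = 0)
  ev <- s$u[, 1] * s$d[1]
  if (stats::cor(ev, m) < 0) ev <- -ev
  ev
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of x and y on the control
#' variables (plus intercept); p-value from
#' t = r sqrt((n - 3) / (1 - r^2)) with df = n - 3 (single control).
#'
#' @param x,y numeric vectors.
#' @param control numeric vector/matrix of control variables.
#' @return list: \code{r}, \code{p} (two-sided), \code{df}.
#' @export
partial_correlation <- function(x, y, control) {
  control <- as.matrix(control)
  n <- length(x)
  if (n <= 3) stop("need more than 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input")
  X <- cbind(1, control)
  rx <- stats::lsfit(X, x, intercept = FALSE)$residuals
  ry <- stats::lsfit(X, y, intercept = FALSE)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 2 - ncol(control)
  t_stat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t_stat), df), df = df)
}
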