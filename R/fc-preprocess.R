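# Reshape a 4D array to a T x V matrix and back.
img_to_matrix <- function(img) {
  d <- dim(img)
  stopifnot(length(d) == 4)
  t(matrix(img, nrow = prod(d[1:3]), ncol = d[4]))
}
matrix_to_img <- function(Y, grid, tr = NULL) {
  img <- array(t(Y), dim = c(grid, nrow(Y)))
  if (!is.null(tr)) attr(img, "tr") <- tr
  img
}

#' Nuisance regression
#'
#' Removes nuisance signals (head motion parameters, tissue and global
#' signals, drift regressors, ...) from every voxel's time series by
#' ordinary least squares: the output is the per-voxel residual of the
#' series regressed on the confounds plus an intercept. Residuals are
#' exactly orthogonal to the confound columns.
#'
#' @param img 4D array (x, y, z, t).
#' @param confounds t x k data.frame or matrix of confound time series
#'   (NULL or zero columns: only the intercept, i.e. demeaning).
#' @return 4D array of residuals, same dimensions, TR attribute preserved.
#' @export
nuisance_regress <- function(img, confounds = NULL) {
  Y <- img_to_matrix(img)
  if (anyNA(Y)) stop("image contains NA values")
  X <- matrix(1, nrow(Y), 1, dimnames = list(NULL, "intercept"))
  if (!is.null(confounds) && NCOL(confounds) > 0) {
    if (NROW(confounds) != nrow(Y))
      stop("confounds have ", NROW(confounds), " rows but image has ",
           nrow(Y), " volumes")
    X <- cbind(X, as.matrix(confounds))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("confound matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  resid <- Y - X %*% qr.coef(qx, Y)
  matrix_to_img(resid, dim(img)[1:3], attr(img, "tr"))
}

# 1D Gaussian convolution matrix with reflective boundary handling;
# rows sum to 1, so constant signals (and the image total) are preserved.
gaussian_band <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    # reflect: 0 -> 1, -1 -> 2, n+1 -> n, n+2 -> n-1 ...
    idx <- ifelse(idx < 1, 1 - idx, idx)
    idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    for (j in seq_along(idx)) K[i, idx[j]] <- K[i, idx[j]] + k[j]
  }
  K
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian smoothing of every volume with a kernel of the given
#' full width at half maximum; sigma = fwhm / (2 sqrt(2 log 2)) per axis.
#' Boundaries are handled by reflection, which conserves the total image
#' sum exactly.
#'
#' @param img 4D array (x, y, z, t) or 3D array.
#' @param fwhm_mm kernel FWHM in mm (0 = identity).
#' @param voxel_size_mm voxel edge length in mm (> 0), default 2.
#' @return smoothed array of identical dimensions.
#' @export
smooth_image <- function(img, fwhm_mm, voxel_size_mm = 2) {
  if (voxel_size_mm <= 0) stop("voxel size must be positive")
  if (fwhm_mm < 0) stop("fwhm must be nonnegative")
  if (fwhm_mm == 0) return(img)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(img)
  is3d <- length(d) == 3
  if (is3d) { dim(img) <- c(d, 1); d <- dim(img) }
  Ks <- lapply(d[1:3], gaussian_band, sigma_vox = sigma)
  out <- img
  for (t_i in seq_len(d[4])) {
    vol <- out[, , , t_i]
    # axis 1
    vol <- array(Ks[[1]] %*% matrix(vol, d[1]), d[1:3])
    # axis 2
    vol <- aperm(array(Ks[[2]] %*% matrix(aperm(vol, c(2, 1, 3)), d[2]),
                       d[c(2, 1, 3)]), c(2, 1, 3))
    # axis 3
    vol <- aperm(array(Ks[[3]] %*% matrix(aperm(vol, c(3, 1, 2)), d[3]),
                       d[c(3, 1, 2)]), c(2, 3, 1))
    out[, , , t_i] <- vol
  }
  if (is3d) dim(out) <- d[1:3]
  out
}

#' Head-motion quality control
#'
#' Summarises a t x 6 realignment-parameter table (3 translations in mm, 3
#' rotations in degrees) into the exclusion metrics: cumulative
#' translation/rotation (maximum Euclidean displacement from the first
#' volume) and mean volume-to-volume translation/rotation. A subject is
#' flagged for exclusion if cumulative translation or rotation exceeds 3 mm
#' or 3 degrees, or mean volume-to-volume translation or rotation exceeds
#' 0.15 mm or 0.1 degrees (all thresholds configurable).
#'
#' @param motion t x 6 matrix or data.frame: translations x/y/z (mm) then
#'   rotations x/y/z (degrees).
#' @param thresholds named list overriding \code{cum_trans} (3),
#'   \code{cum_rot} (3), \code{mean_trans} (0.15), \code{mean_rot} (0.1).
#' @return list of class \code{qc_record}: the four metrics, per-rule flags
#'   and the overall \code{exclude} flag.
#' @export
motion_qc <- function(motion, thresholds = list()) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop("motion table must have 6 columns (3 translations, 3 rotations)")
  th <- utils::modifyList(list(cum_trans = 3, cum_rot = 3,
                               mean_trans = 0.15, mean_rot = 0.1),
                          thresholds)
  trans <- motion[, 1:3, drop = FALSE]
  rot <- motion[, 4:6, drop = FALSE]
  disp <- function(m) sqrt(rowSums(sweep(m, 2, m[1, ])^2))
  step <- function(m) if (nrow(m) < 2) 0 else
    mean(sqrt(rowSums(diff(m)^2)))
  rec <- list(cum_trans = max(disp(trans)), cum_rot = max(disp(rot)),
              mean_trans = step(trans), mean_rot = step(rot))
  rec$flags <- c(cum_trans = rec$cum_trans > th$cum_trans,
                 cum_rot = rec$cum_rot > th$cum_rot,
                 mean_trans = rec$mean_trans > th$mean_trans,
                 mean_rot = rec$mean_rot > th$mean_rot)
  rec$exclude <- any(rec$flags)
  rec$thresholds <- th
  class(rec) <- "qc_record"
  rec
}

#' Temporal signal-to-noise ratio
#'
#' Voxelwise temporal mean divided by temporal SD, plus the in-mask average
#' as the subject-level scalar. Voxels with zero temporal variance are
#' excluded from the average and counted.
#'
#' @param img 4D array.
#' @param mask optional logical 3D array; default: all voxels.
#' @return list: \code{scalar} (mask mean tSNR), \code{map} (3D array, NA
#'   outside mask / at zero-variance voxels), \code{n_zero_variance}.
#' @export
tsnr <- function(img, mask = NULL) {
  d <- dim(img)
  Y <- img_to_matrix(img)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mu <- colMeans(Y)
  s <- apply(Y, 2, stats::sd)
  val <- ifelse(s > 0, mu / s, NA)
  val[!as.logical(mask)] <- NA
  map <- array(val, d[1:3])
  list(scalar = mean(val, na.rm = TRUE), map = map,
       n_zero_variance = sum(s == 0 & as.logical(mask)))
}

#' Flag extreme values at the 5th percentiles
#'
#' Marks values above the upper or below the lower 5th percentile of their
#' empirical distribution -- the rule used to screen subjects on tSNR,
#' mean volume-to-volume motion and outlier-volume proportion.
#'
#' @param x numeric vector.
#' @param tail "both" (default), "lower" or "upper".
#' @return logical vector, TRUE = extreme.
#' @export
flag_extremes <- function(x, tail = c("both", "lower", "upper")) {
  tail <- match.arg(tail)
  lo <- stats::quantile(x, 0.05, na.rm = TRUE, names = FALSE)
  hi <- stats::quantile(x, 0.95, na.rm = TRUE, names = FALSE)
  switch(tail,
         both = x < lo | x > hi,
         lower = x < lo,
         upper = x > hi)
}
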