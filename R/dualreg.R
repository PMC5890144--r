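#' Two-stage dual regression
#'
#' Estimates subject-specific versions of a set of group spatial maps.
#' Stage 1 (spatial regression): every volume is regressed on all G group
#' maps jointly (plus intercept), giving a t x G matrix of subject time
#' courses -- each network's time course controlling for all others.
#' Stage 2 (temporal regression): every voxel's series is regressed on the
#' G variance-normalised stage-1 time courses jointly (plus intercept); the
#' per-voxel coefficients are standardised by the residual noise, yielding
#' one Z-map per component.
#'
#' @param img subject 4D array.
#' @param group_maps 4D array (grid x G) of group component maps.
#' @param mask optional logical 3D array.
#' @return list of class \code{dual_regression}: \code{timecourses}
#'   (t x G), \code{zmaps} (grid x G array, 0 outside the mask),
#'   \code{betas} (raw stage-2 coefficients, same shape).
#' @export
dual_regression <- function(img, group_maps, mask = NULL) {
  grid <- dim(img)[1:3]
  if (!all(dim(group_maps)[1:3] == grid))
    stop("group maps are not on the image grid")
  G <- dim(group_maps)[4]
  Tn <- dim(img)[4]
  if (Tn < G + 1) stop("need at least G+1 timepoints for dual regression")
  if (is.null(mask)) mask <- array(TRUE, grid)
  mvec <- as.logical(mask)
  Y <- img_to_matrix(img)[, mvec, drop = FALSE]      # T x V
  M <- matrix(group_maps, ncol = G)[mvec, , drop = FALSE]  # V x G
  if (kappa(crossprod(scale(M, scale = FALSE))) > 1e8)
    stop("group maps are (near-)collinear over the mask")
  # stage 1: volumes on maps
  X1 <- cbind(1, M)
  tcs <- t(qr.coef(qr(X1), t(Y)))[, -1, drop = FALSE]  # T x G
  # stage 2: voxel series on variance-normalised time courses
  Xt <- scale(tcs)      # unit-SD columns
  X2 <- cbind(1, Xt)
  qx <- qr(X2)
  B <- qr.coef(qx, Y)                        # (G+1) x V
  resid <- Y - X2 %*% B
  df <- Tn - ncol(X2)
  sigma <- sqrt(colSums(resid^2) / df)
  XtXinv <- chol2inv(chol(crossprod(X2)))
  se_scale <- sqrt(diag(XtXinv))[-1]
  B2 <- B[-1, , drop = FALSE]
  Z <- B2 / outer(se_scale, sigma)
  # exact fits (zero residual noise): infinite Z where the coefficient is
  # nonzero, zero where the voxel carries no signal at all
  zero <- sigma == 0
  if (any(zero))
    Z[, zero] <- ifelse(B2[, zero, drop = FALSE] == 0, 0,
                        sign(B2[, zero, drop = FALSE]) * Inf)
  zmaps <- matrix(0, prod(grid), G)
  zmaps[mvec, ] <- t(Z)
  betas <- matrix(0, prod(grid), G)
  betas[mvec, ] <- t(B2)
  structure(list(timecourses = tcs,
                 zmaps = array(zmaps, c(grid, G)),
                 betas = array(betas, c(grid, G)),
                 df = df),
            class = "dual_regression")
}

#' Inter-network functional connectivity matrix
#'
#' Fisher r-to-z transformed Pearson correlations among a selection of
#' stage-1 network time courses. Correlations at +/-1 are capped at
#' 1 - 1e-15 in absolute value and flagged.
#'
#' @param timecourses t x G matrix of stage-1 time courses.
#' @param selection integer indices of the networks of interest (default:
#'   all columns).
#' @return matrix of atanh(r) with NA diagonal; attribute \code{"capped"}
#'   is a logical matrix marking capped entries.
#' @export
internetwork_fc <- function(timecourses, selection = NULL) {
  tcs <- as.matrix(timecourses)
  if (nrow(tcs) < 3) stop("need at least 3 timepoints")
  if (!is.null(selection)) tcs <- tcs[, selection, drop = FALSE]
  if (any(apply(tcs, 2, stats::sd) == 0))
    stop("constant time course in selection")
  r <- stats::cor(tcs)
  capped <- abs(r) >= 1 - 1e-15
  diag(capped) <- FALSE
  r[capped] <- sign(r[capped]) * (1 - 1e-15)
  z <- atanh(r)
  diag(z) <- NA
  attr(z, "capped") <- capped
  z
}
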