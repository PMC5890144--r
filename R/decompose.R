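# Incremental group PCA over subjects (MIGP-style): maintain a running
# m-row basis of the top temporal subspace while concatenating subjects, so
# the full T_total x V matrix is never formed. Returns the top n_keep
# principal rows (n_keep x V).
incremental_pca <- function(mats, n_keep) {
  W <- NULL
  m <- min(2L * n_keep + 10L, sum(vapply(mats, nrow, 0L)))
  for (Y in mats) {
    A <- rbind(W, Y)
    k <- min(m, nrow(A))
    e <- eigen(tcrossprod(A), symmetric = TRUE)
    U <- e$vectors[, seq_len(k), drop = FALSE]
    W <- crossprod(U, A)   # rows scaled by singular values
  }
  W[seq_len(min(n_keep, nrow(W))), , drop = FALSE]
}

# Symmetric fixed-point ICA with the logcosh (tanh) contrast on whitened
# spatial data X (G x V, rows uncorrelated, unit variance). Deterministic
# given the seed used for the initial rotation.
fixed_point_ica <- function(X, seed = 1L, max_iter = 400L, tol = 1e-4) {
  G <- nrow(X)
  V <- ncol(X)
  W <- with_seed(seed, matrix(stats::rnorm(G * G), G, G))
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  achieved <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- W %*% X
    gwx <- tanh(WX)
    gp <- rowMeans(1 - gwx^2)
    W1 <- gwx %*% t(X) / V - diag(gp) %*% W
    W1 <- orth(W1)
    achieved <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (achieved < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fixed-point ICA did not converge: achieved tolerance ",
            signif(achieved, 3), " after ", max_iter, " iterations")
  S <- W %*% X
  # sign convention: positive skewness per map
  sk <- rowMeans(S^3)
  S <- S * sign(ifelse(sk == 0, 1, sk))
  list(S = S, W = W, converged = converged, achieved_tol = achieved)
}

#' Group spatial decomposition (PCA + spatial ICA)
#'
#' Decomposes temporally concatenated multi-subject data into G spatially
#' independent group maps: per-voxel variance normalisation, incremental
#' principal-component reduction of the concatenated time dimension to G
#' components, then a fixed-point negentropy-maximising rotation to
#' spatially independent maps (logcosh contrast, symmetric
#' decorrelation), with each map's sign fixed so its skewness is positive.
#' Group time courses are obtained by regressing each subject's data on the
#' maps and concatenating.
#'
#' @param images named list of 4D arrays on a common grid.
#' @param G number of components (default 20).
#' @param seed integer seed for the ICA initial rotation (deterministic).
#' @param mask optional logical 3D array.
#' @return list of class \code{component_set}: \code{maps} (4D array,
#'   grid x G, z-scored in-mask), \code{timecourses} (T_total x G),
#'   \code{G}, \code{mask}, \code{ica} (convergence diagnostics).
#' @export
group_decompose <- function(images, G = 20L, seed = 1L, mask = NULL) {
  stopifnot(length(images) >= 1)
  grid <- dim(images[[1]])[1:3]
  for (im in images)
    if (!all(dim(im)[1:3] == grid)) stop("images are not on a common grid")
  if (is.null(mask)) mask <- array(TRUE, grid)
  mvec <- as.logical(mask)
  total_t <- sum(vapply(images, function(im) dim(im)[4], 0L))
  if (total_t <= G) stop("total timepoints must exceed G")
  # variance-normalise each subject's voxel series, drop the mean
  mats <- lapply(images, function(im) {
    Y <- img_to_matrix(im)[, mvec, drop = FALSE]
    Y <- scale(Y)
    Y[is.na(Y)] <- 0
    Y
  })
  P <- incremental_pca(mats, G)           # G x V, rows orthogonal
  X <- P / sqrt(rowMeans(P^2))            # whiten spatially: unit-variance rows
  ica <- fixed_point_ica(X, seed = seed)
  S <- ica$S
  maps <- matrix(0, prod(grid), G)
  maps[mvec, ] <- t(S)
  dim(maps) <- c(grid, G)
  tcs <- do.call(rbind, lapply(mats, function(Y) {
    qr.coef(qr(cbind(1, t(S))), t(Y))[-1, , drop = FALSE]
  }))
  structure(list(maps = maps, timecourses = t(tcs), G = G, mask = mask,
                 ica = ica[c("converged", "achieved_tol")]),
            class = "component_set")
}

#' Match component maps to network templates
#'
#' Pearson spatial cross-correlation between every component map and every
#' template over the in-mask voxels, followed by greedy one-to-one
#' assignment in order of descending |r|.
#'
#' @param components a \code{component_set} (or 4D array of maps).
#' @param templates 4D array (grid x n_templates) on the same grid.
#' @param mask optional logical 3D array.
#' @return data.frame, one row per template: \code{template},
#'   \code{component}, \code{r}; attribute \code{"cor_matrix"} holds the
#'   full component x template correlation matrix.
#' @export
match_templates <- function(components, templates, mask = NULL) {
  maps <- if (inherits(components, "component_set")) components$maps
          else components
  if (!all(dim(maps)[1:3] == dim(templates)[1:3]))
    stop("components and templates are not on the same grid")
  grid <- dim(maps)[1:3]
  if (is.null(mask))
    mask <- if (inherits(components, "component_set")) components$mask
            else array(TRUE, grid)
  mvec <- as.logical(mask)
  Gm <- dim(maps)[4]
  Gt <- dim(templates)[4]
  M <- matrix(maps, ncol = Gm)[mvec, , drop = FALSE]
  Tm <- matrix(templates, ncol = Gt)[mvec, , drop = FALSE]
  R <- stats::cor(M, Tm)
  # greedy assignment by descending |r|
  Rw <- abs(R)
  assign <- data.frame(template = integer(), component = integer(),
                       r = numeric())
  while (nrow(assign) < min(Gm, Gt)) {
    ij <- arrayInd(which.max(Rw), dim(Rw))
    assign <- rbind(assign, data.frame(template = ij[2], component = ij[1],
                                       r = R[ij[1], ij[2]]))
    Rw[ij[1], ] <- -Inf
    Rw[, ij[2]] <- -Inf
  }
  assign <- assign[order(assign$template), ]
  rownames(assign) <- NULL
  attr(assign, "cor_matrix") <- R
  assign
}
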