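#' Synthetic network spatial templates
#'
#' Generates G smooth, nonnegative, unit-peak spatial maps on a voxel grid,
#' standing in for intrinsic-network templates. Each template is a cluster
#' of Gaussian blobs around a centre; centres are spread over the grid so
#' that pairwise spatial correlations stay below \code{max_r}. These are
#' synthetic stand-ins for published network atlases, not derived from any
#' real parcellation.
#'
#' @param grid integer vector (nx, ny, nz), default c(24, 24, 12).
#' @param G number of templates (>= 2), default 6.
#' @param seed integer seed; output is a pure function of (arguments, seed).
#' @param sigma blob width in voxels (Gaussian SD), default 2.
#' @param n_blobs satellite blobs per template, default 2.
#' @param max_r maximum allowed pairwise spatial correlation, default 0.3.
#' @param max_tries re-draw attempts before failing, default 20.
#' @return array of dim c(grid, G), each map nonnegative with peak 1.
#' @export
make_network_templates <- function(grid = c(24L, 24L, 12L), G = 6L,
                                   seed = 1L, sigma = NULL, n_blobs = 2L,
                                   max_r = 0.3, max_tries = 40L) {
  stopifnot(G >= 2, length(grid) == 3, all(grid >= 6))
  # blob width scales with the grid so small test grids stay separable
  if (is.null(sigma)) sigma <- max(1, min(grid) / 6)
  coords <- as.matrix(expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                                  z = seq_len(grid[3])))
  blob <- function(centre, s) {
    d2 <- (coords[, 1] - centre[1])^2 + (coords[, 2] - centre[2])^2 +
      (coords[, 3] - centre[3])^2
    exp(-d2 / (2 * s^2))
  }
  with_seed(seed, {
    for (attempt in seq_len(max_tries)) {
      # late attempts shrink the blobs to reduce overlap
      if (attempt > max_tries / 2) sigma <- sigma * 0.9
      maps <- matrix(0, nrow(coords), G)
      # centres: jittered positions on a coarse lattice, spread apart
      centres <- cbind(stats::runif(G, 0.15, 0.85) * grid[1],
                       stats::runif(G, 0.15, 0.85) * grid[2],
                       stats::runif(G, 0.2, 0.8) * grid[3])
      for (g in seq_len(G)) {
        m <- blob(centres[g, ], sigma)
        for (b in seq_len(n_blobs)) {
          off <- stats::rnorm(3, 0, sigma * 1.5)
          m <- m + stats::runif(1, 0.4, 0.8) * blob(centres[g, ] + off, sigma)
        }
        maps[, g] <- m / max(m)
      }
      r <- stats::cor(maps)
      if (max(abs(r[upper.tri(r)])) < max_r) {
        dim(maps) <- c(grid, G)
        return(maps)
      }
    }
  })
  stop("could not place ", G, " templates with pairwise spatial |r| < ",
       max_r, " on this grid")
}
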