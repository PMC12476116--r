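`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(ok, msg, field = NULL) {
  if (!isTRUE(ok)) {
    if (!is.null(field)) msg <- sprintf("invalid field '%s': %s", field, msg)
    stop(msg, call. = FALSE)
  }
}

# Derive a reproducible 31-bit sub-stream seed from a base seed and stream
# labels; keeps every seed handed to set.seed() inside R's integer range.
#' @noRd
.substream_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483646L + 1L)
}

# Pairwise Euclidean distances between rows.
#' @noRd
.pdist <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Cholesky factor of an exponential-covariance kernel over coordinates;
# reused to draw many Gaussian random fields on the same support.
#' @noRd
.gp_chol <- function(coords, length_scale, nugget = 1e-8) {
  K <- exp(-.pdist(coords) / length_scale)
  diag(K) <- diag(K) + nugget
  chol(K)
}

# n_draws smooth standard fields over coords (columns), given a
# precomputed Cholesky factor or a length scale.
#' @noRd
.gp_draw <- function(coords, length_scale, n_draws, L = NULL) {
  if (is.null(L)) L <- .gp_chol(coords, length_scale)
  crossprod(L, matrix(rnorm(ncol(L) * n_draws), ncol(L), n_draws))
}

#' Empirical variogram of a regional map
#'
#' Semivariance `0.5 * (x_i - x_j)^2` of value pairs binned by the distance
#' between their region centroids. Used to check that generated maps carry
#' spatial autocorrelation and to calibrate surrogate maps.
#'
#' @param x numeric vector, one value per region.
#' @param coords numeric matrix of region centroid coordinates (mm).
#' @param n_bins number of equal-width distance bins.
#' @return data frame with columns `distance` (bin midpoint), `gamma`
#'   (mean semivariance) and `n_pairs`.
#' @export
empirical_variogram <- function(x, coords, n_bins = 10) {
  .assert(length(x) == nrow(as.matrix(coords)), "x and coords disagree in length")
  D <- .pdist(coords)
  iu <- upper.tri(D)
  d <- D[iu]
  g <- 0.5 * outer(x, x, "-")[iu]^2
  br <- seq(0, max(d), length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE, labels = FALSE)
  data.frame(
    distance = (br[-1] + br[-(n_bins + 1)]) / 2,
    gamma = as.numeric(tapply(g, factor(bin, levels = seq_len(n_bins)), mean)),
    n_pairs = as.numeric(table(factor(bin, levels = seq_len(n_bins))))
  )
}

# Least-squares fit of the exponential variogram model
# gamma(d) = s * (1 - exp(-d / l)) by grid search over l.
#' @noRd
.fit_length_scale <- function(x, coords, n_bins = 10) {
  vg <- empirical_variogram(x, coords, n_bins)
  vg <- vg[vg$n_pairs > 0 & is.finite(vg$gamma), , drop = FALSE]
  dmax <- max(vg$distance)
  cand <- exp(seq(log(dmax / 50), log(dmax), length.out = 40))
  sse <- vapply(cand, function(l) {
    b <- 1 - exp(-vg$distance / l)
    s <- sum(vg$gamma * b) / sum(b^2)
    sum((vg$gamma - s * b)^2)
  }, numeric(1))
  cand[which.min(sse)]
}

# Half-neighborhood offsets for grid connectivity (each undirected pair once).
#' @noRd
.conn_offsets <- function(connectivity = 26) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  else .assert(connectivity == 26, "connectivity must be 6 or 26")
  keep <- off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 | (off[, 2] == 0 & off[, 1] > 0)))
  off[keep, , drop = FALSE]
}

# Edge list (positions into `coords` rows) linking grid-adjacent voxels
# among the supplied voxel coordinates.
#' @noRd
.grid_edges <- function(coords, dims, connectivity = 26) {
  n <- nrow(coords)
  if (n < 2) return(matrix(integer(0), 0, 2))
  key <- (coords[, 1] - 1) + (coords[, 2] - 1) * dims[1] +
    (coords[, 3] - 1) * dims[1] * dims[2]
  off <- .conn_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- coords + matrix(off[r, ], n, 3, byrow = TRUE)
    inb <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nbkey <- (nb[, 1] - 1) + (nb[, 2] - 1) * dims[1] + (nb[, 3] - 1) * dims[1] * dims[2]
    hit <- match(nbkey, key)
    ok <- inb & !is.na(hit)
    from <- c(from, which(ok)); to <- c(to, hit[ok])
  }
  cbind(from, to)
}
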