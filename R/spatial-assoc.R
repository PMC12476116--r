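#' Reduce a voxel statistic map to region means
#'
#' @param values numeric vector over voxels (e.g. the `t` field of a
#'   `stat_map`, aligned with the panel's voxel columns).
#' @param region_id integer region label per voxel (1..R, 0 = unassigned).
#' @param n_regions number of regions; defaults to `max(region_id)`.
#' @return numeric vector of length `n_regions` with the mean value per
#'   region (`NA` for empty regions).
#' @export
parcellate <- function(values, region_id, n_regions = max(region_id)) {
  .assert(length(values) == length(region_id), "values and region_id lengths differ")
  keep <- region_id > 0
  as.numeric(tapply(values[keep], factor(region_id[keep], levels = seq_len(n_regions)),
                    mean))
}

#' Partial spatial correlation of two regional maps
#'
#' Pearson correlation between the residuals of `x` and `y` after each
#' is regressed (with intercept) on the adjustment map `z`, typically
#' the regional gray-matter probability. With `z = NULL` this is the
#' plain Pearson correlation.
#'
#' @param x,y numeric regional vectors.
#' @param z optional adjustment vector or matrix of vectors.
#' @return partial correlation coefficient.
#' @export
partial_spatial_corr <- function(x, y, z = NULL) {
  .assert(length(x) == length(y), "x and y lengths differ")
  if (is.null(z)) return(cor(x, y))
  Z <- cbind(1, as.matrix(z))
  rx <- .lm.fit(Z, x)$residuals
  ry <- .lm.fit(Z, y)$residuals
  # a map fully explained by the adjustment map has no partial association
  if (sd(rx) <= 1e-12 * max(sd(x), 1) || sd(ry) <= 1e-12 * max(sd(y), 1))
    return(0)
  cor(rx, ry)
}

#' Variogram-matched surrogate maps
#'
#' Generates randomized copies of a regional map that preserve its exact
#' value distribution (every surrogate is a permutation of the observed
#' values) while approximately preserving its spatial autocorrelation:
#' a Gaussian random field with exponential covariance over the region
#' centroids is drawn, and the sorted observed values are assigned in
#' the rank order of the field. The field's length scale is fitted to
#' the observed map's empirical variogram unless supplied.
#'
#' @param x numeric regional map.
#' @param centroids region centroid coordinates (mm), one row per region.
#' @param n_surr number of surrogates.
#' @param seed integer seed.
#' @param length_scale exponential-covariance length scale in mm;
#'   `NULL` fits it to `x`'s variogram.
#' @return matrix with one surrogate per column (`length(x)` x `n_surr`).
#' @export
surrogate_maps <- function(x, centroids, n_surr, seed = 1, length_scale = NULL) {
  centroids <- as.matrix(centroids)
  .assert(length(x) == nrow(centroids), "one centroid row per region", "centroids")
  .assert(n_surr >= 1, "n_surr must be positive", "n_surr")
  if (is.null(length_scale)) length_scale <- .fit_length_scale(x, centroids)
  L <- .gp_chol(centroids, length_scale)
  set.seed(seed)
  fields <- .gp_draw(centroids, length_scale, n_surr, L = L)
  xs <- sort(x)
  out <- apply(fields, 2, function(f) xs[rank(f, ties.method = "first")])
  dimnames(out) <- NULL
  out
}

#' Spatial association of a map with an annotation family
#'
#' Correlates a regional statistic map with each map of a family
#' (neurotransmitter or behavioral-domain maps), optionally partialling
#' out an adjustment vector (gray-matter probability), and computes a
#' two-sided permutation p value against autocorrelation-preserving
#' surrogates of `x`, then Benjamini-Hochberg FDR across the family.
#'
#' @param x regional statistic vector (length R >= 10).
#' @param maps numeric R x k matrix of annotation maps (columns named).
#' @param z optional adjustment vector (e.g. gray-matter probability).
#' @param centroids region centroid coordinates, required unless
#'   `surrogates` is supplied.
#' @param n_surr number of surrogate maps.
#' @param seed integer seed.
#' @param surrogates optional precomputed surrogate matrix from
#'   [surrogate_maps()]; overrides `n_surr`/`seed`.
#' @param length_scale passed to [surrogate_maps()].
#' @return data frame with columns `map`, `r`, `p_perm`, `p_fdr`.
#' @export
assoc_test <- function(x, maps, z = NULL, centroids = NULL, n_surr = 1000,
                       seed = 1, surrogates = NULL, length_scale = NULL) {
  maps <- as.matrix(maps)
  .assert(length(x) >= 10, "need at least 10 regions for a stable correlation")
  .assert(nrow(maps) == length(x), "maps must have one row per region", "maps")
  if (is.null(surrogates)) {
    .assert(!is.null(centroids), "supply either surrogates or centroids", "centroids")
    surrogates <- surrogate_maps(x, centroids, n_surr, seed, length_scale)
  }
  n_surr <- ncol(surrogates)
  resid_on <- function(M) {
    if (is.null(z)) return(scale(M, scale = FALSE))
    Z <- cbind(1, as.matrix(z))
    M - Z %*% .lm.fit(Z, M)$coefficients
  }
  mr <- resid_on(maps)
  xr <- drop(resid_on(matrix(x, ncol = 1)))
  sr <- resid_on(surrogates)
  r_obs <- drop(cor(xr, mr))
  r_null <- cor(sr, mr)                    # n_surr x k
  p_perm <- vapply(seq_along(r_obs), function(j)
    (1 + sum(abs(r_null[, j]) >= abs(r_obs[j]))) / (n_surr + 1), numeric(1))
  data.frame(map = colnames(maps) %||% paste0("map_", seq_along(r_obs)),
             r = r_obs, p_perm = p_perm,
             p_fdr = p.adjust(p_perm, method = "BH"),
             row.names = NULL)
}
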