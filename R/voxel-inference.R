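#' Subjects-by-voxels panel on a 3D grid
#'
#' Container pairing a numeric subjects x voxels matrix with the voxel
#' coordinates (1-based, columns x/y/z) of each column in a grid of the
#' given dimensions, so that cluster geometry can be reconstructed.
#'
#' @param data numeric matrix, subjects in rows, voxels in columns.
#' @param coords integer matrix, one row per voxel column.
#' @param dims integer length-3 grid dimensions.
#' @return object of class `voxel_panel`.
#' @export
voxel_panel <- function(data, coords, dims) {
  data <- as.matrix(data); coords <- as.matrix(coords)
  .assert(ncol(data) == nrow(coords), "one coordinate row per voxel column", "coords")
  .assert(length(dims) == 3 && all(dims >= 1), "dims must be length 3", "dims")
  .assert(all(coords >= 1) && all(coords <= matrix(dims, nrow(coords), 3, byrow = TRUE)),
          "coords outside grid", "coords")
  structure(list(data = data, coords = coords, dims = as.integer(dims)),
            class = "voxel_panel")
}

#' Subjects-by-voxels panel on a white-matter skeleton
#'
#' @param data numeric matrix, subjects in rows, skeleton voxels in columns.
#' @param edges integer matrix with two columns of 1-based voxel indices,
#'   one row per adjacency between skeleton voxels.
#' @param metric name of the diffusion metric carried (e.g. `"AD"`).
#' @return object of class `skeleton_panel`.
#' @export
skeleton_panel <- function(data, edges, metric = "AD") {
  data <- as.matrix(data); edges <- as.matrix(edges)
  .assert(ncol(edges) == 2, "edges must have two columns", "edges")
  if (nrow(edges))
    .assert(all(edges >= 1) && all(edges <= ncol(data)), "edge index out of range", "edges")
  structure(list(data = data, edges = edges, metric = metric),
            class = "skeleton_panel")
}

#' GLM design for mass-univariate association
#'
#' Builds the design matrix (intercept + regressor of interest +
#' nuisance covariates) and checks it is full rank with enough residual
#' degrees of freedom.
#'
#' @param subjects data frame of per-subject variables.
#' @param interest name of the regressor of interest (e.g. `"crp"`).
#' @param covariates character vector of nuisance covariate names.
#' @return list with elements `X` (design matrix), `interest` (column
#'   index of the regressor of interest) and `covariate_cols`.
#' @export
glm_design <- function(subjects, interest, covariates = character(0)) {
  .assert(interest %in% names(subjects), "regressor of interest not found", "interest")
  .assert(all(covariates %in% names(subjects)), "covariate not found", "covariates")
  vars <- c(interest, covariates)
  df <- subjects[, vars, drop = FALSE]
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(data.frame(lapply(df, as.numeric))))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  .assert(nrow(X) > ncol(X) + 2, "too few subjects for the design")
  list(X = X, interest = match(interest, colnames(X)), keep = keep,
       interest_name = interest)
}

# Shared machinery: residualize the regressor of interest and the data on
# the nuisance block, so permutation t maps reduce to cheap cross products
# (Freedman-Lane scheme).
#' @noRd
.glm_engine <- function(Y, design) {
  X <- design$X
  i <- design$interest
  Z <- X[, -i, drop = FALSE]
  Qz <- qr.Q(qr(Z))
  x <- X[, i]
  xres <- x - Qz %*% crossprod(Qz, x)
  cxx <- sum(xres^2)
  .assert(cxx > 1e-12, "regressor of interest is collinear with covariates")
  df <- nrow(X) - ncol(X)
  E <- Y - Qz %*% crossprod(Qz, Y)    # reduced-model residuals
  list(Qz = Qz, xres = xres, cxx = cxx, df = df, E = E,
       Ess = colSums(E^2))
}

# t map for (possibly permuted) reduced-model residuals.
#' @noRd
.glm_t <- function(eng, Ep) {
  b <- drop(crossprod(eng$xres, Ep)) / eng$cxx
  pz <- colSums(crossprod(eng$Qz, Ep)^2)
  rss <- pmax(colSums(Ep^2) - pz - b^2 * eng$cxx, 0)
  se <- sqrt(rss / eng$df / eng$cxx)
  list(t = b / pmax(se, .Machine$double.eps), beta = b, se = se)
}

#' Voxel-wise ordinary least squares with a regressor of interest
#'
#' Fits, for every voxel, `y ~ interest + covariates` and returns the t
#' statistic of the regressor of interest, its coefficient and standard
#' error, and the residual degrees of freedom.
#'
#' @param panel `voxel_panel`/`skeleton_panel` or plain subjects x voxels
#'   matrix; subjects with missing design variables are dropped listwise.
#' @param design output of [glm_design()].
#' @return object of class `stat_map`: list with `t`, `beta`, `se`, `df`
#'   and the interest name.
#' @export
fit_voxelwise_glm <- function(panel, design) {
  Y <- if (is.list(panel)) panel$data else as.matrix(panel)
  Y <- Y[design$keep, , drop = FALSE]
  .assert(all(is.finite(Y)), "panel contains missing values after listwise deletion")
  eng <- .glm_engine(Y, design)
  ft <- .glm_t(eng, Y)
  structure(list(t = ft$t, beta = ft$beta, se = ft$se, df = eng$df,
                 interest = design$interest_name),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map: %d voxels, df = %d, interest = %s, t range [%.3f, %.3f]\n",
              length(x$t), x$df, x$interest, min(x$t), max(x$t)))
  invisible(x)
}

# Freedman-Lane max-statistic permutation null. `stat_fun(tvals)` maps a
# t vector to the per-permutation summary (max cluster size, max TFCE...),
# returning a numeric vector (one entry per sign or statistic tracked).
#' @noRd
.fl_null <- function(Y, design, n_perm, seed, stat_fun) {
  eng <- .glm_engine(Y, design)
  n <- nrow(Y)
  set.seed(seed)
  t(vapply(seq_len(n_perm), function(p) {
    Ep <- eng$E[sample.int(n), , drop = FALSE]
    stat_fun(.glm_t(eng, Ep)$t)
  }, stat_fun(rep(0, ncol(Y)))))
}

# Cluster labels and sizes among suprathreshold voxels of a voxel panel.
#' @noRd
.clusters_at <- function(tvals, crit, coords, dims, connectivity, sign) {
  sup <- which(sign * tvals > crit)
  if (!length(sup)) return(NULL)
  ed <- .grid_edges(coords[sup, , drop = FALSE], dims, connectivity)
  lab <- .label_components_cpp(length(sup), ed)
  list(sup = sup, lab = lab, sizes = tabulate(lab))
}

#' Cluster-extent family-wise error inference by permutation
#'
#' Forms clusters of voxels whose t statistic exceeds the one-sided
#' cluster-defining threshold (separately for positive and negative
#' contrasts) and assigns each cluster a family-wise-error-corrected p
#' value from the permutation null distribution of the maximum cluster
#' extent. Nuisance covariates are handled with the Freedman-Lane scheme:
#' reduced-model residuals are permuted and the covariate fit added back.
#'
#' @param panel a [voxel_panel()].
#' @param design output of [glm_design()].
#' @param cluster_p one-sided cluster-defining voxel p value (default 0.001).
#' @param n_perm number of permutations (>= 100 recommended; must be >= 1).
#' @param connectivity 6 or 26 neighbor connectivity.
#' @param seed integer seed for the permutation stream.
#' @return list of class `cluster_result` with `clusters` (data frame:
#'   sign, size, peak voxel coordinates, peak t, `p_fwe`), `labels`
#'   (signed cluster labels per voxel, 0 = background), the `stat_map`,
#'   and the per-sign null maxima.
#' @export
cluster_fwe <- function(panel, design, cluster_p = 0.001, n_perm = 1000,
                        connectivity = 26, seed = 1) {
  .assert(inherits(panel, "voxel_panel"), "panel must be a voxel_panel", "panel")
  .assert(cluster_p > 0 && cluster_p < 1, "cluster_p must be in (0,1)", "cluster_p")
  .assert(n_perm >= 1, "n_perm must be a positive integer", "n_perm")
  stat <- fit_voxelwise_glm(panel, design)
  crit <- qt(1 - cluster_p, stat$df)
  Y <- panel$data[design$keep, , drop = FALSE]

  max_size <- function(tv) {
    vapply(c(1, -1), function(s) {
      cl <- .clusters_at(tv, crit, panel$coords, panel$dims, connectivity, s)
      if (is.null(cl)) 0 else max(cl$sizes)
    }, numeric(1))
  }
  null_max <- .fl_null(Y, design, n_perm, seed, max_size)

  labels <- integer(ncol(Y))
  rows <- list()
  for (s in c(1, -1)) {
    cl <- .clusters_at(stat$t, crit, panel$coords, panel$dims, connectivity, s)
    if (is.null(cl)) next
    nullv <- null_max[, if (s > 0) 1 else 2]
    for (k in seq_along(cl$sizes)) {
      mem <- cl$sup[cl$lab == k]
      labels[mem] <- s * (length(rows) + 1)
      pk <- mem[which.max(s * stat$t[mem])]
      rows[[length(rows) + 1]] <- data.frame(
        cluster = length(rows) + 1, sign = s, size = cl$sizes[k],
        peak_x = panel$coords[pk, 1], peak_y = panel$coords[pk, 2],
        peak_z = panel$coords[pk, 3], peak_t = stat$t[pk],
        p_fwe = (1 + sum(nullv >= cl$sizes[k])) / (n_perm + 1))
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), sign = numeric(0), size = integer(0),
               peak_x = integer(0), peak_y = integer(0), peak_z = integer(0),
               peak_t = numeric(0), p_fwe = numeric(0))
  clusters <- clusters[order(clusters$p_fwe, -clusters$size), , drop = FALSE]
  structure(list(clusters = clusters, labels = labels, stat = stat,
                 null_max = null_max, cluster_p = cluster_p, n_perm = n_perm),
            class = "cluster_result")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates `extent(h, v)^E * h^H` over thresholds `h = dh, 2dh, ...`
#' up to each voxel's statistic, where extent is the size of the
#' connected component containing the voxel among values >= h. Negative
#' input values contribute nothing (apply to `-t` for the negative
#' contrast).
#'
#' @param tvals numeric statistic per skeleton voxel.
#' @param edges adjacency edge list (two columns, 1-based indices).
#' @param E,H extent and height exponents (defaults 0.5 and 2).
#' @param dh integration step; default `max(tvals)/n_steps`.
#' @param n_steps number of integration steps when `dh` is `NULL`.
#' @return numeric TFCE score per voxel.
#' @export
tfce_transform <- function(tvals, edges, E = 0.5, H = 2, dh = NULL, n_steps = 100) {
  .assert(E > 0 && H > 0, "E and H must be positive")
  x <- pmax(as.numeric(tvals), 0)
  if (all(x == 0)) return(numeric(length(x)))
  if (is.null(dh)) dh <- max(x) / n_steps
  .assert(dh > 0, "dh must be positive", "dh")
  .tfce_cpp(x, as.matrix(edges), E, H, dh)
}

#' TFCE family-wise error inference on a skeleton panel
#'
#' Voxel-wise corrected p values for both contrast signs from the
#' permutation null of the maximum TFCE statistic (Freedman-Lane
#' permutation of reduced-model residuals).
#'
#' @param panel a [skeleton_panel()].
#' @param design output of [glm_design()].
#' @param E,H,n_steps TFCE parameters (see [tfce_transform()]); the step
#'   is set to `max/n_steps` of each map being enhanced.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list of class `tfce_result` with the `stat_map`, per-voxel
#'   TFCE scores and corrected p values for each sign (`p_pos`,
#'   `p_neg`), and the null maxima.
#' @export
tfce_fwe <- function(panel, design, E = 0.5, H = 2, n_steps = 100,
                     n_perm = 1000, seed = 1) {
  .assert(inherits(panel, "skeleton_panel"), "panel must be a skeleton_panel", "panel")
  .assert(n_perm >= 1, "n_perm must be a positive integer", "n_perm")
  stat <- fit_voxelwise_glm(panel, design)
  ed <- panel$edges
  enh <- function(tv) tfce_transform(tv, ed, E, H, n_steps = n_steps)
  tf_pos <- enh(stat$t)
  tf_neg <- enh(-stat$t)
  Y <- panel$data[design$keep, , drop = FALSE]
  null_max <- .fl_null(Y, design, n_perm, seed,
                       function(tv) c(max(enh(tv)), max(enh(-tv))))
  p_of <- function(tf, nullv)
    (1 + vapply(tf, function(v) sum(nullv >= v), numeric(1))) / (n_perm + 1)
  structure(list(stat = stat, tfce_pos = tf_pos, tfce_neg = tf_neg,
                 p_pos = p_of(tf_pos, null_max[, 1]),
                 p_neg = p_of(tf_neg, null_max[, 2]),
                 null_max = null_max, n_perm = n_perm,
                 params = list(E = E, H = H, n_steps = n_steps)),
            class = "tfce_result")
}

#' Per-subject mean signal within regions of interest
#'
#' @param panel panel object or subjects x voxels matrix.
#' @param roi either an integer label vector over voxels (0 = background;
#'   one ROI per distinct positive label) or a list of voxel index
#'   vectors.
#' @return numeric matrix, subjects x ROIs.
#' @export
extract_roi <- function(panel, roi) {
  Y <- if (is.list(panel) && !is.null(panel$data)) panel$data else as.matrix(panel)
  if (!is.list(roi)) {
    lv <- sort(unique(roi[roi > 0]))
    roi <- lapply(lv, function(l) which(roi == l))
    names(roi) <- paste0("roi_", lv)
  }
  .assert(length(roi) > 0, "no ROI supplied", "roi")
  out <- vapply(roi, function(idx) {
    .assert(length(idx) >= 1 && all(idx >= 1 & idx <= ncol(Y)),
            "ROI index out of range", "roi")
    rowMeans(Y[, idx, drop = FALSE])
  }, numeric(nrow(Y)))
  out <- matrix(out, nrow = nrow(Y),
                dimnames = list(NULL, names(roi) %||% paste0("roi_", seq_along(roi))))
  out
}
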