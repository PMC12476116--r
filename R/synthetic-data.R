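#' Specification of a synthetic two-group cohort
#'
#' Defines sample sizes, covariate distributions and planted effect
#' sizes for the synthetic cohort. Serum CRP is drawn log-normal
#' (clamped to 0.02-6.39 mg/L) to mimic the right-skewed distributions
#' typical of inflammation markers; default log-scale parameters match
#' a patient-group mean near 0.98 mg/L with SD near 1.27 mg/L. The
#' mediation structural model is `M = a * X + e` and
#' `Y = c' * X + b * M + covariate effects + e`, where X is
#' standardized log CRP and M is a latent mediator later embedded as
#' the planted-cluster BOLD amplitude, so that extracted cluster fALFF
#' acts as the mediator end to end.
#'
#' @param n_patients,n_controls group sizes (>= 4; defaults 120 / 118).
#' @param seed integer master seed; identical seeds reproduce every
#'   downstream output bit-identically.
#' @param crp_meanlog,crp_sdlog log-scale location and scale of CRP
#'   (mg/L); SDs must be positive.
#' @param crp_range clamp range for CRP in mg/L.
#' @param age_mean,age_sd,edu_mean,edu_sd length-2 (patients, controls)
#'   covariate distributions, years.
#' @param female_prop length-2 proportion of female subjects.
#' @param fd_mean,fd_sd frame-wise displacement (mm).
#' @param bmi_mean,bmi_sd body-mass index (kg/m^2).
#' @param beta_crp_falff standardized planted CRP effect on the
#'   low-frequency amplitude inside the seeded cluster (patients only).
#' @param beta_crp_ad standardized planted (negative) CRP effect on the
#'   skeleton diffusion metric in the planted strip.
#' @param a,b,c_prime standardized mediation path coefficients.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 120, n_controls = 118, seed = 1,
                        crp_meanlog = -0.513, crp_sdlog = 0.993,
                        crp_range = c(0.02, 6.39),
                        age_mean = c(42.89, 43.77), age_sd = c(11.03, 13.89),
                        female_prop = c(81 / 120, 79 / 118),
                        edu_mean = c(8.87, 11.64), edu_sd = c(3.66, 4.67),
                        fd_mean = 0.13, fd_sd = 0.05,
                        bmi_mean = 23, bmi_sd = 3.3,
                        beta_crp_falff = 0.6, beta_crp_ad = -0.6,
                        a = 0.5, b = 0.5, c_prime = 0) {
  spec <- list(n_patients = n_patients, n_controls = n_controls, seed = seed,
               crp_meanlog = crp_meanlog, crp_sdlog = crp_sdlog,
               crp_range = crp_range, age_mean = age_mean, age_sd = age_sd,
               female_prop = female_prop, edu_mean = edu_mean, edu_sd = edu_sd,
               fd_mean = fd_mean, fd_sd = fd_sd, bmi_mean = bmi_mean,
               bmi_sd = bmi_sd, beta_crp_falff = beta_crp_falff,
               beta_crp_ad = beta_crp_ad, a = a, b = b, c_prime = c_prime)
  .assert(n_patients >= 4, "need at least 4 patients", "n_patients")
  .assert(n_controls >= 4, "need at least 4 controls", "n_controls")
  .assert(is.numeric(seed) && length(seed) == 1, "seed must be a single integer", "seed")
  .assert(crp_sdlog > 0, "SD must be positive", "crp_sdlog")
  for (f in c("age_sd", "edu_sd", "fd_sd", "bmi_sd"))
    .assert(all(spec[[f]] > 0), "SD must be positive", f)
  .assert(all(female_prop >= 0 & female_prop <= 1), "must be in [0,1]", "female_prop")
  for (f in c("beta_crp_falff", "beta_crp_ad", "a", "b"))
    .assert(abs(spec[[f]]) < 1, "standardized effect must be in (-1,1)", f)
  structure(spec, class = "cohort_spec")
}

#' Specification of the synthetic acquisition grid
#'
#' @param shape voxel dimensions (length 3); default 24^3 resolves the
#'   cross-voxel geometry at desk scale.
#' @param voxel_size isotropic voxel size in mm.
#' @param tr repetition time in seconds.
#' @param n_timepoints number of BOLD timepoints (>= 64).
#' @param mask logical array of `shape`; default is a central sphere.
#' @param cluster_seed_voxels integer matrix of voxel coordinates (one
#'   row per voxel) where the CRP effect is planted; must lie inside
#'   the mask. Default: a 3x3x3 block near the mask center.
#' @return validated list of class `grid_spec`.
#' @export
grid_spec <- function(shape = c(24, 24, 24), voxel_size = 3, tr = 2,
                      n_timepoints = 200, mask = NULL,
                      cluster_seed_voxels = NULL) {
  .assert(length(shape) == 3 && all(shape >= 4), "shape must be length 3, >= 4", "shape")
  .assert(n_timepoints >= 64, "need at least 64 timepoints", "n_timepoints")
  .assert(tr > 0 && voxel_size > 0, "tr and voxel_size must be positive")
  if (is.null(mask)) {
    ctr <- (shape + 1) / 2
    g <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                               z = seq_len(shape[3])))
    r2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
    mask <- array(r2 <= (min(shape) * 0.45)^2, dim = shape)
  }
  .assert(all(dim(mask) == shape), "mask shape mismatch", "mask")
  .assert(any(mask), "mask is empty", "mask")
  if (is.null(cluster_seed_voxels)) {
    ctr <- round((dim(mask) + 1) / 2)
    cluster_seed_voxels <- as.matrix(expand.grid(
      x = ctr[1] + (-1:1), y = ctr[2] + (-1:1), z = ctr[3] + (-1:1)))
  }
  cluster_seed_voxels <- as.matrix(cluster_seed_voxels)
  inmask <- mask[cluster_seed_voxels]
  .assert(all(inmask), "cluster_seed_voxels must lie inside the mask",
          "cluster_seed_voxels")
  structure(list(shape = as.integer(shape), voxel_size = voxel_size, tr = tr,
                 n_timepoints = as.integer(n_timepoints), mask = mask,
                 cluster_seed_voxels = cluster_seed_voxels),
            class = "grid_spec")
}

#' Generate the per-subject phenotype and covariate table
#'
#' One row per subject with group label, serum CRP (mg/L, log-normal,
#' clamped to the spec range), demographic covariates, clinical scores
#' and the latent mediator. Within patients, standardized log CRP (X)
#' drives the latent mediator `m_latent = a X + sqrt(1-a^2) e`, and the
#' sustained-attention score `cpt` follows
#' `c' X + b m_latent - 0.1 z_age + 0.1 z_edu + noise`; controls get
#' the same covariate structure without the planted paths. A
#' depression-severity score (`hamd`) differs by group.
#'
#' @param spec a [cohort_spec()].
#' @return data frame of class `subject_table` with columns
#'   `subject_id`, `group` ("MDD"/"HC"), `crp`, `age`, `sex`
#'   (1 = female), `education`, `fd`, `bmi`, `hamd`, `cpt`, `m_latent`.
#' @export
generate_subject_table <- function(spec) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec", "spec")
  set.seed(.substream_seed(spec$seed, 1))
  n <- c(spec$n_patients, spec$n_controls)
  grp <- rep(c("MDD", "HC"), n)
  draw <- function(mean2, sd2) c(rnorm(n[1], mean2[1], sd2[1]),
                                 rnorm(n[2], mean2[2], sd2[2]))
  age <- draw(spec$age_mean, spec$age_sd)
  edu <- pmax(draw(spec$edu_mean, spec$edu_sd), 0)
  sex <- rbinom(sum(n), 1, rep(spec$female_prop, n))
  fd <- pmax(rnorm(sum(n), spec$fd_mean, spec$fd_sd), 0.01)
  bmi <- pmax(rnorm(sum(n), spec$bmi_mean, spec$bmi_sd), 14)
  crp <- pmin(pmax(rlnorm(sum(n), spec$crp_meanlog, spec$crp_sdlog),
                   spec$crp_range[1]), spec$crp_range[2])
  pat <- grp == "MDD"
  z <- numeric(sum(n))
  z[pat] <- drop(scale(log(crp[pat])))
  z[!pat] <- drop(scale(log(crp[!pat])))
  e_m <- rnorm(sum(n))
  m <- numeric(sum(n))
  m[pat] <- spec$a * z[pat] + sqrt(1 - spec$a^2) * e_m[pat]
  m[!pat] <- e_m[!pat]
  zage <- drop(scale(age)); zedu <- drop(scale(edu))
  noise_sd <- sqrt(max(0.1, 1 - spec$c_prime^2 - spec$b^2 -
                         2 * spec$a * spec$b * spec$c_prime))
  cpt <- numeric(sum(n))
  cpt[pat] <- spec$c_prime * z[pat] + spec$b * m[pat] -
    0.1 * zage[pat] + 0.1 * zedu[pat] + rnorm(n[1], 0, noise_sd)
  cpt[!pat] <- 0.8 - 0.1 * zage[!pat] + 0.1 * zedu[!pat] + rnorm(n[2], 0, noise_sd)
  hamd <- pmax(c(rnorm(n[1], 28.84, 11.42), rnorm(n[2], 1.13, 2.55)), 0)
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(sum(n))),
                    group = grp, crp = crp, age = age, sex = sex,
                    education = edu, fd = fd, bmi = bmi, hamd = hamd,
                    cpt = cpt, m_latent = m, stringsAsFactors = FALSE)
  class(out) <- c("subject_table", "data.frame")
  out
}

# Amplitude deviate embedded in the planted cluster: rebuilds the shared
# residual of m_latent so that the planted amplitude correlates with
# standardized log CRP at exactly beta_crp_falff within patients.
#' @noRd
.planted_amplitude_deviate <- function(spec, subjects) {
  pat <- subjects$group == "MDD"
  dev <- subjects$m_latent        # controls: pure noise, CRP-independent
  if (any(pat) && abs(spec$a) > 0) {
    z <- drop(scale(log(subjects$crp[pat])))
    e <- (subjects$m_latent[pat] - spec$a * z) / sqrt(1 - spec$a^2)
    b <- spec$beta_crp_falff
    dev[pat] <- b * z + sqrt(1 - b^2) * e
  }
  dev
}

#' Generate synthetic BOLD-like 4D volumes
#'
#' Each in-mask voxel's series is broadband Gaussian noise plus a
#' low-frequency sinusoid (0.05 Hz, inside the 0.01-0.1 Hz band) with a
#' voxel-specific random phase. Inside the planted cluster the sinusoid
#' amplitude of a patient scales linearly with standardized log CRP
#' (slope `beta_crp_falff`, exact-correlation construction sharing the
#' latent-mediator residual); elsewhere, and for controls, the
#' amplitude is CRP-independent. Out-of-mask voxels are all zero.
#'
#' @param spec a [cohort_spec()].
#' @param grid a [grid_spec()]; `n_timepoints * tr` must cover at least
#'   one cycle of 0.01 Hz.
#' @param subjects output of [generate_subject_table()].
#' @param subject_idx subjects to generate (default all). Each subject
#'   uses an independent sub-stream seed, so any subset is reproducible.
#' @param amp0 baseline sinusoid amplitude (noise SD is 1).
#' @param amp_gain gain of the planted amplitude deviation.
#' @return list of 4D arrays (x, y, z, time), one per requested subject.
#' @export
generate_bold <- function(spec, grid, subjects, subject_idx = NULL,
                          amp0 = 1, amp_gain = 1) {
  .assert(inherits(grid, "grid_spec"), "grid must be a grid_spec", "grid")
  .assert(grid$n_timepoints * grid$tr >= 100,
          "n_timepoints * tr too short to resolve 0.01 Hz")
  subject_idx <- subject_idx %||% seq_len(nrow(subjects))
  dev <- .planted_amplitude_deviate(spec, subjects)
  nt <- grid$n_timepoints
  tt <- (seq_len(nt) - 1) * grid$tr
  maskv <- which(grid$mask)
  nv <- length(maskv)
  dims <- dim(grid$mask)
  # positions of planted voxels among in-mask voxels
  lin <- grid$cluster_seed_voxels[, 1] +
    (grid$cluster_seed_voxels[, 2] - 1) * dims[1] +
    (grid$cluster_seed_voxels[, 3] - 1) * dims[1] * dims[2]
  planted_pos <- match(lin, maskv)
  lapply(subject_idx, function(i) {
    set.seed(.substream_seed(spec$seed, 2, i))
    phase <- runif(nv, 0, 2 * pi)
    amp <- rep(amp0, nv)
    amp[planted_pos] <- pmax(amp0 * (1 + amp_gain * dev[i]), 0.05)
    sig <- sin(outer(tt * (2 * pi * 0.05), rep(1, nv)) +
                 matrix(phase, nt, nv, byrow = TRUE))
    series <- sweep(sig, 2, amp, "*") + matrix(rnorm(nt * nv), nt, nv)
    vol <- array(0, dim = c(dims, nt))
    flat <- matrix(0, prod(dims), nt)
    flat[maskv, ] <- t(series)
    array(flat, dim = c(dims, nt))
  })
}

#' Compute the standardized fALFF panel for a synthetic cohort
#'
#' Streams over subjects: generates each subject's BOLD volume,
#' computes raw fALFF per in-mask voxel and standardizes by the
#' in-mask global mean, keeping only the fALFF map. Memory therefore
#' stays flat in the number of subjects.
#'
#' @inheritParams generate_bold
#' @param band,spectrum passed to [compute_falff()].
#' @return a [voxel_panel()] of standardized fALFF values over in-mask
#'   voxels, with attribute `planted_pos` (columns of the planted
#'   cluster).
#' @export
generate_falff_panel <- function(spec, grid, subjects, band = c(0.01, 0.1),
                                 spectrum = "amplitude", amp0 = 1, amp_gain = 1) {
  maskv <- which(grid$mask)
  dims <- dim(grid$mask)
  coords <- arrayInd(maskv, dims)
  n <- nrow(subjects)
  out <- matrix(NA_real_, n, length(maskv))
  for (i in seq_len(n)) {
    vol <- generate_bold(spec, grid, subjects, subject_idx = i,
                         amp0 = amp0, amp_gain = amp_gain)[[1]]
    flat <- matrix(vol, prod(dims), grid$n_timepoints)
    raw <- compute_falff(t(flat[maskv, , drop = FALSE]), tr = grid$tr,
                         band = band, spectrum = spectrum)
    out[i, ] <- standardize_global_mean(as.numeric(raw))
  }
  pan <- voxel_panel(out, coords, dims)
  lin <- grid$cluster_seed_voxels[, 1] +
    (grid$cluster_seed_voxels[, 2] - 1) * dims[1] +
    (grid$cluster_seed_voxels[, 3] - 1) * dims[1] * dims[2]
  attr(pan, "planted_pos") <- match(lin, maskv)
  pan
}

#' Generate a synthetic skeletonized diffusion panel
#'
#' Subjects x skeleton-voxel matrix of an axial-diffusivity-like metric:
#' baseline plus spatially smooth noise (moving-average kernel along the
#' skeleton), with a planted CRP slope (default negative) in a
#' contiguous voxel strip for patients, built so the within-patient
#' CRP-value correlation in planted voxels equals `beta_crp_ad`.
#' Adjacency is the chain of consecutive skeleton voxels.
#'
#' @param spec a [cohort_spec()].
#' @param subjects output of [generate_subject_table()].
#' @param n_voxels number of skeleton voxels.
#' @param planted integer indices of the planted strip.
#' @param base baseline metric value.
#' @param noise_sd SD of the smooth noise field.
#' @return a [skeleton_panel()] with attribute `planted`.
#' @export
generate_skeleton_panel <- function(spec, subjects, n_voxels = 200,
                                    planted = 61:90, base = 1.2,
                                    noise_sd = 0.1) {
  .assert(all(planted >= 1 & planted <= n_voxels), "planted strip outside skeleton",
          "planted")
  set.seed(.substream_seed(spec$seed, 3))
  n <- nrow(subjects)
  pat <- subjects$group == "MDD"
  z <- numeric(n)
  z[pat] <- drop(scale(log(subjects$crp[pat])))
  beta <- spec$beta_crp_ad
  delta <- noise_sd * beta / sqrt(1 - beta^2)
  kern <- c(1, 2, 3, 2, 1); kern <- kern / sqrt(sum(kern^2))
  smooth_noise <- function() {
    e <- rnorm(n_voxels + length(kern) - 1)
    as.numeric(stats::filter(e, kern, sides = 1))[length(kern):(n_voxels + length(kern) - 1)]
  }
  data <- t(vapply(seq_len(n), function(i) {
    v <- base + noise_sd * smooth_noise()
    if (pat[i]) v[planted] <- v[planted] + delta * z[i]
    v
  }, numeric(n_voxels)))
  edges <- cbind(seq_len(n_voxels - 1), 2:n_voxels)
  pan <- skeleton_panel(data, edges, metric = "AD")
  attr(pan, "planted") <- planted
  pan
}

#' Generate a synthetic region atlas on the grid
#'
#' Partitions the in-mask voxels into `n_regions` spatially compact
#' regions (k-means on voxel millimeter coordinates), with region
#' centroids and a smooth gray-matter probability per region. A
#' desk-scale stand-in for a volumetric parcellation.
#'
#' @param grid a [grid_spec()].
#' @param n_regions number of regions (>= 10).
#' @param seed integer seed.
#' @return list of class `region_atlas`: `region_id` (label per in-mask
#'   voxel, aligned with [generate_falff_panel()] columns), `coords`
#'   (voxel coordinates), `centroids` (region centers, mm),
#'   `gm_probability`, `n_regions`.
#' @export
generate_region_atlas <- function(grid, n_regions = 60, seed = 1) {
  .assert(n_regions >= 10, "need at least 10 regions", "n_regions")
  maskv <- which(grid$mask)
  coords <- arrayInd(maskv, dim(grid$mask))
  .assert(length(maskv) >= n_regions * 4, "mask too small for the requested regions")
  mm <- coords * grid$voxel_size
  set.seed(.substream_seed(seed, 4))
  km <- kmeans(mm, centers = n_regions, nstart = 3, iter.max = 50)
  .assert(all(tabulate(km$cluster, n_regions) > 0), "empty region produced")
  g <- drop(.gp_draw(km$centers, length_scale = 20, n_draws = 1))
  gm <- pmin(0.95, pmax(0.05, 0.6 + 0.15 * (g - mean(g)) / sd(g)))
  structure(list(region_id = km$cluster, coords = coords, centroids = km$centers,
                 gm_probability = gm, n_regions = n_regions,
                 voxel_size = grid$voxel_size),
            class = "region_atlas")
}

# Regional footprint of the planted cluster: fraction of each region's
# voxels inside the cluster, diffused over centroids with an exponential
# kernel and standardized. Used as the phenotype pattern that planted
# genes / annotation maps are built from.
#' @noRd
.region_effect_pattern <- function(atlas, grid, decay = 10) {
  dims <- dim(grid$mask)
  lin <- grid$cluster_seed_voxels[, 1] +
    (grid$cluster_seed_voxels[, 2] - 1) * dims[1] +
    (grid$cluster_seed_voxels[, 3] - 1) * dims[1] * dims[2]
  pos <- match(lin, which(grid$mask))
  frac <- tabulate(atlas$region_id[pos], atlas$n_regions) /
    tabulate(atlas$region_id, atlas$n_regions)
  W <- exp(-.pdist(atlas$centroids) / decay)
  as.numeric(scale(W %*% frac))
}

#' Generate a synthetic region-by-gene expression matrix
#'
#' Each gene is a Gaussian random field over the region centroids
#' (exponential covariance with the stated length scale), so gene maps
#' carry spatial autocorrelation. Genes belonging to the planted
#' category are noisy copies of the supplied phenotype pattern. Genes
#' are z-scored per gene. A category table maps >= 20 categories to
#' member genes (random, possibly overlapping, sets).
#'
#' @param atlas a [generate_region_atlas()] result (or any list with a
#'   `centroids` matrix).
#' @param n_genes number of genes.
#' @param phenotype regional phenotype pattern the planted category
#'   tracks (length = number of regions).
#' @param n_categories number of categories (>= 20).
#' @param planted_size number of genes in the planted category.
#' @param size_range size range of the other categories.
#' @param noise_sd noise added to planted-category genes, relative to
#'   the unit-variance phenotype pattern.
#' @param length_scale GP length scale in mm.
#' @param seed integer seed.
#' @return list of class `expression_set`: `expr` (regions x genes,
#'   z-scored), `categories` (data frame `category_id`, `gene_id`),
#'   `planted_category` (id of the planted category),
#'   `planted_genes`.
#' @export
generate_expression <- function(atlas, n_genes = 500, phenotype,
                                n_categories = 25, planted_size = 15,
                                size_range = c(8, 30), noise_sd = 0.4,
                                length_scale = 15, seed = 1) {
  .assert(n_categories >= 20, "need at least 20 categories", "n_categories")
  R <- nrow(atlas$centroids)
  .assert(length(phenotype) == R, "phenotype length must match region count")
  set.seed(.substream_seed(seed, 5))
  L <- .gp_chol(atlas$centroids, length_scale)
  expr <- .gp_draw(atlas$centroids, length_scale, n_genes, L = L)
  ph <- drop(scale(phenotype))
  planted_genes <- sprintf("g%04d", seq_len(planted_size))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  for (j in seq_len(planted_size))
    expr[, j] <- ph + noise_sd * drop(crossprod(L, rnorm(R)))
  expr <- scale(expr)
  dimnames(expr) <- list(NULL, gene_ids)
  other <- lapply(seq_len(n_categories - 1), function(k) {
    sz <- sample(size_range[1]:size_range[2], 1)
    sample(gene_ids[-seq_len(planted_size)], sz)
  })
  cats <- data.frame(
    category_id = c(rep("planted", planted_size),
                    rep(sprintf("cat%02d", seq_len(n_categories - 1)),
                        lengths(other))),
    gene_id = c(planted_genes, unlist(other)),
    stringsAsFactors = FALSE)
  structure(list(expr = expr, categories = cats,
                 planted_category = "planted", planted_genes = planted_genes),
            class = "expression_set")
}

#' Generate synthetic regional annotation maps
#'
#' Smooth region-level maps emulating neurotransmitter receptor /
#' transporter densities or behavioral-domain activation maps. A stated
#' subset is constructed to correlate with the phenotype pattern at the
#' target correlation `r_target`; the rest are independent smooth
#' fields.
#'
#' @param atlas region atlas (for centroids).
#' @param k_maps number of maps.
#' @param phenotype regional phenotype pattern.
#' @param planted indices of maps built to track the phenotype.
#' @param r_target population correlation of planted maps with the
#'   phenotype.
#' @param length_scale GP length scale (mm).
#' @param seed integer seed.
#' @param prefix column-name prefix.
#' @return regions x k numeric matrix with named columns and attribute
#'   `planted`.
#' @export
generate_annotation_maps <- function(atlas, k_maps, phenotype, planted = 1:2,
                                     r_target = 0.6, length_scale = 15,
                                     seed = 1, prefix = "map") {
  R <- nrow(atlas$centroids)
  .assert(length(phenotype) == R, "phenotype length must match region count")
  .assert(all(planted >= 1 & planted <= k_maps), "planted index out of range", "planted")
  .assert(abs(r_target) < 1, "r_target must be in (-1,1)", "r_target")
  set.seed(.substream_seed(seed, 6))
  L <- .gp_chol(atlas$centroids, length_scale)
  ph <- drop(scale(phenotype))
  maps <- apply(.gp_draw(atlas$centroids, length_scale, k_maps, L = L), 2,
                function(g) drop(scale(g)))
  for (j in planted)
    maps[, j] <- r_target * ph + sqrt(1 - r_target^2) * maps[, j]
  colnames(maps) <- sprintf("%s_%02d", prefix, seq_len(k_maps))
  attr(maps, "planted") <- colnames(maps)[planted]
  maps
}
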