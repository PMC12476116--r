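test_that("cohort table matches the specified sample structure", {
  spec <- cohort_spec(seed = 301)
  tab <- generate_subject_table(spec)
  expect_equal(nrow(tab), 238)
  expect_equal(sum(tab$group == "MDD"), 120)
  expect_equal(sum(tab$group == "HC"), 118)
  expect_true(all(tab$crp >= 0.02 & tab$crp <= 6.39))
  expect_true(all(tab$sex %in% 0:1))
  # planted population indirect effect is the product of the paths
  expect_equal(spec$a * spec$b, 0.25)
  expect_identical(tab, generate_subject_table(spec))
  expect_false(identical(tab, generate_subject_table(cohort_spec(seed = 302))))
})

test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_patients = 2), "n_patients")
  expect_error(cohort_spec(crp_sdlog = 0), "crp_sdlog")
  expect_error(cohort_spec(a = 1.2), "'a'")
  expect_error(grid_spec(n_timepoints = 10), "n_timepoints")
  expect_error(grid_spec(shape = c(8, 8, 8),
                         cluster_seed_voxels = cbind(1, 1, 1)),
               "cluster_seed_voxels")
})

test_that("planted amplitude correlates with CRP at the target effect size", {
  cors <- vapply(1:100, function(r) {
    spec <- cohort_spec(seed = r)
    tab <- generate_subject_table(spec)
    dev <- inflamap:::.planted_amplitude_deviate(spec, tab)
    pat <- tab$group == "MDD"
    cor(log(tab$crp[pat]), dev[pat])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.6), 0.02)
  expect_lt(sd(cors), 0.1)
  # null build: no CRP dependence
  spec0 <- cohort_spec(seed = 5, beta_crp_falff = 0)
  tab0 <- generate_subject_table(spec0)
  dev0 <- inflamap:::.planted_amplitude_deviate(spec0, tab0)
  pat <- tab0$group == "MDD"
  expect_lt(abs(cor(log(tab0$crp[pat]), dev0[pat])), 0.2)
})

test_that("BOLD volumes are masked, reproducible, and carry the planted band signal", {
  spec <- cohort_spec(n_patients = 60, n_controls = 4, seed = 311)
  grid <- grid_spec(shape = c(10, 10, 10), n_timepoints = 96)
  tab <- generate_subject_table(spec)
  v1 <- generate_bold(spec, grid, tab, subject_idx = 3)[[1]]
  v2 <- generate_bold(spec, grid, tab, subject_idx = 3)[[1]]
  expect_identical(v1, v2)
  out_voxel <- which(!grid$mask, arr.ind = TRUE)[1, ]
  expect_equal(v1[out_voxel[1], out_voxel[2], out_voxel[3], ], rep(0, 96))
  expect_error(generate_bold(spec, grid_spec(shape = c(10, 10, 10), tr = 1,
                                             n_timepoints = 64), tab),
               "0.01 Hz")
})

test_that("extracted fALFF tracks CRP inside the planted cluster only", {
  spec <- cohort_spec(n_patients = 120, n_controls = 4, seed = 321)
  grid <- grid_spec(shape = c(10, 10, 10), n_timepoints = 96)
  tab <- generate_subject_table(spec)
  mdd <- tab[tab$group == "MDD", , drop = FALSE]
  pan <- generate_falff_panel(spec, grid, mdd)
  planted <- attr(pan, "planted_pos")
  lcrp <- log(mdd$crp)
  r_cluster <- cor(lcrp, rowMeans(pan$data[, planted]))
  expect_equal(r_cluster, 0.6, tolerance = 0.15)
  r_voxel <- apply(pan$data[, planted], 2, cor, y = lcrp)
  expect_true(all(r_voxel > 0.3 & r_voxel < 0.85))
  outside <- setdiff(seq_len(ncol(pan$data)), planted)
  r_out <- apply(pan$data[, sample(outside, 50)], 2, cor, y = lcrp)
  expect_lt(max(abs(r_out)), 0.4)
})

test_that("skeleton panel plants the stated negative CRP slope", {
  cors <- vapply(1:100, function(r) {
    spec <- cohort_spec(n_patients = 120, n_controls = 4, seed = 4000 + r)
    tab <- generate_subject_table(spec)
    skel <- generate_skeleton_panel(spec, tab)
    pat <- tab$group == "MDD"
    mean(apply(skel$data[pat, attr(skel, "planted")], 2, cor,
               y = log(tab$crp[pat])))
  }, numeric(1))
  expect_lt(abs(mean(cors) - (-0.6)), 0.02)
  expect_lt(sd(cors), 0.1)
  spec <- cohort_spec(seed = 1)
  tab <- generate_subject_table(spec)
  expect_identical(generate_skeleton_panel(spec, tab)$data,
                   generate_skeleton_panel(spec, tab)$data)
})

test_that("region atlas partitions the mask into compact labeled regions", {
  grid <- grid_spec(shape = c(12, 12, 12), n_timepoints = 64)
  atlas <- generate_region_atlas(grid, n_regions = 20, seed = 2)
  expect_equal(atlas$n_regions, 20)
  expect_true(all(tabulate(atlas$region_id, 20) > 0))
  expect_true(all(is.finite(atlas$centroids)))
  expect_true(all(atlas$gm_probability > 0 & atlas$gm_probability < 1))
  expect_error(generate_region_atlas(grid, n_regions = 5), "10 regions")
})

test_that("expression matrix has planted genes, full shape, and autocorrelation", {
  cent <- test_centroids(40)
  set.seed(331)
  pattern <- smooth_map(cent, 20)
  atlas_like <- list(centroids = cent)
  es <- generate_expression(atlas_like, n_genes = 150, phenotype = pattern,
                            seed = 331)
  expect_equal(dim(es$expr), c(40, 150))
  expect_false(anyNA(es$expr))
  expect_gte(length(unique(es$categories$category_id)), 20)
  # noise -> 0 limit: planted genes converge on the phenotype pattern
  es0 <- generate_expression(atlas_like, n_genes = 50, phenotype = pattern,
                             noise_sd = 1e-6, seed = 332)
  r0 <- cor(es0$expr[, es0$planted_genes], pattern)
  expect_true(all(r0 > 0.999))
  # non-planted genes are not systematically phenotype-aligned
  means <- vapply(1:20, function(r) {
    e <- generate_expression(atlas_like, n_genes = 60, phenotype = pattern,
                             seed = 5000 + r)
    mean(cor(e$expr[, -seq_len(15)], pattern))
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
  # variogram of gene maps rises with distance up to the length scale
  vg <- rowMeans(vapply(16:40, function(j)
    empirical_variogram(es$expr[, j], cent, n_bins = 6)$gamma, numeric(6)))
  expect_lt(vg[1], vg[4])
})

test_that("annotation maps hit the target phenotype correlation", {
  cent <- test_centroids(60)
  set.seed(341)
  pattern <- smooth_map(cent, 20)
  maps <- generate_annotation_maps(list(centroids = cent), 30, pattern,
                                   planted = 1:10, r_target = 0.6, seed = 341)
  r_planted <- cor(maps[, 1:10], pattern)
  expect_equal(mean(r_planted), 0.6, tolerance = 0.12)
  r_other <- cor(maps[, 11:30], pattern)
  expect_lt(abs(mean(r_other)), 0.25)
  expect_identical(maps, generate_annotation_maps(list(centroids = cent), 30,
                                                  pattern, planted = 1:10,
                                                  r_target = 0.6, seed = 341))
})
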