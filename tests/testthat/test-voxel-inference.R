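test_that("voxel-wise GLM matches the lm oracle on random panels", {
  for (seed in c(1, 2, 3)) {
    subj <- random_subjects(30, seed)
    des <- glm_design(subj, "crp", c("age", "sex"))
    set.seed(seed + 100)
    Y <- matrix(rnorm(30 * 5), 30)
    sm <- fit_voxelwise_glm(Y, des)
    expect_s3_class(sm, "stat_map")
    expect_equal(sm$df, 30 - 4)
    for (j in 1:5) {
      f <- summary(lm(Y[, j] ~ crp + age + sex, data = subj))$coefficients
      expect_equal(sm$t[j], f["crp", "t value"], tolerance = 1e-8)
      expect_equal(sm$beta[j], f["crp", "Estimate"], tolerance = 1e-8)
    }
  }
})

test_that("GLM degenerate cases: exact signal, partialled covariate, collinearity", {
  subj <- random_subjects(40, 5)
  des <- glm_design(subj, "crp", c("age", "sex"))
  exact <- matrix(-2.5 * subj$crp, ncol = 1)     # exact negative CRP effect
  sm <- fit_voxelwise_glm(exact, des)
  expect_lt(sm$t[1], -1e6)
  cov_only <- matrix(subj$age, ncol = 1)         # panel equals a covariate
  expect_lt(abs(fit_voxelwise_glm(cov_only, des)$t[1]), 1e-6)
  subj$crp2 <- subj$crp * 2
  expect_error(glm_design(subj, "crp", c("age", "crp2")), "collinear")
})

test_that("GLM p values are calibrated under a permuted regressor", {
  set.seed(21)
  subj <- random_subjects(60, 22)
  subj$crp <- sample(subj$crp)
  des <- glm_design(subj, "crp", c("age", "sex"))
  Y <- matrix(rnorm(60 * 1000), 60)
  sm <- fit_voxelwise_glm(Y, des)
  p <- 2 * pt(-abs(sm$t), sm$df)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.02)
})

test_that("TFCE matches closed forms for isolated voxels and uniform clusters", {
  no_edges <- matrix(integer(0), 0, 2)
  t0 <- 3
  expect_equal(tfce_transform(t0, no_edges, E = 0.5, H = 2, n_steps = 2000),
               t0^3 / 3, tolerance = 2e-3)
  e0 <- 5; h0 <- 2.5
  chain <- cbind(1:(e0 - 1), 2:e0)
  tf <- tfce_transform(rep(h0, e0), chain, E = 0.5, H = 2, n_steps = 2000)
  expect_equal(tf, rep(sqrt(e0) * h0^3 / 3, e0), tolerance = 2e-3)
  expect_equal(tfce_transform(rep(0, 6), chain), rep(0, 6))
})

test_that("TFCE is monotone in the input statistic", {
  set.seed(9)
  edges <- cbind(1:29, 2:30)
  tv <- abs(rnorm(30))
  dh <- max(tv + 1) / 100
  base <- tfce_transform(tv, edges, dh = dh)
  for (i in c(3, 17, 30)) {
    tv2 <- tv; tv2[i] <- tv2[i] + 0.8
    expect_true(all(tfce_transform(tv2, edges, dh = dh) >= base - 1e-12))
  }
})

test_that("cluster-extent FWE recovers a planted CRP cluster", {
  spec <- cohort_spec(n_patients = 120, n_controls = 4, seed = 31)
  grid <- grid_spec(shape = c(12, 12, 12), n_timepoints = 128)
  subj <- generate_subject_table(spec)
  mdd <- subj[subj$group == "MDD", , drop = FALSE]
  pan <- generate_falff_panel(spec, grid, mdd)
  mdd$crp <- log(mdd$crp)
  des <- glm_design(mdd, "crp", c("age", "sex", "education", "fd"))
  res <- cluster_fwe(pan, des, n_perm = 300, seed = 32)
  sig <- res$clusters[res$clusters$p_fwe < 0.05 & res$clusters$sign > 0, ]
  expect_gte(nrow(sig), 1)
  planted <- attr(pan, "planted_pos")
  hit <- which(res$labels %in% sig$cluster)
  expect_gte(length(intersect(hit, planted)) / length(planted), 0.5)
})

test_that("cluster FWE handles empty results and rejects bad inputs", {
  subj <- random_subjects(20, 41)
  des <- glm_design(subj, "crp", "age")
  set.seed(42)
  pan <- voxel_panel(matrix(rnorm(20 * 27), 20),
                     as.matrix(expand.grid(1:3, 1:3, 1:3)), c(3, 3, 3))
  res <- cluster_fwe(pan, des, cluster_p = 1e-9, n_perm = 50, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_true(all(res$labels == 0))
  expect_error(cluster_fwe(pan, des, n_perm = 0), "n_perm")
})

test_that("TFCE-FWE recovers the planted negative strip and is deterministic", {
  spec <- cohort_spec(seed = 51)
  subj <- generate_subject_table(spec)
  skel <- generate_skeleton_panel(spec, subj)
  mdd_rows <- which(subj$group == "MDD")
  mdd <- subj[mdd_rows, , drop = FALSE]
  mdd$crp <- log(mdd$crp)
  des <- glm_design(mdd, "crp", c("age", "sex", "education"))
  pan <- skeleton_panel(skel$data[mdd_rows, , drop = FALSE], skel$edges)
  res <- tfce_fwe(pan, des, n_perm = 300, seed = 52)
  planted <- attr(skel, "planted")
  expect_gte(mean(res$p_neg[planted] < 0.05), 0.8)
  expect_lt(mean(res$p_pos < 0.05), 0.1)
  res2 <- tfce_fwe(pan, des, n_perm = 300, seed = 52)
  expect_identical(res$p_neg, res2$p_neg)
})

test_that("ROI extraction averages member voxels", {
  Y <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(unname(extract_roi(Y, list(a = 2))), matrix(c(2, 6), 2))
  expect_equal(unname(extract_roi(matrix(3, 4, 6), list(r = 1:6))), matrix(3, 4, 1))
  # checkerboard ROI: voxels 1 and 3 -> means 2 and 6
  expect_equal(unname(extract_roi(Y, c(1, 0, 1, 0))), matrix(c(2, 6), 2))
  expect_error(extract_roi(Y, list(bad = 9)), "out of range")
})
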