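test_that("pooled t statistics reproduce printed demographic comparisons", {
  edu <- two_sample_t(mean = c(8.87, 11.64), sd = c(3.66, 4.67), n = c(120, 118))
  expect_equal(edu$statistic, -5.091, tolerance = 0.01)
  expect_lt(edu$p, 0.001)
  age <- two_sample_t(mean = c(42.89, 43.77), sd = c(11.03, 13.89), n = c(120, 118))
  expect_equal(age$statistic, -0.540, tolerance = 0.01)
  expect_equal(age$p, 0.590, tolerance = 0.01)
})

test_that("raw-vector t tests agree with stats::t.test for both variants", {
  set.seed(201)
  x <- rnorm(25, 1); y <- rnorm(30, 0.4, 1.6)
  pooled <- two_sample_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(pooled$p, ref$p.value, tolerance = 1e-10)
  welch <- two_sample_t(x, y, variant = "welch")
  refw <- t.test(x, y)
  expect_equal(welch$statistic, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-10)
  same <- two_sample_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("2x2 chi-square matches the printed sex comparison and the oracle", {
  tab <- rbind(c(81, 39), c(79, 39))
  res <- chi_square_2x2(tab)
  expect_lt(abs(res$statistic - 0.008), 5e-4)
  expect_lt(abs(res$p - 0.928), 2e-3)
  expect_equal(res$df, 1)
  for (seed in 1:4) {
    set.seed(seed)
    tb <- matrix(rpois(4, 40) + 5, 2, 2)
    expect_equal(chi_square_2x2(tb)$statistic, oracle_chisq(tb), tolerance = 1e-12)
  }
  expect_equal(chi_square_2x2(rbind(c(20, 40), c(10, 20)))$statistic, 0)
})

test_that("partial correlation matches Pearson and the closed-form oracle", {
  set.seed(211)
  x <- rnorm(80); y <- 0.4 * x + rnorm(80); z <- rnorm(80)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  expect_lt(abs(partial_correlation(x, z, covariates = z)$r), 1e-10)
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(50); b <- rnorm(50); cc <- rnorm(50)
    expect_equal(partial_correlation(a, b, cc)$r, oracle_partial_r1(a, b, cc),
                 tolerance = 1e-10)
  }
  fam <- roi_clinical_corr(cbind(r1 = x, r2 = y), cbind(c1 = z, c2 = y),
                           covariates = rnorm(80))
  expect_equal(fam$p_fdr, p.adjust(fam$p, "BH"))
})

test_that("Fisher z comparison follows the closed form and its symmetries", {
  same <- fisher_z_compare(0.4, 100, 0.4, 90)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- fisher_z_compare(0.5, 60, -0.2, 80)
  ba <- fisher_z_compare(-0.2, 80, 0.5, 60)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  z_manual <- (atanh(0.3) - atanh(0)) / sqrt(1 / (120 - 3) + 1 / (118 - 3))
  got <- fisher_z_compare(0.3, 120, 0, 118)
  expect_equal(got$z, z_manual, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(z_manual)), tolerance = 1e-12)
  expect_error(fisher_z_compare(1, 10, 0, 10), "in \\(-1, 1\\)")
})

test_that("mediation paths satisfy the OLS identity and match lm coefficients", {
  set.seed(221)
  n <- 120
  cov <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  x <- rnorm(n)
  m <- 0.5 * x + 0.2 * cov[, 1] + rnorm(n)
  y <- 0.4 * m + 0.1 * x - 0.1 * cov[, 2] + rnorm(n)
  med <- mediate(x, m, y, covariates = cov, n_boot = 200, seed = 1)
  expect_equal(med$c, med$c_prime + med$a * med$b, tolerance = 1e-10)
  fa <- lm(m ~ x + cov)
  fb <- lm(y ~ x + m + cov)
  expect_equal(med$a, unname(coef(fa)["x"]), tolerance = 1e-10)
  expect_equal(med$b, unname(coef(fb)["m"]), tolerance = 1e-10)
  expect_equal(med$c_prime, unname(coef(fb)["x"]), tolerance = 1e-10)
  expect_lte(med$ci[1], med$ci[2])
})

test_that("mediation rejects degenerate inputs", {
  x <- rnorm(30)
  expect_error(mediate(x, rep(1, 30), rnorm(30), n_boot = 10), "zero variance")
  expect_error(mediate(x[1:10], rnorm(10), rnorm(10), n_boot = 10),
               "complete cases")
})

test_that("mediation recovers the generator's planted indirect effect", {
  spec <- cohort_spec(n_patients = 2000, n_controls = 4, seed = 77)
  tab <- generate_subject_table(spec)
  p <- tab[tab$group == "MDD", ]
  med <- mediate(drop(scale(log(p$crp))), p$m_latent, p$cpt,
                 covariates = p[, c("age", "sex", "education")],
                 n_boot = 600, seed = 3)
  expect_equal(med$indirect, spec$a * spec$b, tolerance = 0.05)
  expect_gt(med$ci[1], 0)
})
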