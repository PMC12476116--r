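make_expression_fixture <- function(seed = 111, R = 40, n_genes = 200) {
  cent <- test_centroids(R)
  set.seed(seed)
  pattern <- smooth_map(cent, 20)
  atlas_like <- list(centroids = cent)
  es <- generate_expression(atlas_like, n_genes = n_genes, phenotype = pattern,
                            n_categories = 22, seed = seed)
  list(cent = cent, pattern = pattern, es = es)
}

test_that("gene scores hit the exact limits and are centered under noise", {
  fx <- make_expression_fixture()
  ph <- fx$pattern
  expr <- cbind(g1 = ph, g2 = -ph, fx$es$expr[, 1:50])
  gs <- gene_score(expr, ph)
  expect_equal(unname(gs["g1"]), 1)
  expect_equal(unname(gs["g2"]), -1)
  set.seed(5)
  noise <- matrix(rnorm(40 * 1000), 40)
  colnames(noise) <- paste0("n", 1:1000)
  expect_lt(abs(mean(gene_score(noise, ph))), 0.02)
  expect_lt(abs(mean(gene_score(noise, ph, method = "pearson"))), 0.02)
})

test_that("ensemble GCEA ranks the planted category first", {
  fx <- make_expression_fixture()
  sur <- surrogate_maps(fx$pattern, fx$cent, 500, seed = 7)
  res <- gcea_ensemble(fx$es$expr, fx$pattern, fx$es$categories, sur)
  expect_s3_class(res, "gcea_result")
  expect_true(all(res$p_ens > 0 & res$p_ens <= 1))
  planted <- res[res$category_id == "planted", ]
  expect_equal(planted$p_ens, min(res$p_ens))
  expect_lt(planted$p_ens, 0.05)
  expect_equal(planted$direction, 1)
})

test_that("GCEA skips undersized categories and validates surrogates", {
  fx <- make_expression_fixture()
  cats <- rbind(fx$es$categories,
                data.frame(category_id = "tiny", gene_id = "g0100"))
  sur <- surrogate_maps(fx$pattern, fx$cent, 120, seed = 8)
  expect_message(res <- gcea_ensemble(fx$es$expr, fx$pattern, cats, sur),
                 "tiny")
  expect_false("tiny" %in% res$category_id)
  expect_error(gcea_ensemble(fx$es$expr, fx$pattern, cats,
                             matrix(numeric(0), 40, 0)), "empty")
})

test_that("GCEA null p values are roughly uniform for unrelated phenotypes", {
  cent <- test_centroids(30)
  set.seed(121)
  atlas_like <- list(centroids = cent)
  ps <- vapply(1:40, function(r) {
    ph <- smooth_map(cent, 20)
    es <- generate_expression(atlas_like, n_genes = 60, phenotype = smooth_map(cent, 20),
                              n_categories = 20, planted_size = 5,
                              size_range = c(5, 10), seed = 1000 + r)
    sur <- surrogate_maps(ph, cent, 100, seed = r, length_scale = 20)
    cats <- es$categories[es$categories$category_id == "cat05", ]
    gcea_ensemble(es$expr, ph, cats, sur)$p_ens
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lte(mean(ps < 0.1), 0.3)
})

test_that("first PLS component matches the SVD oracle and finds informative genes", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("g", 1:6)))
    y <- rnorm(10)
    fit <- pls_first_component(X, y)
    orc <- oracle_pls_svd(X, y)
    expect_equal(fit$r, orc$r, tolerance = 1e-8)
    expect_equal(unname(fit$loadings), orc$w, tolerance = 1e-8)
  }
  set.seed(9)
  R <- 60
  ph <- rnorm(R)
  X <- cbind(info = ph + 0.1 * rnorm(R), matrix(rnorm(R * 30), R))
  colnames(X)[-1] <- paste0("noise", 1:30)
  fit <- pls_first_component(X, ph)
  expect_equal(names(which.max(abs(fit$loadings))), "info")
  # duplicated informative gene shares the top loadings
  X2 <- cbind(X, info2 = X[, "info"])
  fit2 <- pls_first_component(X2, ph)
  top2 <- names(sort(abs(fit2$loadings), decreasing = TRUE))[1:2]
  expect_setequal(top2, c("info", "info2"))
})

test_that("PLS permutation p detects planted signal and stays near-null otherwise", {
  fx <- make_expression_fixture()
  sur <- surrogate_maps(fx$pattern, fx$cent, 300, seed = 17)
  pp <- pls_permutation_p(fx$es$expr, fx$pattern, sur)
  expect_lt(pp$p_perm, 0.05)
  expect_identical(pp$p_perm,
                   pls_permutation_p(fx$es$expr, fx$pattern, sur)$p_perm)
})

test_that("top-loading selection follows the shared 25% budget split by sign", {
  set.seed(31)
  w <- rnorm(5013)
  names(w) <- paste0("g", seq_along(w))
  sets <- select_top_loadings(w)
  expect_equal(length(sets$pls_plus) + length(sets$pls_minus), 1253)
  expect_length(intersect(sets$pls_plus, sets$pls_minus), 0)
  # invariant to positive rescaling
  sets2 <- select_top_loadings(17.3 * w)
  expect_identical(sets, sets2)
  wpos <- abs(w[1:100])
  expect_length(select_top_loadings(wpos)$pls_minus, 0)
  all_sel <- select_top_loadings(w, fraction = 1)
  expect_equal(length(all_sel$pls_plus) + length(all_sel$pls_minus), 5013)
})

test_that("robust sigmoid normalization maps genes to the unit interval", {
  set.seed(41)
  e <- matrix(rexp(200), 20, 10)
  ne <- normalize_expression(e)
  expect_true(all(ne >= 0 & ne <= 1))
  expect_equal(dim(ne), dim(e))
  # rank order within gene preserved
  expect_equal(order(ne[, 1]), order(e[, 1]))
})
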