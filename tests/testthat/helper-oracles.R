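# Independent textbook-formula oracles used to cross-check the
# implementation. These deliberately take a different computational route
# than the package code.

# Benjamini-Hochberg step-up by its definition: adjusted p_i is the
# smallest over j >= i (in sorted order) of min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  padj_sorted <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# Partial correlation with a single covariate by the closed form
# r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
oracle_partial_r1 <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Pearson chi-square by the definitional sum over cells.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# First PLS direction via SVD of the predictor-response cross-covariance.
oracle_pls_svd <- function(X, y) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  s <- svd(crossprod(Xc, matrix(yc)))
  w <- s$u[, 1]
  scores <- drop(Xc %*% w)
  if (cor(scores, yc) < 0) { w <- -w; scores <- -scores }
  list(w = w, scores = scores, r = cor(scores, yc))
}

# Small subject data frame with random regressors for design tests.
random_subjects <- function(n, seed) {
  set.seed(seed)
  data.frame(crp = rnorm(n), age = rnorm(n), sex = rbinom(n, 1, 0.5),
             education = rnorm(n))
}

# Smooth regional map via an exponential-covariance Gaussian field.
smooth_map <- function(centroids, length_scale = 20) {
  K <- exp(-as.matrix(dist(centroids)) / length_scale)
  diag(K) <- diag(K) + 1e-8
  as.numeric(crossprod(chol(K), rnorm(nrow(centroids))))
}

# Fixed region centroid cloud reused across spatial tests.
test_centroids <- function(R = 40, seed = 101, extent = 60) {
  set.seed(seed)
  matrix(runif(R * 3, 0, extent), R, 3)
}
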