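#' Two-sample t test from raw vectors or printed summaries
#'
#' Accepts either raw group vectors or group summaries (means, SDs and
#' sizes), so statistics printed in demographic tables can be recomputed
#' directly. The pooled variant assumes equal variances; Welch does not.
#'
#' @param x,y raw numeric vectors for the two groups, or `NULL` when
#'   summaries are supplied.
#' @param mean,sd,n length-2 numeric vectors of group summaries
#'   (group 1 first), used when `x`/`y` are `NULL`.
#' @param variant `"pooled"` or `"welch"`.
#' @return list of class `group_comp`: `statistic`, `df`, `p`,
#'   `mean`, `sd`, `n`.
#' @export
two_sample_t <- function(x = NULL, y = NULL, mean = NULL, sd = NULL, n = NULL,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (!is.null(x) || !is.null(y)) {
    .assert(!is.null(x) && !is.null(y), "supply both group vectors")
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    mean <- c(base::mean(x), base::mean(y))
    sd <- c(stats::sd(x), stats::sd(y))
    n <- c(length(x), length(y))
  }
  .assert(length(mean) == 2 && length(sd) == 2 && length(n) == 2,
          "summaries must have one entry per group")
  .assert(all(n >= 2) && all(sd >= 0), "need n >= 2 and sd >= 0 per group")
  d <- mean[1] - mean[2]
  if (variant == "pooled") {
    sp2 <- ((n[1] - 1) * sd[1]^2 + (n[2] - 1) * sd[2]^2) / (sum(n) - 2)
    se <- sqrt(sp2 * (1 / n[1] + 1 / n[2]))
    df <- sum(n) - 2
  } else {
    v <- sd^2 / n
    se <- sqrt(sum(v))
    df <- se^4 / (v[1]^2 / (n[1] - 1) + v[2]^2 / (n[2] - 1))
  }
  tstat <- if (se == 0 && d == 0) 0 else d / se
  structure(list(statistic = tstat, df = df,
                 p = 2 * pt(-abs(tstat), df),
                 mean = mean, sd = sd, n = n, variant = variant),
            class = "group_comp")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1), as used
#' for a sex-by-group contingency table.
#'
#' @param counts 2x2 matrix (or something coercible) of counts.
#' @return list of class `group_comp` with `statistic`, `df`, `p` and
#'   the table.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- matrix(as.numeric(as.matrix(counts)), 2, 2)
  .assert(all(counts >= 0) && all(rowSums(counts) > 0) && all(colSums(counts) > 0),
          "counts must be non-negative with positive margins", "counts")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, table = counts),
            class = "group_comp")
}

#' @export
print.group_comp <- function(x, ...) {
  cat(sprintf("statistic = %.3f, df = %.1f, p = %.4g\n", x$statistic, x$df, x$p))
  invisible(x)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each (with intercept) on the covariates; reduces to the plain
#' Pearson correlation with no covariates. The p value uses the t
#' distribution with `n - 2 - k` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric vector, matrix or data frame.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  dat <- cbind(x = x, y = y,
               if (!is.null(covariates)) as.matrix(data.frame(covariates)))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  k <- ncol(dat) - 2
  .assert(n > k + 3, "too few complete cases")
  if (k > 0) {
    Z <- cbind(1, dat[, -(1:2), drop = FALSE])
    rx <- .lm.fit(Z, dat[, 1])$residuals
    ry <- .lm.fit(Z, dat[, 2])$residuals
  } else {
    rx <- dat[, 1]; ry <- dat[, 2]
  }
  # a variable fully explained by the covariates has no partial association
  if (sd(rx) <= 1e-12 * max(sd(dat[, 1]), 1) ||
      sd(ry) <= 1e-12 * max(sd(dat[, 2]), 1)) {
    r <- 0
  } else r <- cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df, n = n)
}

#' ROI-by-clinical partial correlations with FDR over the family
#'
#' Every (ROI measure, clinical variable) pair is tested with
#' [partial_correlation()] and Benjamini-Hochberg correction is applied
#' across all pairs of the family.
#'
#' @param roi subjects x measures numeric matrix (columns named).
#' @param clinical subjects x variables numeric matrix or data frame.
#' @param covariates optional covariates passed through.
#' @return data frame: `measure`, `clinical`, `r`, `n`, `p`, `p_fdr`.
#' @export
roi_clinical_corr <- function(roi, clinical, covariates = NULL) {
  roi <- as.matrix(roi); clinical <- as.matrix(clinical)
  rows <- list()
  for (i in seq_len(ncol(roi))) for (j in seq_len(ncol(clinical))) {
    pc <- partial_correlation(roi[, i], clinical[, j], covariates)
    rows[[length(rows) + 1]] <- data.frame(
      measure = colnames(roi)[i] %||% paste0("roi_", i),
      clinical = colnames(clinical)[j] %||% paste0("var_", j),
      r = pc$r, n = pc$n, p = pc$p)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Compare two independent correlations via Fisher's z
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p value.
#'
#' @param r1,r2 correlation coefficients.
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  .assert(abs(r1) < 1 && abs(r2) < 1, "correlations must lie in (-1, 1)")
  .assert(n1 > 3 && n2 > 3, "need more than 3 observations per group")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Covariate-adjusted mediation with percentile bootstrap
#'
#' Fits the three ordinary least squares path models (covariates in
#' every equation): `m ~ x` (path a), `y ~ x + m` (paths c' and b) and
#' `y ~ x` (total effect c). The indirect effect is `a * b`, with a
#' percentile bootstrap confidence interval over subject resamples. On
#' any complete-case fit the OLS identity `c = c' + a * b` holds.
#'
#' @param x exposure (e.g. CRP), numeric vector.
#' @param m mediator (e.g. ROI imaging value).
#' @param y outcome (clinical score).
#' @param covariates optional vector/matrix/data frame of covariates.
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return object of class `mediation_result`: unstandardized paths
#'   `a`, `b`, `c`, `c_prime`, `indirect`, bootstrap `ci` for the
#'   indirect effect, standard errors, `n`, `n_boot`, `seed`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 5000, seed = 1,
                    conf = 0.95) {
  dat <- cbind(x = x, m = m, y = y,
               if (!is.null(covariates)) as.matrix(data.frame(covariates)))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  .assert(n >= 20, "need at least 20 complete cases")
  .assert(all(apply(dat, 2, stats::sd) > 0), "zero variance in a model variable")
  Zc <- if (ncol(dat) > 3) dat[, -(1:3), drop = FALSE] else NULL
  xv <- dat[, 1]; mv <- dat[, 2]; yv <- dat[, 3]

  paths <- function(idx) {
    xs <- xv[idx]; ms <- mv[idx]; ys <- yv[idx]
    Z <- if (is.null(Zc)) NULL else Zc[idx, , drop = FALSE]
    Xa <- cbind(1, xs, Z)
    Xb <- cbind(1, xs, ms, Z)
    a <- .lm.fit(Xa, ms)$coefficients[2]
    fb <- .lm.fit(Xb, ys)$coefficients
    cf <- .lm.fit(Xa, ys)$coefficients[2]
    c(a = a, c_prime = fb[2], b = fb[3], c = cf)
  }
  est <- paths(seq_len(n))

  # standard errors of the point fits via lm for the two path models
  d1 <- data.frame(mv = mv, xv = xv)
  d2 <- data.frame(yv = yv, xv = xv, mv = mv)
  if (!is.null(Zc)) { d1 <- cbind(d1, Zc); d2 <- cbind(d2, Zc) }
  se_a <- summary(stats::lm(mv ~ ., data = d1))$coefficients["xv", 2]
  sm2 <- summary(stats::lm(yv ~ ., data = d2))$coefficients
  se <- c(a = se_a, c_prime = sm2["xv", 2], b = sm2["mv", 2])

  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    p <- paths(sample.int(n, replace = TRUE))
    p[["a"]] * p[["b"]]
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha)))
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 c = unname(est["c"]), c_prime = unname(est["c_prime"]),
                 indirect = unname(est["a"] * est["b"]),
                 ci = ci, conf = conf, se = se, boot = boot,
                 n = n, n_boot = n_boot, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (n = %d): a = %.4f, b = %.4f, c' = %.4f, c = %.4f\n",
              x$n, x$a, x$b, x$c_prime, x$c))
  cat(sprintf("indirect a*b = %.4f, %d%% bootstrap CI [%.4f, %.4f] (%d resamples)\n",
              x$indirect, round(100 * x$conf), x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}
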