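#' Per-gene spatial association with a phenotype map
#'
#' Correlation (Spearman by default, for robustness to non-Gaussian
#' expression; Pearson available) between each gene's regional
#' expression profile and a regional phenotype vector.
#'
#' @param expr regions x genes numeric matrix (columns named by gene).
#' @param phenotype numeric regional vector.
#' @param method `"spearman"` or `"pearson"`.
#' @return named numeric vector of per-gene association scores.
#' @export
gene_score <- function(expr, phenotype, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  .assert(nrow(expr) == length(phenotype), "expr rows must match phenotype length")
  .assert(!anyNA(expr) && !anyNA(phenotype), "missing values in expression or phenotype")
  drop(cor(expr, phenotype, method = method))
}

#' Ensemble-null gene-category enrichment analysis (GCEA)
#'
#' For each gene category, the observed score is the mean member-gene
#' association with the phenotype. The null preserves both spatial
#' autocorrelation and gene-gene co-expression: category scores are
#' recomputed against each surrogate phenotype map using the *real*
#' expression matrix, and the ensemble p value is the two-sided (on
#' `|score|`; or one-sided) rank of the observed score in that null.
#'
#' @param expr regions x genes matrix.
#' @param phenotype regional phenotype vector.
#' @param categories data frame with columns `category_id` and `gene_id`
#'   mapping categories to member genes (gene ids must appear in
#'   `colnames(expr)`).
#' @param surrogates regions x n_surr matrix of surrogate phenotypes
#'   (from [surrogate_maps()]); at least 100 columns.
#' @param min_size categories with fewer annotated member genes are
#'   skipped (with a message).
#' @param method correlation method for [gene_score()].
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return data frame of class `gcea_result`: `category_id`, `size`,
#'   `score`, `direction`, `p_ens`.
#' @export
gcea_ensemble <- function(expr, phenotype, categories, surrogates,
                          min_size = 5, method = "spearman",
                          alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  surrogates <- as.matrix(surrogates)
  .assert(ncol(surrogates) >= 1, "surrogate ensemble is empty", "surrogates")
  if (ncol(surrogates) < 100)
    warning("fewer than 100 surrogates; ensemble p values will be coarse")
  .assert(all(c("category_id", "gene_id") %in% names(categories)),
          "categories needs category_id and gene_id columns", "categories")
  expr <- as.matrix(expr)
  genes <- colnames(expr)
  .assert(!is.null(genes), "expr must have gene column names", "expr")
  .assert(all(categories$gene_id %in% genes), "category member absent from expression matrix")

  if (method == "spearman") {
    X <- apply(expr, 2, rank)
    ph <- rank(phenotype)
    S <- apply(surrogates, 2, rank)
  } else {
    X <- expr; ph <- phenotype; S <- surrogates
  }
  obs_gene <- drop(cor(X, ph))
  null_gene <- cor(X, S)                       # genes x n_surr

  split_idx <- split(match(categories$gene_id, genes), categories$category_id)
  sizes <- lengths(split_idx)
  skip <- sizes < min_size
  if (any(skip))
    message("skipping ", sum(skip), " categor", if (sum(skip) == 1) "y" else "ies",
            " below min_size = ", min_size, ": ",
            paste(names(split_idx)[skip], collapse = ", "))
  split_idx <- split_idx[!skip]
  n_surr <- ncol(surrogates)
  rows <- lapply(names(split_idx), function(cid) {
    idx <- split_idx[[cid]]
    obs <- mean(obs_gene[idx])
    nul <- colMeans(null_gene[idx, , drop = FALSE])
    exceed <- if (alternative == "two.sided") sum(abs(nul) >= abs(obs))
              else sum(nul >= obs)
    data.frame(category_id = cid, size = length(idx), score = obs,
               direction = sign(obs), p_ens = (1 + exceed) / (n_surr + 1))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_ens, -abs(out$score)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gcea_result", "data.frame")
  out
}

#' First partial least squares component of expression vs phenotype
#'
#' PLS1: the first latent component maximizes covariance between the
#' gene-expression predictors and the phenotype response. With a single
#' response the weight vector is the (normalized) cross-covariance
#' `X'y`, equivalently the first left singular vector of the
#' cross-covariance matrix. Weights are sign-aligned so the component
#' score-phenotype correlation `r` is non-negative.
#'
#' @param expr regions x genes matrix (columns named).
#' @param phenotype regional phenotype vector.
#' @return list of class `pls_result`: `r` (correlation of component
#'   scores with the phenotype), `scores` (per region), `loadings`
#'   (per-gene weights, unit norm).
#' @export
pls_first_component <- function(expr, phenotype) {
  X <- scale(as.matrix(expr), center = TRUE, scale = FALSE)
  y <- phenotype - mean(phenotype)
  .assert(nrow(X) == length(y), "expr rows must match phenotype length")
  w <- drop(crossprod(X, y))
  nw <- sqrt(sum(w^2))
  .assert(nw > 0, "phenotype is orthogonal to every gene (zero cross-covariance)")
  w <- w / nw
  scores <- drop(X %*% w)
  r <- cor(scores, y)
  if (r < 0) { w <- -w; scores <- -scores; r <- -r }
  names(w) <- colnames(expr)
  structure(list(r = r, scores = scores, loadings = w), class = "pls_result")
}

#' Permutation p value for the first PLS component
#'
#' Refits the first component against each surrogate phenotype and
#' returns the one-sided rank `p = (1 + #\{r_null >= r_obs\}) / (n + 1)`.
#'
#' @param expr regions x genes matrix.
#' @param phenotype regional phenotype vector.
#' @param surrogates regions x n_surr surrogate phenotype matrix.
#' @return list with `r`, `p_perm` and the null correlations.
#' @export
pls_permutation_p <- function(expr, phenotype, surrogates) {
  surrogates <- as.matrix(surrogates)
  .assert(ncol(surrogates) >= 1, "surrogate ensemble is empty", "surrogates")
  obs <- pls_first_component(expr, phenotype)
  r_null <- apply(surrogates, 2, function(s) pls_first_component(expr, s)$r)
  list(r = obs$r, p_perm = (1 + sum(r_null >= obs$r)) / (ncol(surrogates) + 1),
       r_null = r_null)
}

#' Select strongly contributing genes from PLS loadings
#'
#' Ranks genes by absolute loading, keeps a total budget of
#' `floor(fraction * n_genes)` genes, and splits the kept genes by
#' loading sign into a positive (PLS+) and a negative (PLS-) set. The
#' selection is invariant to positive rescaling of the loadings.
#'
#' @param loadings named numeric vector of gene loadings.
#' @param fraction total fraction of genes to keep (default 0.25).
#' @return list with character vectors `pls_plus` and `pls_minus`.
#' @export
select_top_loadings <- function(loadings, fraction = 0.25) {
  .assert(fraction > 0 && fraction <= 1, "fraction must be in (0,1]", "fraction")
  n <- length(loadings)
  budget <- floor(fraction * n)
  ord <- order(abs(loadings), decreasing = TRUE)
  sel <- ord[seq_len(budget)]
  nm <- names(loadings) %||% as.character(seq_len(n))
  list(pls_plus = nm[sel[loadings[sel] > 0]],
       pls_minus = nm[sel[loadings[sel] < 0]])
}

#' Scaled robust sigmoid normalization of an expression matrix
#'
#' Per-gene robust sigmoid `1 / (1 + exp(-(x - median) / (IQR/1.35)))`
#' rescaled to the unit interval; a light normalizer for synthetic or
#' already-assembled region x gene matrices.
#'
#' @param expr regions x genes matrix.
#' @return normalized matrix of the same shape.
#' @export
normalize_expression <- function(expr) {
  expr <- as.matrix(expr)
  apply(expr, 2, function(g) {
    s <- stats::IQR(g) / 1.35
    if (s <= 0) return(rep(0.5, length(g)))
    v <- plogis((g - stats::median(g)) / s)
    (v - min(v)) / max(max(v) - min(v), .Machine$double.eps)
  })
}
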