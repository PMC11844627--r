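# Multivariate mapping and inference: PCA, Ward.D2 clustering, k-means,
# Spearman correlation matrices, the two-group test decision tree, Hedges' g.

#' Principal component analysis with a fixed sign convention
#'
#' Thin wrapper around \code{stats::prcomp} on the transposed feature-by-
#' sample matrix (samples become observations). Each loading vector's sign is
#' fixed so its largest-magnitude element is positive, making plots
#' comparable across runs; scores are flipped accordingly.
#'
#' @param mat Feature-by-sample numeric matrix with no missing values
#'   (impute first, e.g. [filter_and_impute()]). Callers pass pre-transformed
#'   input (z-scored genes, or log10 mitoPPS) and that choice is recorded in
#'   \code{provenance}.
#' @param center,scale Passed to \code{prcomp} (defaults: center only).
#' @param provenance Free-text note on the input transform.
#' @return A \code{mito_pca}: list with \code{scores} (samples x PCs),
#'   \code{loadings} (features x PCs), \code{var_fraction},
#'   \code{cum_var_fraction}, \code{center}, \code{scale},
#'   \code{provenance}.
#' @export
run_pca <- function(mat, center = TRUE, scale = FALSE, provenance = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  if (anyNA(mat)) {
    stop("matrix has missing values; run filter_and_impute() or drop incomplete rows first")
  }
  fit <- stats::prcomp(t(mat), center = center, scale. = scale)
  flip <- apply(fit$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(fit$rotation, 2L, flip, "*")
  scores <- sweep(fit$x, 2L, flip, "*")
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(scores = scores, loadings = loadings,
         var_fraction = vf, cum_var_fraction = cumsum(vf),
         center = center, scale = scale, provenance = provenance),
    class = "mito_pca"
  )
}

#' @export
print.mito_pca <- function(x, ...) {
  k <- min(3L, length(x$var_fraction))
  cat("PCA: ", nrow(x$scores), " samples, ", nrow(x$loadings), " features\n",
      "  variance explained by PC1..PC", k, ": ",
      paste(sprintf("%.1f%%", 100 * x$var_fraction[seq_len(k)]), collapse = ", "),
      " (cumulative ", sprintf("%.1f%%", 100 * x$cum_var_fraction[k]), ")\n",
      sep = "")
  invisible(x)
}

#' Ward.D2 hierarchical clustering
#'
#' Euclidean distances followed by Ward's D2 agglomeration
#' (Lance-Williams update on squared distances, \code{stats::hclust}
#' \code{method = "ward.D2"}). Deterministic; merge heights are
#' non-decreasing.
#'
#' @param mat Numeric matrix.
#' @param axis Cluster \code{"columns"} (samples; default) or \code{"rows"}
#'   (features).
#' @return An \code{hclust} object.
#' @export
ward_cluster <- function(mat, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  x <- if (axis == "columns") t(mat) else mat
  if (nrow(x) < 2L) stop("need at least 2 items to cluster")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}

#' Seeded k-means row clustering
#'
#' Reproducible k-means over matrix rows (as used for heatmap row ordering):
#' a fixed seed plus multiple random restarts keeping the best
#' within-cluster sum of squares.
#'
#' @param mat Numeric matrix (rows are the items to cluster).
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed.
#' @param nstart Random restarts (default 25).
#' @return Named integer vector of cluster labels (one per row).
#' @export
kmeans_rows <- function(mat, k, seed = 1L, nstart = 25L) {
  stopifnot(is.matrix(mat), k >= 1L, k <= nrow(mat))
  if (k == 1L) {
    return(stats::setNames(rep(1L, nrow(mat)), rownames(mat)))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fit <- stats::kmeans(mat, centers = k, nstart = nstart, iter.max = 100L)
  stats::setNames(fit$cluster, rownames(mat))
}

#' Spearman correlation matrix with p-values
#'
#' Rank-based correlation between all pairs of rows or columns; ties get
#' average ranks. P-values use the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} df (adequate at the
#' sample sizes involved); for \eqn{|\rho| = 1} the p-value is 0.
#'
#' @param mat Numeric matrix.
#' @param axis Correlate \code{"columns"} (default) or \code{"rows"}.
#' @return List of two symmetric matrices, \code{rho} (unit diagonal) and
#'   \code{p}.
#' @export
spearman_matrix <- function(mat, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  x <- if (axis == "columns") mat else t(mat)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 paired observations")
  rho <- stats::cor(x, method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-15] <- 0
  diag(p) <- 0
  list(rho = rho, p = p)
}

#' Two-group comparison with assumption-gated test selection
#'
#' Picks the comparison test by a fixed decision tree: Shapiro-Wilk on each
#' group gates normality (both p > \code{alpha_gates}), Fligner-Killeen
#' gates variance homogeneity. Normal + homogeneous uses Student's t; normal
#' + heterogeneous Welch's t; non-normal + homogeneous the Wilcoxon rank-sum
#' (Mann-Whitney); non-normal + heterogeneous the Brunner-Munzel test. The
#' choice is a deterministic function of the two gates. Hedges' g is
#' reported alongside regardless of the test chosen.
#'
#' @param x,y Numeric vectors (each n >= 3).
#' @param alpha_gates Significance level of the two gate tests (default
#'   0.05).
#' @return A \code{mito_group_comparison}: list with \code{test} (one of
#'   \code{"student_t"}, \code{"welch_t"}, \code{"wilcoxon"},
#'   \code{"brunner_munzel"}), \code{p_value}, \code{statistic},
#'   \code{normality_p} (per group), \code{variance_p}, \code{hedges_g},
#'   \code{n}.
#' @export
compare_groups <- function(x, y, alpha_gates = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("each group needs at least 3 finite values")
  }
  norm_p <- c(x = stats::shapiro.test(x)$p.value,
              y = stats::shapiro.test(y)$p.value)
  var_p <- stats::fligner.test(list(x, y))$p.value
  normal <- all(norm_p > alpha_gates)
  homogeneous <- var_p > alpha_gates

  if (normal && homogeneous) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    test <- "student_t"
  } else if (normal) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    test <- "welch_t"
  } else if (homogeneous) {
    ht <- stats::wilcox.test(x, y, exact = FALSE)
    test <- "wilcoxon"
  } else {
    ht <- brunner_munzel(x, y)
    test <- "brunner_munzel"
  }
  structure(
    list(test = test,
         p_value = unname(ht$p.value),
         statistic = unname(ht$statistic),
         normality_p = norm_p,
         variance_p = unname(var_p),
         hedges_g = hedges_g(x, y),
         n = c(x = length(x), y = length(y))),
    class = "mito_group_comparison"
  )
}

#' @export
print.mito_group_comparison <- function(x, ...) {
  cat("Two-group comparison (n = ", x$n[1], " vs ", x$n[2], ")\n",
      "  gates: Shapiro-Wilk p = ", format(x$normality_p[1], digits = 3), " / ",
      format(x$normality_p[2], digits = 3),
      ", Fligner-Killeen p = ", format(x$variance_p, digits = 3), "\n",
      "  test: ", x$test, ", p = ", format(x$p_value, digits = 4),
      ", Hedges' g = ", format(x$hedges_g, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Brunner-Munzel test
#'
#' Rank-based test of the stochastic-equality hypothesis
#' \eqn{P(X < Y) + 0.5 P(X = Y) = 0.5}, valid under unequal variances and
#' non-normality. Uses the t approximation with Satterthwaite-style degrees
#' of freedom.
#'
#' @param x,y Numeric vectors.
#' @return List with \code{statistic}, \code{df}, \code{p.value}, and
#'   \code{estimate} (the relative effect \eqn{\hat p = P(X < Y) + 0.5
#'   P(X = Y)}).
#' @export
brunner_munzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pooled <- n1 * v1 + n2 * v2
  if (pooled == 0) {
    # no rank variance (e.g. complete separation): p-value degenerates
    stat <- sign(m2 - m1) * Inf
    df <- n1 + n2 - 2
  } else {
    stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(pooled)
    df <- pooled^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs(stat), df = df)
  list(statistic = stat, df = df, p.value = p,
       estimate = (m2 - (n2 + 1) / 2) / n1)
}

#' Hedges' g effect size
#'
#' Pooled-SD Cohen's d with the small-sample bias correction
#' \eqn{J = 1 - 3/(4\,df - 1)}, \eqn{df = n_x + n_y - 2}. Positive when
#' \code{x} has the larger mean; swapping the groups flips the sign only.
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @return Numeric scalar.
#' @export
hedges_g <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least 2 values")
  df <- nx + ny - 2
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df)
  if (sp == 0) return(0)
  d <- (mean(x) - mean(y)) / sp
  d * (1 - 3 / (4 * df - 1))
}
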