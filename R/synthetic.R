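# Synthetic expression data with known ground truth: per-sample scale
# factors (mitochondrial content), planted pathway prioritizations, and
# multiplicative log-normal noise, so every pipeline stage is testable
# without external data.

#' Miniature three-level pathway hierarchy
#'
#' A fixed 12-pathway hierarchy (2 level-1 branches, 4 level-2 pathways, 6
#' level-3 leaves) whose leaves partition the synthetic gene set evenly.
#' Parents carry the union of their children's genes, mirroring the nesting
#' of the real annotation. Used as the generator's default shape and as the
#' in-code test fixture.
#'
#' @param n_genes Total genes, split evenly over the 6 leaves (must be a
#'   multiple of 6).
#' @param gene_prefix Prefix for the synthetic gene symbols.
#' @return A \code{mito_hierarchy}.
#' @export
mini_hierarchy <- function(n_genes = 300L, gene_prefix = "G") {
  if (n_genes %% 6L != 0L) stop("n_genes must be a multiple of 6")
  leaves <- c("A1a", "A1b", "A2a", "B1a", "B1b", "B2a")
  per <- n_genes / 6L
  genes_all <- paste0(gene_prefix, sprintf("%04d", seq_len(n_genes)))
  leaf_genes <- split(genes_all, rep(leaves, each = per))[leaves]

  branch <- function(leaf) substr(leaf, 1, 1)          # A / B
  limb <- function(leaf) substr(leaf, 1, 2)            # A1 / A2 / B1 / B2
  l1_ids <- c(A = "MitoGroupA", B = "MitoGroupB")
  l2_short <- c(A1 = "PathA1", A2 = "PathA2", B1 = "PathB1", B2 = "PathB2")
  l2_ids <- stats::setNames(paste(l1_ids[substr(names(l2_short), 1, 1)],
                                  l2_short, sep = " > "), names(l2_short))
  l3_ids <- stats::setNames(paste(l2_ids[limb(leaves)], paste0("Leaf", leaves),
                                  sep = " > "), leaves)

  genes <- c(
    lapply(c(A = "A", B = "B"), function(b)
      unlist(leaf_genes[branch(leaves) == b], use.names = FALSE)),
    lapply(names(l2_short), function(lb)
      unlist(leaf_genes[limb(leaves) == lb], use.names = FALSE)),
    leaf_genes
  )
  names(genes) <- c(l1_ids, l2_ids, l3_ids)

  nodes <- data.frame(
    id = names(genes),
    name = c(unname(l1_ids), unname(l2_short), paste0("Leaf", leaves)),
    level = c(1L, 1L, rep(2L, 4), rep(3L, 6)),
    parent_id = c(NA, NA, unname(l1_ids[substr(names(l2_short), 1, 1)]),
                  unname(l2_ids[limb(leaves)])),
    n_genes = vapply(genes, length, integer(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(nodes = nodes, genes = genes, gene_universe = genes_all,
         species = "human"),
    class = "mito_hierarchy"
  )
}

#' Configuration for the synthetic-data generator
#'
#' Defines the conditions a synthetic dataset emulates. Defaults give the
#' standard validation fixture: 300 genes in the 12-pathway
#' [mini_hierarchy()], 24 samples in 4 groups, per-sample mitochondrial
#' content drawn log-normally (sdlog 0.5, a severalfold spread as seen
#' between tissues), neutral priorities, and moderate multiplicative noise
#' (sigma 0.1 on the natural-log scale).
#'
#' @param n_genes Genes (multiple of 6).
#' @param n_samples Samples.
#' @param groups Group label per sample (recycled from
#'   \code{paste0("grp", 1:n_groups)} when \code{NULL}).
#' @param n_groups Number of groups when \code{groups} is \code{NULL}.
#' @param priorities Planted prioritization factors: named list mapping a
#'   group label to a named numeric vector of per-pathway factors (keyed by
#'   pathway id of the [mini_hierarchy()] *leaf* carrying the genes; 1 =
#'   neutral). Unlisted groups/pathways are neutral.
#' @param scale_factors Per-sample positive scale factors (mitochondrial
#'   content); \code{NULL} draws them log-normally (sdlog 0.5).
#' @param sigma Sdlog of the multiplicative log-normal noise (0 = noiseless).
#' @param missing_rate Fraction of cells set to \code{NA} (intensity mode).
#' @param mode \code{"intensity"} (log-normal values) or \code{"count"}
#'   (Poisson draws around the same mean, for exercising the TMM path).
#' @param base_meanlog,base_sdlog Log-normal parameters of the per-gene
#'   baseline expression.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the config including the seed.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_genes = 300L, n_samples = 24L, groups = NULL,
                             n_groups = 4L, priorities = list(),
                             scale_factors = NULL, sigma = 0.1,
                             missing_rate = 0, mode = c("intensity", "count"),
                             base_meanlog = log(100), base_sdlog = 1,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(groups)) {
    groups <- rep(paste0("grp", seq_len(n_groups)), length.out = n_samples)
  }
  stopifnot(length(groups) == n_samples, sigma >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(scale_factors)) {
    stopifnot(length(scale_factors) == n_samples, all(scale_factors > 0))
  }
  for (g in names(priorities)) {
    if (any(priorities[[g]] <= 0)) stop("priority factors must be positive")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
         groups = groups, priorities = priorities,
         scale_factors = scale_factors, sigma = sigma,
         missing_rate = missing_rate, mode = mode,
         base_meanlog = base_meanlog, base_sdlog = base_sdlog,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic expression dataset with known truth
#'
#' Expression is built multiplicatively:
#' \code{expr(g, s) = base(g) * scale(s) * priority(group(s), pathway(g)) *
#' LogNormal(0, sigma)}; count mode instead draws Poisson counts around that
#' mean. With all priorities 1 and sigma 0 every sample has the same profile
#' up to its scale factor, the null model of proportional pathway
#' expression: every mitoPPS is exactly 1. Planting a priority factor on a
#' pathway multiplies its genes' expression in that group, creating a known
#' prioritization to be recovered.
#'
#' @param config A [synthetic_config()].
#' @return List: \code{expr} (gene x sample matrix; counts in count mode),
#'   \code{hierarchy} (the [mini_hierarchy()]), \code{samples} (data.frame
#'   \code{sample_id}, \code{group}), and \code{truth} (list with
#'   \code{base}, \code{scale}, \code{groups}, \code{priority}
#'   (group x leaf-pathway factor matrix), \code{gene_pathway} (leaf id per
#'   gene), \code{expected_scores} (noiseless pathway x sample score
#'   matrix over all 12 pathways), and the \code{config}).
#' @export
#' @examples
#' d <- generate_synthetic(synthetic_config(sigma = 0, seed = 42))
#' pps <- compute_mitopps(score_pathways(d$expr, d$hierarchy))
#' range(pps)  # all 1 under the null model
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  h <- mini_hierarchy(config$n_genes)
  leaves <- h$nodes$id[h$nodes$level == 3L]
  gene_pathway <- stats::setNames(rep(leaves, vapply(h$genes[leaves], length, integer(1))),
                                  unlist(h$genes[leaves], use.names = FALSE))
  gene_pathway <- gene_pathway[h$gene_universe]

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  base <- stats::setNames(
    stats::rlnorm(config$n_genes, config$base_meanlog, config$base_sdlog),
    h$gene_universe)
  scale <- config$scale_factors
  if (is.null(scale)) scale <- stats::rlnorm(config$n_samples, 0, 0.5)
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  names(scale) <- sample_ids

  group_levels <- unique(config$groups)
  priority <- matrix(1, length(group_levels), length(leaves),
                     dimnames = list(group_levels, leaves))
  for (g in names(config$priorities)) {
    v <- config$priorities[[g]]
    unknown <- setdiff(names(v), leaves)
    if (length(unknown)) {
      stop("priority factors must be keyed by leaf pathway id; unknown: ",
           paste(unknown, collapse = ", "))
    }
    priority[g, names(v)] <- v
  }

  # noiseless mean: base x sample scale x group/pathway priority
  pr_gene <- priority[, gene_pathway[h$gene_universe], drop = FALSE]  # group x gene
  mean_mat <- outer(base, scale) *
    t(pr_gene[match(config$groups, group_levels), , drop = FALSE])
  dimnames(mean_mat) <- list(h$gene_universe, sample_ids)

  expr <- if (config$mode == "count") {
    m <- matrix(stats::rpois(length(mean_mat), lambda = mean_mat),
                nrow = nrow(mean_mat), dimnames = dimnames(mean_mat))
    storage.mode(m) <- "double"
    m
  } else if (config$sigma > 0) {
    mean_mat * matrix(stats::rlnorm(length(mean_mat), 0, config$sigma),
                      nrow = nrow(mean_mat))
  } else {
    mean_mat
  }

  if (config$missing_rate > 0 && config$mode == "intensity") {
    drop <- stats::runif(length(expr)) < config$missing_rate
    expr[drop] <- NA_real_
  }

  expected_scores <- t(vapply(h$nodes$id, function(p) {
    colMeans(mean_mat[h$genes[[p]], , drop = FALSE])
  }, numeric(config$n_samples)))

  list(
    expr = new_expression_matrix(expr,
      unit = if (config$mode == "count") "count" else "intensity"),
    hierarchy = h,
    samples = data.frame(sample_id = sample_ids, group = config$groups,
                         stringsAsFactors = FALSE),
    truth = list(base = base, scale = scale, groups = config$groups,
                 priority = priority, gene_pathway = gene_pathway,
                 expected_scores = expected_scores, config = config)
  )
}

#' Recovery of planted prioritizations from computed mitoPPS
#'
#' Compares group-mean mitoPPS against the planted priority factors over the
#' leaf pathways. The rank correlation is the mean Spearman correlation,
#' within each group that carries planted (non-neutral) variation, between
#' that group's planted factors and its mean mitoPPS per leaf; groups with
#' uniform factors are skipped, because with an all-sample reference their
#' mitoPPS shift inversely to the planted groups' by construction. The
#' detection table reports, for every group with a planted factor, whether
#' the pathway with the largest group-vs-rest mitoPPS difference is the
#' planted one.
#'
#' @param mitopps A [compute_mitopps()] matrix on the synthetic data.
#' @param truth The \code{truth} element from [generate_synthetic()].
#' @return List: \code{rank_correlation}; \code{detection} (data.frame per
#'   planted group: \code{group}, \code{planted}, \code{top_ranked},
#'   \code{detected}).
#' @export
recovery_report <- function(mitopps, truth) {
  leaves <- colnames(truth$priority)
  groups <- rownames(truth$priority)
  kept <- colnames(mitopps)
  grp_of <- stats::setNames(truth$groups,
                            sprintf("S%03d", seq_along(truth$groups)))[kept]

  group_mean <- t(vapply(groups, function(g) {
    rowMeans(unclass(mitopps)[leaves, grp_of == g, drop = FALSE])
  }, numeric(length(leaves))))  # groups x leaves

  varying <- groups[apply(truth$priority, 1L, function(v) stats::sd(v) > 0)]
  rank_cor <- if (!length(varying)) NA_real_ else {
    mean(vapply(varying, function(g) {
      stats::cor(truth$priority[g, ], group_mean[g, ], method = "spearman")
    }, numeric(1)))
  }

  planted_groups <- groups[apply(truth$priority != 1, 1L, any)]
  detection <- do.call(rbind, lapply(planted_groups, function(g) {
    diff <- group_mean[g, ] - colMeans(group_mean[setdiff(groups, g), , drop = FALSE])
    top <- leaves[which.max(diff)]
    planted_p <- leaves[which.max(truth$priority[g, ])]
    data.frame(group = g, planted = planted_p, top_ranked = top,
               detected = identical(top, planted_p), stringsAsFactors = FALSE)
  }))
  list(rank_correlation = rank_cor, detection = detection)
}
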