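# MitoPathway composite scores, bespoke gene-list scores, pathway ratios,
# between-group fold differences.

#' MitoPathway composite scores
#'
#' Scores every pathway in the hierarchy for every sample as the arithmetic
#' mean of its member genes' expression -- over the member genes *present* in
#' the matrix, never over child-pathway sub-scores. Pathways whose gene
#' coverage (present members / annotated members) falls below
#' \code{min_coverage} are still scored but flagged unreliable; pathways with
#' no member present get \code{NA}, never a silent zero. Scores inherit the
#' expression unit, so scaling a sample's expression by c scales all its
#' pathway scores by c.
#'
#' @param expr Gene-by-sample expression matrix restricted to (or at least
#'   intersecting) the mitochondrial gene universe; rows keyed by canonical
#'   symbol.
#' @param hierarchy A [load_mitocarta()] hierarchy.
#' @param min_coverage Coverage fraction below which a pathway is flagged.
#' @return Pathway-by-sample \code{score_matrix}: a numeric matrix with
#'   attributes \code{coverage} (named fraction per pathway),
#'   \code{low_coverage} (flagged pathway ids) and \code{unit}.
#' @export
score_pathways <- function(expr, hierarchy, min_coverage = 0.5) {
  stopifnot(is.matrix(expr), inherits(hierarchy, "mito_hierarchy"))
  ids <- hierarchy$nodes$id
  scores <- matrix(NA_real_, length(ids), ncol(expr),
                   dimnames = list(ids, colnames(expr)))
  coverage <- stats::setNames(numeric(length(ids)), ids)
  for (p in ids) {
    members <- hierarchy$genes[[p]]
    present <- intersect(members, rownames(expr))
    coverage[p] <- length(present) / length(members)
    if (length(present)) {
      scores[p, ] <- colMeans(expr[present, , drop = FALSE])
    }
  }
  attr(scores, "coverage") <- coverage
  attr(scores, "low_coverage") <- ids[coverage < min_coverage]
  attr(scores, "unit") <- expression_unit(expr)
  class(scores) <- c("score_matrix", class(scores))
  scores
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("MitoPathway score matrix: ", nrow(x), " pathways x ", ncol(x),
      " samples (unit: ", attr(x, "unit"), ")\n", sep = "")
  low <- attr(x, "low_coverage")
  if (length(low)) {
    cat("  ", length(low), " pathway(s) below coverage threshold\n", sep = "")
  }
  invisible(x)
}

#' Mean-expression score for an ad-hoc gene list
#'
#' Same semantics as a pathway score, for a caller-supplied list (e.g. a
#' fatty-acid-oxidation panel, or proliferation {MKI67, TOP2A, RRM2} and
#' senescence {CDKN2A, CDKN1A, TP53} indices): the per-sample mean over the
#' listed genes present in the matrix.
#'
#' @param expr Gene-by-sample matrix.
#' @param genes Character vector of gene symbols (>= 1 must be present).
#' @param name Optional label.
#' @return List: \code{score} (named per-sample vector), \code{used} and
#'   \code{absent} gene vectors, \code{name}.
#' @export
gene_list_score <- function(expr, genes, name = "gene_list") {
  stopifnot(is.matrix(expr))
  present <- intersect(genes, rownames(expr))
  if (!length(present)) stop("none of the listed genes is present in the matrix")
  list(
    score = colMeans(expr[present, , drop = FALSE]),
    used = present,
    absent = setdiff(genes, present),
    name = name
  )
}

#' Per-sample ratio of two pathway scores
#'
#' @param scores A [score_pathways()] matrix.
#' @param numerator,denominator Pathway ids (full path or unambiguous short
#'   name).
#' @return Named numeric vector of per-sample ratios; samples with a zero or
#'   non-finite denominator get \code{NA} and are listed in the
#'   \code{flagged} attribute rather than returned as silent \code{Inf}.
#' @export
pathway_ratio <- function(scores, numerator, denominator) {
  num <- scores[match_score_row(scores, numerator), ]
  den <- scores[match_score_row(scores, denominator), ]
  bad <- !is.finite(den) | den == 0 | !is.finite(num)
  out <- num / den
  out[bad] <- NA_real_
  attr(out, "flagged") <- colnames(scores)[bad]
  out
}

match_score_row <- function(scores, id) {
  i <- match(id, rownames(scores))
  if (is.na(i)) {
    hits <- grep(paste0("(^| > )", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", id), "$"),
                 rownames(scores))
    if (length(hits) == 1L) return(hits)
    if (length(hits) > 1L) {
      stop("pathway '", id, "' is ambiguous among scored pathways: ",
           paste(rownames(scores)[hits], collapse = " | "))
    }
    stop("pathway '", id, "' not found in score matrix")
  }
  i
}

#' Fold difference of a pathway score between two sample groups
#'
#' Two summaries are offered because population contrasts and matched-donor
#' contrasts answer different questions: \code{ratio_of_means} divides the
#' group means (the default for unpaired tissue-vs-tissue contrasts), while
#' \code{mean_of_ratios} averages per-pair ratios and is the natural summary
#' when samples are donor-matched (pairing by position in \code{group_a} /
#' \code{group_b}).
#'
#' @param scores A [score_pathways()] matrix.
#' @param pathway Pathway id.
#' @param group_a,group_b Sample id vectors (non-empty; \code{mean_of_ratios}
#'   requires equal lengths, paired by position).
#' @param summary \code{"ratio_of_means"} or \code{"mean_of_ratios"}.
#' @return List: \code{fold}, \code{summary}, \code{n_a}, \code{n_b}; in
#'   paired mode also \code{ratios} (per-pair) and \code{range}.
#' @export
fold_difference <- function(scores, pathway, group_a, group_b,
                            summary = c("ratio_of_means", "mean_of_ratios")) {
  summary <- match.arg(summary)
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  row <- match_score_row(scores, pathway)
  a <- scores[row, group_a]; b <- scores[row, group_b]
  if (any(c(a, b) <= 0, na.rm = TRUE)) {
    stop("fold differences require strictly positive scores")
  }
  if (summary == "ratio_of_means") {
    list(fold = mean(a) / mean(b), summary = summary,
         n_a = length(a), n_b = length(b))
  } else {
    if (length(a) != length(b)) {
      stop("mean_of_ratios pairs samples by position; groups must have equal length")
    }
    r <- a / b
    list(fold = mean(r), summary = summary, ratios = r, range = range(r),
         n_a = length(a), n_b = length(b))
  }
}

#' Radar-chart axis bounds
#'
#' Axis limits used when drawing pathway radar charts: the dataset maximum
#' padded upward by 10\% of its magnitude and the minimum padded downward by
#' 10\% of its magnitude, so plots of the same dataset are reproducible.
#'
#' @param x Numeric vector or matrix of the values to be drawn.
#' @return Numeric vector \code{c(lower, upper)}.
#' @export
radar_bounds <- function(x) {
  lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
  c(lower = lo - 0.1 * abs(lo), upper = hi + 0.1 * abs(hi))
}
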