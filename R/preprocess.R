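# Normalization and cleaning: TMM scaling, detection filtering,
# half-minimum imputation, standard transforms.

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scale factors for a raw count matrix,
#' via \code{edgeR::calcNormFactors}: the reference sample is the one whose
#' 75th-percentile count fraction is closest to the mean across samples; for
#' every other sample a precision-weighted trimmed mean of log2 expression
#' ratios (M) is taken after trimming 30\% of M values and 5\% of A values,
#' with genes that are zero in either member of the pair excluded; factors
#' are re-centered so their product is 1. Library-size differences with
#' identical composition are therefore absorbed entirely by
#' library-size x factor.
#'
#' @param counts Non-negative gene-by-sample count matrix (>= 2 samples).
#' @param m_trim,a_trim Trim fractions for M and A values (canonical 0.30 /
#'   0.05).
#' @return Named numeric vector of per-sample factors (product 1), with
#'   attributes \code{lib_size}, \code{reference} (the reference sample id)
#'   and \code{method = "TMM"}.
#' @export
#' @examples
#' counts <- matrix(rpois(200, 50), 50, 4,
#'                  dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
#' f <- tmm_factors(counts)
#' prod(f)  # 1
tmm_factors <- function(counts, m_trim = 0.30, a_trim = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2L)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  # reference choice mirrors the canonical rule so it can be reported
  f75 <- apply(counts, 2L, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))[1]
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                              logratioTrim = m_trim, sumTrim = a_trim,
                              doWeighting = TRUE)
  f <- stats::setNames(as.numeric(f), colnames(counts))
  attr(f, "lib_size") <- lib
  attr(f, "reference") <- colnames(counts)[ref]
  attr(f, "method") <- "TMM"
  f
}

#' Scale counts into normalized counts per million
#'
#' Divides each column by (library size x normalization factor) and
#' multiplies by 1e6, yielding TMM-normalized CPM -- the "nTPM"-style unit
#' used for pathway scoring. With unit factors this is plain CPM.
#'
#' @param counts Count matrix.
#' @param factors Factors from [tmm_factors()], or \code{NULL} for plain CPM.
#' @return Expression matrix (unit \code{"normalized-count"}).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  stopifnot(is.matrix(counts))
  lib <- colSums(counts)
  if (is.null(factors)) {
    factors <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
  }
  if (!is.null(colnames(counts))) {
    miss <- setdiff(colnames(counts), names(factors))
    if (length(miss)) {
      stop("no normalization factor for sample(s): ", paste(miss, collapse = ", "))
    }
    factors <- factors[colnames(counts)]
  }
  out <- sweep(counts, 2L, lib * as.numeric(factors), "/") * 1e6
  new_expression_matrix(out, unit = "normalized-count")
}

#' Detection filtering and half-minimum imputation
#'
#' Cleans a proteomics-style intensity matrix with missing values: genes
#' observed in no sample are removed first; if the input is on a log10 scale
#' it is exponentiated back to linear intensities; every remaining missing
#' cell is then set to half of that gene's minimum observed value (a low but
#' non-zero stand-in below the detection limit). Idempotent: a second pass
#' changes nothing.
#'
#' @param intensities Gene-by-sample matrix with missing values as \code{NA}
#'   (missingness is explicit, never conflated with zero).
#' @param assume_log10 If \code{TRUE}, values are \code{10^x}-transformed
#'   before imputation.
#' @return List: \code{expr} (complete matrix) and \code{report} with
#'   \code{n_removed_genes}, \code{n_imputed_values}, \code{fraction_imputed}
#'   (of cells after removal) and \code{imputed_value} (named per-gene vector,
#'   \code{NA} for genes needing no imputation).
#' @export
filter_and_impute <- function(intensities, assume_log10 = FALSE) {
  stopifnot(is.matrix(intensities))
  all_missing <- rowSums(!is.na(intensities)) == 0L
  mat <- intensities[!all_missing, , drop = FALSE]
  if (assume_log10) mat <- 10^mat
  na_idx <- is.na(mat)
  half_min <- apply(mat, 1L, function(x) {
    if (anyNA(x)) min(x, na.rm = TRUE) / 2 else NA_real_
  })
  if (any(na_idx)) {
    mat[na_idx] <- half_min[row(mat)[na_idx]]
  }
  report <- list(
    n_removed_genes = sum(all_missing),
    n_imputed_values = sum(na_idx),
    fraction_imputed = sum(na_idx) / length(mat),
    imputed_value = half_min
  )
  list(expr = new_expression_matrix(mat, unit = expression_unit(intensities)),
       report = report)
}

#' Standard matrix transforms
#'
#' @param mat Expression (or score) matrix.
#' @param mode \code{"zscore_by_gene"} centers and scales each row to mean 0,
#'   sd 1 across samples (constant rows map to zero with a warning);
#'   \code{"log10"} / \code{"log2"} take logs, requiring strictly positive
#'   entries unless \code{pseudocount > 0}.
#' @param pseudocount Added before log transforms.
#' @return Transformed matrix (same dimnames).
#' @export
transform_expression <- function(mat, mode = c("zscore_by_gene", "log10", "log2"),
                                 pseudocount = 0) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat))
  if (mode == "zscore_by_gene") {
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1L, stats::sd)
    flat <- sdv == 0 | is.na(sdv)
    if (any(flat)) {
      warning(sum(flat), " constant gene(s) mapped to all-zero z-scores")
      sdv[flat] <- 1
    }
    out <- (mat - mu) / sdv
    out[flat, ] <- 0
    return(out)
  }
  x <- mat + pseudocount
  if (any(x <= 0, na.rm = TRUE)) {
    stop("log transform needs strictly positive values; supply a pseudocount")
  }
  if (mode == "log10") log10(x) else log2(x)
}
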