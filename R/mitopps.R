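# Mitochondrial Pathway Prioritization Scores (mitoPPS): ratio-based
# prioritization of each pathway relative to all other pathways and samples.

#' Compute mitochondrial Pathway Prioritization Scores
#'
#' For sample \eqn{S_i} and pathway \eqn{P_i}, the mitoPPS is the average
#' over all other pathways \eqn{P_n} of the within-sample score ratio
#' \eqn{Score(S_i,P_i)/Score(S_i,P_n)}, each ratio normalized by its
#' arithmetic mean across the reference samples:
#' \deqn{mitoPPS(S_i,P_i) = \frac{1}{n'-1} \sum_{P_n \neq P_i}
#'   \frac{Score(S_i,P_i)/Score(S_i,P_n)}
#'        {\frac{1}{x'}\sum_{S_x} Score(S_x,P_i)/Score(S_x,P_n)}}
#' with \eqn{n'} pathways and \eqn{x'} reference samples. A value of 1 is
#' average priority, >1 prioritized, <1 deprioritized. Because every term is
#' a within-sample ratio, multiplying one sample's expression (hence all its
#' pathway scores) by a positive constant changes nothing: the metric is
#' independent of overall mitochondrial content. With the reference being all
#' samples, each pathway's mitoPPS averages to exactly 1 across samples.
#'
#' Samples whose inclusion would create non-finite ratios (any zero, negative
#' or missing pathway score) are handled per \code{on_nonfinite}: the default
#' \code{"exclude"} drops them and records them in the \code{excluded}
#' attribute; \code{"error"} stops; \code{"epsilon"} floors offending scores
#' at the smallest positive score times 1e-3 and keeps the samples.
#'
#' @param scores Pathway-by-sample [score_pathways()] matrix (>= 2 pathways).
#'   Pathways that are missing (\code{NA}) in every sample -- e.g. zero gene
#'   coverage -- are dropped with a warning before anything else.
#' @param reference Sample ids whose average ratios form the denominator;
#'   \code{NULL} (default) uses all retained samples. Passing a control
#'   subset gives the control-referenced variant: controls then average to 1
#'   and every other sample is expressed relative to the control profile.
#' @param on_nonfinite Policy for samples with nonpositive/missing scores.
#' @return A \code{mitopps_matrix}: pathways x retained samples, all entries
#'   positive and finite, with attributes \code{reference} (ids used) and
#'   \code{excluded} (named list: offending pathways per dropped sample).
#' @seealso [finite_check()], [prioritization_percent()], [log10_mitopps()],
#'   [dynamic_range()]
#' @export
#' @examples
#' s <- matrix(c(2, 1, 1, 1, 1, 1), nrow = 3,
#'             dimnames = list(c("P1", "P2", "P3"), c("S1", "S2")))
#' compute_mitopps(s)  # S1/P1 = 4/3, S2/P1 = 2/3, S1/P2 = 5/6, ...
compute_mitopps <- function(scores, reference = NULL,
                            on_nonfinite = c("exclude", "error", "epsilon")) {
  on_nonfinite <- match.arg(on_nonfinite)
  stopifnot(is.matrix(scores))
  mat <- unclass(scores)
  attributes(mat) <- attributes(mat)[c("dim", "dimnames")]

  all_na <- rowSums(is.finite(mat)) == 0L
  if (any(all_na)) {
    warning(sum(all_na), " pathway(s) with no finite score dropped: ",
            paste(utils::head(rownames(mat)[all_na], 3), collapse = ", "))
    mat <- mat[!all_na, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("mitoPPS needs at least 2 scored pathways")

  offenders <- finite_check(mat)
  excluded <- list()
  if (length(offenders)) {
    if (on_nonfinite == "error") {
      stop("nonpositive/missing scores in sample(s): ",
           paste(names(offenders), collapse = ", "))
    } else if (on_nonfinite == "epsilon") {
      eps <- min(mat[is.finite(mat) & mat > 0]) * 1e-3
      bad <- !is.finite(mat) | mat <= 0
      mat[bad] <- eps
    } else {
      excluded <- offenders
      mat <- mat[, setdiff(colnames(mat), names(offenders)), drop = FALSE]
      if (ncol(mat) == 0L) stop("all samples excluded by the finite check")
    }
  }

  if (is.null(reference)) {
    ref_ids <- colnames(mat)
  } else {
    ref_ids <- setdiff(reference, names(excluded))
    miss <- setdiff(ref_ids, colnames(mat))
    if (length(miss)) stop("reference sample(s) not in score matrix: ",
                           paste(miss, collapse = ", "))
    if (!length(ref_ids)) stop("reference sample set is empty")
  }

  n <- nrow(mat)
  # denominator: mean over reference samples of the pathway-pair ratio matrix
  denom <- matrix(0, n, n)
  for (s in ref_ids) {
    col <- mat[, s]
    denom <- denom + outer(col, 1 / col)
  }
  denom <- denom / length(ref_ids)

  pps <- matrix(NA_real_, n, ncol(mat), dimnames = dimnames(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    m <- outer(col, 1 / col) / denom
    pps[, j] <- (rowSums(m) - 1) / (n - 1)  # diagonal term is exactly 1
  }
  attr(pps, "reference") <- ref_ids
  attr(pps, "excluded") <- excluded
  class(pps) <- c("mitopps_matrix", class(pps))
  pps
}

#' Control-referenced mitoPPS
#'
#' Convenience wrapper for treatment/longitudinal designs: the denominator of
#' the mitoPPS formula is averaged over the designated control samples only,
#' so a sample matching the controls' average ratio profile scores 1 in every
#' pathway, and the mean-1 invariant holds over the control subset rather
#' than over all samples.
#'
#' @inheritParams compute_mitopps
#' @param control_ids Sample ids forming the reference (subset of the score
#'   matrix's columns).
#' @return A \code{mitopps_matrix} (see [compute_mitopps()]).
#' @export
control_referenced_mitopps <- function(scores, control_ids,
                                       on_nonfinite = c("exclude", "error", "epsilon")) {
  stopifnot(length(control_ids) >= 1L)
  compute_mitopps(scores, reference = control_ids,
                  on_nonfinite = match.arg(on_nonfinite))
}

#' @export
print.mitopps_matrix <- function(x, ...) {
  cat("mitoPPS matrix: ", nrow(x), " pathways x ", ncol(x), " samples",
      " (reference: ", length(attr(x, "reference")), " sample(s))\n", sep = "")
  excl <- attr(x, "excluded")
  if (length(excl)) {
    cat("  excluded sample(s): ", paste(names(excl), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Samples that would produce non-finite mitoPPS ratios
#'
#' A sample breaks the ratio machinery as soon as one of its pathway scores
#' is zero, negative or missing (it would appear in a denominator). This
#' reports those samples with their offending pathways without modifying
#' anything.
#'
#' @param scores Pathway-by-sample score matrix.
#' @return Named list (one element per offending sample) of character vectors
#'   of offending pathway ids; empty list when all scores are positive and
#'   finite.
#' @export
finite_check <- function(scores) {
  stopifnot(is.matrix(scores))
  bad <- !is.finite(scores) | scores <= 0
  cols <- which(colSums(bad) > 0L)
  out <- lapply(cols, function(j) rownames(scores)[bad[, j]])
  names(out) <- colnames(scores)[cols]
  out
}

#' Express mitoPPS as prioritization percent
#'
#' Affine map \code{(value - 1) * 100}: a mitoPPS of 2.1 is +110\%
#' prioritization, 0.35 is -65\%, 1 is 0\%.
#'
#' @param m A \code{mitopps_matrix} (or any numeric array).
#' @return Same shape, in percent units.
#' @export
prioritization_percent <- function(m) {
  out <- (unclass(m) - 1) * 100
  attributes(out) <- attributes(unclass(m))[c("dim", "dimnames")]
  out
}

#' mitoPPS on the log10 scale
#'
#' On this scale 0 is average priority, +1 a tenfold prioritization, -1 a
#' tenfold deprioritization -- the scale used for heatmap displays.
#'
#' @param m A \code{mitopps_matrix} (positive entries).
#' @return log10-transformed matrix.
#' @export
log10_mitopps <- function(m) {
  out <- log10(unclass(m))
  attributes(out) <- attributes(unclass(m))[c("dim", "dimnames")]
  out
}

#' Per-pathway mitoPPS dynamic range
#'
#' The delta between the highest and lowest mitoPPS of each pathway across a
#' sample subset, on the linear scale -- used to compare inter-tissue
#' diversity against within-cell-type plasticity.
#'
#' @param m A \code{mitopps_matrix}.
#' @param samples Sample ids (default: all columns).
#' @return Named numeric vector (one delta per pathway).
#' @export
dynamic_range <- function(m, samples = colnames(m)) {
  if (!length(samples)) stop("sample subset must be non-empty")
  sub <- unclass(m)[, samples, drop = FALSE]
  apply(sub, 1L, function(x) max(x) - min(x))
}
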