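# Independent oracles, deliberately naive and kept separate from the
# production code paths they check.

# Literal triple-loop evaluation of the mitoPPS double sum.
mitopps_oracle <- function(scores, reference = colnames(scores)) {
  n <- nrow(scores)
  out <- matrix(NA_real_, n, ncol(scores), dimnames = dimnames(scores))
  for (j in seq_len(ncol(scores))) {
    for (i in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) {
        if (k == i) next
        num <- scores[i, j] / scores[k, j]
        den <- mean(scores[i, reference] / scores[k, reference])
        acc <- acc + num / den
      }
      out[i, j] <- acc / (n - 1)
    }
  }
  out
}

# Naive transcription of the published TMM algorithm (reference column by
# 75th-percentile count fraction; doubly trimmed, precision-weighted mean of
# log2 ratios; factors re-centered to geometric mean 1).
tmm_oracle <- function(counts, m_trim = 0.30, a_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))[1]
  nr <- counts[, ref]; Nr <- lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    no <- counts[, j]; No <- lib[j]
    keep <- no > 0 & nr > 0
    o <- no[keep]; r <- nr[keep]
    M <- log2((o / No) / (r / Nr))
    A <- (log2(o / No) + log2(r / Nr)) / 2
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * m_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    w <- (No - o) / (No * o) + (Nr - r) / (Nr * r)  # delta-method variance of M
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Naive Ward.D2 agglomeration via the Lance-Williams update on the
# distance matrix (alpha_i = (n_i+n_k)/(n_i+n_j+n_k), beta = -n_k/..,
# gamma = 0, applied to squared distances).
ward_d2_oracle <- function(x) {
  d2 <- as.matrix(dist(x))^2
  n <- nrow(d2)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_val <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a >= b) next
        v <- d2[active[a], active[b]]
        if (v < best_val) { best_val <- v; best <- c(active[a], active[b]) }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(best_val)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      newd <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * best_val) /
        (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- newd
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Spearman via explicit rank transform + Pearson.
spearman_oracle <- function(a, b) {
  cor(rank(a), rank(b), method = "pearson")
}
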