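# Mutual information (in bits) and adjusted mutual information of two
# clusterings, the comparison at the heart of the correlation matrix.

entropy_bits <- function(x) {
  p <- tabulate(match(x, unique(x)))
  p <- p / sum(p)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

#' Mutual information of two clusterings, in bits
#'
#' `I(X,Y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )` over the empirical
#' joint distribution of labels; terms with `p(x,y) = 0` contribute 0.
#'
#' @param x,y label vectors of equal length (any atomic type).
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stopf("clustering vectors differ in length (%d vs %d)",
          length(x), length(y))
  n <- length(x)
  tab <- table(x, y)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  ratio <- pxy / outer(px, py)
  sum(ifelse(pxy > 0, pxy * log2(ratio), 0))
}

# Expected mutual information (bits) under the fixed-marginals permutation
# model (hypergeometric over contingency cells).
expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1L, ai + bj - n)
    hi <- min(ai, bj)
    if (hi < lo) next
    nij <- lo:hi
    logp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
      lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
      lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
      lgamma(n - ai - bj + nij + 1)
    emi <- emi + sum((nij / n) * log2(n * nij / (ai * bj)) * exp(logp))
  }
  emi
}

#' Adjusted mutual information of two clusterings
#'
#' Mutual information rescaled so that its expectation under random
#' clusterings with the same label marginals is approximately 0 and
#' self-agreement of a non-degenerate clustering is exactly 1:
#' `AMI = (I - E[I]) / (mean(H(X), H(Y)) - E[I])`, with `E[I]` the expected
#' mutual information under the fixed-marginals permutation model and
#' entropies in bits.  A clustering with a single label carries no
#' information; any comparison involving one is defined as 0.
#'
#' @inheritParams mutual_information
#' @return dimensionless AMI, `<= 1`; can be slightly negative for
#'   anti-correlated finite samples.
#' @export
adjusted_mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stopf("clustering vectors differ in length (%d vs %d)",
          length(x), length(y))
  n <- length(x)
  a <- as.integer(table(x)); b <- as.integer(table(y))
  if (length(a) < 2L || length(b) < 2L) return(0)
  mi <- mutual_information(x, y)
  emi <- expected_mi(a, b, n)
  denom <- (entropy_bits(x) + entropy_bits(y)) / 2 - emi
  if (abs(denom) < 1e-12) return(0)
  (mi - emi) / denom
}
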