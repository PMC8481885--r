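#' Cumulative hypergeometric test for shared miRNAs
#'
#' Probability that an mRNA with `n` miRNA partners and a lncRNA with `m`
#' miRNA partners, drawn from a universe of `N` miRNAs, share at least
#' (`tail = "ge"`) or more than (`tail = "gt"`) `x` miRNAs by chance.
#' Under the null the shared count follows a hypergeometric distribution;
#' the upper tail is summed in log space (log-binomials with
#' log-sum-exp), so the result is stable for large counts and is clamped
#' to `[0, 1]`.
#'
#' `tail = "gt"` computes `P(X > x) = 1 - sum_{k=0}^{x} C(m,k) C(N-m,n-k)
#' / C(N,n)`; `tail = "ge"` computes the conventional enrichment tail
#' `P(X >= x)`. The two differ by the point mass at `x`, which matters
#' whenever the observed overlap sits at the edge of its support; `"ge"`
#' is the default as the conservative standard for over-representation.
#'
#' @param N Universe size: total number of distinct miRNAs in the
#'   DMG-miRNA interaction sub-table for the run.
#' @param n Number of miRNAs associated with the mRNA.
#' @param m Number of miRNAs associated with the lncRNA, counted after
#'   restriction to the universe (so `m <= N` always holds).
#' @param x Observed shared miRNA count.
#' @param tail `"ge"` for `P(X >= x)` (default) or `"gt"` for
#'   `P(X > x)`.
#' @return Numeric vector of probabilities in `[0, 1]`, recycled over the
#'   longest argument.
#' @examples
#' hypergeom_cerna_p(10, 3, 4, 3, tail = "ge") # 4/120
#' @export
hypergeom_cerna_p <- function(N, n, m, x, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  len <- max(length(N), length(n), length(m), length(x))
  N <- rep_len(as.numeric(N), len)
  n <- rep_len(as.numeric(n), len)
  m <- rep_len(as.numeric(m), len)
  x <- rep_len(as.numeric(x), len)

  if (any(N < 1)) abort("violated precondition: N >= 1")
  if (any(n < 0) || any(n > N)) abort("violated precondition: 0 <= n <= N")
  if (any(m < 0) || any(m > N)) abort("violated precondition: 0 <= m <= N")
  if (any(x < 0)) abort("violated precondition: x >= 0")
  if (any(x > pmin(n, m))) abort("violated precondition: x <= min(n, m)")

  lo <- if (tail == "ge") x else x + 1
  vapply(seq_len(len), function(i) {
    k_min <- max(lo[i], 0, n[i] + m[i] - N[i])
    k_max <- min(n[i], m[i])
    if (k_min > k_max) return(0)
    k <- k_min:k_max
    lp <- lchoose(m[i], k) + lchoose(N[i] - m[i], n[i] - k) -
      lchoose(N[i], n[i])
    mx <- max(lp)
    p <- exp(mx) * sum(exp(lp - mx))
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a p-value vector. Output order matches input
#' order, values are clamped to at most 1 and are monotone in the sorted
#' order. An empty input returns an empty vector.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  check_that(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
             "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
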