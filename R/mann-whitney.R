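#' Exact Mann-Whitney U test
#'
#' Exact two-sided Mann-Whitney (Wilcoxon rank-sum) test by complete
#' enumeration of the permutation null: every assignment of the pooled
#' values into groups of the observed sizes is counted, via a
#' generating-function recursion over rank sums. Ties are handled with
#' midrank scoring, and the enumeration is tie-adjusted (it conditions on
#' the observed pooled values, so tied midranks are enumerated exactly).
#' No normal approximation is ever used; requests beyond `n + m = 40` are
#' an error pointing at approximate methods, which are out of scope here.
#'
#' Under complete separation of equal-sized samples (n per group) the
#' two-sided p is `2 / choose(2n, n)`; at n = 15 this is 1.289e-08.
#'
#' @param a,b numeric samples (non-empty).
#' @return list with `U` (the Mann-Whitney statistic of sample `a`,
#'   midrank-scored), `p_two_sided` (exact) and `p_one_sided` (exact,
#'   smaller tail).
#' @examples
#' exactMannWhitney(1:3, 4:6)$p_two_sided  # 2 / choose(6, 3) = 0.1
#' @export
exactMannWhitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(a); m <- length(b); N <- n + m
  if (N > 40L)
    stop("exact enumeration supported up to n + m = 40 (got ", N, "); ",
         "use a normal-approximation test outside this package for ",
         "larger samples", call. = FALSE)
  r2 <- as.integer(round(2 * rank(c(a, b))))   # doubled midranks: integers
  w_obs <- sum(r2[seq_len(n)])
  # counts[k + 1, s + 1] = number of k-subsets of the pooled doubled
  # midranks with sum s; filled by the subset-sum recursion
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
  counts <- matrix(0, n + 1L, smax + 1L)
  counts[1L, 1L] <- 1
  for (x in r2) {
    for (k in seq(n, 1L)) {                # high k first: 0/1 inclusion
      row <- counts[k, ]
      if (any(row != 0)) {
        keep <- seq_len(smax + 1L - x)
        counts[k + 1L, keep + x] <- counts[k + 1L, keep + x] + row[keep]
      }
    }
  }
  dist <- counts[n + 1L, ]
  total <- sum(dist)                       # = choose(N, n)
  mu2 <- n * (N + 1L)                      # doubled mean rank-sum
  lo <- min(w_obs, 2L * mu2 - w_obs)
  hi <- max(w_obs, 2L * mu2 - w_obs)
  idx <- seq_along(dist) - 1L
  p_lower <- sum(dist[idx <= lo]) / total
  p_upper <- sum(dist[idx >= hi]) / total
  p_two <- min(1, p_lower + p_upper)
  U <- (w_obs - n * (n + 1L)) / 2          # midrank U of sample a
  list(U = U, p_two_sided = p_two,
       p_one_sided = min(p_lower, p_upper))
}
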