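#' Upper-tail hypergeometric overlap p-value
#'
#' Significance of the overlap between two gene sets drawn from a common
#' background of `N` genes:
#' \deqn{p = 1 - \sum_{i=0}^{m-1} \frac{{n \choose i}{N-n \choose M-i}}{{N \choose M}}
#'         = P(X \ge m), \quad X \sim \mathrm{Hypergeom}(N, n, M)}
#' with `n` and `M` the two set sizes and `m` the observed overlap. The sum is
#' evaluated on the upper tail in log-space (via `lchoose`), which is exact
#' for `m = 0` (p = 1) and numerically stable for large `N`.
#'
#' @param N background (universe) size.
#' @param M size of the second set (e.g. the condition-B module).
#' @param n size of the first set (e.g. the condition-A module).
#' @param m observed overlap count.
#' @return the upper-tail probability, in (0, 1].
#' @examples
#' hypergeomOverlapP(N = 4, M = 2, n = 2, m = 2) # 1/6
#' hypergeomOverlapP(N = 100, M = 10, n = 10, m = 0) # 1
#' @export
hypergeomOverlapP <- function(N, M, n, m) {
  for (nm in c("N", "M", "n", "m")) {
    v <- get(nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v != floor(v))
      stop("'", nm, "' must be a single non-negative integer")
  }
  if (M > N) stop("M must satisfy M <= N (got M=", M, ", N=", N, ")")
  if (n > N) stop("n must satisfy n <= N (got n=", n, ", N=", N, ")")
  if (m > min(n, M)) stop("m must satisfy m <= min(n, M) (got m=", m,
                          ", min=", min(n, M), ")")
  if (m == 0) return(1)
  i <- seq(m, min(n, M))
  terms <- lchoose(n, i) + lchoose(N - n, M - i) - lchoose(N, M)
  p <- sum(exp(terms))
  min(max(p, .Machine$double.xmin), 1)
}
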