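#' Jenks natural-breaks classification
#'
#' Exact optimal univariate classification (Fisher's dynamic programme):
#' partitions the sorted values into `k` contiguous classes minimising the
#' total within-class sum of squared deviations. Deterministic and
#' invariant to the input order; breaks are reported as the upper value of
#' each of the first `k - 1` classes.
#'
#' @param values Numeric vector to classify.
#' @param k Number of classes (`k >= 2`, and at most the number of
#'   distinct values).
#' @return Numeric vector of `k - 1` break points; a value `v` belongs to
#'   class `findInterval(v, breaks, left.open = TRUE) + 1`.
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)  # 3
#' @export
jenks_breaks <- function(values, k) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (k < 2) stop("k must be >= 2")
  if (length(unique(values)) < k) {
    stop("k exceeds the number of distinct values")
  }
  v <- sort(values)
  n <- length(v)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  # sse of v[i..j]
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  cost <- matrix(Inf, n, k)
  back <- matrix(0L, n, k)
  for (j in seq_len(n)) cost[j, 1L] <- sse(1L, j)
  for (m in 2:k) {
    for (j in m:n) {
      for (i in m:j) {
        cand <- cost[i - 1L, m - 1L] + sse(i, j)
        if (cand < cost[j, m]) {
          cost[j, m] <- cand
          back[j, m] <- i
        }
      }
    }
  }
  # recover class boundaries
  breaks <- numeric(k - 1L)
  j <- n
  for (m in k:2) {
    i <- back[j, m]
    breaks[m - 1L] <- v[i - 1L]
    j <- i - 1L
  }
  breaks
}
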