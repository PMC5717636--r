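#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test with an exact p-value from the full permutation
#' distribution of signed midranks. Zero differences are dropped before
#' ranking; ties in \code{|d|} receive midranks. The statistic is
#' \eqn{T^+}, the sum of the ranks of the positive differences. The exact
#' null distribution is built by convolution over the doubled ranks (each
#' doubled midrank is an integer), which is equivalent to enumerating all
#' \eqn{2^n} sign assignments; the two-sided p doubles the smaller tail
#' probability and is capped at 1, matching the convention of the classical
#' exact-rank-test implementations.
#'
#' @param x,y Paired numeric vectors (the test is on \code{x - y}).
#' @return Object of class \code{exact_wilcoxon}: \code{T_plus},
#'   \code{p_value}, \code{n_used} (pairs after dropping zeros).
#' @examples
#' w <- wilcoxon_signed_rank_exact(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
#' w$T_plus   # 15
#' w$p_value  # 2/32
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (!n) stop("all differences are zero; the test is undefined")
  r <- rank(abs(d))                       # midranks for ties
  t_plus <- sum(r[d > 0])
  dist <- signed_rank_distribution(r)     # over doubled-rank support
  t2 <- round(2 * t_plus)
  sup <- seq_along(dist) - 1              # support 0..sum(2r)
  p_le <- sum(dist[sup <= t2 + 1e-9])
  p_ge <- sum(dist[sup >= t2 - 1e-9])
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(T_plus = t_plus, p_value = p, n_used = n),
            class = "exact_wilcoxon")
}

# internal: exact distribution of sum of a random subset of doubled ranks.
# Returns probability vector over 0..sum(2r) (index = value + 1).
signed_rank_distribution <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  p <- numeric(total + 1)
  p[1] <- 1
  for (v in r2) {
    shifted <- c(numeric(v), p[seq_len(total + 1 - v)])
    p <- (p + shifted) / 2
  }
  p
}

#' @export
print.exact_wilcoxon <- function(x, ...) {
  cat(sprintf("Exact Wilcoxon signed-rank: T+ = %g, N = %d, p = %.4g\n",
              x$T_plus, x$n_used, x$p_value))
  invisible(x)
}

#' Median and range of a sample
#'
#' @param values Numeric vector (the median of an even-sized sample is the
#'   mean of the two middle values).
#' @return Named numeric vector \code{c(median =, min =, max =)}.
#' @export
median_range <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values")
  c(median = stats::median(values), min = min(values), max = max(values))
}

#' Count values strictly below a threshold
#'
#' @param values Numeric vector.
#' @param threshold Cut-off; values \code{< threshold} are counted.
#' @return Integer count.
#' @export
count_below <- function(values, threshold) {
  sum(values < threshold, na.rm = TRUE)
}
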