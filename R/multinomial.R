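as_count_vector <- function(d) {
  if (inherits(d, "event_counts") || is.data.frame(d)) d <- d$d
  d <- as.numeric(d)
  if (any(d < 0) || any(d != round(d))) {
    stop("counts must be non-negative integers")
  }
  d
}

#' Multinomial log-probability of a regional count pattern
#'
#' Log of the multinomial pmf
#' \eqn{k! / \prod_j d_j! \prod_j \theta_j^{d_j}} with \eqn{k = \sum_j d_j},
#' evaluated with log-gamma functions so that pooled counts in the thousands
#' stay numerically safe.  A region with \eqn{\theta_j = 0} but \eqn{d_j > 0}
#' gives `-Inf` (an impossible pattern), not an error.
#'
#' @param d non-negative integer counts (vector, or an `event_counts`
#'   tibble whose `d` column is used).
#' @param theta probabilities, same length as `d`, summing to 1.
#' @return log-probability (scalar).
#' @examples
#' exp(multinomial_log_pmf(c(2, 1), c(0.5, 0.5))) # 3 * 0.125
#' @export
multinomial_log_pmf <- function(d, theta) {
  d <- as_count_vector(d)
  theta <- as.numeric(theta)
  if (length(d) != length(theta)) {
    stop("d and theta must have the same length")
  }
  if (any(theta < 0) || abs(sum(theta) - 1) > 1e-8) {
    stop("theta must be probabilities summing to 1")
  }
  k <- sum(d)
  lt <- ifelse(d == 0, 0, d * log(theta))
  lgamma(k + 1) - sum(lgamma(d + 1)) + sum(lt)
}

#' Pearson chi-square test of a regional count pattern against the null
#'
#' Classical test of `H0: theta = a` against unrestricted patterning, with
#' the Pearson statistic \eqn{\sum_j (d_j - k a_j)^2 / (k a_j)} on
#' \eqn{n - 1} degrees of freedom.  The approximation needs a moderate
#' expected count in every region; a warning is emitted when any
#' \eqn{k a_j < 5} (use a lower peak threshold or larger regions).
#'
#' @inheritParams multinomial_log_pmf
#' @param a null relative statistical volumes (positive, sum 1).
#' @return tibble with `statistic`, `df`, `p_value`, `k`.
#' @export
chisq_pattern_test <- function(d, a) {
  d <- as_count_vector(d)
  a <- as.numeric(a)
  if (length(d) != length(a)) stop("d and a must have the same length")
  if (any(a <= 0) || abs(sum(a) - 1) > 1e-8) {
    stop("a must be strictly positive and sum to 1")
  }
  k <- sum(d)
  if (k == 0) stop("no events to test (k = 0)")
  expected <- k * a
  if (any(expected < 5)) {
    warning("expected counts below 5 in some regions; ",
            "the chi-square approximation may be poor")
  }
  stat <- sum((d - expected)^2 / expected)
  df <- length(d) - 1
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE), k = k)
}

#' Small-volume binomial p-value for an event excess
#'
#' With a bipartition (a small region of interest versus the rest of the
#' search volume), the null probability of observing `d1` or more of the `k`
#' events in the small volume is the upper binomial tail
#' \eqn{p = \sum_{i = d_1}^{k} Binomial(i; k, a_1)}, inclusive of the
#' observed count.  For a deficit test use `tail = "deficit"`, the mirrored
#' lower tail \eqn{\sum_{i=0}^{d_1}}.
#'
#' @param d1 observed events in the region of interest.
#' @param k total events in the search volume.
#' @param a1 the region's relative statistical volume, in (0, 1).
#' @param tail `"excess"` (default) or `"deficit"`.
#' @return p-value (scalar).
#' @examples
#' binomial_svc_pvalue(8, 10, 0.5) # 56/1024
#' @export
binomial_svc_pvalue <- function(d1, k, a1, tail = c("excess", "deficit")) {
  tail <- match.arg(tail)
  stopifnot(length(d1) == 1, length(k) == 1, length(a1) == 1)
  if (d1 < 0 || d1 != round(d1) || k != round(k)) {
    stop("d1 and k must be non-negative integers")
  }
  if (d1 > k) stop("d1 cannot exceed k")
  if (a1 <= 0 || a1 >= 1) stop("a1 must lie strictly between 0 and 1")
  if (tail == "excess") {
    pbinom(d1 - 1, k, a1, lower.tail = FALSE)
  } else {
    pbinom(d1, k, a1)
  }
}

#' Predictive variance of a regional count under a Dirichlet prior
#'
#' For a bipartition with prior mean `a` and concentration `c`, the prior
#' predictive count in the region of interest is beta-binomial with variance
#' \deqn{var = k a (1 - a) [1 + (k - 1) / (c + 1)].}
#' As \eqn{c \to \infty} the prior collapses to the point null and the
#' variance to the binomial \eqn{k a (1 - a)}: the null model concentrates
#' predictive mass near `a`, which is the Occam's-razor mechanism that lets a
#' sharper model win whenever the data are consistent with it.
#'
#' @param k total event count (>= 1).
#' @param a regional prior mean, in (0, 1).
#' @param c Dirichlet concentration, > 0; `Inf` gives the binomial variance.
#' @return predictive variance (scalar).
#' @examples
#' dirmult_predictive_variance(10, 0.5, 4) # 7: beta-binomial(2, 2)
#' @export
dirmult_predictive_variance <- function(k, a, c) {
  stopifnot(k >= 1, k == round(k), a > 0, a < 1, c > 0)
  base <- k * a * (1 - a)
  if (is.infinite(c)) return(base)
  base * (1 + (k - 1) / (c + 1))
}
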