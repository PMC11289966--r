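# Simultaneous multinomial confidence intervals, Sison & Glaz (1995).
#
# The coverage probability that every category count X_i of a
# Multinomial(N, p-hat) draw lies within +/- c of its observed count n_i is
# approximated by representing the multinomial as independent Poisson(n_i)
# variables conditioned on their sum being N:
#
#   nu(c) = prod_i P(|Y_i - n_i| <= c) * P(sum of truncated Y = N) / P(W = N)
#
# with Y_i ~ Poisson(n_i) truncated to [n_i - c, n_i + c] and W ~ Poisson(N).
# P(sum = N) is evaluated by an Edgeworth expansion using the first four
# central moments of the truncated Poissons; the moments are computed here
# exactly by direct summation over each truncation range (the ranges are
# tiny), avoiding any closed-form moment algebra.

# Edgeworth-corrected approximation of nu(c) for integer half-width c
sg_coverage <- function(cc, counts) {
  N <- sum(counts)
  k <- length(counts)
  m1 <- m2 <- m3 <- m4 <- pin <- numeric(k)
  for (i in seq_len(k)) {
    a <- max(0, counts[i] - cc)
    b <- counts[i] + cc
    s <- a:b
    w <- stats::dpois(s, counts[i])
    pin[i] <- sum(w)
    w <- w / pin[i]
    mu <- sum(s * w)
    d <- s - mu
    m1[i] <- mu
    m2[i] <- sum(d^2 * w)
    m3[i] <- sum(d^3 * w)
    m4[i] <- sum(d^4 * w)
  }
  s2 <- sum(m2)
  if (s2 == 0) {
    # fully truncated (degenerate) case: the conditioned sum is deterministic
    return(prod(pin) * as.numeric(sum(m1) == N) / stats::dpois(N, N))
  }
  sg <- sqrt(s2)
  g1 <- sum(m3) / sg^3
  g2 <- sum(m4 - 3 * m2^2) / s2^2
  z <- (N - sum(m1)) / sg
  edge <- (1 + g1 * (z^3 - 3 * z) / 6 +
             g2 * (z^4 - 6 * z^2 + 3) / 24 +
             g1^2 * (z^6 - 15 * z^4 + 45 * z^2 - 15) / 72) * stats::dnorm(z)
  prod(pin) * (edge / sg) / stats::dpois(N, N)
}

#' Sison-Glaz simultaneous intervals for multinomial proportions
#'
#' Simultaneous confidence intervals for the 13 region proportions: the
#' smallest integer half-width `c` with approximate simultaneous coverage
#' below the level is found (truncated-Poisson / Edgeworth approximation of
#' the multinomial coverage probability), the deficit is linearly
#' interpolated towards `c + 1` with constant `2*gamma`, and every category
#' receives the interval `[p_r - c/N, p_r + c/N + 2*gamma/N]`, clamped to
#' `[0, 1]`. All 13 pre-clamp widths are identical by construction; low
#' counts clamp their lower bound at 0.
#'
#' @param region_counts 13-vector of non-negative counts (clockface 0..12).
#' @param level simultaneous confidence level (default 0.95).
#' @return 13 interval-estimate rows (method `"sison-glaz"`) with a
#'   `region` column.
#' @export
prevalence_sison_glaz <- function(region_counts, level = 0.95) {
  if (length(region_counts) != n_regions()) {
    stop("region_counts must have length 13", call. = FALSE)
  }
  stopifnot(all(region_counts >= 0))
  N <- sum(region_counts)
  if (N < 1) stop("at least one observation required", call. = FALSE)
  cc <- 1L
  while (sg_coverage(cc, region_counts) < level && cc < N) cc <- cc + 1L
  c_low <- cc - 1L
  v0 <- sg_coverage(c_low, region_counts)
  v1 <- sg_coverage(cc, region_counts)
  gamma <- (level - v0) / (v1 - v0)
  # degenerate inputs can reach the level at c = 0; no widening then
  if (!is.finite(gamma)) gamma <- 0
  gamma <- min(max(gamma, 0), 1)
  # interval built from the largest c with nu(c) < level, widened upward
  # by the interpolation term
  p <- region_counts / N
  lower <- pmax(0, p - c_low / N)
  upper <- pmin(1, p + c_low / N + 2 * gamma / N)
  out <- interval_estimate(mean = p, lower = lower, upper = upper,
                           method = "sison-glaz",
                           n_success = region_counts, n_total = N)
  cbind(region = 0:12, out)
}
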