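# numeric-integration oracle for the Beta posterior: unnormalised kernel
# p^(n+a-1) (1-p)^(N-n+b-1) on a dense grid; mean and equal-tailed
# quantiles by trapezoid integration / CDF inversion
beta_posterior_oracle <- function(n, N, a = 1, b = 1, grid = 4e5) {
  p <- seq(0, 1, length.out = grid + 1)
  logk <- (n + a - 1) * log(p) + (N - n + b - 1) * log1p(-p)
  logk[!is.finite(logk)] <- -Inf
  k <- exp(logk - max(logk))
  w <- c(0.5, rep(1, grid - 1), 0.5) / grid      # trapezoid weights
  z <- sum(k * w)
  mean <- sum(p * k * w) / z
  cdf <- cumsum(k * w) / z
  qfun <- function(q) p[which.max(cdf >= q)]
  list(mean = mean, lower = qfun(0.025), upper = qfun(0.975))
}

test_that("conjugate drainage posterior matches dense numerical integration", {
  set.seed(11)
  for (i in 1:6) {
    N <- sample(5:200, 1)
    n <- sample(0:N, 1)
    est <- drainage_bayes(n, N)
    orc <- beta_posterior_oracle(n, N)
    expect_lt(abs(est$mean - orc$mean), 1e-6)
    expect_lt(abs(est$lower - orc$lower), 1e-5)
    expect_lt(abs(est$upper - orc$upper), 1e-5)
  }
})

test_that("Bayesian drainage estimates reproduce known cells", {
  e <- drainage_bayes(671, 869)
  expect_equal(round_half_up(100 * c(e$mean, e$lower, e$upper)),
               c(77.2, 74.3, 79.9))
  expect_equal(round_half_up(100 * drainage_bayes(5, 869)$mean), 0.7)
  # closed form for zero successes under the uniform prior
  e0 <- drainage_bayes(0, 10)
  expect_equal(e0$mean, 1 / 12)
  expect_equal(e0$lower, 1 - 0.975^(1 / 11))
  expect_error(drainage_bayes(11, 10), "0..n_total")
})

test_that("logit-scale Wald intervals reproduce known cells and symmetry", {
  e <- drainage_regression(72, 869)
  expect_equal(round_half_up(100 * c(e$mean, e$lower, e$upper)),
               c(8.3, 6.6, 10.3))
  expect_equal(round_half_up(100 * drainage_regression(17, 24)$mean), 70.8)
  s <- drainage_regression(5, 10)
  expect_equal(s$mean, 0.5)
  expect_equal(s$lower, 1 - s$upper, tolerance = 1e-12)
})

test_that("degenerate regression cells fall back to one-sided exact bounds", {
  lo <- drainage_regression(0, 20)
  expect_true(lo$degenerate)
  expect_equal(lo$mean, 0)
  expect_equal(lo$lower, 0)
  expect_equal(lo$upper, qbeta(0.975, 1, 20))
  hi <- drainage_regression(20, 20)
  expect_true(hi$degenerate)
  expect_equal(hi$upper, 1)
  expect_equal(hi$lower, qbeta(0.025, 20, 1))
})

test_that("Dirichlet-multinomial prevalence matches known cells and normalises", {
  counts <- as.vector(anmu_contingency()$region_totals)
  est <- prevalence_bayes(counts)
  r2 <- est[est$region == 2, ]
  expect_equal(round_half_up(100 * c(r2$mean, r2$lower, r2$upper)),
               c(22.7, 20.0, 25.5))
  expect_equal(round_half_up(100 * est$mean[est$region == 0]), 12.7)
  expect_equal(sum(est$mean), 1, tolerance = 1e-12)

  one <- c(1, rep(0, 12))
  e1 <- prevalence_bayes(one)
  expect_equal(e1$mean[1], 2 / 14)
  expect_equal(e1$mean[2], 1 / 14)
  expect_equal(sum(e1$mean), 1, tolerance = 1e-12)
  expect_error(prevalence_bayes(rep(1, 12)), "length 13")
})

test_that("Sison-Glaz intervals share pre-clamp width and clamp correctly", {
  counts <- as.vector(anmu_contingency()$region_totals)
  est <- prevalence_sison_glaz(counts)
  # identical pre-clamp widths: reconstruct from cells without clamping
  raw_width <- (est$mean - est$lower) + (est$upper - est$mean)
  unclamped <- est$lower > 0 & est$upper < 1
  expect_true(sum(unclamped) >= 10)
  expect_equal(diff(range(raw_width[unclamped])), 0, tolerance = 1e-12)
  # low-count regions clamp at zero
  expect_equal(est$lower[est$region == 7], 0)
  expect_equal(est$lower[est$region == 8], 0)
  # near-degenerate concentration: dominant category clamps its upper
  # bound at 1, its lower bound stays the shared half-width below p-hat
  conc <- c(2, rep(0, 11), 38)
  e1 <- prevalence_sison_glaz(conc)
  expect_equal(e1$upper[13], 1)
  expect_true(e1$lower[13] > 0.5 && e1$lower[13] < 38 / 40)
  expect_equal(e1$lower[2], 0)
  # fully concentrated counts are handled without widening blow-up
  all_in_one <- c(rep(0, 5), 40, rep(0, 7))
  e2 <- prevalence_sison_glaz(all_in_one)
  expect_true(all(is.finite(c(e2$lower, e2$upper))))
  expect_equal(e2$upper[6], 1)
  expect_error(prevalence_sison_glaz(rep(0, 13)), "at least one")
})

test_that("Sison-Glaz simultaneous coverage is near nominal by simulation", {
  counts <- as.vector(anmu_contingency()$region_totals)
  p <- counts / sum(counts)
  set.seed(7)
  draws <- stats::rmultinom(2000, sum(counts), p)
  hits <- vapply(seq_len(ncol(draws)), function(j) {
    ci <- prevalence_sison_glaz(draws[, j])
    all(p >= ci$lower - 1e-12 & p <= ci$upper + 1e-12)
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("bootstrap percentiles match the exhaustive binomial oracle", {
  co <- toy_cohort(20, 7)
  cfg <- bootstrap_config(B = 2e5, seed = 99, unit = "tumour")
  est <- drainage_bootstrap(co, "internal-mammary", cfg = cfg)
  # tumour-level replicate counts are exactly Binomial(20, 7/20)
  expect_lt(abs(est$lower - qbinom(0.025, 20, 7 / 20) / 20), 1e-3)
  expect_lt(abs(est$upper - qbinom(0.975, 20, 7 / 20) / 20), 1e-3)
  expect_lt(abs(est$mean - 7 / 20), 3 * sqrt(0.35 * 0.65 / 20) / sqrt(2e5))
})

test_that("bootstrap mean converges to the sample proportion", {
  pre <- preprocess_cohort(anmu_cohort())
  cfg <- bootstrap_config(B = 4000, seed = 3)
  est <- drainage_bootstrap(pre, "axilla-I-anterior", cfg = cfg)
  p <- 671 / 869
  sd_rep <- sqrt(p * (1 - p) / 869)
  expect_lt(abs(est$mean - p), 3 * sd_rep / sqrt(cfg$B) + 1e-4)
  # degenerate cohort: every tumour drains to the field
  all_drain <- toy_cohort(10, 10)
  d <- drainage_bootstrap(all_drain, "internal-mammary",
                          cfg = bootstrap_config(B = 200, seed = 1))
  expect_equal(c(d$mean, d$lower, d$upper), c(1, 1, 1))
  expect_no_error(
    drainage_bootstrap(pre, "interval", region = 5L,
                       cfg = bootstrap_config(B = 10, seed = 1)))
  expect_error(
    drainage_bootstrap(toy_cohort(5, 2), "interval", region = 9L),
    "no tumours in region")
})

test_that("patient-level resampling keeps bilateral tumours together", {
  # one bilateral patient always drains, one unilateral never does:
  # attainable replicate proportions are limited to {0, 2/3, 1}
  co <- sln_cohort(patient_id = c("A", "A", "B"), side = c("L", "R", "L"),
                   clockface = c(2L, 10L, 2L), nipple_distance_cm = 3,
                   node_fields = c("interval", "interval",
                                   "axilla-I-anterior"))
  cfg <- bootstrap_config(B = 500, seed = 5)
  est <- drainage_bootstrap(preprocess_cohort(co), "interval", cfg = cfg)
  # replicate proportions can only be 0 (B,B; prob 1/4), 2/3 (A,B) or
  # 1 (A,A; prob 1/4): the 2.5/97.5 percentiles land in the end blocks
  expect_equal(est$lower, 0)
  expect_equal(est$upper, 1)
  expect_true(est$mean > 0 && est$mean < 1)
})

test_that("bootstrap prevalence conserves the simplex", {
  pre <- preprocess_cohort(anmu_cohort())
  est <- prevalence_bootstrap(pre, cfg = bootstrap_config(B = 1000,
                                                          seed = 4))
  expect_equal(sum(est$mean), 1, tolerance = 1e-12)
  single <- toy_cohort(6, 3, region = 4L)
  e1 <- prevalence_bootstrap(single, cfg = bootstrap_config(B = 100,
                                                            seed = 1))
  expect_equal(e1$mean[e1$region == 4], 1)
  expect_equal(e1$lower[e1$region == 4], 1)
  expect_equal(e1$upper[e1$region == 4], 1)
  expect_true(all(e1$mean[e1$region != 4] == 0))
})

test_that("three interval methods agree for well-populated cells", {
  ct <- anmu_contingency()
  pre <- preprocess_cohort(anmu_cohort())
  cfg <- bootstrap_config(B = 2000, seed = 8)
  n_field <- colSums(ct$field_counts)
  for (f in names(n_field)[n_field >= 20]) {
    ba <- drainage_bayes(n_field[[f]], ct$N)
    re <- drainage_regression(n_field[[f]], ct$N)
    bo <- drainage_bootstrap(pre, f, cfg = cfg)
    for (col in c("mean", "lower", "upper")) {
      vals <- c(ba[[col]], re[[col]], bo[[col]])
      expect_lt(diff(range(vals)), 0.01)
    }
  }
})

test_that("per-field prevalence restricts and conserves counts", {
  pre <- preprocess_cohort(anmu_cohort())
  est <- prevalence_by_field(pre, "axilla-I-anterior", methods = "bayes")
  expect_equal(unique(est$n_total), 671L)
  expect_equal(est$n_success[est$region == 0], 87L)
  # restricted counts sum to the field total for every field
  ct <- anmu_contingency()
  for (f in node_fields()) {
    e <- prevalence_by_field(pre, f, methods = "bayes")
    expect_equal(sum(e$n_success), unname(colSums(ct$field_counts)[f]))
  }
  expect_error(prevalence_by_field(toy_cohort(4, 0), "internal-mammary"),
               "no tumours drain")
  # a field drained by exactly one tumour: its region gets mean 2/14
  e1 <- prevalence_by_field(toy_cohort(5, 1, region = 3L),
                            "internal-mammary", methods = "bayes")
  expect_equal(e1$mean[e1$region == 3], 2 / 14)
})

test_that("drainage_table covers scopes and refuses bootstrap on marginals", {
  ct <- anmu_contingency()
  tab <- drainage_table(ct, methods = c("bayes", "regression"))
  expect_equal(nrow(tab), 24L)
  expect_setequal(unique(tab$node_field), node_fields())
  per <- drainage_table(ct, methods = "bayes", scope = "per-region")
  r7 <- per[per$region == 7 & per$node_field == "internal-mammary", ]
  expect_equal(round_half_up(100 * r7$mean), 69.2)
  # empty cells get the prior-driven mean, degenerate regression flagged
  per_reg <- drainage_table(ct, methods = c("bayes", "regression"),
                            scope = "per-region")
  zero <- per_reg[per_reg$region == 4 & per_reg$node_field == "axilla-III", ]
  expect_equal(zero$mean[zero$method == "bayes"], 1 / (56 + 2))
  expect_true(zero$degenerate[zero$method == "regression"])
  expect_error(drainage_table(ct, methods = "bootstrap"),
               "patient-level resampling")
})
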