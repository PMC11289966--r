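#' Interval-estimate rows
#'
#' Every interval method in the package returns rows of a common shape:
#' `mean`, `lower`, `upper` (probabilities), `method`, `n_success`,
#' `n_total` and a `degenerate` flag. Helper kept internal; the exported
#' estimators document their own posteriors/procedures.
#'
#' @noRd
interval_estimate <- function(mean, lower, upper, method, n_success, n_total,
                              degenerate = FALSE) {
  stopifnot(all(lower <= upper + 1e-12))
  data.frame(mean = mean, lower = lower, upper = upper, method = method,
             n_success = as.integer(n_success), n_total = as.integer(n_total),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Bootstrap configuration
#'
#' @param B number of bootstrap replicates (default 10,000).
#' @param seed optional integer seed; set for reproducible resampling.
#' @param unit resampling unit: `"patient"` (default; a resampled patient
#'   carries all of their tumours) or `"tumour"`.
#' @param level two-sided percentile interval level (default 0.95).
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(B = 10000L, seed = NULL,
                             unit = c("patient", "tumour"), level = 0.95) {
  unit <- match.arg(unit)
  stopifnot(B >= 1L, level > 0, level < 1)
  structure(list(B = as.integer(B), seed = seed, unit = unit, level = level),
            class = "bootstrap_config")
}

#' Bayesian drainage-probability estimate
#'
#' Conjugate model for the probability that a tumour drains to a given node
#' field: uniform Beta(1, 1) prior and binomial likelihood, giving posterior
#' `Beta(n_drain + a, n_total - n_drain + b)`. The point estimate is the
#' posterior mean and the interval the equal-tailed credible interval. With
#' the default uniform prior the posterior mean is
#' `(n_drain + 1) / (n_total + 2)`.
#'
#' @param n_drain tumours draining to the field.
#' @param n_total tumours at risk.
#' @param level credible level (default 0.95).
#' @param prior `c(a, b)` Beta prior parameters, default `c(1, 1)`.
#' @return One interval-estimate row, method `"bayes"`.
#' @export
drainage_bayes <- function(n_drain, n_total, level = 0.95, prior = c(1, 1)) {
  stopifnot(length(prior) == 2L, all(prior > 0), n_total >= 1)
  if (n_drain < 0 || n_drain > n_total) {
    stop("n_drain must lie in 0..n_total", call. = FALSE)
  }
  a <- n_drain + prior[1]
  b <- n_total - n_drain + prior[2]
  alpha <- (1 - level) / 2
  interval_estimate(
    mean = a / (a + b),
    lower = stats::qbeta(alpha, a, b),
    upper = stats::qbeta(1 - alpha, a, b),
    method = "bayes", n_success = n_drain, n_total = n_total
  )
}

#' Regression (logit-Wald) drainage-probability estimate
#'
#' Fitted value and Wald interval from the saturated logistic model with the
#' node-field indicator as response: the fitted probability is the observed
#' proportion, and the interval is computed on the log-odds scale,
#' `logit(p) +/- z * sqrt(1/n_drain + 1/(n_total - n_drain))`, then
#' back-transformed. When region is the (categorical) predictor the
#' saturated fit per region equals that region's proportion, so the same
#' formula applies cell-wise.
#'
#' Degenerate cells (`n_drain` 0 or `n_total`) have undefined log-odds; the
#' defined-side bound is replaced by the exact (Clopper-Pearson) one-sided
#' binomial bound and the row flagged `degenerate`.
#'
#' @inheritParams drainage_bayes
#' @param level confidence level (default 0.95).
#' @return One interval-estimate row, method `"regression"`.
#' @export
drainage_regression <- function(n_drain, n_total, level = 0.95) {
  stopifnot(n_total >= 1)
  if (n_drain < 0 || n_drain > n_total) {
    stop("n_drain must lie in 0..n_total", call. = FALSE)
  }
  p <- n_drain / n_total
  alpha <- (1 - level) / 2
  if (n_drain == 0) {
    return(interval_estimate(
      mean = 0, lower = 0,
      upper = stats::qbeta(1 - alpha, n_drain + 1, n_total - n_drain),
      method = "regression", n_success = n_drain, n_total = n_total,
      degenerate = TRUE))
  }
  if (n_drain == n_total) {
    return(interval_estimate(
      mean = 1, lower = stats::qbeta(alpha, n_drain, n_total - n_drain + 1),
      upper = 1,
      method = "regression", n_success = n_drain, n_total = n_total,
      degenerate = TRUE))
  }
  z <- stats::qnorm(1 - alpha)
  se <- sqrt(1 / n_drain + 1 / (n_total - n_drain))
  lo <- stats::qlogis(p) - z * se
  hi <- stats::qlogis(p) + z * se
  interval_estimate(
    mean = p, lower = stats::plogis(lo), upper = stats::plogis(hi),
    method = "regression", n_success = n_drain, n_total = n_total
  )
}

# per-unit resampling summaries: list(num = numerator per unit (or matrix),
# den = tumours per unit)
bootstrap_units <- function(cohort, cfg) {
  if (cfg$unit == "patient") {
    ids <- factor(cohort$patient_id)
  } else {
    ids <- factor(seq_len(nrow(cohort)))
  }
  ids
}

# generic percentile bootstrap over units for a per-unit numerator vector;
# statistic per replicate is sum(num) / sum(den)
bootstrap_ratio <- function(num, den, cfg) {
  n_units <- length(den)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  alpha <- (1 - cfg$level) / 2
  idx <- sample.int(n_units, n_units * cfg$B, replace = TRUE)
  dim(idx) <- c(n_units, cfg$B)
  nums <- colSums(matrix(num[idx], n_units, cfg$B))
  dens <- colSums(matrix(den[idx], n_units, cfg$B))
  props <- nums / dens
  c(mean = mean(props),
    lower = unname(stats::quantile(props, alpha)),
    upper = unname(stats::quantile(props, 1 - alpha)))
}

#' Bootstrap drainage-probability estimate
#'
#' Non-parametric percentile bootstrap of the proportion of tumours draining
#' to a node field. Resampling is at patient level by default: each
#' replicate draws patients with replacement (bilateral patients carry both
#' tumours) and recomputes the proportion among the replicate's tumours.
#' Point estimate is the mean over replicates; bounds are the 2.5/97.5
#' percentiles (at the default level).
#'
#' @param cohort preprocessed `sln_cohort`.
#' @param field node-field label.
#' @param region optional clockface region 0..12; when given, the cohort is
#'   restricted to that region *before* resampling.
#' @param cfg a [bootstrap_config()].
#' @return One interval-estimate row, method `"bootstrap"`.
#' @export
drainage_bootstrap <- function(cohort, field, region = NULL,
                               cfg = bootstrap_config()) {
  assert_node_fields(field)
  stopifnot(length(field) == 1L)
  if (!is.null(region)) {
    assert_regions(region)
    cohort <- cohort[cohort$clockface == region, , drop = FALSE]
    if (nrow(cohort) == 0L) {
      stop(sprintf("no tumours in region %d", region), call. = FALSE)
    }
  }
  drains <- vapply(split_fields(cohort$node_fields),
                   function(f) field %in% f, logical(1))
  ids <- bootstrap_units(cohort, cfg)
  num <- as.vector(rowsum(as.numeric(drains), ids))
  den <- as.vector(rowsum(rep(1, nrow(cohort)), ids))
  q <- bootstrap_ratio(num, den, cfg)
  interval_estimate(mean = q[["mean"]], lower = q[["lower"]],
                    upper = q[["upper"]], method = "bootstrap",
                    n_success = sum(drains), n_total = nrow(cohort))
}

#' Bayesian tumour-prevalence estimates
#'
#' Conjugate model for the distribution of tumours over the 13 clockface
#' regions: flat Dirichlet(1, ..., 1) prior and multinomial likelihood,
#' giving posterior `Dirichlet(counts + 1)`. Each region is summarised by
#' its marginal posterior mean `(n_r + 1) / (N + 13)` and the equal-tailed
#' interval of the marginal `Beta(n_r + 1, N - n_r + 12)`.
#'
#' @param region_counts 13-vector of tumour counts, clockface 0..12.
#' @param level credible level.
#' @param prior 13-vector of positive Dirichlet concentrations (default all 1).
#' @return 13 interval-estimate rows (method `"bayes"`), with a `region`
#'   column.
#' @export
prevalence_bayes <- function(region_counts, level = 0.95,
                             prior = rep(1, 13)) {
  if (length(region_counts) != n_regions()) {
    stop("region_counts must have length 13", call. = FALSE)
  }
  stopifnot(all(region_counts >= 0), sum(region_counts) >= 1,
            length(prior) == n_regions(), all(prior > 0))
  a <- region_counts + prior
  a0 <- sum(a)
  alpha <- (1 - level) / 2
  out <- interval_estimate(
    mean = a / a0,
    lower = stats::qbeta(alpha, a, a0 - a),
    upper = stats::qbeta(1 - alpha, a, a0 - a),
    method = "bayes", n_success = region_counts,
    n_total = sum(region_counts)
  )
  cbind(region = 0:12, out)
}

#' Bootstrap tumour-prevalence estimates
#'
#' Patient-level percentile bootstrap of the 13 region proportions: each
#' replicate resamples units with replacement and recomputes the full
#' proportion vector (which sums to 1 within each replicate).
#'
#' @param cohort preprocessed `sln_cohort`.
#' @param cfg a [bootstrap_config()].
#' @return 13 interval-estimate rows (method `"bootstrap"`) with a `region`
#'   column.
#' @export
prevalence_bootstrap <- function(cohort, cfg = bootstrap_config()) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  ids <- bootstrap_units(cohort, cfg)
  reg <- cohort$clockface
  # per-unit 13-vector of region counts
  num <- rowsum(outer(reg, 0:12, "==") + 0, ids)
  den <- as.vector(rowsum(rep(1, nrow(cohort)), ids))
  n_units <- length(den)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  alpha <- (1 - cfg$level) / 2
  idx <- sample.int(n_units, n_units * cfg$B, replace = TRUE)
  dim(idx) <- c(n_units, cfg$B)
  dens <- colSums(matrix(den[idx], n_units, cfg$B))
  means <- lower <- upper <- numeric(n_regions())
  for (r in seq_len(n_regions())) {
    props <- colSums(matrix(num[, r][idx], n_units, cfg$B)) / dens
    means[r] <- mean(props)
    lower[r] <- unname(stats::quantile(props, alpha))
    upper[r] <- unname(stats::quantile(props, 1 - alpha))
  }
  counts <- as.vector(table(factor(reg, levels = 0:12)))
  out <- interval_estimate(mean = means, lower = lower, upper = upper,
                           method = "bootstrap", n_success = counts,
                           n_total = nrow(cohort))
  cbind(region = 0:12, out)
}

#' Drainage-probability table
#'
#' One row per node field (whole breast) or per region x node field, for
#' each requested method. Accepts either a preprocessed cohort or an
#' `sln_contingency`; the bootstrap needs patient-level records, so it is
#' only available from a cohort.
#'
#' @param x an `sln_cohort` (preprocessed) or `sln_contingency`.
#' @param methods subset of `c("bayes", "bootstrap", "regression")`.
#' @param scope `"whole-breast"` or `"per-region"`.
#' @param level interval level.
#' @param cfg [bootstrap_config()] used when `"bootstrap"` is requested.
#' @return Data frame of interval-estimate rows with `node_field` (and
#'   `region` for per-region scope) columns.
#' @export
drainage_table <- function(x, methods = c("bayes", "bootstrap", "regression"),
                           scope = c("whole-breast", "per-region"),
                           level = 0.95, cfg = bootstrap_config()) {
  scope <- match.arg(scope)
  methods <- match.arg(methods, several.ok = TRUE)
  is_cohort <- inherits(x, "sln_cohort") ||
    (is.data.frame(x) && all(cohort_columns %in% names(x)))
  if ("bootstrap" %in% methods && !is_cohort) {
    stop(paste("bootstrap estimates need tumour-level records for",
               "patient-level resampling; supply a cohort, not a",
               "contingency table"), call. = FALSE)
  }
  ct <- if (is_cohort) build_contingency(x) else x
  if (!inherits(ct, "sln_contingency")) {
    stop("x must be an sln_cohort or sln_contingency", call. = FALSE)
  }
  nf <- node_fields()
  rows <- list()
  cells <- if (scope == "whole-breast") {
    data.frame(region = NA_integer_, node_field = nf,
               n = colSums(ct$field_counts), N = ct$N)
  } else {
    expand.grid(region = 0:12, node_field = nf, stringsAsFactors = FALSE)
  }
  if (scope == "per-region") {
    cells$n <- ct$field_counts[cbind(cells$region + 1L,
                                     match(cells$node_field, nf))]
    cells$N <- ct$region_totals[cells$region + 1L]
  }
  for (i in seq_len(nrow(cells))) {
    if (cells$N[i] == 0L) next
    for (m in methods) {
      est <- switch(m,
        bayes = drainage_bayes(cells$n[i], cells$N[i], level = level),
        regression = drainage_regression(cells$n[i], cells$N[i],
                                         level = level),
        bootstrap = drainage_bootstrap(
          x, cells$node_field[i],
          region = if (scope == "per-region") cells$region[i] else NULL,
          cfg = cfg)
      )
      rows[[length(rows) + 1L]] <-
        cbind(region = cells$region[i], node_field = cells$node_field[i],
              est)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tumour-prevalence table
#'
#' All-methods prevalence summary over the 13 clockface regions
#' (unconditional, i.e. across the whole cohort).
#'
#' @inheritParams drainage_table
#' @return Data frame of interval-estimate rows with a `region` column.
#' @export
prevalence_table <- function(x, methods = c("bayes", "bootstrap",
                                            "sison-glaz"),
                             level = 0.95, cfg = bootstrap_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  is_cohort <- inherits(x, "sln_cohort") ||
    (is.data.frame(x) && all(cohort_columns %in% names(x)))
  if ("bootstrap" %in% methods && !is_cohort) {
    stop("bootstrap estimates need tumour-level records; supply a cohort",
         call. = FALSE)
  }
  counts <- if (is_cohort) {
    as.vector(table(factor(x$clockface, levels = 0:12)))
  } else {
    as.vector(x$region_totals)
  }
  rows <- list()
  for (m in methods) {
    est <- switch(m,
      bayes = prevalence_bayes(counts, level = level),
      `sison-glaz` = prevalence_sison_glaz(counts, level = level),
      bootstrap = prevalence_bootstrap(x, cfg = cfg)
    )
    rows[[length(rows) + 1L]] <- est
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tumour prevalence conditional on a node field
#'
#' Restricts the cohort to tumours draining to `field` and estimates the
#' 13 region proportions among them, by any of the three prevalence methods.
#'
#' @param cohort preprocessed `sln_cohort`.
#' @param field node-field label.
#' @param methods subset of `c("bayes", "bootstrap", "sison-glaz")`.
#' @param level interval level.
#' @param cfg [bootstrap_config()].
#' @return Data frame of interval-estimate rows with `region` and
#'   `node_field` columns; `n_total` is the restricted count.
#' @export
prevalence_by_field <- function(cohort, field,
                                methods = c("bayes", "bootstrap",
                                            "sison-glaz"),
                                level = 0.95, cfg = bootstrap_config()) {
  assert_node_fields(field)
  methods <- match.arg(methods, several.ok = TRUE)
  drains <- vapply(split_fields(cohort$node_fields),
                   function(f) field %in% f, logical(1))
  sub <- cohort[drains, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no tumours drain to %s", field), call. = FALSE)
  }
  class(sub) <- c("sln_cohort", "data.frame")
  out <- prevalence_table(sub, methods = methods, level = level, cfg = cfg)
  cbind(node_field = field, out)
}
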