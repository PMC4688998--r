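#' Prediction accuracy with Fisher-z confidence interval
#'
#' Accuracy is the Pearson correlation between predicted genomic breeding
#' values and observed phenotypic scores, with the asymptotic 95% interval
#' tanh(atanh(r) +/- z / sqrt(n - 3)). A Spearman rank correlation is added
#' when the phenotype distribution is flagged as highly skewed.
#'
#' @param gbv,phenotypes Paired numeric vectors (n >= 4).
#' @param skew_flag Add the Spearman correlation? Default: automatic via
#'   [skewness_flag()] on the phenotypes when n >= 10.
#' @param conf_level Confidence level of the interval.
#' @return One-row tibble: `n`, `pearson_r`, `ci_low`, `ci_high`,
#'   `ci_length`, `spearman_rho` (NA unless flagged). Zero variance in
#'   either vector yields NA values with a `reason` column.
#' @export
accuracy <- function(gbv, phenotypes, skew_flag = NULL, conf_level = 0.95) {
  stopifnot(length(gbv) == length(phenotypes))
  ok <- stats::complete.cases(gbv, phenotypes)
  gbv <- gbv[ok]; phenotypes <- phenotypes[ok]
  n <- length(gbv)
  stopifnot(n >= 4)
  if (is.null(skew_flag))
    skew_flag <- n >= 10 && skewness_flag(phenotypes)
  if (stats::sd(gbv) == 0 || stats::sd(phenotypes) == 0) {
    return(tibble::tibble(n = n, pearson_r = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, ci_length = NA_real_,
                          spearman_rho = NA_real_,
                          reason = "zero variance"))
  }
  r <- stats::cor(gbv, phenotypes)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z / sqrt(n - 3)
  ci <- tanh(atanh(r) + c(-half, half))
  tibble::tibble(
    n = n, pearson_r = r, ci_low = ci[1], ci_high = ci[2],
    ci_length = ci[2] - ci[1],
    spearman_rho = if (isTRUE(skew_flag))
      stats::cor(gbv, phenotypes, method = "spearman") else NA_real_,
    reason = NA_character_)
}

#' Flag a highly skewed score distribution
#'
#' TRUE when the absolute sample Fisher-Pearson skewness
#' |m3 / m2^(3/2)| (moment estimator) exceeds 1. A constant vector is
#' flagged skewed by convention, with a warning.
#'
#' @param scores Numeric vector, n >= 10.
#' @return Logical scalar.
#' @export
skewness_flag <- function(scores) {
  stopifnot(length(scores) >= 10)
  m2 <- mean((scores - mean(scores))^2)
  if (m2 < 1e-12) {
    warning("constant score vector: flagged skewed by convention")
    return(TRUE)
  }
  m3 <- mean((scores - mean(scores))^3)
  abs(m3 / m2^1.5) > 1
}

#' Realized selection differential from GBV tails
#'
#' Ranks individuals by GBV, then contrasts the phenotypes of the k
#' individuals with the most favourable GBV against the k with the least
#' favourable (two-sample Welch t-test), signed so that a positive
#' differential means selection on GBV moved the phenotype in the
#' favourable direction. The directional differential contrasts the
#' favourable tail against the whole family mean (one-sample t-test).
#' GBV ties spanning the k-th rank are broken by stable input order.
#'
#' @param gbv,phenotypes Paired numeric vectors.
#' @param k Tail size (default 50); `2k <= n` required.
#' @param direction `"high"` when a high score is favourable, `"low"` for
#'   defect traits where a low score is favourable.
#' @return One-row tibble: `k`, `diff_top_minus_bottom`, `t_statistic`,
#'   `p_value`, `directional_diff`, `directional_p`.
#' @export
selection_differential <- function(gbv, phenotypes, k = 50,
                                   direction = c("high", "low")) {
  direction <- match.arg(direction)
  n <- length(gbv)
  stopifnot(length(phenotypes) == n, 2 * k <= n)
  sgn <- if (direction == "high") 1 else -1
  ord <- order(sgn * gbv, decreasing = TRUE)  # favourable first, stable
  best <- phenotypes[ord[seq_len(k)]]
  worst <- phenotypes[ord[seq(n - k + 1, n)]]
  tt <- stats::t.test(best, worst)
  dir_diff <- sgn * (mean(best) - mean(phenotypes))
  dt <- stats::t.test(best, mu = mean(phenotypes))
  tibble::tibble(
    k = k,
    diff_top_minus_bottom = sgn * (mean(best) - mean(worst)),
    t_statistic = unname(sgn * tt$statistic),
    p_value = tt$p.value,
    directional_diff = dir_diff,
    directional_p = dt$p.value)
}

#' Aggregate a per-family per-trait accuracy grid
#'
#' Reproduces the shape of a family-by-trait accuracy report: per-family
#' mean over all traits, per-family mean over a declared subset of
#' symmetrically distributed traits, per-trait mean over families, the
#' global maximum, and the per-family mean confidence-interval length.
#' Missing cells (trait not scored in a family) are skipped and counted.
#'
#' @param records Tibble with columns `family`, `trait`, `pearson_r` and
#'   optionally `ci_length`.
#' @param symmetric_traits Traits entering the four-trait mean.
#' @return List of tibbles: `by_family` (`family`, `mean_all`,
#'   `mean_symmetric`, `mean_ci_length`, `n_cells`), `by_trait` (`trait`,
#'   `mean_r`), and scalars `max_r`, `n_missing_cells`.
#' @export
aggregate_report <- function(records,
                             symmetric_traits = c("attractiveness",
                                                  "fruit_cropping",
                                                  "fruit_size",
                                                  "percent_russet")) {
  full_grid <- tidyr::expand_grid(family = unique(records$family),
                                  trait = unique(records$trait))
  n_missing <- nrow(dplyr::anti_join(full_grid, records,
                                     by = c("family", "trait")))
  by_family <- records |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      mean_all = mean(.data$pearson_r),
      mean_symmetric = mean(.data$pearson_r[.data$trait %in% symmetric_traits]),
      mean_ci_length = if ("ci_length" %in% names(records))
        mean(.data$ci_length) else NA_real_,
      n_cells = dplyr::n(), .groups = "drop")
  by_trait <- records |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(mean_r = mean(.data$pearson_r), .groups = "drop")
  list(by_family = by_family, by_trait = by_trait,
       max_r = max(records$pearson_r), n_missing_cells = n_missing)
}

#' Correlation between family relatedness and per-family accuracy
#'
#' Pearson correlation, across families, between a family-averaged
#' relatedness measure and the family's accuracy for a trait.
#'
#' @param relatedness Tibble `family`, `measure`, `mean` (as produced by
#'   [family_relatedness_summary()], possibly with a pedigree row bound on).
#' @param accuracies Tibble `family`, `trait`, `pearson_r`.
#' @param trait Trait to correlate.
#' @return Tibble `measure`, `correlation`, `n_families`.
#' @export
relatedness_accuracy_correlation <- function(relatedness, accuracies, trait) {
  acc <- dplyr::filter(accuracies, .data$trait == !!trait)
  purrr::map_dfr(split(relatedness, relatedness$measure), function(d) {
    j <- dplyr::inner_join(d, acc, by = "family")
    if (nrow(j) < 3) stop("need >= 3 families with both measures")
    if (stats::sd(j$mean) == 0 || stats::sd(j$pearson_r) == 0)
      stop("zero variance across families")
    tibble::tibble(measure = d$measure[1],
                   correlation = stats::cor(j$mean, j$pearson_r),
                   n_families = nrow(j))
  })
}

#' No-intercept regression of accuracy on sqrt(heritability)
#'
#' Under the phenotype-as-proxy argument, the accuracy of predicting
#' phenotypic scores is proportional to sqrt(h2); the proportionality
#' constant is the no-intercept least-squares slope sum(x y) / sum(x^2)
#' with x = sqrt(h2).
#'
#' @param mean_accuracy Per-trait mean accuracies.
#' @param h2 Per-trait heritabilities (same order); traits with h2 = 0 are
#'   dropped.
#' @return Slope (scalar).
#' @export
accuracy_h2_regression <- function(mean_accuracy, h2) {
  stopifnot(length(mean_accuracy) == length(h2))
  keep <- h2 > 0
  if (!any(keep)) stop("all heritabilities are zero")
  x <- sqrt(h2[keep]); y <- mean_accuracy[keep]
  stopifnot(length(x) >= 2)
  sum(x * y) / sum(x^2)
}

#' Convert an estimated pi into an implied QTL count
#'
#' @param pi_hat Posterior mean proportion of SNPs in the model, in [0, 1].
#' @param p Number of SNPs.
#' @return `round(pi_hat * p)`.
#' @export
pi_to_nqtl <- function(pi_hat, p) {
  stopifnot(pi_hat >= 0, pi_hat <= 1, p > 0)
  round(pi_hat * p)
}

#' Check the accuracy decomposition cor(ghat, y) = cor(ghat, TBV) sqrt(h2)
#'
#' On synthetic data with known true breeding values, builds a phenotype
#' y = TBV + independent residual scaled so var(TBV)/var(y) = h2 and
#' returns both sides of the proportionality identity together with their
#' difference.
#'
#' @param gbv Predicted breeding values.
#' @param tbv True breeding values (same length).
#' @param h2 Narrow-sense heritability used to scale the residual.
#' @param seed Optional seed for the residual draw.
#' @return One-row tibble: `cor_gbv_y`, `cor_gbv_tbv`, `expected`
#'   (= cor_gbv_tbv * sqrt(h2)), `difference`.
#' @export
appendix_accuracy_decomposition <- function(gbv, tbv, h2, seed = NULL) {
  stopifnot(length(gbv) == length(tbv), h2 > 0, h2 <= 1)
  if (stats::sd(tbv) == 0) stop("degenerate true breeding values")
  if (!is.null(seed)) set.seed(seed)
  resid_sd <- stats::sd(tbv) * sqrt((1 - h2) / h2)
  y <- tbv + stats::rnorm(length(tbv), sd = resid_sd)
  c1 <- stats::cor(gbv, y)
  c2 <- stats::cor(gbv, tbv)
  tibble::tibble(cor_gbv_y = c1, cor_gbv_tbv = c2,
                 expected = c2 * sqrt(h2), difference = c1 - c2 * sqrt(h2))
}
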