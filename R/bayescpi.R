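#' Build a training-centered marker design matrix
#'
#' Centers every SNP column on its mean over the training individuals (no
#' per-SNP variance scaling); columns with zero variance in the training set
#' carry no information for the regression and are excluded (the exclusion
#' list is kept so the genomic relationship matrix can drop the same SNPs).
#'
#' @param genotypes Dosage matrix (individuals x SNPs), fractional imputed
#'   dosages allowed.
#' @param training_ids Ids (row names) of the training individuals.
#' @return Object of class `gs_design`: list with `W` (centered matrix over
#'   all rows of `genotypes`), `training_ids`, `centers` (training means per
#'   retained SNP) and `excluded` (dropped SNP ids).
#' @export
design_matrix <- function(genotypes, training_ids) {
  stopifnot(all(training_ids %in% rownames(genotypes)))
  if (anyNA(genotypes)) stop("NA in genotype matrix; impute first")
  tr <- genotypes[training_ids, , drop = FALSE]
  v <- matrixStats_colVars(tr)
  keep <- v > 0
  if (!any(keep)) stop("all SNPs monomorphic in the training set")
  centers <- colMeans(tr[, keep, drop = FALSE])
  W <- sweep(genotypes[, keep, drop = FALSE], 2, centers)
  structure(list(W = W, training_ids = training_ids, centers = centers,
                 excluded = colnames(genotypes)[!keep]),
            class = "gs_design")
}

# population-variance column variances without extra deps
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  colMeans(X^2) - colMeans(X)^2
}

#' Fit a BayesC-pi whole-genome regression by Gibbs sampling
#'
#' Markers enter the model through a point-mass mixture prior: each effect
#' is zero with probability 1 - pi and drawn from N(0, sigma_beta^2) with
#' probability pi, with a common effect variance. The Gibbs sampler cycles
#' over per-SNP inclusion indicators (Bernoulli from the conditional odds),
#' effect draws, the common effect variance and residual variance
#' (scaled-inverse-chi-square), pi (Beta posterior), and the intercept.
#' Reported SNP effects are posterior means of the mixture draws, so
#' excluded-state zeros shrink the estimate.
#'
#' Priors: pi ~ Beta(1, 1); sigma_beta^2 and sigma_e^2 scaled-inverse-
#' chi-square with nu = 4.2 and scales set by partitioning var(y) with an
#' assumed prior heritability `h2_prior`, spreading the genetic part over
#' the markers expected in the model.
#'
#' @param design A `gs_design` from [design_matrix()], or a centered
#'   numeric matrix of training rows.
#' @param y Named numeric vector of training phenotypes (typically BLUPs);
#'   names must match design rows when `design` is a `gs_design`.
#' @param iterations,burn_in,thin Chain settings (defaults 50000 / 10000 /
#'   10; scale down for quick runs).
#' @param seed Integer seed for the chain.
#' @param pi_fixed Optional value at which pi is fixed (e.g. `1` turns the
#'   model into SNP-BLUP/ridge); `NULL` samples pi.
#' @param fixed_variances Optional numeric `c(sigma_beta2, sigma_e2)` at
#'   which both variances are held (no variance sampling); with `pi_fixed =
#'   1` this makes the posterior mean of the effects the exact ridge
#'   solution at lambda = sigma_e2 / sigma_beta2, which is the closed-form
#'   oracle used in the tests.
#' @param h2_prior Prior heritability used to set the variance scales.
#' @param nu Prior degrees of freedom for both variances.
#' @return Object of class `gs_bayescpi` with per-SNP posterior summaries,
#'   `pi_hat`, variance components, the intercept, the training centers
#'   (for [predict_gbv()]) and the chain settings.
#' @export
fit_bayescpi <- function(design, y, iterations = 50000L, burn_in = 10000L,
                         thin = 10L, seed = 1L, pi_fixed = NULL,
                         fixed_variances = NULL, h2_prior = 0.5, nu = 4.2) {
  if (inherits(design, "gs_design")) {
    W <- design$W[design$training_ids, , drop = FALSE]
    centers <- design$centers
    if (!is.null(names(y))) {
      stopifnot(all(design$training_ids %in% names(y)))
      y <- y[design$training_ids]
    }
  } else {
    W <- design
    centers <- attr(design, "centers")
  }
  stopifnot(nrow(W) == length(y), iterations > burn_in)
  if (anyNA(W)) stop("NaN/NA in design matrix")
  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-12) stop("phenotype is constant; nothing to fit")

  p <- ncol(W)
  msx <- mean(matrixStats_colVars(W))
  pi0 <- if (is.null(pi_fixed)) 0.5 else pi_fixed
  sb2_target <- h2_prior * vy / max(pi0 * p * msx, 1e-12)
  S_beta <- sb2_target * (nu - 2) / nu
  S_e <- (1 - h2_prior) * vy * (nu - 2) / nu

  set.seed(seed)
  fit <- bayescpi_gibbs(W, y, as.integer(iterations), as.integer(burn_in),
                        as.integer(thin), nu, S_beta, nu, S_e,
                        sample_pi = is.null(pi_fixed),
                        pi_init = if (is.null(pi_fixed)) 0.5 else pi_fixed,
                        pi_a = 1, pi_b = 1,
                        sample_var = is.null(fixed_variances),
                        sb2_init = if (is.null(fixed_variances)) 0 else
                          fixed_variances[1],
                        se2_init = if (is.null(fixed_variances)) 0 else
                          fixed_variances[2])
  structure(list(
    snp = colnames(W),
    effect = stats::setNames(as.vector(fit$beta_mean), colnames(W)),
    effect_sd = stats::setNames(as.vector(fit$beta_sd), colnames(W)),
    inclusion_prob = stats::setNames(as.vector(fit$inclusion_prob),
                                     colnames(W)),
    pi_hat = fit$pi_hat, sigma_beta2 = fit$sigma_beta2,
    sigma_e2 = fit$sigma_e2, intercept = fit$intercept,
    centers = centers, n_samples = fit$n_samples,
    chain = list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = seed, pi_fixed = pi_fixed, h2_prior = h2_prior,
                 nu = nu)),
    class = "gs_bayescpi")
}

#' @export
print.gs_bayescpi <- function(x, ...) {
  cat(sprintf(
    "<gs_bayescpi> %d SNPs, pi_hat = %.4f, sigma_beta2 = %.3g, sigma_e2 = %.3g\n",
    length(x$effect), x$pi_hat, x$sigma_beta2, x$sigma_e2))
  cat(sprintf("  chain: %d iterations, %d burn-in, thin %d (%d samples)\n",
              x$chain$iterations, x$chain$burn_in, x$chain$thin, x$n_samples))
  invisible(x)
}

#' @export
tidy.gs_bayescpi <- function(x, ...) {
  tibble::tibble(snp = x$snp, effect = unname(x$effect),
                 effect_sd = unname(x$effect_sd),
                 inclusion_prob = unname(x$inclusion_prob))
}

#' @export
glance.gs_bayescpi <- function(x, ...) {
  tibble::tibble(pi_hat = x$pi_hat, sigma_beta2 = x$sigma_beta2,
                 sigma_e2 = x$sigma_e2, intercept = x$intercept,
                 n_snps = length(x$effect), n_samples = x$n_samples)
}

#' Predict genomic breeding values
#'
#' ghat_i = sum_m w_im * posterior-mean effect_m, where application dosages
#' are centered with the training means stored in the model (the intercept
#' is excluded: GBVs are deviations).
#'
#' @param model A `gs_bayescpi`.
#' @param genotypes Dosage matrix for the individuals to predict (raw
#'   dosages; centering is applied here), or a `gs_design` sharing the
#'   model's SNPs.
#' @return Tibble with columns `id`, `gbv`.
#' @export
predict_gbv <- function(model, genotypes) {
  if (inherits(genotypes, "gs_design")) genotypes <- genotypes$W +
      rep(genotypes$centers, each = nrow(genotypes$W))
  missing <- setdiff(model$snp, colnames(genotypes))
  if (length(missing) > 0)
    stop("SNPs absent from genotype matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  X <- genotypes[, model$snp, drop = FALSE]
  W <- sweep(X, 2, model$centers)
  tibble::tibble(id = rownames(X),
                 gbv = as.vector(W %*% model$effect))
}

#' SNP effects relative to the phenotypic standard deviation
#'
#' @param model A `gs_bayescpi`.
#' @param y_train Training phenotype vector (sd must be positive).
#' @return Tibble `snp`, `rel_effect` (= |effect| / sd(y)), with attributes
#'   `max_rel_effect` and `frac_below_1e4` (fraction of relative effects
#'   under 1e-4, the "effectively zero" mass).
#' @export
relative_effects <- function(model, y_train) {
  s <- stats::sd(y_train)
  if (!is.finite(s) || s <= 0) stop("zero phenotypic standard deviation")
  rel <- abs(model$effect) / s
  out <- tibble::tibble(snp = model$snp, rel_effect = unname(rel))
  attr(out, "max_rel_effect") <- max(rel)
  attr(out, "frac_below_1e4") <- mean(rel < 1e-4)
  out
}

#' Fraction of model SNPs that were directly genotyped
#'
#' Among SNPs with posterior inclusion probability at or above the
#' threshold, the proportion belonging to the directly genotyped
#' (low-density panel) set rather than being imputed.
#'
#' @param model A `gs_bayescpi`.
#' @param genotyped_snps Character vector of directly genotyped SNP ids.
#' @param threshold Inclusion-probability cutoff in (0, 1).
#' @return Proportion in [0, 1]; `NA` with a warning when no SNP clears the
#'   threshold.
#' @export
genotyped_fraction <- function(model, genotyped_snps, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  included <- model$snp[model$inclusion_prob >= threshold]
  if (length(included) == 0) {
    warning("no SNPs at or above the inclusion threshold")
    return(NA_real_)
  }
  mean(included %in% genotyped_snps)
}
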