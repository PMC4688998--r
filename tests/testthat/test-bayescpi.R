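test_that("design matrix centers on training means and drops monomorphics", {
  g <- rbind(t1 = c(0, 1, 2), t2 = c(2, 1, 2), t3 = c(1, 1, 1),
             a1 = c(0, 0, 0))
  colnames(g) <- c("s1", "s2", "s3")  # s2 constant in training only
  d <- design_matrix(g, c("t1", "t2", "t3"))
  expect_equal(d$excluded, "s2")
  expect_true(all(abs(colMeans(d$W[c("t1", "t2", "t3"), ])) < 1e-10))
  expect_equal(unname(d$W["a1", "s1"]), 0 - 1)
  g[1, 1] <- NA
  expect_error(design_matrix(g, c("t1", "t2", "t3")), "NA")
})

test_that("near-null data yields near-zero posterior effects", {
  set.seed(2)
  n <- 40; p <- 30
  W <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("i", 1:n), paste0("s", 1:p)))
  W <- scale(W, scale = FALSE)
  y <- rnorm(n, sd = 0.05)
  fit <- fit_bayescpi(W, y, iterations = 3000, burn_in = 500, thin = 2,
                      seed = 3)
  expect_true(all(abs(fit$effect) < pmax(3 * fit$effect_sd, 1e-3)))
  expect_error(fit_bayescpi(W, rep(1, n), iterations = 100, burn_in = 10),
               "constant")
})

test_that("pi fixed at 1 matches the closed-form ridge solution", {
  set.seed(14)
  n <- 50; p <- 100
  W <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("i", 1:n), paste0("s", 1:p)))
  W <- scale(W, scale = FALSE)
  b_true <- rnorm(p, sd = 0.1)
  y <- drop(W %*% b_true) + rnorm(n)
  # stage 1: estimate the posterior-mean variances
  fit0 <- fit_bayescpi(W, y, iterations = 6000, burn_in = 1000, thin = 2,
                       seed = 5, pi_fixed = 1)
  expect_equal(fit0$pi_hat, 1)
  # stage 2: condition on those variances; the posterior mean of the
  # effects is then the ridge solution at lambda = sigma_e2 / sigma_beta2
  fit <- fit_bayescpi(W, y, iterations = 22000, burn_in = 2000, thin = 2,
                      seed = 5, pi_fixed = 1,
                      fixed_variances = c(fit0$sigma_beta2, fit0$sigma_e2))
  lambda <- fit0$sigma_e2 / fit0$sigma_beta2
  ridge <- drop(solve(crossprod(W) + diag(lambda, p),
                      crossprod(W, y - mean(y))))
  mcse <- fit$effect_sd / sqrt(fit$n_samples)
  z <- abs(unname(fit$effect) - ridge) / mcse
  # 100 simultaneous 3-sigma comparisons: ~97% should be inside the band
  expect_gte(mean(z <= 3), 0.95)
  expect_lt(max(z), 6)
  expect_gt(stats::cor(unname(fit$effect), ridge), 0.999)
})

test_that("pi and the causal set are recovered on sparse simulated data", {
  pop <- recovery_pop()
  y <- liability_phenotype(pop)
  d <- design_matrix(pop$genotypes[pop$training_ids, ], pop$training_ids)
  fit <- memo("recovery_fit",
              fit_bayescpi(d, y, iterations = 8000, burn_in = 2000,
                           thin = 5, seed = 6))
  expect_gte(fit$pi_hat, 0.005)
  expect_lte(fit$pi_hat, 0.08)

  causal_snps <- pop$map$snp[pop$architecture$causal[[1]]]
  top5 <- fit$snp[rank(-fit$inclusion_prob) <= ceiling(0.05 * length(fit$snp))]
  expect_gte(sum(causal_snps %in% top5), 10)
})

test_that("chains are seed-reproducible and stable across seeds", {
  set.seed(8)
  n <- 150; p <- 200
  W <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("i", 1:n), paste0("s", 1:p)))
  W <- scale(W, scale = FALSE)
  b <- numeric(p); b[sample.int(p, 10)] <- rnorm(10, sd = 0.4)
  y <- drop(W %*% b) + rnorm(n)
  f1 <- fit_bayescpi(W, y, iterations = 4000, burn_in = 1000, thin = 2,
                     seed = 11)
  f2 <- fit_bayescpi(W, y, iterations = 4000, burn_in = 1000, thin = 2,
                     seed = 11)
  expect_identical(f1$effect, f2$effect)
  expect_identical(f1$pi_hat, f2$pi_hat)

  f3 <- fit_bayescpi(W, y, iterations = 4000, burn_in = 1000, thin = 2,
                     seed = 12)
  expect_lt(abs(f1$pi_hat - f3$pi_hat), 0.05)
})

test_that("GBV prediction is linear in the stored effects", {
  model <- structure(list(
    snp = c("s1", "s2"), effect = c(s1 = 1, s2 = 0),
    centers = c(s1 = 1.3, s2 = 1.0), intercept = 5), class = "gs_bayescpi")
  g <- rbind(a = c(2, 1), b = c(1.3, 0))
  colnames(g) <- c("s1", "s2")
  out <- predict_gbv(model, g)
  expect_equal(out$gbv, c(0.7, 0))

  model2 <- model; model2$effect <- model$effect * 2
  expect_equal(predict_gbv(model2, g)$gbv, 2 * out$gbv)

  model0 <- model; model0$effect[] <- 0
  expect_true(all(predict_gbv(model0, g)$gbv == 0))

  colnames(g) <- c("s1", "sX")
  expect_error(predict_gbv(model, g), "s2")
})

test_that("relative effects and genotyped fraction follow their formulas", {
  model <- structure(list(
    snp = c("a", "b"), effect = c(a = 0.2, b = -0.4),
    inclusion_prob = c(a = 0.9, b = 0.1)), class = "gs_bayescpi")
  y <- c(0, 2, 4)  # sd = 2
  re <- relative_effects(model, y)
  expect_equal(re$rel_effect, c(0.1, 0.2))
  expect_equal(attr(re, "max_rel_effect"), 0.2)
  expect_error(relative_effects(model, rep(1, 3)), "zero")

  expect_equal(genotyped_fraction(model, c("a", "b"), 0.5), 1.0)
  expect_equal(genotyped_fraction(model, "zzz", 0.5), 0.0)
  model$inclusion_prob <- c(a = 0.1, b = 0.1)
  expect_warning(out <- genotyped_fraction(model, "a", 0.5), "threshold")
  expect_true(is.na(out))

  ten <- structure(list(
    snp = paste0("s", 1:10),
    effect = rep(0.1, 10),
    inclusion_prob = rep(0.8, 10)), class = "gs_bayescpi")
  expect_equal(genotyped_fraction(ten, paste0("s", 1:2), 0.5), 0.2)
})

test_that("holdout accuracy grows with training size and dies under permutation", {
  pop <- recovery_pop()
  ids <- pop$training_ids
  set.seed(33)
  y_all <- stats::setNames(liability_phenotype(pop, seed = 33), ids)
  # half-of-families holdout (families 5-8); accuracy is the mean
  # within-family correlation, as family means otherwise dominate
  holdout <- ids[401:800]
  tbv_hold <- pop$architecture$tbv[holdout, 1]
  fam <- stats::setNames(pop$pedigree$family[match(ids, pop$pedigree$id)],
                         ids)
  within_cor <- function(g)
    mean(purrr::map_dbl(split(seq_along(holdout), fam[holdout]),
                        function(ix) stats::cor(g[ix], tbv_hold[ix])))

  acc_at_n <- function(n_train, seed) {
    tr <- ids[seq_len(n_train)]
    d <- design_matrix(pop$genotypes[c(tr, holdout), ], tr)
    fit <- fit_bayescpi(d, y_all[tr], iterations = 2500, burn_in = 500,
                        thin = 5, seed = seed)
    within_cor(predict_gbv(fit, pop$genotypes[holdout, ])$gbv)
  }
  accs <- purrr::map_dbl(c(100, 200, 400), function(n)
    mean(purrr::map_dbl(1:3, ~acc_at_n(n, .x))))
  expect_true(all(diff(accs) > 0))

  # permuted phenotypes carry no signal; the fitted effect vector is one
  # noise draw shared by all families, so average over 5 permutations
  tr <- ids[1:400]
  d <- design_matrix(pop$genotypes[c(tr, holdout), ], tr)
  r_perm <- purrr::map_dbl(1:5, function(s) {
    set.seed(s)
    y_perm <- stats::setNames(sample(y_all[tr]), tr)
    fit <- fit_bayescpi(d, y_perm, iterations = 2500, burn_in = 500,
                        thin = 5, seed = s + 100)
    within_cor(predict_gbv(fit, pop$genotypes[holdout, ])$gbv)
  })
  expect_lt(abs(mean(r_perm)), 0.1)
})

test_that("tidy and glance summarise a fitted model", {
  set.seed(4)
  W <- scale(matrix(rnorm(600), 30), scale = FALSE)
  colnames(W) <- paste0("s", 1:20)
  rownames(W) <- paste0("i", 1:30)
  fit <- fit_bayescpi(W, rnorm(30), iterations = 500, burn_in = 100,
                      thin = 2, seed = 2)
  td <- tidy(fit)
  expect_equal(names(td), c("snp", "effect", "effect_sd", "inclusion_prob"))
  expect_equal(nrow(td), 20)
  gl <- glance(fit)
  expect_true(all(c("pi_hat", "sigma_beta2", "sigma_e2") %in% names(gl)))
})
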