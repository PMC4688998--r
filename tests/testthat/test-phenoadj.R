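ref_pheno <- function(scores_by_cell, ids = paste0("R", 1:4)) {
  # scores_by_cell: tibble(year, location, shift) recycled over reference ids
  tidyr::crossing(id = ids, scores_by_cell) |>
    dplyr::mutate(trait = "t1", score = score) |>
    dplyr::select(id, trait, year, location, score)
}

test_that("environment effects are recovered from reference genotypes", {
  one <- tibble::tibble(id = rep(paste0("R", 1:3), 2), trait = "t1",
                        year = "y1", location = "L1", score = c(2, 3, 4, 2, 3, 4))
  eff <- estimate_environment_effects(one, paste0("R", 1:3))
  expect_true(all(eff$effect == 0))

  # location B exactly +1 over A
  base <- tidyr::crossing(id = paste0("R", 1:3), location = c("A", "B")) |>
    dplyr::mutate(trait = "t1", year = "y1",
                  score = 2 + (id == "R2") + (location == "B"))
  eff <- estimate_environment_effects(base, paste0("R", 1:3))
  effB <- eff$effect[eff$term == "location" & eff$level == "B"]
  expect_equal(effB, 1.0)

  expect_error(
    estimate_environment_effects(
      dplyr::bind_rows(base, tibble::tibble(id = "X", trait = "t1",
                                            year = "y1", location = "C",
                                            score = 3)),
      paste0("R", 1:3)),
    "location level: C")
})

test_that("reference-design least squares matches the normal-equations oracle", {
  set.seed(21)
  d <- tidyr::crossing(id = paste0("R", 1:5), year = c("y1", "y2", "y3"),
                       location = c("L1", "L2")) |>
    dplyr::mutate(trait = "t1",
                  score = stats::rnorm(dplyr::n(), mean = 3))
  eff <- estimate_environment_effects(d, paste0("R", 1:5))

  # oracle: explicit treatment-coded design, solve X'X b = X'y
  X <- cbind(1,
             outer(d$id, paste0("R", 2:5), `==`) * 1,
             (d$year == "y2") * 1, (d$year == "y3") * 1,
             (d$location == "L2") * 1)
  b <- solve(crossprod(X), crossprod(X, d$score))
  expect_equal(eff$effect[eff$term == "year" & eff$level == "y2"], b[6],
               tolerance = 1e-10)
  expect_equal(eff$effect[eff$term == "year" & eff$level == "y3"], b[7],
               tolerance = 1e-10)
  expect_equal(eff$effect[eff$term == "location" & eff$level == "L2"], b[8],
               tolerance = 1e-10)
})

test_that("adjustment subtracts effects and averages records", {
  ph <- tibble::tibble(id = c("a", "a", "b"), trait = "t1",
                       year = c("y1", "y2", "y1"),
                       location = "L1", score = c(3, 4, 2))
  eff0 <- tibble::tibble(trait = "t1",
                         term = c("year", "year", "location"),
                         level = c("y1", "y2", "L1"), effect = c(0, 0, 0))
  adj <- adjust_phenotypes(ph, eff0)
  expect_equal(adj$adjusted, adj$score)

  eff <- tibble::tibble(trait = "t1",
                        term = c("year", "year", "location"),
                        level = c("y1", "y2", "L1"),
                        effect = c(0.5, 1, -0.5))
  adj <- adjust_phenotypes(ph, eff)
  expect_equal(adj$adjusted, c(3, 3.5, 2))
  m <- adjusted_means(adj)
  expect_equal(m$adjusted_mean[m$id == "a"], mean(c(3, 3.5)))
  expect_equal(m$n_records[m$id == "a"], 2L)

  ph_bad <- dplyr::mutate(ph, year = c("y1", "y9", "y1"))
  expect_error(adjust_phenotypes(ph_bad, eff), "unadjustable")
})

test_that("EM-REML handles degenerate data and recovers simulated h2", {
  A <- diag(10); dimnames(A) <- list(letters[1:10], letters[1:10])
  y <- stats::setNames(rep(2, 10), letters[1:10])
  vc <- reml_variance_components(y, A)
  expect_equal(vc$sigma_a2, 0)
  expect_equal(vc$h2, 0)

  # parameter recovery: sigma_a2 = sigma_e2 = 1, multi-generation pedigree;
  # the single-fit sampling sd of h2 at n ~ 500 is ~0.15, so recovery is
  # judged on the mean over three independent replicates
  h2s <- purrr::map_dbl(1:3, function(s) {
    cfg <- sim_config(n_founders = 24, n_training_families = 24,
                      training_family_sizes = rep(18, 24),
                      n_application_families = 0,
                      application_family_sizes = integer(0),
                      n_reference_genotypes = 0, seed = s)
    ped <- generate_pedigree(cfg)
    A <- build_a_matrix(ped)
    set.seed(s + 1000)
    L <- t(chol(A + diag(1e-8, nrow(A))))
    y <- stats::setNames(drop(L %*% stats::rnorm(nrow(A))) +
                           stats::rnorm(nrow(A)) + 3, ped$id)
    vc <- reml_variance_components(y, A, max_iter = 5000)
    expect_true(vc$converged)
    vc$h2
  })
  expect_equal(mean(h2s), 0.5, tolerance = 0.3)

  out <- glance(vc <- reml_variance_components(
    stats::setNames(stats::rnorm(40), paste0("i", 1:40)),
    `dimnames<-`(diag(40), list(paste0("i", 1:40), paste0("i", 1:40)))))
  expect_equal(out$h2, vc$h2)
  expect_equal(tidy(vc)$estimate, c(vc$sigma_a2, vc$sigma_e2))
})

test_that("clone-replicate REML matches the one-way ANOVA oracle", {
  set.seed(5)
  n_clone <- 40; r <- 5
  sa <- 0.8; se <- 0.4
  a <- rep(stats::rnorm(n_clone, sd = sqrt(sa)), each = r)
  y <- 3 + a + stats::rnorm(n_clone * r, sd = sqrt(se))
  ids <- paste0("c", rep(seq_len(n_clone), each = r), "_", rep(1:r, n_clone))
  names(y) <- ids
  # copies of a clone share the same genetic effect: A is block of ones
  A <- kronecker(diag(n_clone), matrix(1, r, r))
  dimnames(A) <- list(ids, ids)
  vc <- reml_variance_components(y, A)

  grp <- rep(seq_len(n_clone), each = r)
  msb <- sum(tapply(y, grp, function(v) r * (mean(v) - mean(y))^2)) /
    (n_clone - 1)
  msw <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2))) /
    (n_clone * (r - 1))
  sa_hat <- (msb - msw) / r
  se_hat <- msw
  expect_equal(vc$sigma_e2, se_hat, tolerance = 0.05)
  expect_equal(vc$h2, sa_hat / (sa_hat + se_hat), tolerance = 0.1)
})

test_that("BLUP limits and the GLS oracle hold", {
  fs <- ped_tbl(c("pa", "ma", paste0("k", 1:8)),
                sire = c(NA, NA, rep("pa", 8)), dam = c(NA, NA, rep("ma", 8)))
  A <- build_a_matrix(fs)
  set.seed(77)
  y <- stats::setNames(stats::rnorm(10, mean = 3), fs$id)

  # no-shrinkage limit
  b <- animal_model_blup(y, A, list(sigma_a2 = 1e8, sigma_e2 = 1))
  expect_equal(stats::setNames(b$blup, b$id), y - attr(b, "mu"),
               tolerance = 1e-5)

  # full-shrinkage limit
  expect_warning(b0 <- animal_model_blup(y, A, list(sigma_a2 = 0,
                                                    sigma_e2 = 1)),
                 "zero")
  expect_true(all(b0$blup == 0))

  # dense GLS oracle: ahat = sa A V^-1 (y - 1 mu), mu by GLS
  sa <- 0.7; se <- 1.3
  V <- sa * A + se * diag(10)
  Vi <- solve(V)
  one <- rep(1, 10)
  mu <- drop((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  ahat <- drop(sa * A %*% Vi %*% (y - mu))
  b <- animal_model_blup(y, A, list(sigma_a2 = sa, sigma_e2 = se))
  expect_equal(b$blup, unname(ahat), tolerance = 1e-8)
  expect_equal(attr(b, "mu"), mu, tolerance = 1e-8)
})

test_that("h2 is scale invariant and BLUP tracks TBV with heritability", {
  cfg <- sim_config(n_founders = 10, n_training_families = 4,
                    training_family_sizes = rep(60, 4),
                    n_application_families = 0,
                    application_family_sizes = integer(0),
                    n_reference_genotypes = 0, seed = 13L)
  ped <- generate_pedigree(cfg)
  A <- build_a_matrix(ped)
  ids <- ped$id[ped$role == "training"]
  Asub <- A[ids, ids]
  set.seed(19)
  L <- t(chol(Asub + diag(1e-8, length(ids))))
  g <- drop(L %*% stats::rnorm(length(ids)))

  cors <- purrr::map_dbl(c(0.1, 0.3, 0.6), function(h2) {
    mean(purrr::map_dbl(1:5, function(rep) {
      y <- stats::setNames(
        sqrt(h2) * g / stats::sd(g) +
          stats::rnorm(length(ids), sd = sqrt(1 - h2)), ids)
      vc <- reml_variance_components(y, Asub)
      b <- animal_model_blup(y, Asub, vc)
      stats::cor(b$blup, g)
    }))
  })
  expect_true(all(diff(cors) > 0))

  y <- stats::setNames(g + stats::rnorm(length(ids)), ids)
  vc1 <- reml_variance_components(y, Asub)
  vc2 <- reml_variance_components(y * 10, Asub)
  expect_equal(vc2$h2, vc1$h2, tolerance = 1e-4)
  expect_equal(vc2$sigma_a2, 100 * vc1$sigma_a2, tolerance = 1e-3)
})
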