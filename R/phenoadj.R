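#' Estimate year and location effects from replicated reference genotypes
#'
#' Reference genotypes are clones scored in every location and year, and are
#' the only individuals connecting environments. Their records are fit by
#' least squares with genotype identity as a blocking factor and additive
#' year and location effects, the first level of each factor constrained to
#' zero (treatment contrasts).
#'
#' @param phenotypes Phenotype tibble (`id`, `trait`, `year`, `location`,
#'   `score`). All year and location levels present here must carry at least
#'   one reference record, otherwise an error names the missing level.
#' @param reference_ids Ids of the reference genotypes.
#' @return Tibble with columns `trait`, `term` ("year" or "location"),
#'   `level`, `effect`; every observed level appears (baselines as 0).
#' @export
estimate_environment_effects <- function(phenotypes, reference_ids) {
  ref <- dplyr::filter(phenotypes, .data$id %in% reference_ids)
  if (nrow(ref) == 0) stop("no reference-genotype records")
  for (f in c("year", "location")) {
    missing <- setdiff(unique(phenotypes[[f]]), unique(ref[[f]]))
    if (length(missing) > 0)
      stop("no reference records for ", f, " level: ",
           paste(missing, collapse = ", "))
  }
  purrr::map_dfr(split(ref, ref$trait), function(d) {
    trait <- d$trait[1]
    yl <- sort(unique(d$year)); ll <- sort(unique(d$location))
    d$year <- factor(d$year, levels = yl)
    d$location <- factor(d$location, levels = ll)
    terms <- c("score ~ 1",
               if (dplyr::n_distinct(d$id) > 1) "id",
               if (length(yl) > 1) "year",
               if (length(ll) > 1) "location")
    fit <- stats::lm(stats::as.formula(paste(terms, collapse = " + ")),
                     data = d)
    cf <- stats::coef(fit)
    pick <- function(term, levels) {
      eff <- stats::setNames(rep(0, length(levels)), levels)
      hit <- paste0(term, levels)
      found <- intersect(hit, names(cf))
      eff[sub(term, "", found)] <- cf[found]
      eff[is.na(eff)] <- 0
      tibble::tibble(trait = trait, term = term, level = levels,
                     effect = unname(eff))
    }
    dplyr::bind_rows(pick("year", yl), pick("location", ll))
  })
}

#' Adjust phenotype records for year and location effects
#'
#' Adjusted score = raw score - estimated year effect - estimated location
#' effect. Adjustment can push values outside the raw 1-5 ordinal range.
#'
#' @param phenotypes Phenotype tibble.
#' @param env_effects Effect tibble from [estimate_environment_effects()];
#'   every observed (trait, year) and (trait, location) must be covered.
#' @return The phenotype tibble with an extra `adjusted` column.
#' @export
adjust_phenotypes <- function(phenotypes, env_effects) {
  lk <- function(term) {
    env_effects |>
      dplyr::filter(.data$term == !!term) |>
      dplyr::select("trait", level = "level", eff = "effect")
  }
  out <- phenotypes |>
    dplyr::left_join(lk("year"), by = c("trait", year = "level")) |>
    dplyr::rename(year_eff = "eff") |>
    dplyr::left_join(lk("location"), by = c("trait", location = "level")) |>
    dplyr::rename(loc_eff = "eff")
  bad <- dplyr::filter(out, is.na(.data$year_eff) | is.na(.data$loc_eff))
  if (nrow(bad) > 0)
    stop("records with unadjustable year/location level, e.g. (",
         bad$year[1], ", ", bad$location[1], ") for trait ", bad$trait[1])
  out |>
    dplyr::mutate(adjusted = .data$score - .data$year_eff - .data$loc_eff) |>
    dplyr::select(-"year_eff", -"loc_eff")
}

#' Per-individual adjusted phenotype means
#'
#' @param adjusted Output of [adjust_phenotypes()].
#' @return Tibble with `id`, `trait`, `adjusted_mean`, `n_records`.
#' @export
adjusted_means <- function(adjusted) {
  adjusted |>
    dplyr::group_by(.data$id, .data$trait) |>
    dplyr::summarise(adjusted_mean = mean(.data$adjusted),
                     n_records = dplyr::n(), .groups = "drop")
}

# Solve the single-trait animal-model mixed-model equations in the
# eigenbasis of A. With A = U diag(d) U' and one overall mean, the
# coefficient matrix becomes an arrow matrix whose random-effect block is
# diagonal, so the solve and the trace terms needed by EM-REML are O(n).
# Returns mu, ahat (original basis), a'A^-1 a and tr(A^-1 Caa).
.mme_solve <- function(ystar, x, d, sum_y, lambda, U) {
  m <- 1 + lambda / d
  Minv_x <- x / m
  s <- length(ystar) - sum(x * Minv_x)
  mu <- (sum_y - sum(Minv_x * ystar)) / s
  alpha <- (ystar - x * mu) / m
  ahat <- as.vector(U %*% alpha)
  aAinva <- sum(alpha^2 / d)
  trAinvCaa <- sum(1 / (d * m)) + sum((Minv_x / sqrt(d))^2) / s
  list(mu = mu, ahat = ahat, alpha = alpha,
       aAinva = aAinva, trAinvCaa = trAinvCaa)
}

.eigen_A <- function(A, floor = 1e-8) {
  eig <- eigen(A, symmetric = TRUE)
  eig$values <- pmax(eig$values, floor)
  eig
}

#' EM-REML variance components under the animal model
#'
#' Fits y = mu + a + e with a ~ N(0, A sigma_a2) and independent residuals
#' by expectation-maximisation REML on Henderson's mixed-model equations,
#' iterating until the relative change in both components drops below
#' `tolerance`. A single eigendecomposition of A makes each iteration O(n).
#'
#' @param y Named numeric vector of phenotypes (one per individual), names
#'   matching rows of `A`.
#' @param A Additive relationship matrix covering the names of `y`.
#' @param tolerance Relative-change convergence criterion.
#' @param max_iter Maximum EM iterations; non-convergence returns the last
#'   iterate flagged `converged = FALSE`.
#' @return Object of class `gs_varcomp`: list with `sigma_a2`, `sigma_e2`,
#'   `h2`, `mu`, `converged`, `iterations`, `n`. `h2` is reported as 0 when
#'   both components collapse below 1e-12 (degenerate data).
#' @export
reml_variance_components <- function(y, A, tolerance = 1e-6,
                                     max_iter = 1000L) {
  ids <- names(y)
  stopifnot(!is.null(ids), all(ids %in% rownames(A)))
  A <- A[ids, ids]
  n <- length(y)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-12) {
    return(structure(list(sigma_a2 = 0, sigma_e2 = 0, h2 = 0,
                          mu = mean(y), converged = TRUE, iterations = 0L,
                          n = n), class = "gs_varcomp"))
  }
  eig <- .eigen_A(A)
  U <- eig$vectors; d <- eig$values
  ystar <- as.vector(crossprod(U, y))
  x <- as.vector(crossprod(U, rep(1, n)))
  sum_y <- sum(y)
  yty <- sum(y^2)

  sa <- se <- vy / 2
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    sol <- .mme_solve(ystar, x, d, sum_y, lambda = se / sa, U = U)
    sa_new <- (sol$aAinva + sol$trAinvCaa * se) / n
    se_new <- (yty - sol$mu * sum_y - sum(sol$alpha * ystar)) / (n - 1)
    if (abs(sa_new - sa) < tolerance * max(sa, 1e-12) &&
        abs(se_new - se) < tolerance * max(se, 1e-12)) {
      sa <- sa_new; se <- se_new
      converged <- TRUE
      break
    }
    sa <- max(sa_new, 1e-12); se <- max(se_new, 1e-12)
  }
  h2 <- if (sa + se < 1e-12) 0 else sa / (sa + se)
  sol <- .mme_solve(ystar, x, d, sum_y, lambda = se / sa, U = U)
  structure(list(sigma_a2 = sa, sigma_e2 = se, h2 = h2, mu = sol$mu,
                 converged = converged, iterations = it, n = n),
            class = "gs_varcomp")
}

#' @export
print.gs_varcomp <- function(x, ...) {
  cat(sprintf(
    "<gs_varcomp> sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f (%s, %d it.)\n",
    x$sigma_a2, x$sigma_e2, x$h2,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gs_varcomp <- function(x, ...) {
  tibble::tibble(component = c("sigma_a2", "sigma_e2"),
                 estimate = c(x$sigma_a2, x$sigma_e2))
}

#' @export
glance.gs_varcomp <- function(x, ...) {
  tibble::tibble(h2 = x$h2, sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2,
                 mu = x$mu, n = x$n, converged = x$converged,
                 iterations = x$iterations)
}

#' Animal-model BLUP of genotypic effects
#'
#' Solves Henderson's mixed-model equations for y = mu + a + e at the given
#' variance components and returns the predicted genotypic effect (BLUP) per
#' individual.
#'
#' @param y Named numeric phenotype vector.
#' @param A Additive relationship matrix covering `names(y)`.
#' @param varcomp A `gs_varcomp` (or list with `sigma_a2`, `sigma_e2`).
#' @return Tibble with columns `id` and `blup`; attribute `mu` holds the
#'   estimated mean. If `sigma_a2` is 0 the system is singular and all BLUPs
#'   are returned as 0 with a warning.
#' @export
animal_model_blup <- function(y, A, varcomp) {
  ids <- names(y)
  stopifnot(!is.null(ids), all(ids %in% rownames(A)))
  if (varcomp$sigma_a2 <= 0) {
    warning("sigma_a2 is zero: returning all-zero BLUPs")
    out <- tibble::tibble(id = ids, blup = 0)
    attr(out, "mu") <- mean(y)
    return(out)
  }
  A <- A[ids, ids]
  eig <- .eigen_A(A)
  ystar <- as.vector(crossprod(eig$vectors, y))
  x <- as.vector(crossprod(eig$vectors, rep(1, length(y))))
  sol <- .mme_solve(ystar, x, eig$values, sum(y),
                    lambda = varcomp$sigma_e2 / varcomp$sigma_a2,
                    U = eig$vectors)
  out <- tibble::tibble(id = ids, blup = sol$ahat)
  attr(out, "mu") <- sol$mu
  out
}

#' Variance components and BLUP phenotypes for every trait
#'
#' Convenience wrapper running [reml_variance_components()] and
#' [animal_model_blup()] per trait on per-individual adjusted means.
#'
#' @param adj_means Tibble from [adjusted_means()], restricted to the
#'   individuals to analyse (typically the training population).
#' @param A Additive relationship matrix.
#' @param tolerance,max_iter Passed to [reml_variance_components()].
#' @return List with `blups` (tibble `id`, `trait`, `blup`) and `varcomp`
#'   (tibble `trait`, `sigma_a2`, `sigma_e2`, `h2`, `converged`).
#' @export
fit_trait_blups <- function(adj_means, A, tolerance = 1e-6,
                            max_iter = 5000L) {
  pieces <- purrr::map(split(adj_means, adj_means$trait), function(d) {
    y <- stats::setNames(d$adjusted_mean, d$id)
    vc <- reml_variance_components(y, A, tolerance, max_iter)
    bl <- animal_model_blup(y, A, vc)
    list(blups = dplyr::mutate(bl, trait = d$trait[1], .after = "id"),
         varcomp = dplyr::mutate(glance(vc), trait = d$trait[1],
                                 .before = 1))
  })
  list(blups = purrr::map_dfr(pieces, "blups"),
       varcomp = purrr::map_dfr(pieces, "varcomp"))
}
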