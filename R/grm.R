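#' Standardize dosages on training means and standard deviations
#'
#' w_im = (x_im - mean_train,m) / sd_train,m, with the per-SNP mean and
#' standard deviation computed over the training individuals only and the
#' sd using the divide-by-N (population) convention, which makes the mean
#' training diagonal of the resulting relationship matrix exactly 1. SNPs
#' monomorphic in the training set are excluded and listed.
#'
#' @param X Dosage matrix over training and application individuals.
#' @param training_ids Row names of the training individuals.
#' @return List with `W` (standardized matrix), `excluded` (dropped SNP
#'   ids), `centers` and `sds`.
#' @export
standardize_dosages <- function(X, training_ids) {
  stopifnot(all(training_ids %in% rownames(X)))
  tr <- X[training_ids, , drop = FALSE]
  mu <- colMeans(tr)
  sd_n <- sqrt(colMeans(tr^2) - mu^2)
  keep <- sd_n > 0
  if (!any(keep)) stop("all SNPs monomorphic in the training set")
  W <- sweep(X[, keep, drop = FALSE], 2, mu[keep])
  W <- sweep(W, 2, sd_n[keep], "/")
  list(W = W, excluded = colnames(X)[!keep],
       centers = mu[keep], sds = sd_n[keep])
}

#' Genomic relationship matrix G = W'W / p
#'
#' With `W` the training-standardized dosage matrix (individuals in rows
#' here, so the computation is W W' / p over individuals), `p` the number
#' of retained SNPs. By construction the mean relatedness of any individual
#' to the training set is exactly zero and the mean training diagonal is
#' exactly 1.
#'
#' @param W Standardized matrix from [standardize_dosages()] (individuals x
#'   SNPs).
#' @param p Number of SNPs; defaults to `ncol(W)`.
#' @return Symmetric numeric matrix with id dimnames, class `gs_grm`.
#' @export
compute_g <- function(W, p = ncol(W)) {
  if (p == 0) stop("p = 0: no SNPs retained")
  G <- tcrossprod(W) / p
  class(G) <- c("gs_grm", class(G))
  G
}

#' Mean of an individual's k highest relationships to the training set
#'
#' Sorts the individual's genomic relationships to all training individuals
#' in decreasing order and averages the first k. `spec` is either a count
#' (k >= 1) or a fraction of the training size (rounded to the nearest
#' integer, minimum 1). Self-relationships are excluded when the individual
#' is itself in the training set.
#'
#' @param G Relationship matrix with id dimnames.
#' @param individual Single id.
#' @param training_ids Training ids (non-empty).
#' @param spec Count (`>= 1`) or fraction (`< 1`) of the training set.
#' @return Mean of the k highest relatedness values.
#' @export
top_n_relatedness <- function(G, individual, training_ids, spec = 10) {
  if (length(training_ids) == 0) stop("empty training set")
  others <- setdiff(training_ids, individual)
  k <- if (spec < 1) max(1L, round(spec * length(others))) else as.integer(spec)
  stopifnot(k >= 1, k <= length(others))
  vals <- G[individual, others]
  mean(sort(vals, decreasing = TRUE)[seq_len(k)])
}

#' Family-level summary of top-N genomic relatedness
#'
#' For every application individual, computes the top-10, top-5% and
#' top-25% relatedness to the training population, then summarises each
#' statistic within family by its mean and standard deviation (divide by
#' N-1; `NA` for single-individual families).
#'
#' @param G Relationship matrix.
#' @param families Named list (family -> ids) or tibble with `id`,
#'   `family`.
#' @param training_ids Training ids.
#' @param specs Named vector of top-N specs (counts or fractions).
#' @return Tibble with `family`, `measure`, `mean`, `sd`, `n`.
#' @export
family_relatedness_summary <- function(G, families, training_ids,
                                       specs = c(top10 = 10, top5pct = 0.05,
                                                 top25pct = 0.25)) {
  if (is.data.frame(families))
    families <- split(families$id, families$family)
  stopifnot(length(families) > 0, all(lengths(families) > 0))
  purrr::imap_dfr(families, function(ids, fam) {
    purrr::imap_dfr(specs, function(spec, measure) {
      vals <- purrr::map_dbl(ids, ~top_n_relatedness(G, .x, training_ids, spec))
      tibble::tibble(family = fam, measure = measure, mean = mean(vals),
                     sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
                     n = length(vals))
    })
  })
}

#' LD decay: mean r-squared by map-distance bin
#'
#' Squared Pearson correlation between dosage columns for all
#' within-chromosome marker pairs, averaged per distance bin, plus the mean
#' over physically adjacent pairs.
#'
#' @param X Dosage (or standardized) matrix restricted to the individuals
#'   of interest (typically the training population).
#' @param map Genetic map covering the columns of `X`.
#' @param breaks Bin edges in cM.
#' @param max_pairs_per_chrom Optional cap on pairs per chromosome (random
#'   subsample, seeded) to bound cost on dense maps; `Inf` disables.
#' @return List with `bins` (tibble `bin`, `mean_r2`, `n_pairs`; empty bins
#'   reported with `NA`) and `adjacent_mean_r2`.
#' @export
ld_decay <- function(X, map, breaks = c(0, 1, 5, 20, Inf),
                     max_pairs_per_chrom = 50000) {
  stopifnot(ncol(X) == nrow(map))
  per_chrom <- split(seq_len(nrow(map)), map$chrom)
  if (any(lengths(per_chrom) < 2)) stop("need >= 2 SNPs per chromosome")
  dist_all <- numeric(0); r2_all <- numeric(0); adj_r2 <- numeric(0)
  for (cols in per_chrom) {
    C <- suppressWarnings(stats::cor(X[, cols, drop = FALSE]))
    pos <- map$pos_cM[cols]
    m <- length(cols)
    pr <- which(upper.tri(C), arr.ind = TRUE)
    if (nrow(pr) > max_pairs_per_chrom)
      pr <- pr[sample.int(nrow(pr), max_pairs_per_chrom), , drop = FALSE]
    r2 <- C[pr]^2
    d <- abs(pos[pr[, 2]] - pos[pr[, 1]])
    ok <- !is.na(r2)
    dist_all <- c(dist_all, d[ok]); r2_all <- c(r2_all, r2[ok])
    adj <- C[cbind(seq_len(m - 1), 2:m)]^2
    adj_r2 <- c(adj_r2, adj[!is.na(adj)])
  }
  bin <- cut(dist_all, breaks, right = FALSE)
  bins <- tibble::tibble(bin = levels(bin)) |>
    dplyr::left_join(
      tibble::tibble(bin = as.character(bin), r2 = r2_all) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n()),
      by = "bin") |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L))
  list(bins = bins, adjacent_mean_r2 = mean(adj_r2))
}
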