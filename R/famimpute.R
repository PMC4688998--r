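# Family-based two-step imputation: phase the high-density parents from
# their informative offspring, then decode each low-density offspring's
# parental-haplotype origin with a 4-state HMM and fill untyped SNPs with
# the posterior expected dosage.

# offspring allele transmitted by `parent` at one SNP, deduced from the
# offspring dosage and the other parent's genotype; NA when ambiguous
.transmitted_allele <- function(g_off, g_other) {
  t <- rep(NA_real_, length(g_off))
  t[!is.na(g_off) & g_off == 0] <- 0
  t[!is.na(g_off) & g_off == 2] <- 1
  het <- !is.na(g_off) & g_off == 1 & !is.na(g_other)
  t[het & g_other == 0] <- 1
  t[het & g_other == 2] <- 0
  t
}

#' Phase high-density parent genotypes from informative offspring
#'
#' For every parent of the requested families, heterozygous SNPs are phased
#' chromosome by chromosome with a greedy minimum-recombination chain:
#' adjacent heterozygous sites are linked in coupling or repulsion by a
#' majority vote over offspring whose transmitted allele is deducible at
#' both sites. Homozygous SNPs are trivially phased; heterozygous SNPs that
#' cannot be linked to the chain are flagged unphased. Haplotype labels are
#' arbitrary per chromosome (a whole-chromosome swap is unobservable).
#'
#' @param genotypes High-density dosage matrix (rows: genotyped parents and
#'   offspring; columns in map order).
#' @param pedigree Pedigree tibble linking offspring to sire/dam.
#' @param map Genetic map for the columns of `genotypes`.
#' @param parents Character ids of parents to phase; default every sire/dam
#'   of a genotyped offspring that is itself genotyped.
#' @param max_conflict Maximum tolerated fraction of Mendelian conflicts
#'   between a parent and its offspring before a pedigree-inconsistency
#'   error is raised.
#' @return Object of class `gs_parent_haplotypes`: named list per parent
#'   with numeric vectors `h1`, `h2` (alleles, NA at unphased sites),
#'   logical `phased`, and the parent dosage `g`; plus attributes `map`.
#' @export
phase_parents <- function(genotypes, pedigree, map, parents = NULL,
                          max_conflict = 0.05) {
  stopifnot(ncol(genotypes) == nrow(map))
  ped <- tibble::as_tibble(pedigree)
  typed <- rownames(genotypes)
  if (is.null(parents)) {
    off <- ped[ped$id %in% typed & !is.na(ped$sire) & !is.na(ped$dam), ]
    parents <- intersect(unique(c(off$sire, off$dam)), typed)
  }
  chrom_split <- split(seq_len(nrow(map)), map$chrom)

  res <- purrr::map(parents, function(pid) {
    g <- genotypes[pid, ]
    kids <- ped[!is.na(ped$sire) & !is.na(ped$dam) &
                  (ped$sire == pid | ped$dam == pid) & ped$id %in% typed, ]
    other <- ifelse(kids$sire == pid, kids$dam, kids$sire)
    # Mendelian conflict rate parent vs offspring
    if (nrow(kids) > 0) {
      K <- genotypes[kids$id, , drop = FALSE]
      conf <- sweep(K, 2, g, function(k, gp)
        (!is.na(k)) & ((k == 0 & gp == 2) | (k == 2 & gp == 0)))
      rate <- mean(conf, na.rm = TRUE)
      if (is.finite(rate) && rate > max_conflict)
        stop("parent '", pid, "' shows ", sprintf("%.1f%%", 100 * rate),
             " Mendelian conflicts with its offspring (pedigree inconsistency)")
    }
    # transmitted alleles per offspring x SNP
    tmat <- matrix(NA_real_, nrow(kids), ncol(genotypes))
    for (k in seq_len(nrow(kids))) {
      g_other <- if (other[k] %in% typed) genotypes[other[k], ] else
        rep(NA_real_, ncol(genotypes))
      tmat[k, ] <- .transmitted_allele(genotypes[kids$id[k], ], g_other)
    }
    h1 <- h2 <- rep(NA_real_, length(g))
    phased <- rep(FALSE, length(g))
    hom <- !is.na(g) & g != 1
    h1[hom] <- h2[hom] <- g[hom] / 2
    phased[hom] <- TRUE
    for (cols in chrom_split) {
      hets <- cols[!is.na(g[cols]) & g[cols] == 1]
      if (length(hets) == 0) next
      orient <- 1  # allele carried by h1 at the current het site
      h1[hets[1]] <- 1; h2[hets[1]] <- 0
      phased[hets[1]] <- TRUE
      prev <- hets[1]; prev_orient <- 1
      anchors <- prev
      if (length(hets) > 1) {
        for (j in hets[-1]) {
          # aggregate coupling votes over the 10 most recent phased sites:
          # a kid that carried h1 at an anchor votes for the allele it
          # received at j being the h1 allele there
          votes1 <- 0; votes0 <- 0
          tj <- tmat[, j]
          for (a in rev(utils::tail(anchors, 10))) {
            ta <- tmat[, a]
            ok <- which(!is.na(ta) & !is.na(tj))
            if (length(ok) == 0) next
            from_h1 <- ta[ok] == h1[a]
            votes1 <- votes1 + sum(tj[ok][from_h1]) +
              sum(1 - tj[ok][!from_h1])
            votes0 <- votes0 + sum(1 - tj[ok][from_h1]) +
              sum(tj[ok][!from_h1])
          }
          linked <- votes1 + votes0 > 0
          h1[j] <- if (linked) as.numeric(votes1 >= votes0) else 1
          h2[j] <- 1 - h1[j]
          phased[j] <- linked
          anchors <- c(anchors, j)
        }
      }
    }
    list(h1 = h1, h2 = h2, phased = phased, g = g)
  })
  names(res) <- parents
  structure(res, class = "gs_parent_haplotypes", map = map)
}

# allele-1 probability carried by each of a parent's two haplotypes;
# unphased het sites get 0.5 on both, untyped parents their frequency
.hap_probs <- function(hap, p, fallback = 0.5) {
  if (is.null(hap)) {
    f <- rep(fallback, p)
    return(cbind(f, f))
  }
  a1 <- hap$h1; a2 <- hap$h2
  un <- !hap$phased | is.na(a1)
  g <- hap$g
  a1[un] <- ifelse(!is.na(g[un]), g[un] / 2, fallback)
  a2[un] <- a1[un]
  cbind(a1, a2)
}

# forward-backward over the 4 ordered states (father hap, mother hap),
# factorized 2x2; returns posterior state probs (p x 4) and log-likelihood
.fb_chromosome <- function(obs, af, am, rf, rm, eps) {
  p <- length(obs)
  # emission[s, j]: states ordered (f1m1, f1m2, f2m1, f2m2)
  emit <- matrix(1, 4, p)
  typed <- which(!is.na(obs))
  for (j in typed) {
    pf <- c(af[j, 1], af[j, 1], af[j, 2], af[j, 2])
    pm <- c(am[j, 1], am[j, 2], am[j, 1], am[j, 2])
    pd <- rbind((1 - pf) * (1 - pm),
                pf * (1 - pm) + (1 - pf) * pm,
                pf * pm)
    like <- rep(eps / 2, 3); like[obs[j] + 1] <- 1 - eps
    emit[, j] <- colSums(pd * like)
  }
  fwd <- matrix(0, 4, p); bwd <- matrix(0, 4, p)
  scal <- numeric(p)
  v <- 0.25 * emit[, 1]
  scal[1] <- sum(v); fwd[, 1] <- v / scal[1]
  tmix <- function(v, r_f, r_m) {
    # apply factorized transition to a 4-vector (state order as above)
    M <- matrix(v, 2, 2, byrow = TRUE)        # rows: father hap, cols: mother
    Tf <- matrix(c(1 - r_f, r_f, r_f, 1 - r_f), 2, 2)
    Tm <- matrix(c(1 - r_m, r_m, r_m, 1 - r_m), 2, 2)
    as.vector(t(Tf %*% M %*% Tm))
  }
  if (p > 1) {
    for (j in 2:p) {
      v <- tmix(fwd[, j - 1], rf[j], rm[j]) * emit[, j]
      scal[j] <- sum(v)
      fwd[, j] <- v / scal[j]
    }
  }
  bwd[, p] <- 1
  if (p > 1) {
    for (j in (p - 1):1) {
      v <- tmix(bwd[, j + 1] * emit[, j + 1], rf[j + 1], rm[j + 1])
      bwd[, j] <- v / sum(v)
    }
  }
  post <- fwd * bwd
  post <- sweep(post, 2, colSums(post), "/")
  list(post = t(post), loglik = sum(log(scal)))
}

#' Impute offspring genotypes from phased parents
#'
#' Per chromosome, each offspring's paternal and maternal haplotype origins
#' follow independent two-state Markov chains with Haldane switch
#' probabilities between adjacent markers; the joint 4-state chain is
#' decoded by the forward-backward algorithm. Typed markers emit the
#' observed dosage with genotyping-error rate `eps`; untyped markers are
#' filled with the posterior expected dosage implied by the decoded origins
#' and the parental haplotypes. Observed entries pass through unchanged.
#'
#' @param offspring_geno Dosage matrix for the offspring (NA = untyped),
#'   columns in map order (all high-density SNPs).
#' @param phased A `gs_parent_haplotypes` from [phase_parents()].
#' @param pedigree Pedigree tibble giving each offspring's sire and dam.
#' @param map Genetic map for the columns.
#' @param eps Genotyping-error emission probability.
#' @param max_conflict Offspring with a higher fraction of Mendelian-
#'   impossible typed observations are flagged and imputed with emissions
#'   down-weighted (error rate raised to 0.2).
#' @return Object of class `gs_imputed`: list with `dosage` (expected
#'   dosage in [0,2], observed entries passed through), `hard` (rounded
#'   calls), `origin_post` (max posterior origin probability per SNP),
#'   `typed` (logical), `flagged` (ids failing the Mendelian check).
#' @export
impute_offspring <- function(offspring_geno, phased, pedigree, map,
                             eps = 0.01, max_conflict = 0.05) {
  stopifnot(ncol(offspring_geno) == nrow(map))
  ped <- tibble::as_tibble(pedigree)
  ids <- rownames(offspring_geno)
  p <- nrow(map)
  chrom_split <- split(seq_len(p), map$chrom)
  d <- diff_within_chrom(map)
  r_f <- ifelse(is.na(d), 0.5, haldane_r(d))

  dosage <- matrix(NA_real_, length(ids), p, dimnames = dimnames(offspring_geno))
  origin <- matrix(NA_real_, length(ids), p, dimnames = dimnames(offspring_geno))
  flagged <- character(0)

  for (i in seq_along(ids)) {
    rec <- ped[ped$id == ids[i], ]
    if (nrow(rec) == 0 || is.na(rec$sire) || is.na(rec$dam))
      stop("offspring '", ids[i], "' has no recorded parents")
    hf <- phased[[rec$sire]]; hm <- phased[[rec$dam]]
    af <- .hap_probs(hf, p); am <- .hap_probs(hm, p)
    obs <- offspring_geno[i, ]
    # Mendelian-impossible observations given parental dosages
    gf <- if (!is.null(hf)) hf$g else rep(NA_real_, p)
    gm <- if (!is.null(hm)) hm$g else rep(NA_real_, p)
    typed <- !is.na(obs)
    imposs <- typed & !is.na(gf) & !is.na(gm) &
      ((obs == 0 & (gf == 2 | gm == 2)) |
         (obs == 2 & (gf == 0 | gm == 0)) |
         (obs == 1 & ((gf == 0 & gm == 0) | (gf == 2 & gm == 2))))
    eps_i <- eps
    if (sum(typed) > 0 && mean(imposs[typed]) > max_conflict) {
      flagged <- c(flagged, ids[i])
      eps_i <- max(eps, 0.2)
    }
    for (cols in chrom_split) {
      fb <- .fb_chromosome(obs[cols], af[cols, , drop = FALSE],
                           am[cols, , drop = FALSE],
                           r_f[cols], r_f[cols], eps_i)
      post <- fb$post  # markers x 4
      pf <- post[, 1] + post[, 2]   # P(father hap 1)
      pm <- post[, 1] + post[, 3]   # P(mother hap 1)
      ef <- pf * af[cols, 1] + (1 - pf) * af[cols, 2]
      em <- pm * am[cols, 1] + (1 - pm) * am[cols, 2]
      dosage[i, cols] <- ef + em
      origin[i, cols] <- apply(post, 1, max)
    }
    dosage[i, typed] <- obs[typed]  # exact pass-through
  }
  structure(list(dosage = dosage, hard = round(dosage),
                 origin_post = origin, typed = !is.na(offspring_geno),
                 flagged = flagged),
            class = "gs_imputed")
}

#' @export
print.gs_imputed <- function(x, ...) {
  cat(sprintf("<gs_imputed> %d individuals x %d SNPs; %.1f%% typed; %d flagged\n",
              nrow(x$dosage), ncol(x$dosage), 100 * mean(x$typed),
              length(x$flagged)))
  invisible(x)
}

#' Fill sporadically missing high-density genotypes
#'
#' Individuals whose parents are both genotyped in the matrix are completed
#' through the family haplotype HMM ([phase_parents()] +
#' [impute_offspring()]), which exploits linkage to neighbouring typed
#' markers. For individuals without genotyped parents (founders, parents
#' themselves) each missing entry is restricted to the dosages compatible
#' with any available parental genotype and set to the most frequent
#' compatible dosage among full sibs; remaining ambiguity falls back on the
#' expected dosage under the observed family (or population) allele
#' frequency.
#'
#' @param genotypes High-density dosage matrix (NA = missing).
#' @param pedigree Pedigree tibble.
#' @param map Genetic map for the columns (required for the HMM route; when
#'   `NULL` only the family-vote rule is used).
#' @param eps Genotyping-error rate for the HMM route.
#' @return Numeric matrix with all entries filled (fractional where only an
#'   expectation is available).
#' @export
fill_sporadic_missing <- function(genotypes, pedigree, map = NULL,
                                  eps = 0.01) {
  if (!anyNA(genotypes)) return(genotypes)
  ped <- tibble::as_tibble(pedigree)
  out <- genotypes * 1.0
  ids_all <- rownames(out)

  if (!is.null(map)) {
    sire_v <- stats::setNames(ped$sire, ped$id)
    dam_v <- stats::setNames(ped$dam, ped$id)
    need <- ids_all[rowSums(is.na(out)) > 0]
    hmm_ids <- need[!is.na(sire_v[need]) & !is.na(dam_v[need]) &
                      sire_v[need] %in% ids_all & dam_v[need] %in% ids_all]
    if (length(hmm_ids) > 0) {
      fams <- split(hmm_ids, paste(sire_v[hmm_ids], dam_v[hmm_ids]))
      for (fam in fams) {
        pr <- c(sire_v[fam[1]], dam_v[fam[1]])
        ph <- phase_parents(out, ped, map, parents = unname(pr))
        imp <- impute_offspring(out[fam, , drop = FALSE], ph, ped, map,
                                eps = eps)
        out[fam, ] <- imp$dosage
      }
    }
    if (!anyNA(out)) return(out)
  }
  ids <- rownames(out)
  fam_key <- stats::setNames(paste(ped$sire, ped$dam), ped$id)
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  allowed_set <- function(gf, gm) {
    tf <- if (is.na(gf)) 0:1 else if (gf == 0) 0 else if (gf == 2) 1 else 0:1
    tm <- if (is.na(gm)) 0:1 else if (gm == 0) 0 else if (gm == 2) 1 else 0:1
    sort(unique(outer(tf, tm, `+`)))
  }
  pop_freq <- colMeans(out, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(out)) > 0)) {
    col <- out[, j]
    for (i in which(is.na(col))) {
      id <- ids[i]
      gf <- if (!is.na(sire[id]) && sire[id] %in% ids) col[sire[id]] else NA
      gm <- if (!is.na(dam[id]) && dam[id] %in% ids) col[dam[id]] else NA
      ok <- allowed_set(gf, gm)
      if (length(ok) == 1) { out[i, j] <- ok; next }
      sibs <- ids[which(fam_key[ids] == fam_key[id] & ids != id)]
      sib_g <- col[sibs]
      sib_g <- sib_g[!is.na(sib_g) & sib_g %in% ok]
      if (length(sib_g) > 0) {
        tab <- table(sib_g)
        top <- as.numeric(names(tab)[tab == max(tab)])
        if (length(top) == 1) { out[i, j] <- top; next }
      }
      fam_obs <- col[c(sibs, sire[id], dam[id])]
      fam_obs <- fam_obs[!is.na(fam_obs)]
      f <- if (length(fam_obs) > 0) mean(fam_obs) / 2 else pop_freq[j]
      if (is.na(f)) f <- 0.5
      e <- 2 * f
      out[i, j] <- min(max(e, min(ok)), max(ok))
    }
  }
  out
}
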