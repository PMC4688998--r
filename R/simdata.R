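#' Haldane map function
#'
#' Recombination fraction between two loci separated by `d_cM` centiMorgans
#' under Haldane's model (independent crossovers, no interference):
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cM Numeric vector of map distances in centiMorgans.
#' @return Numeric vector of recombination fractions in [0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  stopifnot(is.numeric(d_cM), all(d_cM >= 0, na.rm = TRUE))
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Simulation configuration for a pedigreed multi-family breeding population
#'
#' Bundles every parameter of the synthetic world: pedigree layout (training
#' and application full-sib families sharing parents), genome (chromosome
#' count, length and marker density), trait architecture (sparsity `pi_true`,
#' per-trait narrow-sense heritability), the ordinal scoring model
#' (threshold cut points on the liability scale), and the year/location
#' design with replicated reference genotypes.
#'
#' Defaults emulate the full-scale design the package targets: 20 training
#' full-sib families totalling ~980 individuals derived from a pool of
#' related parents, 5 application families of sizes 662/172/269/109/178
#' (total 1390) that share parents with the training set, a 17-chromosome
#' genome of ~1350 cM carrying ~7820 SNPs, ten ordinal 1-5 traits with
#' heritabilities spanning 0.03-0.67, and 29 clonally replicated reference
#' genotypes scored in every location and year.
#'
#' @param n_founders Number of pedigree founders (unknown parents).
#' @param n_training_families,training_family_sizes Training full-sib
#'   families and their sizes.
#' @param n_application_families,application_family_sizes Application
#'   full-sib families and their sizes.
#' @param shared_parent_fraction Probability that an application-family
#'   parent is drawn from the training parent pool rather than being an
#'   unrelated external founder.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length Genome
#'   layout; `chromosome_length` in cM.
#' @param pi_true Proportion of SNPs that are causal, in (0, 1].
#' @param h2_target Per-trait narrow-sense heritability, recycled to
#'   `n_traits`; each value in [0, 1].
#' @param n_traits Number of traits.
#' @param trait_names Optional character vector of trait names.
#' @param year_effects,location_effects Named numeric vectors of additive
#'   offsets on the liability scale.
#' @param n_reference_genotypes Clonal reference genotypes replicated across
#'   all locations and years.
#' @param ordinal_thresholds Four strictly increasing liability cut points
#'   mapping liability to scores 1-5. The default places roughly quintile
#'   mass in each score; see [skewed_thresholds()] for defect-trait presets.
#' @param seed Integer seed from which all randomness flows.
#' @return A list of class `sim_config`.
#' @seealso [simulate_population()]
#' @export
sim_config <- function(n_founders = 24,
                       n_training_families = 20,
                       training_family_sizes = rep(49, n_training_families),
                       n_application_families = 5,
                       application_family_sizes = c(662, 172, 269, 109, 178),
                       shared_parent_fraction = 5 / 9,
                       n_chromosomes = 17,
                       markers_per_chromosome = 460,
                       chromosome_length = 80,
                       pi_true = 0.02,
                       h2_target = c(0.35, 0.25, 0.45, 0.40, 0.03,
                                     0.15, 0.67, 0.60, 0.30, 0.20),
                       n_traits = length(h2_target),
                       trait_names = NULL,
                       year_effects = c(y1 = 0, y2 = 0.2, y3 = -0.1),
                       location_effects = c(L1 = 0, L2 = 0.3, L3 = -0.2, L4 = 0.1),
                       n_reference_genotypes = 29,
                       ordinal_thresholds = stats::qnorm(c(0.2, 0.4, 0.6, 0.8)),
                       seed = 1L) {
  h2_target <- rep_len(h2_target, n_traits)
  if (is.null(trait_names)) {
    trait_names <- if (n_traits == 10) {
      c("attractiveness", "fruit_cropping", "fruit_size", "percent_russet",
        "fruit_cracking", "preharvest_dropping", "percent_over_colour",
        "over_colour", "ground_colour", "type_of_colour")
    } else {
      paste0("trait", seq_len(n_traits))
    }
  }
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_training_families = as.integer(n_training_families),
    training_family_sizes = as.integer(rep_len(training_family_sizes,
                                               n_training_families)),
    n_application_families = as.integer(n_application_families),
    application_family_sizes = as.integer(rep_len(application_family_sizes,
                                                  n_application_families)),
    shared_parent_fraction = shared_parent_fraction,
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    chromosome_length = chromosome_length,
    pi_true = pi_true,
    h2_target = h2_target,
    n_traits = as.integer(n_traits),
    trait_names = trait_names,
    year_effects = year_effects,
    location_effects = location_effects,
    n_reference_genotypes = as.integer(n_reference_genotypes),
    ordinal_thresholds = ordinal_thresholds,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_founders >= 2,
    all(cfg$training_family_sizes > 0),
    all(cfg$application_family_sizes > 0) || cfg$n_application_families == 0,
    cfg$pi_true > 0, cfg$pi_true <= 1,
    all(cfg$h2_target >= 0), all(cfg$h2_target <= 1),
    cfg$shared_parent_fraction >= 0, cfg$shared_parent_fraction <= 1,
    cfg$n_chromosomes >= 1, cfg$markers_per_chromosome >= 1,
    cfg$chromosome_length >= 0,
    length(cfg$ordinal_thresholds) == 4,
    !is.unsorted(cfg$ordinal_thresholds, strictly = TRUE),
    length(cfg$year_effects) >= 1, length(cfg$location_effects) >= 1
  )
  invisible(cfg)
}

#' Small-preset configuration for fast end-to-end runs
#'
#' 5 training families of 100, 2 application families of 100, 1000 SNPs on
#' 5 chromosomes of 100 cM, 3 traits. Completes the full pipeline on one CPU
#' in minutes; used throughout the tests and the acceptance script.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_small <- function(...) {
  defaults <- list(
    n_founders = 12,
    n_training_families = 5,
    training_family_sizes = rep(100, 5),
    n_application_families = 2,
    application_family_sizes = c(100, 100),
    n_chromosomes = 5,
    markers_per_chromosome = 200,
    chromosome_length = 100,
    h2_target = c(0.6, 0.3, 0.1),
    n_reference_genotypes = 8,
    seed = 1L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Skewed ordinal thresholds for defect traits
#'
#' Concentrates roughly 75% of the liability mass in score 1, emulating the
#' highly skewed score distributions of defect traits such as fruit cracking
#' and pre-harvest dropping, where most seedlings show no defect.
#'
#' @return Numeric vector of four increasing liability cut points.
#' @export
skewed_thresholds <- function() {
  stats::qnorm(c(0.75, 0.90, 0.97, 0.995))
}

#' Generate a multi-family pedigree
#'
#' Builds a pedigree of founders, intermediate ancestors, a shared parent
#' pool, training full-sib families, and application full-sib families whose
#' parents are re-drawn from the training parent pool with probability
#' `shared_parent_fraction` (otherwise a new unrelated external founder is
#' created). Clonal reference genotypes are appended as stand-alone founders
#' with no pedigree links.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; default uses `config$seed`.
#' @return A tibble with columns `id`, `sire`, `dam` (NA = unknown),
#'   `family` (NA outside full-sib families) and `role` (one of founder,
#'   intermediate, parent, external, training, application, reference),
#'   topologically ordered (parents precede offspring).
#' @export
generate_pedigree <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  founders <- sprintf("F%02d", seq_len(config$n_founders))
  ped <- tibble::tibble(id = founders, sire = NA_character_,
                        dam = NA_character_, family = NA_character_,
                        role = "founder")

  # intermediate ancestors: children of random founder pairs, so that the
  # parent pool is inter-related via shared ancestry (skipped for very
  # small founder sets, where the founders themselves are the parents)
  n_inter <- if (config$n_founders >= 6) config$n_founders %/% 2L else 0L
  inter <- character(n_inter)
  if (n_inter > 0) for (k in seq_len(n_inter)) {
    pr <- sample(founders, 2L)
    inter[k] <- sprintf("I%02d", k)
    ped <- dplyr::bind_rows(ped, tibble::tibble(
      id = inter[k], sire = pr[1], dam = pr[2],
      family = NA_character_, role = "intermediate"))
  }
  candidates <- c(founders, inter)
  n_parent_pool <- min(length(candidates), max(4L, min(24L, config$n_founders)))
  if (n_parent_pool < 2)
    stop("requested parents exceed available individuals")
  pool <- sample(candidates, n_parent_pool)

  new_rows <- list()
  fam_parents <- list()
  for (f in seq_len(config$n_training_families)) {
    pr <- sample(pool, 2L)
    fam <- sprintf("T%02d", f)
    fam_parents[[fam]] <- pr
    sz <- config$training_family_sizes[f]
    new_rows[[fam]] <- tibble::tibble(
      id = sprintf("%s_%03d", fam, seq_len(sz)),
      sire = pr[1], dam = pr[2], family = fam, role = "training")
  }
  training_parents <- unique(unlist(fam_parents))

  n_ext <- 0L
  for (f in seq_len(config$n_application_families)) {
    fam <- sprintf("A%d", f)
    pr <- character(2)
    for (j in 1:2) {
      if (stats::runif(1) < config$shared_parent_fraction) {
        pr[j] <- sample(training_parents, 1L)
      } else {
        n_ext <- n_ext + 1L
        pr[j] <- sprintf("X%02d", n_ext)
        ped <- dplyr::bind_rows(ped, tibble::tibble(
          id = pr[j], sire = NA_character_, dam = NA_character_,
          family = NA_character_, role = "external"))
      }
    }
    if (pr[1] == pr[2]) pr[2] <- sample(setdiff(training_parents, pr[1]), 1L)
    sz <- config$application_family_sizes[f]
    new_rows[[fam]] <- tibble::tibble(
      id = sprintf("%s_%03d", fam, seq_len(sz)),
      sire = pr[1], dam = pr[2], family = fam, role = "application")
  }

  refs <- if (config$n_reference_genotypes > 0) {
    tibble::tibble(id = sprintf("R%02d", seq_len(config$n_reference_genotypes)),
                   sire = NA_character_, dam = NA_character_,
                   family = NA_character_, role = "reference")
  } else NULL

  out <- dplyr::bind_rows(c(list(ped), new_rows, list(refs)))
  if (anyDuplicated(out$id)) stop("duplicated pedigree ids generated")
  sort_and_validate(out)
}

#' Build an evenly spaced genetic map
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `snp`, `chrom`, `pos_cM`; markers evenly
#'   spaced from 0 to `chromosome_length` on each chromosome.
#' @export
make_genetic_map <- function(config) {
  m <- config$markers_per_chromosome
  purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
    pos <- if (m == 1) 0 else seq(0, config$chromosome_length, length.out = m)
    tibble::tibble(
      snp = sprintf("S%02d_%04d", ch, seq_len(m)),
      chrom = ch, pos_cM = pos)
  })
}

#' Drop genes through a pedigree with recombination
#'
#' Founder haplotypes are drawn independently per SNP from `founder_freqs`
#' (linkage equilibrium among founders; LD in the population arises from
#' pedigree structure alone). Each non-founder inherits one recombinant
#' gamete per parent; between adjacent markers a switch of parental
#' haplotype occurs with the Haldane probability [haldane_r()] of the map
#' distance, with a fresh random start on each chromosome and no
#' interference.
#'
#' @param pedigree Topologically ordered pedigree tibble (see
#'   [generate_pedigree()]); all parent ids must be recorded.
#' @param map Genetic map tibble (`snp`, `chrom`, `pos_cM`), positions
#'   non-decreasing within chromosome.
#' @param founder_freqs Per-SNP allele-1 frequency in (0, 1); recycled.
#' @param seed Optional integer seed.
#' @return Object of class `gs_haplotypes`: list with integer matrices `h1`,
#'   `h2` (individuals x SNPs, rownames = ids, colnames = SNP ids) and the
#'   `map`. Use [dosages()] for the 0/1/2 dosage matrix.
#' @export
gene_drop <- function(pedigree, map, founder_freqs = 0.5, seed = NULL) {
  if (nrow(map) == 0) stop("empty genetic map")
  if (any(diff_within_chrom(map) < 0, na.rm = TRUE))
    stop("map positions must be non-decreasing within chromosome")
  founder_freqs <- rep_len(founder_freqs, nrow(map))
  if (any(founder_freqs <= 0 | founder_freqs >= 1))
    stop("founder frequencies must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)

  p <- nrow(map)
  n <- nrow(pedigree)
  ids <- pedigree$id
  idx <- stats::setNames(seq_len(n), ids)
  known <- function(x) !is.na(x)
  bad <- c(pedigree$sire, pedigree$dam)
  bad <- bad[!is.na(bad)]
  if (!all(bad %in% ids)) stop("unknown parent id: ", setdiff(bad, ids)[1])

  # per-gap switch probability; chromosome starts get 0.5 (independent start)
  d <- diff_within_chrom(map)
  r_gap <- ifelse(is.na(d), 0.5, haldane_r(d))

  h1 <- matrix(0L, n, p, dimnames = list(ids, map$snp))
  h2 <- h1
  gamete <- function(pi_) {
    switches <- stats::rbinom(p, 1L, r_gap)
    use2 <- cumsum(switches) %% 2L == 1L
    out <- h1[pi_, ]
    out[use2] <- h2[pi_, use2]
    out
  }
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; dm <- pedigree$dam[i]
    h1[i, ] <- if (known(s)) gamete(idx[[s]]) else
      stats::rbinom(p, 1L, founder_freqs)
    h2[i, ] <- if (known(dm)) gamete(idx[[dm]]) else
      stats::rbinom(p, 1L, founder_freqs)
  }
  structure(list(h1 = h1, h2 = h2, map = map), class = "gs_haplotypes")
}

# lag differences of pos_cM, NA at the first marker of each chromosome
diff_within_chrom <- function(map) {
  d <- c(NA_real_, diff(map$pos_cM))
  d[c(TRUE, diff(map$chrom) != 0)] <- NA_real_
  d
}

#' Dosage matrix from phased haplotypes
#'
#' @param haplos A `gs_haplotypes` object.
#' @return Integer matrix of allele dosages in 0/1/2 (individuals x SNPs).
#' @export
dosages <- function(haplos) {
  stopifnot(inherits(haplos, "gs_haplotypes"))
  haplos$h1 + haplos$h2
}

#' Assign a sparse additive trait architecture
#'
#' For each trait, `round(pi_true * p)` causal SNPs are sampled uniformly
#' without replacement; their effects are drawn from a zero-mean normal and
#' rescaled so the realized additive variance (variance of the true breeding
#' values over all individuals) equals `h2_target`, placing phenotypes on a
#' unit-variance liability scale. Non-causal effects are exactly zero.
#'
#' @param genotypes Dosage matrix (individuals x SNPs).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return Object of class `gs_architecture`: list with `effects` (SNPs x
#'   traits, zero outside causal sets), `causal` (list of causal column
#'   indices per trait), `tbv` (individuals x traits true breeding values),
#'   `pi_true` and `h2_target`.
#' @export
assign_architecture <- function(genotypes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(genotypes)
  n_causal <- round(config$pi_true * p)
  if (n_causal > p) stop("fewer SNPs than requested causal count")
  n_causal <- max(1L, n_causal)
  centered <- scale(genotypes, center = TRUE, scale = FALSE)
  effects <- matrix(0, p, config$n_traits,
                    dimnames = list(colnames(genotypes), config$trait_names))
  tbv <- matrix(0, nrow(genotypes), config$n_traits,
                dimnames = list(rownames(genotypes), config$trait_names))
  causal <- vector("list", config$n_traits)
  for (t in seq_len(config$n_traits)) {
    h2 <- config$h2_target[t]
    cs <- sort(sample.int(p, n_causal))
    causal[[t]] <- cs
    if (h2 > 0) {
      b <- stats::rnorm(n_causal)
      g <- centered[, cs, drop = FALSE] %*% b
      s <- stats::sd(g)
      if (s > 0) b <- b * sqrt(h2) / s
      effects[cs, t] <- b
      tbv[, t] <- centered[, cs, drop = FALSE] %*% b
    }
  }
  structure(list(effects = effects, causal = causal, tbv = tbv,
                 pi_true = config$pi_true, h2_target = config$h2_target),
            class = "gs_architecture")
}

#' Simulate ordinal phenotype records
#'
#' Liability = true breeding value + year effect + location effect + normal
#' residual with variance `1 - h2` (so that var(TBV)/(var(TBV)+var(resid))
#' hits the target heritability on the unit-variance liability scale of
#' [assign_architecture()]). The ordinal score is 1 + the number of
#' thresholds below the liability.
#'
#' Training individuals are scored at one location (assigned per family) in
#' every year of `config$year_effects`; application individuals at one
#' location in a single year; reference genotypes receive one record per
#' trait in every location x year combination.
#'
#' @param architecture A `gs_architecture`.
#' @param pedigree Pedigree tibble with `role`/`family` columns as produced
#'   by [generate_pedigree()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return Tibble with columns `id`, `trait`, `year`, `location`, `score`.
#' @export
simulate_phenotypes <- function(architecture, pedigree, config, seed = NULL) {
  if (is.null(config$ordinal_thresholds)) stop("missing threshold vector")
  if (!is.null(seed)) set.seed(seed)
  years <- names(config$year_effects)
  locs <- names(config$location_effects)

  fams <- unique(stats::na.omit(pedigree$family))
  fam_loc <- stats::setNames(rep_len(locs, length(fams)), fams)
  app_year <- years[length(years)]

  design <- dplyr::bind_rows(
    # training: one location, all years
    pedigree |>
      dplyr::filter(.data$role == "training") |>
      dplyr::mutate(location = unname(fam_loc[.data$family])) |>
      tidyr::crossing(year = years) |>
      dplyr::select("id", "year", "location"),
    # application: one location, final year only
    pedigree |>
      dplyr::filter(.data$role == "application") |>
      dplyr::mutate(location = unname(fam_loc[.data$family]),
                    year = app_year) |>
      dplyr::select("id", "year", "location"),
    # reference clones: every location x year cell
    pedigree |>
      dplyr::filter(.data$role == "reference") |>
      dplyr::select("id") |>
      tidyr::crossing(year = years, location = locs)
  )

  thr <- config$ordinal_thresholds
  out <- purrr::map_dfr(seq_len(config$n_traits), function(t) {
    h2 <- config$h2_target[t]
    tbv <- architecture$tbv[design$id, t]
    liab <- tbv + config$year_effects[design$year] +
      config$location_effects[design$location] +
      stats::rnorm(nrow(design), sd = sqrt(max(1 - h2, 1e-12)))
    score <- 1L + rowSums(outer(liab, thr, `>`))
    tibble::tibble(id = design$id, trait = config$trait_names[t],
                   year = design$year, location = design$location,
                   score = as.integer(score))
  })
  out
}

#' Select an evenly spaced low-density SNP panel
#'
#' @param map Genetic map tibble.
#' @param n_snps Total panel size; allocated to chromosomes proportionally
#'   to marker count, minimum one per chromosome, endpoints included.
#' @return Character vector of SNP ids.
#' @export
choose_ld_panel <- function(map, n_snps) {
  stopifnot(n_snps >= dplyr::n_distinct(map$chrom))
  counts <- table(map$chrom)
  alloc <- pmax(1L, round(n_snps * as.numeric(counts) / nrow(map)))
  unlist(purrr::map2(split(map$snp, map$chrom), alloc, function(snps, k) {
    k <- min(k, length(snps))
    snps[unique(round(seq(1, length(snps), length.out = k)))]
  }), use.names = FALSE)
}

#' Mask genotypes to a low-density panel
#'
#' Sets every SNP outside `target_snps` to missing, emulating application
#' individuals genotyped with a small dedicated array. The mean within-
#' chromosome gap between retained markers is attached as attribute
#' `mean_gap_cM` (computed with [panel_mean_gap()]).
#'
#' @param genotypes Dosage matrix (individuals x SNPs).
#' @param map Genetic map covering the columns of `genotypes`.
#' @param target_snps Character vector of SNP ids to keep; must be a subset
#'   of the map.
#' @return Numeric matrix like `genotypes` with non-target entries `NA` and
#'   attribute `mean_gap_cM`.
#' @export
mask_to_low_density <- function(genotypes, map, target_snps) {
  if (length(target_snps) == 0) stop("empty target SNP set")
  if (!all(target_snps %in% map$snp)) stop("target set must be a subset of the map")
  out <- genotypes * 1.0
  out[, !(colnames(out) %in% target_snps)] <- NA_real_
  attr(out, "mean_gap_cM") <- panel_mean_gap(map, target_snps)
  out
}

#' Mean within-chromosome gap of a marker panel
#'
#' @param map Genetic map tibble.
#' @param target_snps SNP ids of the panel.
#' @return Mean distance in cM between adjacent panel markers on the same
#'   chromosome (NA if there are no within-chromosome pairs).
#' @export
panel_mean_gap <- function(map, target_snps) {
  sub <- map[map$snp %in% target_snps, ]
  gaps <- unlist(purrr::map(split(sub$pos_cM, sub$chrom), diff),
                 use.names = FALSE)
  if (length(gaps) == 0) return(NA_real_)
  mean(gaps)
}

#' Simulate a complete pedigreed population
#'
#' One-stop generator: pedigree, map, gene-dropped phased genotypes, sparse
#' trait architecture, ordinal phenotype records, and an evenly spaced
#' low-density panel. All randomness flows from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param n_ld_snps Size of the low-density panel (default one marker per
#'   ~3.7 cM of genome, mirroring a small dedicated genotyping array).
#' @return Object of class `gs_population`: list with `config`, `pedigree`,
#'   `map`, `haplotypes`, `genotypes` (dosage matrix), `architecture`,
#'   `phenotypes`, `ld_panel`, and id vectors `training_ids`,
#'   `application_ids`, `reference_ids`.
#' @export
simulate_population <- function(config = sim_config(),
                                n_ld_snps = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  ped <- generate_pedigree(config, seed = NULL)
  map <- make_genetic_map(config)
  freqs <- stats::runif(nrow(map), 0.1, 0.9)
  haplos <- gene_drop(ped, map, freqs, seed = NULL)
  geno <- dosages(haplos)
  arch <- assign_architecture(geno, config, seed = NULL)
  pheno <- simulate_phenotypes(arch, ped, config, seed = NULL)
  if (is.null(n_ld_snps)) {
    genome_cM <- config$n_chromosomes * config$chromosome_length
    n_ld_snps <- max(config$n_chromosomes * 2L, round(genome_cM / 3.7))
  }
  panel <- choose_ld_panel(map, n_ld_snps)
  structure(list(
    config = config, pedigree = ped, map = map, haplotypes = haplos,
    genotypes = geno, architecture = arch, phenotypes = pheno,
    ld_panel = panel,
    training_ids = ped$id[ped$role == "training"],
    application_ids = ped$id[ped$role == "application"],
    reference_ids = ped$id[ped$role == "reference"]
  ), class = "gs_population")
}

#' @export
print.gs_population <- function(x, ...) {
  cat("<gs_population>\n")
  cat(sprintf("  %d individuals (%d training, %d application, %d reference)\n",
              nrow(x$pedigree), length(x$training_ids),
              length(x$application_ids), length(x$reference_ids)))
  cat(sprintf("  %d SNPs on %d chromosomes; LD panel of %d SNPs\n",
              nrow(x$map), x$config$n_chromosomes, length(x$ld_panel)))
  cat(sprintf("  %d traits, pi_true = %.3f\n",
              x$config$n_traits, x$config$pi_true))
  invisible(x)
}
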