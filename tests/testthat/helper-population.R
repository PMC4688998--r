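# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small multi-family population used across modules
small_pop <- function() memo("small_pop", simulate_population(sim_config_small()))

# training-only population for BayesC-pi parameter recovery:
# n = 800 phenotyped individuals, p = 1000 SNPs, pi_true = 0.02, h2 = 0.6
recovery_pop <- function() memo("recovery_pop", {
  cfg <- sim_config(
    n_founders = 12, n_training_families = 8,
    training_family_sizes = rep(100, 8),
    n_application_families = 0, application_family_sizes = integer(0),
    n_chromosomes = 5, markers_per_chromosome = 200,
    chromosome_length = 100, pi_true = 0.02,
    h2_target = 0.6, n_traits = 1, n_reference_genotypes = 0,
    seed = 42L)
  simulate_population(cfg)
})

# continuous phenotype on the liability scale: TBV + residual at target h2
liability_phenotype <- function(pop, trait = 1, ids = pop$training_ids,
                                seed = 7L) {
  set.seed(seed)
  tbv <- pop$architecture$tbv[ids, trait]
  h2 <- pop$architecture$h2_target[trait]
  tbv + stats::rnorm(length(ids), sd = sqrt(max(1 - h2, 1e-12)))
}

# hand-built pedigree tibble
ped_tbl <- function(id, sire = NA, dam = NA) {
  tibble::tibble(id = as.character(id),
                 sire = as.character(sire), dam = as.character(dam))
}

# printed per-family per-trait accuracy grid used as input for the
# table-arithmetic checks (families AF1..AF5; NA = trait not scored)
published_accuracy_grid <- function() {
  path <- system.file("extdata", "published_accuracy_grid.csv",
                      package = "orchardgs")
  readr::read_csv(path, show_col_types = FALSE)
}

# family fixture with HD parents, HD sibs (for phasing) and LD offspring
impute_fixture <- function(n_chrom = 5, m = 300, n_hd = 10, n_ld = 30,
                           gap_cM = 3.7, seed = 17L) {
  memo(sprintf("impfix_%d_%d_%d_%d_%s_%d", n_chrom, m, n_hd, n_ld,
               gap_cM, seed), {
    cfg <- sim_config(n_founders = 8, n_training_families = 1,
                      training_family_sizes = n_hd + n_ld,
                      n_application_families = 0,
                      application_family_sizes = integer(0),
                      n_chromosomes = n_chrom, markers_per_chromosome = m,
                      chromosome_length = 100,
                      n_reference_genotypes = 0, seed = seed)
    pop <- simulate_population(cfg)
    kids <- pop$training_ids
    list(pop = pop, hd_kids = kids[seq_len(n_hd)],
         ld_kids = kids[seq(n_hd + 1, n_hd + n_ld)],
         panel = choose_ld_panel(pop$map,
                                 round(n_chrom * 100 / gap_cM)))
  })
}

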