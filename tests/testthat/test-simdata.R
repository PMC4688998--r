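test_that("pedigree generation covers minimal and shared-parent designs", {
  cfg <- sim_config(n_founders = 2, n_training_families = 1,
                    training_family_sizes = 2,
                    n_application_families = 0,
                    application_family_sizes = integer(0),
                    n_reference_genotypes = 0, seed = 3L)
  ped <- generate_pedigree(cfg)
  expect_equal(nrow(ped), 4)
  expect_equal(sum(is.na(ped$sire) & is.na(ped$dam)), 2)
  kids <- ped[ped$role == "training", ]
  expect_true(all(kids$sire %in% ped$id), all(kids$dam %in% ped$id))

  # no sharing when the fraction is zero
  cfg0 <- sim_config_small(shared_parent_fraction = 0, seed = 5L)
  ped0 <- generate_pedigree(cfg0)
  tr_par <- unique(unlist(ped0[ped0$role == "training", c("sire", "dam")]))
  ap_par <- unique(unlist(ped0[ped0$role == "application", c("sire", "dam")]))
  expect_length(intersect(ap_par, tr_par), 0)

  # default design shares at least one parent
  ped1 <- generate_pedigree(sim_config(training_family_sizes = rep(2, 20),
                                       application_family_sizes = rep(2, 5)))
  tr_par <- unique(unlist(ped1[ped1$role == "training", c("sire", "dam")]))
  ap_par <- unique(unlist(ped1[ped1$role == "application", c("sire", "dam")]))
  expect_gt(length(intersect(ap_par, tr_par)), 0)
})

test_that("gene drop respects map length zero and Mendelian inheritance", {
  map <- tibble::tibble(snp = paste0("s", 1:40), chrom = rep(1:2, each = 20),
                        pos_cM = rep(0, 40))
  ped <- ped_tbl(c("A", "B", paste0("K", 1:6)),
                 sire = c(NA, NA, rep("A", 6)), dam = c(NA, NA, rep("B", 6)))
  h <- gene_drop(ped, map, founder_freqs = 0.5, seed = 11)
  for (k in paste0("K", 1:6)) {
    for (cols in split(seq_len(40), map$chrom)) {
      pat <- h$h1[k, cols]
      expect_true(identical(pat, h$h1["A", cols]) ||
                    identical(pat, h$h2["A", cols]))
    }
  }

  # offspring dosages always compatible with parental dosages
  pop <- small_pop()
  g <- pop$genotypes
  ped <- pop$pedigree
  kids <- ped[!is.na(ped$sire) & !is.na(ped$dam), ]
  lo <- floor(g[kids$sire, ] / 2) + floor(g[kids$dam, ] / 2)
  hi <- ceiling(g[kids$sire, ] / 2) + ceiling(g[kids$dam, ] / 2)
  gk <- g[kids$id, ]
  expect_true(all(gk >= lo & gk <= hi))
})

test_that("recombinant gamete fraction matches the Haldane closed form", {
  # founder heterozygous at both markers; 10000 paternal meioses
  map <- tibble::tibble(snp = c("m1", "m2"), chrom = 1L, pos_cM = c(0, 10))
  n_off <- 10000
  ped <- ped_tbl(c("P", paste0("o", seq_len(n_off))),
                 sire = c(NA, rep("P", n_off)), dam = NA)
  found <- FALSE
  for (s in 1:50) {
    h <- gene_drop(ped, map, founder_freqs = 0.5, seed = s)
    if (h$h1["P", 1] != h$h2["P", 1] && h$h1["P", 2] != h$h2["P", 2]) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
  gam <- h$h1[paste0("o", seq_len(n_off)), ]
  origin1 <- gam[, 1] == h$h1["P", 1]
  origin2 <- gam[, 2] == h$h1["P", 2]
  rec <- mean(origin1 != origin2)
  expect_equal(rec, haldane_r(10), tolerance = 0.12)
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2)
})

test_that("founder allele frequencies are recovered at large n", {
  map <- tibble::tibble(snp = paste0("s", 1:5), chrom = 1L,
                        pos_cM = seq(0, 40, 10))
  freqs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  ped <- ped_tbl(paste0("F", 1:10000))
  h <- gene_drop(ped, map, founder_freqs = freqs, seed = 2)
  realized <- colMeans(dosages(h)) / 2
  expect_true(all(abs(realized - freqs) < 4 * sqrt(freqs * (1 - freqs) / 20000)))
})

test_that("architecture sampling hits pi, h2 and the degenerate limits", {
  pop <- small_pop()
  g <- pop$genotypes
  cfg_all <- sim_config_small(pi_true = 1, n_traits = 1, h2_target = 0.5)
  arch <- assign_architecture(g, cfg_all, seed = 1)
  expect_length(arch$causal[[1]], ncol(g))

  cfg0 <- sim_config_small(n_traits = 1, h2_target = 0)
  arch0 <- assign_architecture(g, cfg0, seed = 1)
  expect_true(all(arch0$effects == 0))
  expect_true(all(arch0$tbv == 0))

  expect_length(pop$architecture$causal[[1]],
                round(pop$config$pi_true * ncol(g)))
  # realized additive variance equals the target by construction
  expect_equal(unname(apply(pop$architecture$tbv, 2,
                            function(x) stats::var(x) * (length(x) - 1) /
                              length(x))),
               pop$config$h2_target, tolerance = 0.02)
})

test_that("ordinal phenotypes respond to thresholds and env effects", {
  pop <- small_pop()
  cfg <- pop$config

  wide <- sim_config_small(ordinal_thresholds = c(100, 101, 102, 103))
  ph <- simulate_phenotypes(pop$architecture, pop$pedigree, wide, seed = 1)
  expect_true(all(ph$score == 1))

  # location offset propagates to mean scores
  cfg_hi <- sim_config_small(location_effects = c(L1 = 0, L2 = 2))
  pop_hi <- simulate_population(cfg_hi)
  m <- pop_hi$phenotypes |>
    dplyr::filter(id %in% pop_hi$reference_ids) |>
    dplyr::group_by(location) |>
    dplyr::summarise(mean_score = mean(score))
  expect_gt(m$mean_score[m$location == "L2"],
            m$mean_score[m$location == "L1"] + 0.5)

  # reference genotypes cover every location x year cell
  ref <- pop$phenotypes |>
    dplyr::filter(id %in% pop$reference_ids, trait == cfg$trait_names[1])
  expect_equal(nrow(dplyr::distinct(ref, year, location)),
               length(cfg$year_effects) * length(cfg$location_effects))
})

test_that("low-density masking and the gap reporter behave", {
  pop <- small_pop()
  full <- mask_to_low_density(pop$genotypes, pop$map, pop$map$snp)
  expect_true(!anyNA(full))
  attr(full, "mean_gap_cM") <- NULL
  expect_equal(unname(full), unname(pop$genotypes * 1.0))

  one_per_chrom <- pop$map |>
    dplyr::group_by(chrom) |>
    dplyr::slice(1) |>
    dplyr::pull(snp)
  m <- mask_to_low_density(pop$genotypes, pop$map, one_per_chrom)
  expect_true(all(is.na(m[, !(colnames(m) %in% one_per_chrom)])))
  expect_true(!anyNA(m[, one_per_chrom]))
  expect_error(mask_to_low_density(pop$genotypes, pop$map, character(0)),
               "empty")

  # 17-chromosome, 1350-cM genome: mean gap of an endpoint-spanning panel
  cfg <- sim_config(n_chromosomes = 17, markers_per_chromosome = 80,
                    chromosome_length = 1350 / 17)
  map <- make_genetic_map(cfg)
  panel <- choose_ld_panel(map, 364)
  expect_equal(panel_mean_gap(map, panel),
               17 * (1350 / 17) / (length(panel) - 17), tolerance = 1e-9)
})

test_that("seeded simulation is bit-reproducible", {
  a <- simulate_population(sim_config_small(seed = 9L,
                                            training_family_sizes = rep(20, 5),
                                            application_family_sizes = c(20, 20)))
  b <- simulate_population(sim_config_small(seed = 9L,
                                            training_family_sizes = rep(20, 5),
                                            application_family_sizes = c(20, 20)))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$architecture$effects, b$architecture$effects)
})
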