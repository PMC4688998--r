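#' Configuration for an end-to-end pipeline run
#'
#' @param sim A [sim_config()] describing the population (default: the
#'   small preset).
#' @param stages Stages to execute, in order, among `"simulate"`,
#'   `"adjust"`, `"impute"`, `"train"`, `"predict"`, `"evaluate"`. Each
#'   enabled stage requires its predecessors' outputs (supplied via
#'   `inputs` when an earlier stage is disabled).
#' @param chain Chain settings for [fit_bayescpi()].
#' @param directions Named character vector trait -> "high"/"low" giving
#'   the favourable direction; defect traits (russet, cracking, dropping)
#'   default to "low".
#' @param symmetric_traits Traits entering the four-trait mean of
#'   [aggregate_report()].
#' @param k_selected Tail size for [selection_differential()]; capped at
#'   half the family size at run time.
#' @param eps Genotyping-error rate for imputation.
#' @param out_dir Optional directory to write stage outputs to.
#' @param inputs Optional named list of precomputed stage inputs (e.g. a
#'   `population` when `"simulate"` is disabled).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config_small(),
                       stages = c("simulate", "adjust", "impute", "train",
                                  "predict", "evaluate"),
                       chain = list(iterations = 5000L, burn_in = 1000L,
                                    thin = 5L),
                       directions = NULL,
                       symmetric_traits = c("attractiveness",
                                            "fruit_cropping", "fruit_size",
                                            "percent_russet"),
                       k_selected = 50L,
                       eps = 0.01,
                       out_dir = NULL,
                       inputs = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(directions)) {
    defect <- c("percent_russet", "fruit_cracking", "preharvest_dropping")
    directions <- stats::setNames(
      ifelse(sim$trait_names %in% defect, "low", "high"), sim$trait_names)
  }
  structure(list(sim = sim, stages = stages, chain = chain,
                 directions = directions,
                 symmetric_traits = symmetric_traits,
                 k_selected = as.integer(k_selected), eps = eps,
                 out_dir = out_dir, inputs = inputs),
            class = "run_config")
}

.stage_hash <- function(x) digest::digest(x, algo = "md5")

#' Run the end-to-end genomic selection pipeline
#'
#' Executes the enabled stages in order -- simulate the population, adjust
#' phenotypes and fit training BLUPs, impute application genotypes from the
#' low-density panel, train a BayesC-pi model per trait, predict genomic
#' breeding values, and evaluate accuracy / relatedness / selection
#' differentials -- failing fast with the failing stage named. All
#' randomness flows from `config$sim$seed` via fixed per-stage offsets.
#'
#' @param config A [run_config()].
#' @return Object of class `gs_run`: list with the stage outputs
#'   (`population`, `a_matrix`, `env_effects`, `blups`, `varcomp`,
#'   `imputed`, `models`, `gbv`, `evaluation`) and a `manifest` tibble
#'   (stage, seed, wall-time, output hash).
#' @export
run_pipeline <- function(config = run_config()) {
  st <- list()
  manifest <- tibble::tibble(stage = character(), seed = integer(),
                             seconds = numeric(), hash = character())
  note <- function(stage, seed, t0, obj) {
    manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
      stage = stage, seed = as.integer(seed),
      seconds = as.numeric(Sys.time()) - t0, hash = .stage_hash(obj)))
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    note(stage, config$sim$seed, t0, res)
    res
  }
  base_seed <- config$sim$seed

  pop <- run_stage("simulate", function() simulate_population(config$sim))
  if (is.null(pop)) pop <- config$inputs$population
  if (is.null(pop)) stop("no population: enable 'simulate' or supply inputs$population")
  st$population <- pop

  adj <- run_stage("adjust", function() {
    env <- estimate_environment_effects(pop$phenotypes, pop$reference_ids)
    adjusted <- adjust_phenotypes(pop$phenotypes, env)
    am <- adjusted_means(adjusted)
    A <- build_a_matrix(pop$pedigree)
    tb <- fit_trait_blups(dplyr::filter(am, .data$id %in% pop$training_ids), A)
    list(env_effects = env, adjusted = adjusted, a_matrix = A,
         blups = tb$blups, varcomp = tb$varcomp)
  })
  if (!is.null(adj)) st <- c(st, adj)

  imp <- run_stage("impute", function() {
    app <- pop$application_ids
    hd_ids <- setdiff(rownames(pop$genotypes), app)
    ld <- mask_to_low_density(pop$genotypes[app, , drop = FALSE], pop$map,
                              pop$ld_panel)
    app_parents <- unique(unlist(
      pop$pedigree[pop$pedigree$id %in% app, c("sire", "dam")]))
    set.seed(base_seed + 11L)
    phased <- phase_parents(pop$genotypes[hd_ids, , drop = FALSE],
                            pop$pedigree, pop$map,
                            parents = stats::na.omit(app_parents))
    impute_offspring(ld, phased, pop$pedigree, pop$map, eps = config$eps)
  })
  if (!is.null(imp)) st$imputed <- imp

  trained <- run_stage("train", function() {
    geno <- .combined_dosages(pop, st$imputed)
    design <- design_matrix(geno, pop$training_ids)
    models <- purrr::map(split(st$blups, st$blups$trait), function(d) {
      y <- stats::setNames(d$blup, d$id)
      fit_bayescpi(design, y,
                   iterations = config$chain$iterations,
                   burn_in = config$chain$burn_in, thin = config$chain$thin,
                   seed = base_seed + 23L)
    })
    list(design = design, models = models)
  })
  if (!is.null(trained)) { st$design <- trained$design; st$models <- trained$models }

  gbv <- run_stage("predict", function() {
    geno <- .combined_dosages(pop, st$imputed)
    purrr::imap_dfr(st$models, function(m, trait)
      dplyr::mutate(predict_gbv(m, geno[pop$application_ids, , drop = FALSE]),
                    trait = trait, .after = "id"))
  })
  if (!is.null(gbv)) st$gbv <- gbv

  ev <- run_stage("evaluate", function() {
    evaluate_run(pop, st$gbv, st$varcomp, st$a_matrix,
                 design = st$design,
                 directions = config$directions,
                 symmetric_traits = config$symmetric_traits,
                 k_selected = config$k_selected)
  })
  if (!is.null(ev)) st$evaluation <- ev

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_population(pop, file.path(config$out_dir, "population"))
    if (!is.null(st$gbv))
      readr::write_csv(st$gbv, file.path(config$out_dir, "gbv.csv"))
    if (!is.null(st$evaluation))
      readr::write_csv(st$evaluation$accuracy,
                       file.path(config$out_dir, "accuracy.csv"))
  }
  st$manifest <- manifest
  structure(st, class = "gs_run")
}

# training rows keep their true high-density dosages; application rows use
# imputed expected dosages when imputation ran, truth otherwise
.combined_dosages <- function(pop, imputed) {
  geno <- pop$genotypes * 1.0
  if (!is.null(imputed))
    geno[rownames(imputed$dosage), ] <- imputed$dosage
  geno[c(pop$training_ids, pop$application_ids), , drop = FALSE]
}

#' Evaluate predictions against application phenotypes
#'
#' Computes per-family per-trait accuracy with Fisher-z intervals, realized
#' and directional selection differentials, aggregate tables, genomic and
#' pedigree relatedness summaries, relatedness-accuracy correlations, and
#' the no-intercept accuracy ~ sqrt(h2) slope.
#'
#' @param pop A `gs_population`.
#' @param gbv Tibble `id`, `trait`, `gbv`.
#' @param varcomp Tibble with `trait` and `h2` (from [fit_trait_blups()]).
#' @param A Additive relationship matrix (for pedigree relatedness);
#'   optional.
#' @param design Optional `gs_design` used to reuse the SNP exclusion list
#'   for the genomic relationship matrix.
#' @param directions Named trait -> "high"/"low" favourable directions.
#' @param symmetric_traits Traits for the four-trait mean.
#' @param k_selected Selection tail size (capped at floor(family size / 2)).
#' @return List of class `gs_evaluation` with `accuracy`, `report`,
#'   `selection`, `relatedness`, `relatedness_accuracy`, `h2_slope`, `grm`.
#' @export
evaluate_run <- function(pop, gbv, varcomp = NULL, A = NULL, design = NULL,
                         directions = NULL,
                         symmetric_traits = c("attractiveness",
                                              "fruit_cropping", "fruit_size",
                                              "percent_russet"),
                         k_selected = 50L) {
  app_ped <- dplyr::filter(pop$pedigree, .data$role == "application")
  pheno <- pop$phenotypes |>
    dplyr::filter(.data$id %in% app_ped$id) |>
    dplyr::inner_join(dplyr::select(app_ped, "id", "family"), by = "id")
  scored <- dplyr::inner_join(gbv, pheno, by = c("id", "trait"))
  if (is.null(directions))
    directions <- stats::setNames(rep("high", pop$config$n_traits),
                                  pop$config$trait_names)

  acc <- scored |>
    dplyr::group_by(.data$family, .data$trait) |>
    dplyr::group_modify(~accuracy(.x$gbv, .x$score)) |>
    dplyr::ungroup()
  report <- aggregate_report(dplyr::filter(acc, !is.na(.data$pearson_r)),
                             symmetric_traits = symmetric_traits)

  sel <- scored |>
    dplyr::group_by(.data$family, .data$trait) |>
    dplyr::group_modify(function(d, key) {
      k <- min(k_selected, floor(nrow(d) / 2))
      if (k < 2) return(tibble::tibble())
      selection_differential(d$gbv, d$score, k = k,
                             direction = directions[[key$trait]])
    }) |>
    dplyr::ungroup()

  std <- standardize_dosages(.grm_input(pop, design), pop$training_ids)
  G <- compute_g(std$W)
  fams <- split(app_ped$id, app_ped$family)
  rel <- family_relatedness_summary(G, fams, pop$training_ids)
  if (!is.null(A)) {
    pedrel <- purrr::imap_dfr(fams, function(ids, fam) tibble::tibble(
      family = fam, measure = "pedigree",
      mean = pedigree_family_relatedness(A, ids, pop$training_ids),
      sd = NA_real_, n = length(ids)))
    rel <- dplyr::bind_rows(rel, pedrel)
  }

  relacc <- purrr::map_dfr(unique(acc$trait), function(tr) {
    ok <- dplyr::filter(acc, .data$trait == tr, !is.na(.data$pearson_r))
    if (nrow(ok) < 3) return(tibble::tibble())
    dplyr::mutate(relatedness_accuracy_correlation(rel, ok, tr),
                  trait = tr, .before = 1)
  })

  h2_slope <- NA_real_
  if (!is.null(varcomp)) {
    j <- dplyr::inner_join(report$by_trait, varcomp, by = "trait")
    if (sum(j$h2 > 0) >= 2)
      h2_slope <- accuracy_h2_regression(j$mean_r, j$h2)
  }
  structure(list(accuracy = acc, report = report, selection = sel,
                 relatedness = rel, relatedness_accuracy = relacc,
                 h2_slope = h2_slope, grm = G),
            class = "gs_evaluation")
}

.grm_input <- function(pop, design) {
  geno <- pop$genotypes[c(pop$training_ids, pop$application_ids), ,
                        drop = FALSE] * 1.0
  if (!is.null(design))
    geno <- geno[, setdiff(colnames(geno), design$excluded), drop = FALSE]
  geno
}

#' Validate cross-file input consistency
#'
#' Report-only checks: genotype or phenotype ids absent from the pedigree
#' (class `orphan-id`), unsorted map positions within a chromosome
#' (`map-order`), duplicated SNP ids (`dup-snp`), and genotype columns
#' missing from the map (`snp-mismatch`).
#'
#' @param pedigree Pedigree tibble.
#' @param genotypes Dosage matrix.
#' @param phenotypes Phenotype tibble.
#' @param map Genetic map tibble.
#' @return Tibble with columns `class` and `what` (empty when consistent).
#' @export
validate_inputs <- function(pedigree, genotypes = NULL, phenotypes = NULL,
                            map = NULL) {
  issues <- list()
  add <- function(class, what) issues[[length(issues) + 1]] <<-
    tibble::tibble(class = class, what = what)
  if (!is.null(genotypes)) {
    orphan <- setdiff(rownames(genotypes), pedigree$id)
    if (length(orphan) > 0) add("orphan-id", orphan)
  }
  if (!is.null(phenotypes)) {
    orphan <- setdiff(unique(phenotypes$id), pedigree$id)
    if (length(orphan) > 0) add("orphan-id", orphan)
  }
  if (!is.null(map)) {
    bad <- map |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(unsorted = is.unsorted(.data$pos_cM), .groups = "drop") |>
      dplyr::filter(.data$unsorted)
    if (nrow(bad) > 0) add("map-order", paste0("chrom", bad$chrom))
    if (anyDuplicated(map$snp) > 0)
      add("dup-snp", unique(map$snp[duplicated(map$snp)]))
    if (!is.null(genotypes)) {
      miss <- setdiff(colnames(genotypes), map$snp)
      if (length(miss) > 0) add("snp-mismatch", miss)
    }
  }
  if (length(issues) == 0)
    tibble::tibble(class = character(), what = character())
  else dplyr::bind_rows(issues)
}

#' @export
print.gs_run <- function(x, ...) {
  cat("<gs_run>\n")
  print(x$manifest)
  invisible(x)
}
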