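# Plain-text file dialects: pedigree CSV (0 = unknown parent), map TSV,
# genotype TSV (individuals x SNPs, NA = missing), phenotype CSV, truth
# JSON, relationship-matrix TSV with an id header row/column.

#' Write a simulated population to a directory
#'
#' @param pop A `gs_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(pop$pedigree, file.path(dir, "pedigree.csv"))
  readr::write_tsv(pop$map, file.path(dir, "map.tsv"))
  write_genotypes(pop$genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_csv(pop$phenotypes, file.path(dir, "phenotypes.csv"))
  truth <- list(
    causal = purrr::map(pop$architecture$causal, ~pop$map$snp[.x]),
    effects = purrr::array_branch(pop$architecture$effects, 2),
    tbv = purrr::array_branch(pop$architecture$tbv, 2),
    ids = rownames(pop$architecture$tbv),
    pi_true = pop$architecture$pi_true,
    h2_target = pop$architecture$h2_target)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_population
#' @param pedigree Pedigree tibble.
#' @param path Output file.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree
  out$sire <- dplyr::coalesce(out$sire, "0")
  out$dam <- dplyr::coalesce(out$dam, "0")
  readr::write_csv(out, path)
}

#' Read a pedigree CSV (0 or empty = unknown parent)
#' @param path File path.
#' @return Sorted, validated pedigree tibble.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = "c", sire = "c", dam = "c",
                           .default = readr::col_guess()))
  sort_and_validate(ped)
}

#' Write / read a dosage matrix as TSV (individuals x SNPs)
#' @param genotypes Dosage matrix with id rownames.
#' @param path File path.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- tibble::as_tibble(genotypes, rownames = "id")
  readr::write_tsv(df, path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  m
}

#' Read a genetic map TSV (snp, chrom, pos_cM)
#' @param path File path.
#' @export
read_genetic_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(snp = "c", chrom = "i",
                                          pos_cM = "d"))
}

#' Read a phenotype CSV (id, trait, year, location, score)
#' @param path File path.
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(id = "c", trait = "c", year = "c",
                                          location = "c",
                                          .default = readr::col_guess()))
}

#' Write / read a relationship matrix as TSV with id header row and column
#' @param M Symmetric matrix with id dimnames.
#' @param path File path.
#' @export
write_relationship_matrix <- function(M, path) {
  df <- tibble::as_tibble(unclass(M), rownames = "id")
  readr::write_tsv(df, path)
}

#' @rdname write_relationship_matrix
#' @export
read_relationship_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  m
}
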