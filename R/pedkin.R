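#' Sort and validate a pedigree
#'
#' Topologically orders pedigree records so that parents precede offspring,
#' treating `NA` (or `"0"`) parents as unknown. Parents that are referenced
#' but have no record of their own are added as founder records and
#' reported; duplicated ids are dropped (first record kept) with a warning.
#' A cycle (an individual among its own ancestors) is a hard error naming
#' one individual on the cycle.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam` (character;
#'   `NA` or `"0"` = unknown). Extra columns are carried through.
#' @return The reordered pedigree as a tibble, with an attribute `issues`
#'   (tibble of class/id pairs for orphan parents and duplicates).
#' @export
sort_and_validate <- function(pedigree) {
  ped <- tibble::as_tibble(pedigree)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  ped$id <- as.character(ped$id)
  ped$sire <- dplyr::na_if(as.character(ped$sire), "0")
  ped$dam <- dplyr::na_if(as.character(ped$dam), "0")

  issues <- tibble::tibble(class = character(), id = character())
  if (anyDuplicated(ped$id)) {
    dups <- unique(ped$id[duplicated(ped$id)])
    issues <- dplyr::bind_rows(issues,
      tibble::tibble(class = "duplicate-id", id = dups))
    warning("duplicated pedigree ids (first record kept): ",
            paste(dups, collapse = ", "))
    ped <- ped[!duplicated(ped$id), ]
  }
  parents <- unique(stats::na.omit(c(ped$sire, ped$dam)))
  orphans <- setdiff(parents, ped$id)
  if (length(orphans) > 0) {
    issues <- dplyr::bind_rows(issues,
      tibble::tibble(class = "orphan-parent", id = orphans))
    ped <- dplyr::bind_rows(
      tibble::tibble(id = orphans, sire = NA_character_, dam = NA_character_),
      ped)
  }

  # Kahn's algorithm over the parent -> offspring DAG
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", nrow(ped))
  for (i in seq_len(nrow(ped))) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  order <- integer(0)
  queue <- which(indeg == 0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < nrow(ped)) {
    bad <- ped$id[setdiff(seq_len(nrow(ped)), order)][1]
    stop("pedigree cycle detected involving individual '", bad, "'")
  }
  out <- ped[order, ]
  attr(out, "issues") <- issues
  out
}

#' Additive (numerator) relationship matrix by the tabular method
#'
#' Builds the pedigree-expected additive relationship matrix A: for a sorted
#' pedigree, `a_ij = (a_j,sire(i) + a_j,dam(i)) / 2` for `j` preceding `i`,
#' and `a_ii = 1 + F_i` with inbreeding `F_i = a_sire(i),dam(i) / 2`.
#' Unknown parents contribute 0 (unrelated, non-inbred founders).
#'
#' @param pedigree Pedigree data frame; sorted and validated internally via
#'   [sort_and_validate()].
#' @return Symmetric numeric matrix with id dimnames; founder diagonal 1.
#' @export
build_a_matrix <- function(pedigree) {
  ped <- sort_and_validate(pedigree)
  n <- nrow(ped)
  ids <- ped$id
  idx <- stats::setNames(seq_len(n), ids)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[j, s]
      if (!is.na(d)) row <- row + A[j, d]
      row <- row / 2
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  A
}

#' Mean pedigree relatedness of a family to the training population
#'
#' Arithmetic mean of the additive relationships `a_ij` over all pairs with
#' `i` in the family and `j` in the training set; self-pairs (same
#' individual in both sets) are excluded.
#'
#' @param A Additive relationship matrix with id dimnames.
#' @param family_members,training_members Character id vectors, both
#'   non-empty and present in `A`.
#' @return Mean relatedness (scalar).
#' @export
pedigree_family_relatedness <- function(A, family_members, training_members) {
  stopifnot(length(family_members) > 0, length(training_members) > 0)
  missing <- setdiff(c(family_members, training_members), rownames(A))
  if (length(missing) > 0)
    stop("ids not in relationship matrix: ", paste(missing, collapse = ", "))
  block <- A[family_members, training_members, drop = FALSE]
  self <- outer(family_members, training_members, `==`)
  mean(block[!self])
}
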