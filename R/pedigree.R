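#' Validate a pedigree table
#'
#' Pedigrees use the conventional 6-column PED layout: family id, individual
#' id, father, mother, sex and phenotype. Missing parents are encoded as `"0"`
#' (or `NA`). Phenotype 2 marks affected individuals. The table must not
#' contain ancestry loops and every named parent must itself be a row.
#'
#' @param ped A data frame with columns `fid`, `id`, `father`, `mother`,
#'   `sex`, `phenotype`.
#' @return A tibble of class `pedigree` with an additional logical `affected`
#'   column.
#' @examples
#' pedigree(data.frame(
#'   fid = "F1", id = c("I.1", "I.2", "II.2", "II.3"),
#'   father = c("0", "0", "I.1", "I.1"), mother = c("0", "0", "I.2", "I.2"),
#'   sex = c(1, 2, 2, 2), phenotype = c(1, 2, 2, 2)
#' ))
#' @export
pedigree <- function(ped) {
  stop_if_not_df(ped, "ped")
  require_columns(ped, c("fid", "id", "father", "mother", "sex", "phenotype"), "ped")
  ped <- as_tibble(ped) |>
    mutate(
      fid = as.character(.data$fid), id = as.character(.data$id),
      father = as.character(.data$father), mother = as.character(.data$mother),
      sex = as.integer(.data$sex), phenotype = as.integer(.data$phenotype)
    )
  ped$father[is.na(ped$father)] <- "0"
  ped$mother[is.na(ped$mother)] <- "0"
  if (anyDuplicated(ped$id)) abort("Duplicate individual ids in pedigree.")
  named_parents <- setdiff(unique(c(ped$father, ped$mother)), c("0", ped$id))
  if (length(named_parents)) {
    abort(sprintf(
      "Parent(s) not present as individuals: %s.",
      paste(named_parents, collapse = ", ")
    ))
  }
  # ancestry loop check: walk up from every individual
  parents <- function(i) setdiff(c(ped$father[ped$id == i], ped$mother[ped$id == i]), "0")
  for (i in ped$id) {
    frontier <- parents(i)
    seen <- character(0)
    while (length(frontier)) {
      if (i %in% frontier) abort(sprintf("Individual %s is its own ancestor.", i))
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parents))), seen)
    }
  }
  ped$affected <- ped$phenotype == 2L
  class(ped) <- c("pedigree", class(ped))
  ped
}

#' Read a 6-column PED file
#'
#' Whitespace-separated, no header: `FID IID PAT MAT SEX PHENO`.
#'
#' @param path Path to the PED file.
#' @return A [pedigree()] tibble.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_table(
    path,
    col_names = c("fid", "id", "father", "mother", "sex", "phenotype"),
    col_types = "ccccii", progress = FALSE
  )
  pedigree(ped)
}

#' Write a pedigree to a 6-column PED file
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  ped <- pedigree(ped)
  readr::write_tsv(
    ped[, c("fid", "id", "father", "mother", "sex", "phenotype")],
    path,
    col_names = FALSE
  )
  invisible(path)
}

# Parents of `id` as a named list(father=, mother=), "0" -> NA.
ped_parents <- function(ped, id) {
  row <- ped[ped$id == id, ]
  if (nrow(row) != 1) abort(sprintf("Individual %s not in pedigree.", id))
  list(
    father = if (row$father == "0") NA_character_ else row$father,
    mother = if (row$mother == "0") NA_character_ else row$mother
  )
}
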