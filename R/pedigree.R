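#' Read a pedigree file
#'
#' Reads a pedigree CSV with columns `id`, `sire`, `dam`. Unknown parents are
#' coded `0` (or `NA`) and stored as `NA`.
#'
#' @param path Path to a CSV file with a header row `id,sire,dam`.
#' @return A tibble with character columns `id`, `sire`, `dam` (class
#'   `snpblup_pedigree`), topologically sorted so parents precede offspring.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(raw))) {
    stop("pedigree file must have columns id, sire, dam", call. = FALSE)
  }
  as_pedigree(raw[need])
}

#' Coerce a data frame to a pedigree
#'
#' @param x Data frame with columns `id`, `sire`, `dam`; parent codes `0`,
#'   `""` and `NA` all mean unknown.
#' @return A sorted pedigree tibble (see [sort_pedigree()]).
#' @export
as_pedigree <- function(x) {
  ped <- tibble::tibble(
    id   = as.character(x$id),
    sire = as.character(x$sire),
    dam  = as.character(x$dam)
  )
  ped$sire[ped$sire %in% c("0", "", "NA") | is.na(ped$sire)] <- NA_character_
  ped$dam[ped$dam %in% c("0", "", "NA") | is.na(ped$dam)] <- NA_character_
  if (anyDuplicated(ped$id)) {
    stop("duplicated individual ids in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  }
  known <- c(ped$sire, ped$dam)
  known <- known[!is.na(known)]
  missing_parents <- setdiff(known, ped$id)
  if (length(missing_parents) > 0) {
    stop("parents referenced but not present as individuals: ",
         paste(missing_parents, collapse = ", "), call. = FALSE)
  }
  sort_pedigree(ped)
}

#' Topologically sort a pedigree
#'
#' Orders records so that every parent precedes its offspring (Kahn's
#' algorithm); ties are broken by input order, so an already-sorted pedigree
#' is returned unchanged.
#'
#' @param ped Pedigree data frame (columns `id`, `sire`, `dam`).
#' @return The sorted pedigree as a `snpblup_pedigree` tibble.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  if (is_sorted_pedigree(ped)) {
    return(new_pedigree(tibble::as_tibble(ped)))
  }
  idx <- stats::setNames(seq_len(n), ped$id)
  sire_i <- unname(idx[ped$sire])
  dam_i <- unname(idx[ped$dam])
  # level = 1 + max(level of parents); founders are level 0
  level <- rep(NA_integer_, n)
  level[is.na(sire_i) & is.na(dam_i)] <- 0L
  repeat {
    todo <- which(is.na(level))
    if (length(todo) == 0L) break
    ls <- ifelse(is.na(sire_i[todo]), -1L, level[sire_i[todo]])
    ld <- ifelse(is.na(dam_i[todo]), -1L, level[dam_i[todo]])
    ready <- !is.na(ls) & !is.na(ld)
    if (!any(ready)) {
      stop("pedigree contains a cycle involving: ",
           paste(utils::head(ped$id[todo], 5), collapse = ", "),
           call. = FALSE)
    }
    level[todo[ready]] <- pmax(ls[ready], ld[ready]) + 1L
  }
  order_out <- order(level, seq_len(n)) # stable: ties keep input order
  new_pedigree(tibble::as_tibble(ped)[order_out, , drop = FALSE])
}

new_pedigree <- function(tbl) {
  if (!inherits(tbl, "snpblup_pedigree")) {
    class(tbl) <- c("snpblup_pedigree", class(tbl))
  }
  tbl
}

is_sorted_pedigree <- function(ped) {
  pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
  ok_s <- is.na(ped$sire) | pos[ped$sire] < seq_len(nrow(ped))
  ok_d <- is.na(ped$dam) | pos[ped$dam] < seq_len(nrow(ped))
  isTRUE(all(ok_s & ok_d))
}

#' Additive (numerator) relationship matrix from pedigree
#'
#' Builds the additive relationship matrix A by the tabular method:
#' `a_ii = 1 + 0.5 * a(sire_i, dam_i)` and, for j preceding i,
#' `a_ij = 0.5 * (a(j, sire_i) + a(j, dam_i))`, with unknown parents
#' contributing 0. Founders get diagonal 1 and mutual relationship 0.
#'
#' @param ped A pedigree (sorted with [sort_pedigree()] or built by
#'   [as_pedigree()]). An unsorted data frame triggers an error.
#' @return A [relmat] with `method = "PB"`.
#' @export
additive_relationship <- function(ped) {
  if (!is_sorted_pedigree(ped)) {
    stop("pedigree must be topologically sorted; call sort_pedigree() first",
         call. = FALSE)
  }
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    rs <- if (!is.na(si[i])) A[si[i], seq_len(i - 1L)] else numeric(i - 1L)
    rd <- if (!is.na(di[i])) A[di[i], seq_len(i - 1L)] else numeric(i - 1L)
    if (i > 1L) {
      row_i <- 0.5 * (rs + rd)
      A[i, seq_len(i - 1L)] <- row_i
      A[seq_len(i - 1L), i] <- row_i
    }
    asd <- if (!is.na(si[i]) && !is.na(di[i])) A[si[i], di[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
  }
  relmat(A, ids = ped$id, method = "PB")
}

#' Inbreeding coefficients from a relationship matrix
#'
#' The inbreeding coefficient of individual i is `F_i = a_ii - 1`.
#'
#' @param A A [relmat] (typically from [additive_relationship()]).
#' @return Tibble with columns `id`, `F`.
#' @export
inbreeding <- function(A) {
  stopifnot(inherits(A, "snpblup_relmat"))
  tibble::tibble(id = rownames(A), F = unname(diag(unclass_relmat(A))) - 1)
}

#' Selfcoancestry diagonal from parental relationship
#'
#' Diagonal element of a relationship matrix for individual k whose parents
#' have pairwise relationship `a_ij`: `F_k = 1 + 0.5 * a_ij`. Used to fill
#' the blank diagonal of marker-based matrices; an unknown parent contributes
#' `a_ij = 0`.
#'
#' @param a_ij Relationship between the two parents (scalar or vector).
#' @return `1 + 0.5 * a_ij`.
#' @export
selfcoancestry_diagonal <- function(a_ij) {
  a_ij[is.na(a_ij)] <- 0
  1 + 0.5 * a_ij
}
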