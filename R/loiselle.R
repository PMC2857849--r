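#' Loiselle marker-based relatedness (SNPL)
#'
#' Moment estimator of pairwise relatedness from allele-frequency deviations.
#' For each pair (i, j), each locus l and each allele a, the numerator
#' accumulates the mean over the 2 x 2 homologous-chromosome pairs of
#' `(x_ci,a - p_a)(x_cj,a - p_a)` (where `x` is the allele indicator on one
#' chromosome copy), plus the sampling-bias correction
#' `p_a (1 - p_a) / (n_l - 1)`; the denominator accumulates
#' `sum_a p_a (1 - p_a)`. The reported value is the ratio of the two sums
#' over loci usable for the pair.
#'
#' For a biallelic locus with counted-allele dosage `g` and frequency `p`,
#' the per-locus numerator reduces to
#' `2 (g_i/2 - p)(g_j/2 - p) + 2 p (1 - p) / (n_l - 1)` and the per-locus
#' denominator to `2 p (1 - p)`; both alleles of the SNP are summed over.
#'
#' Frequencies and allele counts `n_l` always come from the full panel
#' (reference sample); a locus with a missing call in either member of a pair
#' is excluded from that pair's numerator and denominator. The diagonal is
#' left blank (`NA`), as the estimator defines selfcoancestry only through
#' the parents (see [fill_diagonal()]).
#'
#' @param G A [geno] panel with at least 2 individuals.
#' @param freqs Optional precomputed [allele_frequencies()] table for `G`.
#' @return A [relmat] with `method = "SNPL"` and `NA` diagonal.
#' @export
loiselle_relatedness <- function(G, freqs = allele_frequencies(G)) {
  n <- length(G$ids)
  if (n < 2) stop("at least 2 individuals are required", call. = FALSE)
  p <- freqs$p
  n_l <- freqs$n_alleles
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    stop("all loci are monomorphic: zero denominator", call. = FALSE)
  }
  # drop monomorphic loci: they contribute 0 to both sums
  cnt <- G$counts[, poly, drop = FALSE]
  p <- p[poly]
  n_l <- n_l[poly]

  obs <- !is.na(cnt)            # individuals x loci indicator
  dev <- sweep(cnt / 2, 2, p)   # (g/2 - p), NA where missing
  dev[!obs] <- 0
  obs <- obs * 1

  bias_l <- 2 * p * (1 - p) / (n_l - 1)
  denom_l <- 2 * p * (1 - p)

  cross <- 2 * tcrossprod(dev)                       # sum_l 2 d_i d_j
  shared_bias <- tcrossprod(obs * rep(sqrt(bias_l), each = n))
  shared_denom <- tcrossprod(obs * rep(sqrt(denom_l), each = n))
  if (any(shared_denom[upper.tri(shared_denom)] <= 0)) {
    stop("some pairs share no usable polymorphic locus", call. = FALSE)
  }
  V <- (cross + shared_bias) / shared_denom
  diag(V) <- NA_real_
  relmat(V, ids = G$ids, method = "SNPL")
}

#' Fill the blank diagonal of a marker relationship matrix
#'
#' Marker-based estimators leave the diagonal blank; individual k's diagonal
#' is filled from its parents' relationship in the same matrix:
#' `1 + 0.5 * m(sire_k, dam_k)` (the selfcoancestry rule). When either parent
#' is unknown or absent from the matrix, the diagonal defaults to 1.
#'
#' @param M A [relmat] with computed off-diagonals.
#' @param ped A pedigree covering every id in `M`.
#' @return The [relmat] with a complete diagonal.
#' @export
fill_diagonal <- function(M, ped) {
  ids <- rownames(M)
  missing_ids <- setdiff(ids, ped$id)
  if (length(missing_ids) > 0) {
    stop("ids absent from pedigree: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  V <- unclass_relmat(M)
  ped_idx <- match(ids, ped$id)
  sire <- ped$sire[ped_idx]
  dam <- ped$dam[ped_idx]
  si <- match(sire, ids)
  di <- match(dam, ids)
  a_par <- rep(0, length(ids))
  ok <- !is.na(si) & !is.na(di)
  a_par[ok] <- V[cbind(si[ok], di[ok])]
  diag(V) <- selfcoancestry_diagonal(a_par)
  relmat(V, ids = ids, method = relmat_method(M),
         bending_shift = attr(M, "bending_shift"))
}
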