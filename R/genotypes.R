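#' Genotype panel container
#'
#' Biallelic SNP genotypes stored as an individuals-by-loci matrix of
#' counted-allele dosages in {0, 1, 2} (`NA` = missing call), together with a
#' locus map (chromosome, snp id, position in Morgans). Ploidy is 2.
#'
#' @param counts Numeric matrix, individuals x loci, entries in {0, 1, 2} or
#'   `NA`.
#' @param ids Character vector of individual labels (defaults to rownames).
#' @param map Data frame with columns `chrom`, `snp`, `pos` (position in
#'   Morgans), one row per locus, sorted by chromosome then position.
#' @return A `snpblup_geno` object (list with `ids`, `counts`, `map`).
#' @export
geno <- function(counts, ids = rownames(counts), map) {
  counts <- as.matrix(counts)
  if (is.null(ids)) stop("individual ids are required", call. = FALSE)
  map <- tibble::as_tibble(map)
  if (!all(c("chrom", "snp", "pos") %in% names(map))) {
    stop("map must have columns chrom, snp, pos", call. = FALSE)
  }
  if (nrow(map) != ncol(counts)) {
    stop("map rows (", nrow(map), ") must match genotype columns (",
         ncol(counts), ")", call. = FALSE)
  }
  bad <- !(counts %in% c(0, 1, 2)) & !is.na(counts)
  if (any(bad)) {
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, ]
  counts <- counts[, ord, drop = FALSE]
  dimnames(counts) <- list(as.character(ids), map$snp)
  structure(list(ids = as.character(ids), counts = counts, map = map),
            class = "snpblup_geno")
}

#' @export
print.snpblup_geno <- function(x, ...) {
  cat(sprintf("<genotype panel> %d individuals x %d loci on %d chromosome(s)\n",
              length(x$ids), ncol(x$counts),
              length(unique(x$map$chrom))))
  invisible(x)
}

#' Number of loci in a genotype panel
#' @param G A [geno] panel.
#' @return Integer locus count.
#' @export
n_loci <- function(G) ncol(G$counts)

#' Allele frequencies of the counted allele
#'
#' Per locus: `p = (sum of dosages) / n_l`, where `n_l` is the number of
#' allele copies defined in the sample at that locus (individuals times
#' ploidy minus the number of missing allele copies). The reference sample is
#' always the full panel.
#'
#' @param G A [geno] panel.
#' @return Tibble with columns `chrom`, `snp`, `pos`, `p`, `n_alleles`.
#' @export
allele_frequencies <- function(G) {
  n_miss <- colSums(is.na(G$counts))
  n_l <- 2 * (nrow(G$counts) - n_miss)
  if (any(n_l == 0)) {
    stop("locus with all calls missing: ",
         paste(utils::head(G$map$snp[n_l == 0], 5), collapse = ", "),
         "; drop it before computing frequencies", call. = FALSE)
  }
  p <- colSums(G$counts, na.rm = TRUE) / n_l
  tibble::tibble(chrom = G$map$chrom, snp = G$map$snp, pos = G$map$pos,
                 p = unname(p), n_alleles = unname(n_l))
}

#' Filter loci by minor allele frequency
#'
#' Retains loci with `min(p, 1 - p) > threshold` (strict inequality), in the
#' original order.
#'
#' @param G A [geno] panel.
#' @param threshold MAF threshold; loci at or below it are dropped.
#' @return The filtered [geno] panel.
#' @export
maf_filter <- function(G, threshold = 0.1) {
  p <- allele_frequencies(G)$p
  keep <- pmin(p, 1 - p) > threshold
  if (!any(keep)) {
    stop("no loci pass the MAF > ", threshold, " filter", call. = FALSE)
  }
  geno(G$counts[, keep, drop = FALSE], ids = G$ids,
       map = G$map[keep, , drop = FALSE])
}

#' Restrict a genotype panel to one chromosome
#'
#' @param G A [geno] panel.
#' @param chromosome Chromosome label present in the map.
#' @return The restricted [geno] panel (same individuals).
#' @export
subset_chromosome <- function(G, chromosome) {
  keep <- G$map$chrom == chromosome
  if (!any(keep)) {
    stop("chromosome '", chromosome, "' not present in the genotype map",
         call. = FALSE)
  }
  geno(G$counts[, keep, drop = FALSE], ids = G$ids,
       map = G$map[keep, , drop = FALSE])
}

#' Write a genotype panel to text files
#'
#' The genotype file is a whitespace-separated matrix of dosages with a
#' leading `id` column and a header of SNP ids; missing calls are `NA`. The
#' map file has columns `chrom`, `snp`, `pos`.
#'
#' @param G A [geno] panel.
#' @param geno_path,map_path Output paths.
#' @return `geno_path`, invisibly.
#' @export
write_genotypes <- function(G, geno_path, map_path) {
  df <- data.frame(id = G$ids, G$counts, check.names = FALSE)
  utils::write.table(df, geno_path, quote = FALSE, sep = " ",
                     row.names = FALSE)
  utils::write.table(as.data.frame(G$map), map_path, quote = FALSE,
                     sep = " ", row.names = FALSE)
  invisible(geno_path)
}

#' Read a genotype panel from text files
#'
#' @param geno_path,map_path Files in the [write_genotypes()] format.
#' @return A [geno] panel.
#' @export
read_genotypes <- function(geno_path, map_path) {
  df <- utils::read.table(geno_path, header = TRUE, check.names = FALSE)
  map <- utils::read.table(map_path, header = TRUE, check.names = FALSE,
                           colClasses = c(chrom = "character",
                                          snp = "character"))
  ids <- as.character(df[[1]])
  counts <- as.matrix(df[, -1, drop = FALSE])
  geno(counts, ids = ids, map = map)
}
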