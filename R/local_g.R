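#' Local relationship matrices averaged along a chromosome (SNPC)
#'
#' Emulates the workflow in which locus-specific IBD relationship matrices
#' are computed at a set of positions along one chromosome and then averaged
#' into a single genomic relationship matrix. The local matrix at each
#' position is a deterministic windowed allele-sharing relationship: at each
#' of `n_points` equally spaced positions spanning the chromosome, the
#' `window` loci nearest to that position form a panel and the local matrix
#' is the centred allele-sharing (VanRaden-type) relationship
#' `Z Z' / (2 sum_l p_l (1 - p_l))` with `Z = dosage - 2p`, which has a
#' complete diagonal. Externally computed IBD matrices can be supplied
#' instead via [read_ibd_matrices()] + [average_relmats()].
#'
#' Missing calls are mean-imputed (dosage `2p`) within a window, i.e. they
#' contribute zero to the centred cross-products.
#'
#' @param G A [geno] panel restricted to the chromosome of interest (after
#'   any MAF filtering).
#' @param n_points Number of evaluation positions (default 9).
#' @param window Loci per local panel; default spreads the panel across
#'   points (`ceiling(n_loci / n_points)`), minimum 1.
#' @return A [relmat] with `method = "SNPC"` and complete diagonal.
#' @export
local_relationship_average <- function(G, n_points = 9, window = NULL) {
  if (n_points < 1) stop("n_points must be at least 1", call. = FALSE)
  L <- n_loci(G)
  if (L < n_points) {
    stop("need at least n_points (", n_points, ") loci; have ", L,
         call. = FALSE)
  }
  if (length(unique(G$map$chrom)) > 1) {
    stop("restrict the panel to one chromosome before local averaging",
         call. = FALSE)
  }
  if (is.null(window)) window <- max(1L, ceiling(L / n_points))
  pos <- G$map$pos
  span <- range(pos)
  centers <- if (n_points == 1) {
    mean(span)
  } else {
    seq(span[1], span[2], length.out = n_points)
  }
  freqs <- allele_frequencies(G)
  mats <- lapply(centers, function(ctr) {
    sel <- order(abs(pos - ctr))[seq_len(window)]
    sel <- sort(sel)
    local_allele_sharing(G$counts[, sel, drop = FALSE], freqs$p[sel], G$ids)
  })
  average_relmats(mats, method = "SNPC")
}

# Centred allele-sharing relationship on a locus window; requires at least
# one polymorphic locus in the window.
local_allele_sharing <- function(cnt, p, ids) {
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    stop("a local window contains only monomorphic loci; widen the window ",
         "or filter the panel", call. = FALSE)
  }
  cnt <- cnt[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(cnt, 2, 2 * p)
  Z[is.na(Z)] <- 0
  V <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  relmat(V, ids = ids, method = "SNPC")
}
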