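#' Relationship matrix container
#'
#' A symmetric individuals-by-individuals genetic covariance structure with a
#' method tag recording its provenance: `"PB"` (pedigree additive
#' relationship), `"SNPL"` (Loiselle marker estimator), `"SNPC"` (average of
#' local marker relationship matrices), or any user label for externally
#' computed matrices.
#'
#' @param x Square numeric matrix. Must be symmetric where both entries are
#'   defined; the diagonal may be `NA` (blank) for marker estimators before
#'   [fill_diagonal()].
#' @param ids Character vector of individual labels (row/column names).
#' @param method Provenance tag.
#' @param bending_shift Diagonal shift applied by [bend_to_pd()], 0 if none.
#' @return A `snpblup_relmat`: the matrix with dimnames plus attributes
#'   `method` and `bending_shift`.
#' @export
relmat <- function(x, ids = rownames(x), method = "custom",
                   bending_shift = 0) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop("relationship matrix must be a square matrix", call. = FALSE)
  }
  if (is.null(ids) || length(ids) != nrow(x)) {
    stop("ids must label every row of the matrix", call. = FALSE)
  }
  off_ok <- {
    d <- x - t(x)
    d[is.na(d)] <- 0
    max(abs(d)) < 1e-10
  }
  if (!off_ok) stop("relationship matrix is not symmetric", call. = FALSE)
  dimnames(x) <- list(as.character(ids), as.character(ids))
  structure(x, method = method, bending_shift = bending_shift,
            class = c("snpblup_relmat", "matrix", "array"))
}

unclass_relmat <- function(M) {
  attr(M, "method") <- NULL
  attr(M, "bending_shift") <- NULL
  class(M) <- NULL
  M
}

relmat_method <- function(M) attr(M, "method") %||% "custom"

#' @export
print.snpblup_relmat <- function(x, ...) {
  cat(sprintf("<relationship matrix [%s]> %d x %d individuals\n",
              relmat_method(x), nrow(x), ncol(x)))
  shift <- attr(x, "bending_shift")
  if (!is.null(shift) && shift > 0) {
    cat(sprintf("  bending shift applied to diagonal: %.3g\n", shift))
  }
  k <- min(6L, nrow(x))
  print(round(unclass_relmat(x)[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (nrow(x) > k) cat("  ...\n")
  invisible(x)
}

#' Minimum eigenvalue and positive-definiteness status
#'
#' @param M A [relmat] (diagonal must be filled).
#' @return List with `min_eigenvalue` and logical `positive_definite`
#'   (minimum eigenvalue strictly positive).
#' @export
pd_status <- function(M) {
  lam <- min(eigen(unclass_relmat(M), symmetric = TRUE,
                   only.values = TRUE)$values)
  list(min_eigenvalue = lam, positive_definite = lam > 0)
}

#' Bend a relationship matrix to positive definiteness
#'
#' If the minimum eigenvalue is below `epsilon`, adds `epsilon - lambda_min`
#' to every diagonal element, so the result has minimum eigenvalue
#' `>= epsilon`. The applied shift is recorded in the `bending_shift`
#' attribute (0 when no shift was needed).
#'
#' @param M A [relmat] with no blank diagonal entries.
#' @param epsilon Target lower bound for the minimum eigenvalue.
#' @return The (possibly shifted) [relmat].
#' @export
bend_to_pd <- function(M, epsilon = 1e-6) {
  stopifnot(inherits(M, "snpblup_relmat"))
  V <- unclass_relmat(M)
  if (anyNA(V)) {
    stop("matrix has blank entries; fill the diagonal before bending",
         call. = FALSE)
  }
  lam <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  shift <- max(0, epsilon - lam)
  if (shift > 0) diag(V) <- diag(V) + shift
  relmat(V, ids = rownames(M), method = relmat_method(M),
         bending_shift = attr(M, "bending_shift") + shift)
}

#' Write a relationship matrix to a text file
#'
#' Whitespace-separated full matrix with an id header row and a leading id
#' column; readable by [read_relmat()]. Blank diagonals are written as `NA`.
#'
#' @param M A [relmat].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_relmat <- function(M, path) {
  df <- data.frame(id = rownames(M), unclass_relmat(M), check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = " ", row.names = FALSE)
  invisible(path)
}

#' Read a relationship matrix from a text file
#'
#' @param path File written by [write_relmat()] (or any whitespace-separated
#'   full matrix with an id header row and leading id column).
#' @param method Provenance tag to attach.
#' @return A [relmat].
#' @export
read_relmat <- function(path, method = "custom") {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  V <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(V), ids)) {
    stop("relationship matrix file ", path,
         ": header ids do not match row ids", call. = FALSE)
  }
  relmat(V, ids = ids, method = method)
}

#' Read a set of per-position IBD relationship matrices
#'
#' Ingests externally computed local identity-by-descent matrices (one file
#' per chromosomal position, in the [write_relmat()] format) for averaging
#' into a single genomic relationship matrix.
#'
#' @param paths Character vector of file paths (ordered along the
#'   chromosome).
#' @return List of [relmat] objects with identical ids, suitable for
#'   [average_relmats()].
#' @export
read_ibd_matrices <- function(paths) {
  if (length(paths) < 1) {
    stop("at least one IBD matrix file is required", call. = FALSE)
  }
  mats <- lapply(paths, read_relmat, method = "SNPC")
  ids <- rownames(mats[[1]])
  for (k in seq_along(mats)) {
    if (!identical(rownames(mats[[k]]), ids)) {
      stop("IBD matrix ", paths[k],
           " has ids or dimensions inconsistent with ", paths[1],
           call. = FALSE)
    }
  }
  mats
}

#' Elementwise average of relationship matrices
#'
#' @param mats List of conformable [relmat] objects (same ids, same order).
#' @param method Provenance tag for the result.
#' @return A [relmat]: the elementwise mean.
#' @export
average_relmats <- function(mats, method = "SNPC") {
  if (length(mats) < 1) stop("empty matrix list", call. = FALSE)
  ids <- rownames(mats[[1]])
  for (M in mats) {
    if (!identical(rownames(M), ids)) {
      stop("matrices are not conformable (id mismatch)", call. = FALSE)
    }
  }
  V <- Reduce(`+`, lapply(mats, unclass_relmat)) / length(mats)
  relmat(V, ids = ids, method = method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
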