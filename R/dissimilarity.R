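# The two dissimilarities the niche-space analysis rests on: Jaccard distance
# between binary gene repertoires (D_ij) and Bray-Curtis between
# relative-abundance compositions.

#' Jaccard distance between two gene repertoires
#'
#' \code{1 - |intersection| / |union|} of the gene sets encoded by two binary
#' incidence vectors. Genes absent from both repertoires contribute nothing,
#' so the distance is invariant to padding the gene universe.
#'
#' @param a,b equal-length binary (0/1) vectors.
#' @return dissimilarity in \code{[0, 1]}.
#' @examples
#' jaccard_distance(c(1, 1, 1, 0), c(0, 1, 1, 1))  # shared 2 of 4 -> 0.5
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) stop("repertoires must have equal length", call. = FALSE)
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    stop("repertoires must be binary 0/1 vectors", call. = FALSE)
  }
  union_n <- sum(a == 1 | b == 1)
  if (union_n == 0L) {
    stop("Jaccard distance undefined: both repertoires are empty", call. = FALSE)
  }
  1 - sum(a == 1 & b == 1) / union_n
}

#' Pairwise Jaccard distance matrix over a gene-repertoire matrix
#'
#' Computes the MAG-by-MAG Jaccard distance matrix \code{D} on the full gene
#' universe (no gene filtering): entry \code{(i, j)} is
#' [jaccard_distance()] between rows \code{i} and \code{j}.
#'
#' @param m validated gene matrix (MAG rows, gene columns); at least two
#'   MAGs, no all-zero row.
#' @return square symmetric distance matrix with MAG ids as dimnames.
#' @export
pairwise_jaccard <- function(m) {
  m <- validate_gene_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 MAGs for a distance matrix", call. = FALSE)
  empty <- which(rowSums(m) == 0)
  if (length(empty)) {
    stop("MAG(s) with empty gene repertoire: ",
         paste(rownames(m)[empty], collapse = ", "), call. = FALSE)
  }
  # |intersection| via crossprod; |union| = |a| + |b| - |intersection|
  mm <- m * 1.0
  inter <- tcrossprod(mm)
  sizes <- rowSums(mm)
  un <- outer(sizes, sizes, "+") - inter
  D <- 1 - inter / un
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  validate_distance_matrix(D)
}

#' Bray-Curtis dissimilarity between two compositions
#'
#' \code{sum(|x_i - y_i|) / sum(x_i + y_i)} over taxa, 0 for identical
#' compositions and 1 for disjoint supports.
#'
#' @param x,y equal-length nonnegative vectors (relative abundances), not
#'   both all-zero.
#' @return dissimilarity in \code{[0, 1]}.
#' @examples
#' bray_curtis(c(0.5, 0.5, 0), c(0, 0.5, 0.5))  # 0.5
#' @export
bray_curtis <- function(x, y) {
  x <- validate_composition(x)
  y <- validate_composition(y)
  if (length(x) != length(y)) stop("compositions must have equal length", call. = FALSE)
  denom <- sum(x + y)
  if (denom == 0) {
    stop("Bray-Curtis undefined: both compositions are all-zero", call. = FALSE)
  }
  sum(abs(x - y)) / denom
}
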