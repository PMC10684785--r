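# Principal coordinate analysis of the Jaccard distance matrix: the
# "metagenomic niche space". Classical metric scaling (Gower double
# centering) via stats::cmdscale, with deterministic sign fixing and
# explicit reporting of negative eigenvalues (Jaccard distances are in
# general non-Euclidean; no Cailliez/Lingoes correction is applied).

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical metric scaling: the matrix \code{-0.5 * D^2} is double-centered
#' and eigendecomposed; coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues. Axes whose eigenvalues are not
#' positive carry zero coordinates. For reproducibility each axis is flipped
#' so that its largest-magnitude coordinate is positive.
#'
#' @param D validated square dissimilarity matrix (see
#'   [validate_distance_matrix()]).
#' @param n_axes number of axes to return; at most \code{nrow(D) - 1}.
#' @return an object of class \code{"niche_pcoa"}: a list with \code{ids},
#'   \code{coordinates} (entity x axis), \code{eigenvalues} (all
#'   \code{nrow(D)} values, non-increasing, negatives included),
#'   \code{proportion_explained} (per returned axis, relative to the sum of
#'   positive eigenvalues), and \code{n_negative_eigenvalues}.
#' @export
pcoa <- function(D, n_axes = 3L) {
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 entities", call. = FALSE)
  n_axes <- as.integer(n_axes)
  if (n_axes < 1L || n_axes > n - 1L) {
    stop("n_axes must be between 1 and n - 1 (= ", n - 1L, ")", call. = FALSE)
  }
  if (all(D == 0)) stop("degenerate distance matrix: all distances are zero", call. = FALSE)

  # cmdscale warns when fewer than k eigenvalues are positive; the padding
  # below handles that case explicitly
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1L,
                                         eig = TRUE, add = FALSE, list. = TRUE))
  eig <- sc$eig                       # length n, non-increasing
  tol <- max(abs(eig)) * .Machine$double.eps * n
  pos <- which(eig > tol)

  coords <- matrix(0, n, n_axes, dimnames = list(rownames(D),
                                                 paste0("PCoA", seq_len(n_axes))))
  usable <- intersect(seq_len(n_axes), seq_len(ncol(sc$points)))
  keep <- usable[usable %in% pos]
  if (length(keep)) coords[, keep] <- sc$points[, keep, drop = FALSE]

  # deterministic sign: largest-magnitude coordinate on each axis positive
  for (j in seq_len(n_axes)) {
    col <- coords[, j]
    if (any(col != 0)) {
      top <- which.max(abs(col))
      if (col[top] < 0) coords[, j] <- -col
    }
  }

  pos_sum <- sum(eig[pos])
  prop <- numeric(n_axes)
  prop[keep] <- eig[keep] / pos_sum

  structure(list(ids = rownames(D),
                 coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = prop,
                 n_negative_eigenvalues = sum(eig < -tol)),
            class = "niche_pcoa")
}

#' @export
print.niche_pcoa <- function(x, ...) {
  cat("Principal coordinate analysis:", length(x$ids), "entities,",
      ncol(x$coordinates), "axes\n")
  cat("Proportion explained:",
      paste(sprintf("%.3f", x$proportion_explained), collapse = " "), "\n")
  if (x$n_negative_eigenvalues > 0) {
    cat("Negative eigenvalues:", x$n_negative_eigenvalues,
        "(non-Euclidean input; excluded from coordinates)\n")
  }
  invisible(x)
}

#' Union gene repertoire of a set of detected MAGs
#'
#' Element-wise OR of the selected MAGs' presence/absence rows: a gene is
#' present in the community repertoire if any detected MAG carries it.
#'
#' @param m validated gene matrix.
#' @param detected nonempty character vector of MAG ids (rows of \code{m}).
#' @return binary integer vector over the gene universe of \code{m}.
#' @export
union_repertoire <- function(m, detected) {
  m <- validate_gene_matrix(m)
  detected <- unique(as.character(detected))
  if (length(detected) == 0L) stop("detected set must be nonempty", call. = FALSE)
  missing <- setdiff(detected, rownames(m))
  if (length(missing)) {
    stop("MAG(s) not in gene matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- as.integer(colSums(m[detected, , drop = FALSE]) > 0)
  names(v) <- colnames(m)
  v
}

#' Per-time-point community gene repertoires
#'
#' For each time point, the union repertoire of the MAGs detected there
#' (relative abundance strictly above \code{threshold}). The resulting
#' day-by-gene binary matrix can be fed to [pairwise_jaccard()] and [pcoa()]
#' to ordinate time points by community-level gene composition.
#'
#' @param m validated gene matrix.
#' @param a validated abundance table whose MAG columns appear in \code{m}.
#' @param threshold detection threshold (default 0.001, i.e. 0.1%).
#' @return binary integer matrix, day rownames, gene colnames. Time points
#'   with an empty detected set are dropped with a warning.
#' @export
community_repertoires <- function(m, a, threshold = 0.001) {
  m <- validate_gene_matrix(m)
  a <- validate_abundance_table(a)
  missing <- setdiff(colnames(a), rownames(m))
  if (length(missing)) {
    stop("abundance MAG(s) missing from gene matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(a)), function(k) {
    det <- detect_mags(a[k, ], threshold)
    if (det$n == 0L) return(NULL)
    union_repertoire(m, det$mags)
  })
  empty <- vapply(rows, is.null, logical(1L))
  if (any(empty)) {
    warning("no MAGs detected at day(s) ",
            paste(rownames(a)[empty], collapse = ", "), "; dropped",
            call. = FALSE)
  }
  out <- do.call(rbind, rows[!empty])
  rownames(out) <- rownames(a)[!empty]
  out
}
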