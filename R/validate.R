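# Internal validators shared by every module. All user-facing entry points
# funnel their inputs through these, so downstream numeric code can assume
# well-formed matrices.

SIMPLEX_TOL <- 1e-9

#' Validate a MAG-by-gene presence/absence matrix
#'
#' A gene-repertoire matrix is a binary incidence matrix with MAGs as rows
#' (unique rownames) and annotated genes as columns (unique colnames). It is
#' the substrate of all niche-space computations.
#'
#' @param m numeric matrix; every cell must be exactly 0 or 1.
#' @return the validated matrix (integer storage), invisibly unchanged in
#'   shape and dimnames.
#' @export
validate_gene_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("gene matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("gene matrix must carry MAG rownames and gene colnames", call. = FALSE)
  }
  if (ncol(m) < 1L) stop("gene matrix needs at least one gene column", call. = FALSE)
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup)) {
    stop("duplicate MAG id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (anyNA(m)) stop("gene matrix contains missing values", call. = FALSE)
  if (!all(m == 0 | m == 1)) {
    stop("gene matrix cells must be 0 or 1 (binarize counts first)", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Validate a time-by-MAG relative-abundance table
#'
#' Rows are time points (numeric day labels in strictly increasing order),
#' columns are MAGs. Each row is a composition: nonnegative entries summing
#' to 1 within a strict tolerance of 1e-9.
#'
#' @param a numeric matrix with day rownames and MAG colnames.
#' @return the validated matrix.
#' @export
validate_abundance_table <- function(a) {
  if (!is.matrix(a) || !is.numeric(a)) {
    stop("abundance table must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(a)) || is.null(colnames(a))) {
    stop("abundance table must carry day rownames and MAG colnames", call. = FALSE)
  }
  days <- suppressWarnings(as.numeric(rownames(a)))
  if (anyNA(days)) stop("day labels must be numeric", call. = FALSE)
  if (nrow(a) > 1L && any(diff(days) <= 0)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  dup <- colnames(a)[duplicated(colnames(a))]
  if (length(dup)) {
    stop("duplicate MAG id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (anyNA(a)) stop("abundance table contains missing values", call. = FALSE)
  if (any(a < 0)) stop("abundance values must be nonnegative", call. = FALSE)
  rs <- rowSums(a)
  zero <- which(rs == 0)
  if (length(zero)) {
    stop("all-zero abundance row at day ", rownames(a)[zero[1L]], call. = FALSE)
  }
  off <- which(abs(rs - 1) > SIMPLEX_TOL)
  if (length(off)) {
    stop("abundance row at day ", rownames(a)[off[1L]],
         " sums to ", format(rs[off[1L]], digits = 12),
         " (not 1 within 1e-9); use normalize = TRUE to close to the simplex",
         call. = FALSE)
  }
  a
}

#' Validate a square dissimilarity matrix
#'
#' @param D square numeric matrix with matching row/col ids, zero diagonal,
#'   symmetric, entries in \code{[0, 1]}.
#' @return the validated matrix.
#' @export
validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    stop("distance matrix must be square and numeric", call. = FALSE)
  }
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
    stop("distance matrix must have identical row and column ids", call. = FALSE)
  }
  if (anyNA(D)) stop("distance matrix contains missing values", call. = FALSE)
  if (any(abs(diag(D)) > 0)) stop("distance matrix diagonal must be exactly 0", call. = FALSE)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(D < 0) || any(D > 1)) stop("dissimilarities must lie in [0, 1]", call. = FALSE)
  D
}

# a single composition vector (one abundance row)
validate_composition <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) stop("composition must be numeric", call. = FALSE)
  if (anyNA(x)) stop("composition contains missing values", call. = FALSE)
  if (any(x < 0)) stop("composition entries must be nonnegative", call. = FALSE)
  x
}
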