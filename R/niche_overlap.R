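# Community-scale niche-overlap indices. At each time point the community is
# the set T of MAGs detected above a relative-abundance threshold (default
# 0.1%); gene-repertoire overlap among its members is summarized by three
# indices in [0, 1]:
#   overall mean:          1 - mean of D_ij over ordered pairs i != j in T
#   nearest mean:          1 - mean over i in T of min_{j != i} D_ij
#   weighted nearest mean: 1 - sum over i of p_i * min_{j != i} D_ij,
#                          p_i renormalized over T by default
# All are undefined (NA) when fewer than two MAGs are detected.

#' Detect MAGs at a time point
#'
#' A MAG is detected when its relative abundance is strictly greater than
#' the threshold; a value exactly at the threshold is excluded.
#'
#' @param abundances named nonnegative numeric vector (one abundance row).
#' @param threshold detection threshold as a fraction (default 0.001, the
#'   0.1% convention).
#' @return a list of class \code{"detected_set"} with elements \code{mags}
#'   (character, possibly empty), \code{n}, and \code{p} (abundances of the
#'   detected MAGs, not renormalized).
#' @export
detect_mags <- function(abundances, threshold = 0.001) {
  abundances <- validate_composition(abundances)
  if (is.null(names(abundances))) {
    stop("abundance vector must be named by MAG id", call. = FALSE)
  }
  keep <- abundances > threshold
  structure(list(mags = names(abundances)[keep],
                 n = sum(keep),
                 p = abundances[keep]),
            class = "detected_set")
}

as_detected <- function(T) {
  if (inherits(T, "detected_set")) return(T)
  if (is.character(T)) return(structure(list(mags = T, n = length(T), p = NULL),
                                        class = "detected_set"))
  stop("expected a detected_set or a character vector of MAG ids", call. = FALSE)
}

check_members <- function(D, mags) {
  missing <- setdiff(mags, rownames(D))
  if (length(missing)) {
    stop("detected MAG(s) absent from distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

# minimum off-diagonal distance from each member to the rest of the set
nearest_minima <- function(D, mags) {
  sub <- D[mags, mags, drop = FALSE]
  diag(sub) <- NA_real_
  apply(sub, 1L, min, na.rm = TRUE)
}

#' Niche overlap score: overall mean
#'
#' \code{1 - mean(D_ij)} over all pairs of distinct detected MAGs: 0 when all
#' detected repertoires are completely disjoint, 1 when all are identical.
#'
#' @param D validated dissimilarity matrix over MAG ids.
#' @param T a \code{detected_set} (or character vector of MAG ids).
#' @return score in \code{[0, 1]}, or \code{NA} when fewer than two MAGs are
#'   detected.
#' @export
overlap_overall_mean <- function(D, T) {
  T <- as_detected(T)
  if (T$n < 2L) return(NA_real_)
  check_members(D, T$mags)
  sub <- D[T$mags, T$mags]
  1 - sum(sub) / (T$n * (T$n - 1))
}

#' Niche overlap score: nearest-neighbor mean
#'
#' For each detected MAG take the Jaccard distance to its nearest detected
#' neighbor; the score is one minus the mean of these minima. Sensitive to
#' the presence of close functional analogs rather than to overall spread.
#'
#' @inheritParams overlap_overall_mean
#' @return score in \code{[0, 1]}, or \code{NA} when fewer than two MAGs are
#'   detected.
#' @export
overlap_nearest_mean <- function(D, T) {
  T <- as_detected(T)
  if (T$n < 2L) return(NA_real_)
  check_members(D, T$mags)
  1 - mean(nearest_minima(D, T$mags))
}

#' Niche overlap score: abundance-weighted nearest-neighbor mean
#'
#' As [overlap_nearest_mean()], but each MAG's nearest-neighbor distance is
#' weighted by its relative abundance \code{p_i}. By default the weights are
#' renormalized to sum to 1 over the detected set, which keeps the score in
#' \code{[0, 1]} and reduces it to the unweighted index under uniform
#' abundances; \code{weight_normalization = "global"} uses the raw
#' community-wide relative abundances instead.
#'
#' @inheritParams overlap_overall_mean
#' @param weight_normalization \code{"detected_set"} (default) or
#'   \code{"global"}.
#' @return score, or \code{NA} when fewer than two MAGs are detected.
#' @export
overlap_weighted_nearest_mean <- function(D, T,
                                          weight_normalization = c("detected_set", "global")) {
  weight_normalization <- match.arg(weight_normalization)
  T <- as_detected(T)
  if (T$n < 2L) return(NA_real_)
  if (is.null(T$p)) stop("weighted index needs abundances in the detected set", call. = FALSE)
  check_members(D, T$mags)
  p <- T$p
  if (weight_normalization == "detected_set") p <- p / sum(p)
  1 - sum(p * nearest_minima(D, T$mags))
}

#' Niche-overlap series across a time series
#'
#' Applies [detect_mags()] and all three overlap indices at every time point
#' of an abundance table. Time points with fewer than two detected MAGs get
#' \code{NA} scores.
#'
#' @param D validated dissimilarity matrix whose ids cover the table's MAGs.
#' @param a validated abundance table.
#' @param threshold detection threshold (default 0.001).
#' @param weight_normalization passed to [overlap_weighted_nearest_mean()].
#' @return a data.frame of class \code{"overlap_series"} with columns
#'   \code{day}, \code{n_detected}, \code{overall_mean}, \code{nearest_mean},
#'   \code{weighted_nearest_mean}.
#' @export
overlap_series <- function(D, a, threshold = 0.001,
                           weight_normalization = c("detected_set", "global")) {
  weight_normalization <- match.arg(weight_normalization)
  D <- validate_distance_matrix(D)
  a <- validate_abundance_table(a)
  missing <- setdiff(colnames(a), rownames(D))
  if (length(missing)) {
    stop("abundance MAG(s) missing from distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  days <- as.numeric(rownames(a))
  out <- data.frame(day = days,
                    n_detected = NA_integer_,
                    overall_mean = NA_real_,
                    nearest_mean = NA_real_,
                    weighted_nearest_mean = NA_real_)
  for (k in seq_len(nrow(a))) {
    det <- detect_mags(a[k, ], threshold)
    out$n_detected[k] <- det$n
    out$overall_mean[k] <- overlap_overall_mean(D, det)
    out$nearest_mean[k] <- overlap_nearest_mean(D, det)
    out$weighted_nearest_mean[k] <-
      overlap_weighted_nearest_mean(D, det, weight_normalization)
  }
  class(out) <- c("overlap_series", "data.frame")
  out
}
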