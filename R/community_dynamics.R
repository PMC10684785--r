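# Time-series statistics of community change: RPKM-normalized relative
# abundance from read coverage, the windowed abruptness index, consecutive
# Bray-Curtis beta-diversity, Shannon alpha-diversity, and 0-1 rescaling for
# joint display.

#' Relative abundance from genome read coverage
#'
#' Per time point, each MAG's coverage is normalized as reads per kilobase
#' of genome per million mapped reads:
#' \code{RPKM_i = mapped_reads_i / ((genome_length_bp_i / 1e3) * (total_mapped / 1e6))};
#' relative abundance is then \code{RPKM_i / sum_j RPKM_j}.
#'
#' @param cov long-format coverage data.frame (see [read_coverage_table()]).
#' @return validated abundance matrix (day rows ascending, MAG columns).
#' @export
relative_abundance_from_coverage <- function(cov) {
  need <- c("day", "mag_id", "mapped_reads", "genome_length_bp", "total_mapped")
  missing <- setdiff(need, colnames(cov))
  if (length(missing)) {
    stop("coverage table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(cov$genome_length_bp <= 0)) stop("genome_length_bp must be positive", call. = FALSE)
  if (any(cov$mapped_reads < 0)) stop("mapped_reads must be nonnegative", call. = FALSE)
  if (any(cov$total_mapped <= 0)) stop("total_mapped must be positive", call. = FALSE)
  days <- sort(unique(cov$day))
  mags <- unique(cov$mag_id)
  a <- matrix(NA_real_, length(days), length(mags),
              dimnames = list(days, mags))
  for (d in days) {
    sub <- cov[cov$day == d, ]
    if (anyDuplicated(sub$mag_id)) {
      stop("duplicate coverage rows for day ", d, call. = FALSE)
    }
    if (!setequal(sub$mag_id, mags)) {
      stop("day ", d, " does not cover all MAGs", call. = FALSE)
    }
    rpkm <- sub$mapped_reads /
      ((sub$genome_length_bp / 1e3) * (sub$total_mapped / 1e6))
    if (sum(rpkm) == 0) stop("all-zero mapped reads at day ", d, call. = FALSE)
    a[as.character(d), sub$mag_id] <- rpkm / sum(rpkm)
  }
  validate_abundance_table(a)
}

#' Abruptness of community change around a time point
#'
#' Bray-Curtis dissimilarity between the unweighted mean composition of the
#' window of \code{w} days ending at \code{t} (days \code{t - w + 1 ... t})
#' and that of the following \code{w} days (\code{t + 1 ... t + w}). With
#' the default 5-day windows a score above 0.5 marks turnover of more than
#' half of the community between the windows. Defined only when every day of
#' both windows is present in the table.
#'
#' @param a validated daily abundance table.
#' @param t focal day (must match a day label).
#' @param w window length in days (default 5).
#' @return dissimilarity in \code{[0, 1]}, or \code{NA} when either window
#'   is incomplete.
#' @export
abruptness <- function(a, t, w = 5L) {
  a <- validate_abundance_table(a)
  w <- as.integer(w)
  if (w < 1L) stop("window length must be positive", call. = FALSE)
  days <- as.numeric(rownames(a))
  before <- (t - w + 1L):t
  after <- (t + 1L):(t + w)
  if (!all(before %in% days) || !all(after %in% days)) return(NA_real_)
  mean_before <- colMeans(a[match(before, days), , drop = FALSE])
  mean_after <- colMeans(a[match(after, days), , drop = FALSE])
  bray_curtis(mean_before, mean_after)
}

#' Abruptness series over all time points
#'
#' @inheritParams abruptness
#' @return numeric vector aligned with the table's days; \code{NA} where a
#'   window is incomplete (the first \code{w - 1} and last \code{w} days of
#'   a gap-free daily series).
#' @export
abruptness_series <- function(a, w = 5L) {
  a <- validate_abundance_table(a)
  days <- as.numeric(rownames(a))
  vapply(days, function(t) abruptness(a, t, w), numeric(1L))
}

#' Bray-Curtis beta-diversity between consecutive sampled time points
#'
#' \code{beta_next[k]} is the dissimilarity between the compositions at the
#' k-th and (k+1)-th sampled rows, regardless of the day gap between them
#' (sampled-order neighbors); the last time point is \code{NA}.
#'
#' @param a validated abundance table with at least two rows.
#' @return numeric vector aligned with the table's days.
#' @export
consecutive_beta <- function(a) {
  a <- validate_abundance_table(a)
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 time points", call. = FALSE)
  out <- rep(NA_real_, n)
  for (k in seq_len(n - 1L)) {
    out[k] <- bray_curtis(a[k, ], a[k + 1L, ])
  }
  out
}

#' Shannon alpha-diversity of a composition
#'
#' \code{H' = -sum(x_i * log(x_i))} over positive entries; natural log by
#' default (the conventional nats scale in community ecology).
#'
#' @param x nonnegative composition vector.
#' @param base logarithm base (default \code{exp(1)}).
#' @return \code{H' >= 0}.
#' @export
shannon <- function(x, base = exp(1)) {
  x <- validate_composition(x)
  if (sum(x) == 0) stop("Shannon diversity undefined for an all-zero composition", call. = FALSE)
  p <- x[x > 0]
  -sum(p * log(p, base = base))
}

#' Rescale a series to the unit interval
#'
#' \code{(v - min) / (max - min)} over the defined values; \code{NA}s are
#' preserved. The minimum maps exactly to 0 and the maximum to 1.
#'
#' @param v numeric vector with at least two distinct defined values.
#' @return rescaled vector.
#' @export
rescale01 <- function(v) {
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("need at least 2 defined values to rescale", call. = FALSE)
  lo <- min(v[ok]); hi <- max(v[ok])
  if (hi == lo) stop("cannot rescale a constant series (zero range)", call. = FALSE)
  (v - lo) / (hi - lo)
}

#' Community-dynamics series
#'
#' Per time point: Bray-Curtis beta-diversity to the next sampled time point
#' (\code{beta_next}), the windowed abruptness index (only defined where the
#' table contains every day of both windows, i.e. for dense daily series),
#' Shannon alpha-diversity, and 0-1 rescaled copies of each for joint
#' display.
#'
#' @param a validated abundance table.
#' @param window abruptness window length in days (default 5).
#' @param shannon_base logarithm base for Shannon diversity.
#' @param rescale add \code{*_rescaled} columns (default TRUE). A series
#'   that is constant or has fewer than two defined values gets an
#'   all-\code{NA} rescaled column with a warning.
#' @return a data.frame of class \code{"dynamics_series"}.
#' @export
dynamics_series <- function(a, window = 5L, shannon_base = exp(1),
                            rescale = TRUE) {
  a <- validate_abundance_table(a)
  out <- data.frame(day = as.numeric(rownames(a)),
                    beta_next = consecutive_beta(a),
                    abruptness = abruptness_series(a, window),
                    alpha = apply(a, 1L, shannon, base = shannon_base))
  rownames(out) <- NULL
  if (rescale) {
    for (col in c("beta_next", "abruptness", "alpha")) {
      r <- tryCatch(rescale01(out[[col]]), error = function(e) {
        warning("cannot rescale '", col, "': ", conditionMessage(e), call. = FALSE)
        rep(NA_real_, nrow(out))
      })
      out[[paste0(col, "_rescaled")]] <- r
    }
  }
  class(out) <- c("dynamics_series", "data.frame")
  out
}
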