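# The inferential step: ordinary least-squares regression of community
# change (or alpha-diversity) on a niche-overlap index, with a two-sided
# t-test on the slope and a 95% confidence band for the mean response.

#' OLS regression of a response on a niche-overlap index
#'
#' Fits \code{y ~ x} by ordinary least squares and reports the slope,
#' intercept, coefficient of determination, the two-sided p-value of the
#' zero-slope t-test, and a pointwise confidence band for the mean response
#' at the observed predictor values. \code{NA} pairs are dropped first.
#'
#' @param x predictor series (e.g. an overlap index per time point).
#' @param y response series (e.g. Bray-Curtis change to the next time
#'   point, or Shannon alpha-diversity).
#' @param conf_level confidence level for the band (default 0.95).
#' @return an object of class \code{"overlap_regression"}: a list with
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{p_value},
#'   \code{n}, \code{conf_level}, and \code{band} (data.frame \code{x},
#'   \code{fit}, \code{lower}, \code{upper}, sorted by \code{x}).
#' @export
overlap_regression <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in the predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ord <- order(x)
  ci <- stats::predict(fit, newdata = data.frame(x = x[ord]),
                       interval = "confidence", level = conf_level)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2L, 4L],
                 n = n,
                 conf_level = conf_level,
                 band = data.frame(x = x[ord], fit = ci[, "fit"],
                                   lower = ci[, "lwr"], upper = ci[, "upr"])),
            class = "overlap_regression")
}

#' @export
print.overlap_regression <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, R^2 %.3f, p %.4g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Pair overlap scores with subsequent community change
#'
#' Pairs the overlap index at time point k with the compositional change
#' from k to k + 1 (\code{beta_next} at k): the pairing is lagged, asking
#' whether overlap precedes change, not whether the two co-vary at the same
#' instant. The last time point (no next point) and any \code{NA} on either
#' side are dropped.
#'
#' @param o an \code{overlap_series} data.frame (see [overlap_series()]).
#' @param d a \code{dynamics_series} data.frame on the same time points.
#' @param index which overlap column to pair (default all three).
#' @return data.frame with columns \code{day}, one column per requested
#'   index, and \code{beta_next}; rows with any \code{NA} removed.
#' @export
pair_overlap_with_change <- function(o, d,
                                     index = c("overall_mean", "nearest_mean",
                                               "weighted_nearest_mean")) {
  index <- match.arg(index, several.ok = TRUE)
  if (!all(index %in% colnames(o))) stop("overlap series lacks requested index", call. = FALSE)
  if (!("beta_next" %in% colnames(d))) stop("dynamics series lacks beta_next", call. = FALSE)
  if (!setequal(o$day, d$day)) {
    stop("overlap and dynamics series cover different time points", call. = FALSE)
  }
  d <- d[match(o$day, d$day), ]
  out <- data.frame(day = o$day, o[index], beta_next = d$beta_next)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}
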