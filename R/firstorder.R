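#' Discretization specification for texture analysis
#'
#' @param mode `"fixed-bin-count"` (default) or `"fixed-bin-width"`.
#' @param bins positive integer number of grey levels (default 32).
#' @param width bin width in intensity units (fixed-bin-width mode).
#' @return list of class `apv_discretization`.
#' @export
discretization_spec <- function(mode = c("fixed-bin-count", "fixed-bin-width"),
                                bins = 32L, width = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed-bin-count") {
    bins <- as.integer(bins)
    if (is.na(bins) || bins < 2L)
      stop_apv("apv_validation_error", "bins must be an integer >= 2")
  } else if (is.null(width) || !is.finite(width) || width <= 0) {
    stop_apv("apv_validation_error", "width must be positive")
  }
  structure(list(mode = mode, bins = bins, width = width),
            class = "apv_discretization")
}

#' Discretize region intensities into integer grey levels
#'
#' Fixed-bin-count mode uses equal-width bins spanning the region's own
#' `[min, max]`; bins are half-open with the last bin closed, so the maximum
#' maps to the top level. A constant region collapses to a single level.
#'
#' @param x numeric vector of region intensities (non-empty).
#' @param spec a [discretization_spec()].
#' @return integer vector of levels in `1..L`, with attribute `nlevels`.
#' @export
discretize <- function(x, spec = discretization_spec()) {
  if (!length(x))
    stop_apv("apv_empty_region_error", "cannot discretize an empty region")
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0)
    return(structure(rep(1L, length(x)), nlevels = 1L))
  if (spec$mode == "fixed-bin-count") {
    L <- spec$bins
    w <- (hi - lo) / L
    lev <- pmin(as.integer(floor((x - lo) / w)) + 1L, L)
  } else {
    lev <- as.integer(floor((x - lo) / spec$width)) + 1L
    L <- max(lev)
  }
  structure(lev, nlevels = as.integer(L))
}

FIRSTORDER_NAMES <- c("mean", "median", "sd", "variance", "min", "max",
                      "range", "p10", "p90", "iqr", "skewness", "kurtosis",
                      "energy", "rms", "mad", "entropy", "uniformity",
                      "robust_mean")

#' First-order intensity statistics of a region
#'
#' Eighteen scalars. Moments use the population convention
#' (skewness `m3/m2^1.5`, kurtosis `m4/m2^2`, both 0 on a constant region);
#' `sd`/`variance` use the sample (n-1) convention. `entropy` (bits) and
#' `uniformity` are computed on the discretized level histogram, so a
#' constant region has entropy 0 and uniformity 1. `robust_mean` averages the
#' values inside the `[p10, p90]` band; `mad` is the mean absolute deviation
#' from the mean.
#'
#' @param x numeric vector of region intensities (non-empty).
#' @param spec discretization used for entropy/uniformity.
#' @return named numeric vector of length 18.
#' @export
firstorder_features <- function(x, spec = discretization_spec()) {
  if (!length(x))
    stop_apv("apv_empty_region_error", "empty region has no intensity features")
  n <- length(x)
  m <- mean(x)
  cx <- x - m
  m2 <- mean(cx^2)
  qs <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  lev <- discretize(x, spec)
  p <- tabulate(lev, attr(lev, "nlevels")) / n
  p <- p[p > 0]
  inband <- x >= qs[1] & x <= qs[4]
  c(mean = m,
    median = median(x),
    sd = if (n > 1) sd(x) else 0,
    variance = if (n > 1) var(x) else 0,
    min = min(x), max = max(x), range = max(x) - min(x),
    p10 = qs[1], p90 = qs[4], iqr = qs[3] - qs[2],
    skewness = if (m2 > 0) mean(cx^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(cx^4) / m2^2 else 0,
    energy = sum(x^2),
    rms = sqrt(mean(x^2)),
    mad = mean(abs(cx)),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2),
    robust_mean = if (any(inband)) mean(x[inband]) else m)
}
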