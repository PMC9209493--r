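# Coiflet-1 analysis filters (6 taps). The low-pass sums to sqrt(2); the
# high-pass is the quadrature mirror and sums to 0, so every channel with an
# H along some axis annihilates constants.
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
               0.3848648468648578,    0.8525720202116004,
               0.3378976624574818,   -0.07273261951252645)
COIF1_HI <- c( 0.07273261951252645,   0.3378976624574818,
              -0.8525720202116004,    0.3848648468648578,
               0.07273261951252645,  -0.015655728135791993)

#' Filter a 3D array along one axis (correlation form, symmetric padding)
#'
#' `out[i] = sum_k kern[k] * x[i + k - 1 - padL]` with half-sample symmetric
#' boundary extension (edge value repeated), output the same length as the
#' input — the building block of the stationary wavelet bank and of the
#' phantom generator's Gaussian smoothing.
#'
#' @param arr 3D numeric array.
#' @param kern numeric filter taps.
#' @param axis axis to filter along (1, 2 or 3).
#' @return filtered array, same shape.
#' @export
filter_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  L <- length(kern)
  n <- d[axis]
  if (n < L)
    stop_apv("apv_size_error",
             "axis %d has length %d < filter length %d", axis, n, L)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dim(x) <- c(n, prod(d[-axis]))
  padL <- (L - 1L) %/% 2L
  padR <- L - 1L - padL
  ext <- c(rev(seq_len(padL)), seq_len(n), n + 1L - seq_len(padR))
  xp <- x[ext, , drop = FALSE]
  y <- matrix(0, n, ncol(x))
  for (k in seq_len(L)) y <- y + kern[k] * xp[k:(k + n - 1L), , drop = FALSE]
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

#' One-level stationary 3D wavelet filter bank
#'
#' Separable undecimated (stationary) transform: each channel applies the
#' low-pass (L) or high-pass (H) analysis filter along each of the three
#' axes, in channel-label order (axis 1, axis 2, axis 3). Every channel has
#' the same shape as the input. Default family is coiflet-1 with symmetric
#' boundary padding.
#'
#' @param vol an `apv_volume`.
#' @param filters list with elements `lo` and `hi` (analysis filter taps).
#' @return named list of 8 `apv_volume` channels:
#'   LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH.
#' @export
wavelet_bank <- function(vol, filters = list(lo = COIF1_LO, hi = COIF1_HI)) {
  combos <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- vector("list", 8)
  names(out) <- combos
  # factor the separable transform: filter axis by axis, sharing prefixes
  ax1 <- list(L = filter_axis(vol$grid, filters$lo, 1),
              H = filter_axis(vol$grid, filters$hi, 1))
  for (c1 in c("L", "H")) {
    ax2 <- list(L = filter_axis(ax1[[c1]], filters$lo, 2),
                H = filter_axis(ax1[[c1]], filters$hi, 2))
    for (c2 in c("L", "H")) for (c3 in c("L", "H")) {
      kern <- if (c3 == "L") filters$lo else filters$hi
      out[[paste0(c1, c2, c3)]] <-
        apv_volume(filter_axis(ax2[[c2]], kern, 3), vol$spacing, vol$origin)
    }
  }
  out
}
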