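# Enhancement kinetics and first-order intensity statistics of the lesion.

#' Whole-lesion enhancement and absorption rates
#'
#' With `S_i` the mean lesion-pixel grayscale of phase i, the enhancement
#' rate is `ER_i0 = S_i / S_0` and the absorption rate is
#' `AR_i0 = (S_i - S_0) / S_0 * 100` (percent), for i in {1, 2}. By
#' construction `AR_i0 = (ER_i0 - 1) * 100` exactly.
#'
#' @param s0,s1,s2 Mean lesion grayscales of phases T0, T1, T2; `s0 > 0`.
#' @return Named vector `(ER_10, AR_10, ER_20, AR_20)` (labels T10-T13 of
#'   the feature schema).
#' @export
kinetic_whole <- function(s0, s1, s2) {
  if (s0 <= 0) abort("baseline lesion mean S0 must be > 0", "feature_error")
  er1 <- s1 / s0
  er2 <- s2 / s0
  c(ER_10 = er1, AR_10 = (er1 - 1) * 100,
    ER_20 = er2, AR_20 = (er2 - 1) * 100)
}

#' Pixel-wise enhancement statistics between two phases
#'
#' For every lesion pixel with positive intensity at the earlier phase, the
#' per-pixel enhancement `R = (I_T - I_t) / I_t` is computed; the function
#' returns the population standard deviation, mean and maximum of the set
#' of R values.
#'
#' @param phase_T,phase_t Later / earlier phase image matrices.
#' @param mask Logical lesion mask.
#' @return Named vector `(std, mean, max)`.
#' @export
kinetic_pixelwise <- function(phase_T, phase_t, mask) {
  if (!any(mask)) abort("empty mask", "feature_error")
  iT <- phase_T[mask]
  it <- phase_t[mask]
  keep <- it > 0
  if (!any(keep))
    abort("all lesion pixels are zero at the earlier phase", "feature_error")
  r <- (iT[keep] - it[keep]) / it[keep]
  c(std = pop_sd(r), mean = mean(r), max = max(r))
}

#' First-order intensity statistics of a lesion
#'
#' Over the lesion pixel grayscales: arithmetic mean, population standard
#' deviation, Shannon entropy of the 256-bin histogram (log base 2), the
#' maximum, bias (skewness, third standardized moment) and peak (excess
#' kurtosis). When the standard deviation is 0 both bias and peak are 0 by
#' convention.
#'
#' @param image Grayscale matrix with integer-valued intensities in 0..255
#'   (values are rounded into bins for the entropy term).
#' @param mask Logical lesion mask.
#' @return Named vector `(mean, std, entropy, max, bias, peak)`.
#' @export
stats_features <- function(image, mask) {
  if (!any(mask)) abort("empty mask", "feature_error")
  v <- image[mask]
  m <- mean(v)
  s <- pop_sd(v)
  h <- tabulate(pmin(255L, pmax(0L, as.integer(round(v)))) + 1L, nbins = 256)
  p <- h[h > 0] / sum(h)
  entropy <- -sum(p * log2(p))
  if (s <= .Machine$double.eps) {
    bias <- 0; peak <- 0
  } else {
    z <- (v - m) / s
    bias <- mean(z^3)
    peak <- mean(z^4) - 3
  }
  c(mean = m, std = s, entropy = entropy, max = max(v), bias = bias, peak = peak)
}
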