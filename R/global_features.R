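#' Global (histogram) texture features of masked intensities
#'
#' First-order moments of the raw (unquantized) in-mask intensity
#' distribution, with population (denominator `N_v`) moments:
#' variance, skewness, and excess kurtosis (so a Gaussian scores 0).
#' For a constant region all three are 0 by convention.
#'
#' @param volume a [volume_grid()] or bare 3D numeric array.
#' @param mask a [label_mask()] or logical array.
#' @param compartment mask compartment (ignored for logical masks).
#' @return Named numeric vector `Varianceglobal`, `Skewness`, `Kurtosis`.
#' @export
global_features <- function(volume, mask, compartment = "integral") {
  vals <- unclass(volume)
  sel <- if (is.logical(mask)) mask else mask_select(mask, compartment)
  if (!identical(dim(vals), dim(sel))) stop("volume and mask shapes differ")
  x <- vals[sel]
  if (!length(x)) stop("mask is empty")
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  if (v <= 0)
    return(c(Varianceglobal = 0, Skewness = 0, Kurtosis = 0))
  s <- sum((x - mu)^3) / n / v^1.5
  k <- sum((x - mu)^4) / n / v^2 - 3
  c(Varianceglobal = v, Skewness = s, Kurtosis = k)
}
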