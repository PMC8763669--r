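#' Compute a proton density fat fraction map from water and fat signals
#'
#' The PDFF at each voxel is the fat signal as a fraction of the total
#' (fat + water) signal, expressed in percent: `100 * F / (F + W)`.
#' Voxels where both signals are zero carry no fat-fraction information and
#' are set to 0%; their count is attached as the `n_zero_signal` attribute.
#' Results are clipped to the physical range [0, 100].
#'
#' @param fat,water [volume_grid()]s of modality `"fat"` and `"water"`, on the
#'   same grid, both non-negative.
#' @return A [volume_grid()] of modality `"PDFF"` (percent), with attribute
#'   `n_zero_signal`.
#' @examples
#' f <- volume_grid(array(1, c(3, 3, 3)), modality = "fat")
#' w <- volume_grid(array(3, c(3, 3, 3)), modality = "water")
#' compute_pdff(f, w)[1, 1, 1]  # 25
#' @export
compute_pdff <- function(fat, water) {
  check_same_grid(fat, water)
  if (any(fat < 0) || any(water < 0))
    stop("fat and water signals must be non-negative")
  total <- unclass(fat) + unclass(water)
  zero <- total == 0
  pdff <- array(0, dim = dim(fat))
  pdff[!zero] <- 100 * unclass(fat)[!zero] / total[!zero]
  pdff <- pmin(pmax(pdff, 0), 100)
  out <- volume_grid(array(pdff, dim = dim(fat)),
                     spacing = attr(fat, "spacing"), modality = "PDFF")
  attr(out, "n_zero_signal") <- sum(zero)
  out
}

#' Convert CT attenuation to volumetric bone mineral density
#'
#' Applies the linear (asynchronous) calibration `vBMD = slope * HU +
#' intercept` voxelwise. The calibration coefficients come from the scanner's
#' phantom calibration and are supplied in the run configuration.
#'
#' @param ct a [volume_grid()] of modality `"CT"` (Hounsfield units).
#' @param slope calibration slope in mg/cm^3 per HU; must be non-zero.
#' @param intercept calibration intercept in mg/cm^3.
#' @return A [volume_grid()] of modality `"vBMD"` (mg/cm^3).
#' @export
hu_to_vbmd <- function(ct, slope, intercept) {
  if (attr(ct, "modality") != "CT")
    stop("hu_to_vbmd expects a CT volume")
  if (!is.numeric(slope) || length(slope) != 1L || slope == 0)
    stop("calibration slope must be a single non-zero number")
  volume_grid(array(slope * unclass(ct) + intercept, dim = dim(ct)),
              spacing = attr(ct, "spacing"), modality = "vBMD")
}

#' Mean of a quantitative map under a mask compartment
#'
#' Level-wise extraction: the arithmetic mean of all voxel values under the
#' selected compartment of the label mask. An empty selection marks the
#' vertebra for exclusion rather than crashing: the function returns `NA`
#' with a warning, and callers drop the vertebra from downstream tables.
#'
#' @param volume a [volume_grid()].
#' @param mask a [label_mask()] on the same grid.
#' @param compartment `"integral"` (whole vertebral body) or `"trabecular"`.
#' @return Scalar mean, or `NA_real_` if the selection is empty.
#' @export
mask_mean <- function(volume, mask, compartment = "integral") {
  check_same_grid(volume, mask)
  sel <- mask_select(mask, compartment)
  if (!any(sel)) {
    warning("empty mask selection for compartment '", compartment,
            "'; vertebra excluded")
    return(NA_real_)
  }
  mean(unclass(volume)[sel])
}
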