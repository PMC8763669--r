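#' Quantize masked intensities to a fixed number of gray levels
#'
#' Equal-width binning of the in-mask intensity range [min, max] into
#' `n_levels` bins, the dominant fixed-bin-count convention in radiomics.
#' In-mask voxels get levels 1..`n_levels` (the maximum value falls in the
#' top bin); voxels outside the mask are 0. A constant region maps wholly to
#' level 1. The level map is invariant under affine rescaling of the input
#' intensities (with positive gain), since binning is relative to the
#' region's own min-max range.
#'
#' @param volume a [volume_grid()] (or bare 3D numeric array).
#' @param mask a [label_mask()] (or logical/integer array); in-mask is
#'   `mask >= 1`.
#' @param n_levels number of gray levels, >= 2.
#' @param compartment which mask compartment to quantize over.
#' @return An object of class `quantized_region`: list with `levels`
#'   (integer 3D array), `n_levels`, `n_voxels` (mask voxel count), `range`
#'   (in-mask min/max of the raw values).
#' @export
quantize <- function(volume, mask, n_levels = 32L,
                     compartment = "integral") {
  if (n_levels < 2L) stop("n_levels must be >= 2")
  vals <- unclass(volume)
  sel <- if (is.logical(mask)) mask else mask_select(mask, compartment)
  if (!identical(dim(vals), dim(sel))) stop("volume and mask shapes differ")
  nv <- sum(sel)
  if (nv < 1L) stop("mask is empty")
  x <- vals[sel]
  lo <- min(x); hi <- max(x)
  lev <- array(0L, dim = dim(vals))
  if (hi == lo) {
    lev[sel] <- 1L  # degenerate range: single gray level
  } else {
    width <- (hi - lo) / n_levels
    q <- floor((x - lo) / width) + 1
    lev[sel] <- as.integer(pmin(q, n_levels))
  }
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 n_voxels = nv, range = c(lo, hi)),
            class = "quantized_region")
}

#' @export
print.quantized_region <- function(x, ...) {
  cat(sprintf("<quantized_region> %d gray levels, %d masked voxels\n",
              x$n_levels, x$n_voxels))
  invisible(x)
}
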