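#' 3D scalar volume with voxel spacing and modality tag
#'
#' A `volume_grid` is the package's container for a single 3D scalar field:
#' a CT attenuation volume in Hounsfield units, a water or fat signal volume
#' in arbitrary units, or a derived quantitative map (PDFF in percent,
#' T2* in milliseconds, vBMD in mg/cm^3).
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm.
#' @param modality one of `"CT"`, `"water"`, `"fat"`, `"PDFF"`, `"T2star"`,
#'   `"vBMD"`.
#' @return An object of class `volume_grid`: the array with `spacing` and
#'   `modality` attributes.
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 4)), spacing = c(1.8, 1.8, 1.8), "CT")
#' dim(v)
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1),
                        modality = c("CT", "water", "fat", "PDFF",
                                     "T2star", "vBMD")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!all(is.finite(values)))
    stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive lengths in mm")
  structure(values, spacing = spacing, modality = modality,
            class = c("volume_grid", "array"))
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s, %s voxels, spacing %s mm\n",
              attr(x, "modality"), paste(dim(x), collapse = "x"),
              paste(signif(attr(x, "spacing"), 4), collapse = "x")))
  invisible(x)
}

#' Integer label mask on a voxel grid
#'
#' Labels encode vertebra level and compartment. By convention the mask of a
#' single vertebra uses label 1 for the integral (whole vertebral body)
#' region and label 2 for the trabecular compartment nested inside it, with 0
#' outside; the trabecular voxels carry label 2 only, so the integral region
#' is `labels >= 1`.
#'
#' @param labels integer 3D array, values >= 0.
#' @param spacing voxel spacing in mm (must match the volume it masks).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive lengths in mm")
  structure(labels, spacing = spacing, class = c("label_mask", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s voxels, labels {%s}\n",
              paste(dim(x), collapse = "x"),
              paste(sort(unique(as.integer(x))), collapse = ",")))
  invisible(x)
}

# Logical in-mask selector for a (label_mask, compartment) pair.
# compartment "integral" selects labels >= 1 (trabecular is nested inside the
# vertebral body), "trabecular" selects label 2 exactly.
mask_select <- function(mask, compartment = c("integral", "trabecular")) {
  compartment <- match.arg(compartment)
  if (compartment == "integral") mask >= 1L else mask == 2L
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("grids differ in shape: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  sa <- attr(a, "spacing"); sb <- attr(b, "spacing")
  if (!is.null(sa) && !is.null(sb) && max(abs(sa - sb)) > 1e-6)
    stop("grids differ in voxel spacing; resampling is refused")
  invisible(TRUE)
}

#' Read and write volumes and masks as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that preserve shape, spacing and values
#' (bit-exact for integer masks, to floating-point precision for scalar
#' volumes).
#'
#' @param path file path, conventionally `.nii.gz`.
#' @param modality modality tag attached on read (see [volume_grid()]).
#' @return `read_volume` a [volume_grid()]; `read_mask` a [label_mask()].
#' @name volume_io
NULL

#' @rdname volume_io
#' @param volume a [volume_grid()] to write.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(unclass(volume))
  RNifti::pixdim(img) <- attr(volume, "spacing")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_volume <- function(path, modality = "CT") {
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim = dim(img)),
              spacing = RNifti::pixdim(img)[1:3], modality = modality)
}

#' @rdname volume_io
#' @param mask a [label_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(unclass(mask))
  RNifti::pixdim(img) <- attr(mask, "spacing")
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname volume_io
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  label_mask(array(as.integer(img), dim = dim(img)),
             spacing = RNifti::pixdim(img)[1:3])
}
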