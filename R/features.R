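#' Texture feature menus per modality
#'
#' CT-based analysis carries all 24 features (3 global + 8 GLCM + 13 GLRLM);
#' the water-fat-MRI (PDFF) analysis carries the 11 global + GLCM features
#' only.
#'
#' @param modality `"CT"` or `"PDFF"`.
#' @param prefixed prepend `"CT_"` / `"PDFF_"` as used in feature tables.
#' @return Character vector of feature names.
#' @export
feature_names <- function(modality = c("CT", "PDFF"), prefixed = TRUE) {
  modality <- match.arg(modality)
  glob <- c("Varianceglobal", "Skewness", "Kurtosis")
  glcm <- c("Energy", "Contrast", "Entropy", "Homogeneity", "Correlation",
            "SumAverage", "Variance", "Dissimilarity")
  glrlm <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGLRE", "HGLRE",
             "SRLGLE", "SRHGLE", "LRLGLE", "LRHGLE", "GLV", "RLV")
  nm <- if (modality == "CT") c(glob, glcm, glrlm) else c(glob, glcm)
  if (prefixed) paste0(modality, "_", nm) else nm
}

#' Extract the full texture feature vector of one vertebra
#'
#' Runs the complete texture pipeline on one masked volume: global histogram
#' moments on the raw intensities, quantization to `n_levels` gray levels,
#' 13-direction GLCM (averaged into one rotation-invariant matrix by
#' default, or per-direction features averaged when
#' `glcm_mode = "average_features"`), and — for CT only — the 13-direction
#' merged GLRLM. Feature names are prefixed with the modality as they appear
#' in the cohort feature table.
#'
#' @param volume a [volume_grid()] (CT volume in HU, or PDFF map in percent).
#' @param mask a [label_mask()] on the same grid.
#' @param modality `"CT"` (24 features) or `"PDFF"` (11 features).
#' @param n_levels gray levels for quantization (default 32).
#' @param length_weighting weight merged directions by 1/length (default on).
#' @param glcm_mode average the 13 matrices then compute features
#'   (`"average_matrix"`, default) or average the 13 per-direction feature
#'   vectors (`"average_features"`).
#' @param entropy_base base for GLCM entropy (default 2, bits).
#' @param glv_variant GLV/RLV normalization, see [glrlm_features()].
#' @param compartment mask compartment the features are computed over.
#' @return Named numeric vector (24 for CT, 11 for PDFF).
#' @export
extract_feature_vector <- function(volume, mask,
                                   modality = c("CT", "PDFF"),
                                   n_levels = 32L,
                                   length_weighting = TRUE,
                                   glcm_mode = c("average_matrix",
                                                 "average_features"),
                                   entropy_base = 2,
                                   glv_variant = "probability",
                                   compartment = "integral") {
  modality <- match.arg(modality)
  glcm_mode <- match.arg(glcm_mode)
  check_same_grid(volume, mask)
  dirs <- enumerate_directions()
  glob <- global_features(volume, mask, compartment)
  q <- quantize(volume, mask, n_levels, compartment)
  per_dir <- lapply(seq_len(nrow(dirs)), function(k)
    build_glcm(q, c(dirs$dx[k], dirs$dy[k], dirs$dz[k])))
  if (glcm_mode == "average_matrix") {
    glcm <- glcm_features(average_glcm(per_dir, dirs, length_weighting),
                          entropy_base = entropy_base)
  } else {
    w <- if (length_weighting) 1 / dirs$length else rep(1, nrow(dirs))
    fmat <- vapply(per_dir, glcm_features, numeric(8),
                   entropy_base = entropy_base)
    glcm <- as.numeric(fmat %*% w) / sum(w)
    names(glcm) <- rownames(fmat)
  }
  out <- c(glob, glcm)
  if (modality == "CT") {
    rlm <- build_glrlm(q, dirs, length_weighting)
    out <- c(out, glrlm_features(rlm, variant = glv_variant))
  }
  names(out) <- paste0(modality, "_", names(out))
  out
}
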