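#' Gray-level co-occurrence matrix for a single offset
#'
#' Counts all ordered voxel pairs (v, v + d) with both endpoints inside the
#' mask, symmetrizes by adding the transpose (identifying the offset with its
#' opposite), and normalizes to sum 1 — the joint probability of two adjacent
#' gray levels at offset `d`. Pairs never cross the mask boundary: a pair
#' contributes only if both voxels are in-mask.
#'
#' @param q a [quantize()]d region.
#' @param offset integer length-3 offset `(dx, dy, dz)`, typically a row of
#'   [enumerate_directions()].
#' @return An object of class `co_matrix`: list with `P` (n_levels x
#'   n_levels, sums to 1, symmetric), `n_pairs` (raw symmetric pair count),
#'   and `offset`.
#' @export
build_glcm <- function(q, offset) {
  stopifnot(inherits(q, "quantized_region"), length(offset) == 3L)
  lev <- q$levels
  dm <- dim(lev)
  sx <- src_range(dm[1], offset[1])
  sy <- src_range(dm[2], offset[2])
  sz <- src_range(dm[3], offset[3])
  if (!length(sx) || !length(sy) || !length(sz))
    stop("offset larger than volume; no pairs")
  a <- lev[sx, sy, sz, drop = FALSE]
  b <- lev[sx + offset[1], sy + offset[2], sz + offset[3], drop = FALSE]
  ok <- a > 0L & b > 0L
  if (!any(ok))
    stop("no in-mask voxel pair under offset (",
         paste(offset, collapse = ","), ")")
  ng <- q$n_levels
  counts <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
  C <- matrix(counts, nrow = ng, ncol = ng, byrow = TRUE)
  C <- C + t(C)  # identify d with -d
  structure(list(P = C / sum(C), n_pairs = sum(C), offset = as.integer(offset)),
            class = "co_matrix")
}

# valid source indices along one axis for displacement d
src_range <- function(n, d) seq.int(max(1L, 1L - d), min(n, n - d))

#' Average per-direction co-occurrence matrices
#'
#' Merges the 13 single-direction matrices into one rotation-invariant
#' matrix. With `length_weighting` on (the default) each matrix is weighted
#' by the reciprocal of its offset's Euclidean length, so that directions
#' whose discretization step is physically longer (face and space diagonals)
#' contribute per unit length rather than per step; with it off the mean is
#' uniform. The result is renormalized to sum 1.
#'
#' @param glcms list of `co_matrix` objects (normalized, same size).
#' @param directions the matching [enumerate_directions()] rows.
#' @param length_weighting logical; weights proportional to 1/length.
#' @return A `co_matrix` with `offset = NA` and provenance
#'   `n_directions`.
#' @export
average_glcm <- function(glcms, directions = enumerate_directions(),
                         length_weighting = TRUE) {
  stopifnot(length(glcms) == nrow(directions))
  ng <- nrow(glcms[[1]]$P)
  for (g in glcms)
    if (!all(dim(g$P) == ng)) stop("co-occurrence matrix shape mismatch")
  w <- if (length_weighting) 1 / directions$length else rep(1, nrow(directions))
  P <- Reduce(`+`, Map(function(g, wi) wi * g$P, glcms, w))
  P <- P / sum(P)
  np <- sum(unlist(lapply(glcms, function(g) g$n_pairs)))
  structure(list(P = P, n_pairs = np,
                 offset = NA, n_directions = nrow(directions),
                 length_weighting = length_weighting),
            class = "co_matrix")
}

#' GLCM texture features
#'
#' Second-order features of a normalized symmetric co-occurrence matrix
#' `p(i, j)` over gray levels `i, j = 1..N_g`:
#' \describe{
#'   \item{Energy}{`sum p^2` — uniformity of the co-occurrence distribution.}
#'   \item{Contrast}{`sum (i - j)^2 p` — local intensity variation.}
#'   \item{Entropy}{`-sum p log2 p` over positive entries (bits) —
#'     randomness.}
#'   \item{Homogeneity}{`sum p / (1 + |i - j|)`.}
#'   \item{Correlation}{`(sum ij p - mu_x mu_y) / (sigma_x sigma_y)` with
#'     marginal moments from the row/column sums; 0 when a marginal is
#'     degenerate.}
#'   \item{SumAverage}{`sum (i + j) p`.}
#'   \item{Variance}{`sum (i - mu)^2 p` with `mu = sum i p_x(i)`.}
#'   \item{Dissimilarity}{`sum |i - j| p` — heterogeneity.}
#' }
#'
#' @param glcm a `co_matrix` (normalized; see [build_glcm()]).
#' @param entropy_base base of the entropy logarithm (default 2, bits).
#' @return Named numeric vector of the 8 GLCM features.
#' @export
glcm_features <- function(glcm, entropy_base = 2) {
  P <- glcm$P
  if (abs(sum(P) - 1) > 1e-8) stop("co-occurrence matrix is not normalized")
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)        # row index
  j <- t(i)                               # column index
  px <- rowSums(P)
  mu_x <- sum(seq_len(ng) * px)
  var_x <- sum((seq_len(ng) - mu_x)^2 * px)
  # symmetric P: x and y marginals coincide
  corr <- if (var_x <= 0) 0 else (sum(i * j * P) - mu_x^2) / var_x
  pos <- P > 0
  c(Energy       = sum(P^2),
    Contrast     = sum((i - j)^2 * P),
    Entropy      = -sum(P[pos] * log(P[pos], base = entropy_base)),
    Homogeneity  = sum(P / (1 + abs(i - j))),
    Correlation  = corr,
    SumAverage   = sum((i + j) * P),
    Variance     = var_x,
    Dissimilarity = sum(abs(i - j) * P))
}
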