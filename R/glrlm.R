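#' Gray-level run-length matrix over merged 3D directions
#'
#' A gray-level run is a maximal set of successive in-mask voxels with
#' identical (quantized) gray level arranged collinearly along a lattice
#' direction; the run length is its voxel count. A run is broken where the
#' lattice line leaves the volume, leaves the mask, or the gray level
#' changes. Runs are scanned along every lattice line of each requested
#' direction and the per-direction count matrices `r(i, j)` (gray level `i`,
#' run length `j`) are summed. With `length_weighting` on (default) each
#' direction's counts are scaled by the reciprocal of its offset's Euclidean
#' length before summation, so physically longer diagonal steps contribute
#' per unit length.
#'
#' @param q a [quantize()]d region.
#' @param directions rows of [enumerate_directions()] (default all 13); a
#'   single-row subset gives a single-direction matrix.
#' @param length_weighting logical; scale each direction by 1/length.
#' @return An object of class `run_length_matrix`: list with `R` (n_levels x
#'   max-run-length matrix of possibly weighted counts), `n_runs` (sum of
#'   `R`), `n_runs_raw` (unweighted run count), `n_voxels`, `weight_total`
#'   (sum of direction weights; equals the direction count when unweighted),
#'   `n_directions`.
#' @export
build_glrlm <- function(q, directions = enumerate_directions(),
                        length_weighting = TRUE) {
  stopifnot(inherits(q, "quantized_region"))
  if (q$n_voxels < 1L) stop("mask is empty")
  lev <- q$levels
  dm <- dim(lev)
  ng <- q$n_levels
  lmax <- max(dm)
  R <- matrix(0, nrow = ng, ncol = lmax)
  n_runs_raw <- 0
  w <- if (length_weighting) 1 / directions$length else rep(1, nrow(directions))
  for (k in seq_len(nrow(directions))) {
    d <- c(directions$dx[k], directions$dy[k], directions$dz[k])
    Rd <- matrix(0, nrow = ng, ncol = lmax)
    for (line in lattice_lines(dm, d)) {
      runs <- rle(lev[line])
      keep <- runs$values > 0L
      if (any(keep)) {
        idx <- (runs$lengths[keep] - 1L) * ng + runs$values[keep]
        tab <- tabulate(idx, nbins = ng * lmax)
        Rd <- Rd + matrix(tab, nrow = ng)
      }
    }
    n_runs_raw <- n_runs_raw + sum(Rd)
    R <- R + w[k] * Rd
  }
  jmax <- max(1L, max(which(colSums(R) > 0)))
  structure(list(R = R[, seq_len(jmax), drop = FALSE], n_runs = sum(R),
                 n_runs_raw = n_runs_raw, n_voxels = q$n_voxels,
                 weight_total = sum(w), n_directions = nrow(directions),
                 length_weighting = length_weighting),
            class = "run_length_matrix")
}

# All lattice lines of a 3D box along direction d, as linear-index vectors.
# A line starts at any in-bounds voxel v with v - d out of bounds and follows
# v, v + d, v + 2d, ... while in bounds. Cached per (dim, d): line geometry
# depends only on the box shape.
lattice_lines <- local({
  cache <- new.env(parent = emptyenv())
  function(dm, d) {
    key <- paste(c(dm, d), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    ax <- seq_len(dm[1]); ay <- seq_len(dm[2]); az <- seq_len(dm[3])
    g <- expand.grid(x = ax, y = ay, z = az)
    prev_out <- (g$x - d[1] < 1) | (g$x - d[1] > dm[1]) |
                (g$y - d[2] < 1) | (g$y - d[2] > dm[2]) |
                (g$z - d[3] < 1) | (g$z - d[3] > dm[3])
    starts <- g[prev_out, ]
    steps_axis <- function(pos, dd, n) {
      if (dd > 0) n - pos else if (dd < 0) pos - 1L else rep(Inf, length(pos))
    }
    len <- 1L + pmin(steps_axis(starts$x, d[1], dm[1]),
                     steps_axis(starts$y, d[2], dm[2]),
                     steps_axis(starts$z, d[3], dm[3]))
    step <- d[1] + d[2] * dm[1] + d[3] * dm[1] * dm[2]
    lin0 <- starts$x + (starts$y - 1L) * dm[1] + (starts$z - 1L) * dm[1] * dm[2]
    lines <- lapply(seq_along(lin0), function(s)
      lin0[s] + step * (seq_len(len[s]) - 1L))
    cache[[key]] <- lines
    lines
  }
})

#' GLRLM texture features
#'
#' The thirteen run-length features, computed from the run probabilities
#' `p(i, j) = r(i, j) / n_r` (gray level `i`, run length `j`, total run count
#' `n_r`):
#' short/long-run emphasis (SRE, LRE), gray-level and run-length
#' non-uniformity (GLN, RLN), run percentage (RP), low/high gray-level run
#' emphasis (LGLRE, HGLRE), the four joint emphases (SRLGLE, SRHGLE, LRLGLE,
#' LRHGLE), and the run-probability-weighted gray-level and run-length
#' variances (GLV, RLV). RP is the run count per masked voxel and per merged
#' direction: `n_r / (N_v * W)` where `W` is the total direction weight, so a
#' fully uniform unweighted single direction gives RP in (0, 1].
#'
#' `variant = "count_normalized"` switches GLV/RLV to the matrix-cell
#' normalization used by some radiomics toolboxes
#' (`mean over cells of (i * p(i,j) - mu)^2` and the run-length analogue);
#' the default weights by run probability.
#'
#' @param rlm a `run_length_matrix` from [build_glrlm()].
#' @param variant `"probability"` (default) or `"count_normalized"` GLV/RLV.
#' @return Named numeric vector of the 13 GLRLM features.
#' @export
glrlm_features <- function(rlm, variant = c("probability",
                                            "count_normalized")) {
  variant <- match.arg(variant)
  R <- rlm$R
  nr <- rlm$n_runs
  if (nr <= 0) stop("empty run-length matrix")
  ng <- nrow(R); lmax <- ncol(R)
  i <- matrix(seq_len(ng), ng, lmax)
  j <- matrix(seq_len(lmax), ng, lmax, byrow = TRUE)
  p <- R / nr
  mu_g <- sum(p * i)
  mu_r <- sum(p * j)
  if (variant == "probability") {
    glv <- sum(p * (i - mu_g)^2)
    rlv <- sum(p * (j - mu_r)^2)
  } else {
    m_g <- sum(i * p) / (ng * lmax)
    m_r <- sum(j * p) / (ng * lmax)
    glv <- sum((i * p - m_g)^2) / (ng * lmax)
    rlv <- sum((j * p - m_r)^2) / (ng * lmax)
  }
  c(SRE    = sum(p / j^2),
    LRE    = sum(p * j^2),
    GLN    = sum(rowSums(R)^2) / nr,
    RLN    = sum(colSums(R)^2) / nr,
    RP     = nr / (rlm$n_voxels * rlm$weight_total),
    LGLRE  = sum(p / i^2),
    HGLRE  = sum(p * i^2),
    SRLGLE = sum(p / (i^2 * j^2)),
    SRHGLE = sum(p * i^2 / j^2),
    LRLGLE = sum(p * j^2 / i^2),
    LRHGLE = sum(p * i^2 * j^2),
    GLV    = glv,
    RLV    = rlv)
}
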