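#' The 13 direction classes of the 3D 26-neighborhood
#'
#' Every voxel on a 3D lattice has 26 neighbors, given by the non-zero
#' offsets of \{-1, 0, 1\}^3. Because a co-occurrence pair or a run at offset
#' `d` is the same object at offset `-d`, opposite offsets are identified,
#' leaving exactly 13 direction classes. Texture matrices are computed per
#' class and then averaged (GLCM) or summed (GLRLM); averaging over all 13
#' makes the features invariant under the lattice rotations and reflections.
#'
#' The per-offset Euclidean length in voxel units is 1 for the 3 axis
#' directions, sqrt(2) for the 6 face diagonals, and sqrt(3) for the 4 space
#' diagonals; it is used for the optional 1/length weighting when directions
#' are merged.
#'
#' @return A data frame with columns `dx`, `dy`, `dz` (integer offsets; the
#'   representative of each class has its last non-zero component positive)
#'   and `length` (Euclidean length in voxel units). Exactly 13 rows.
#' @examples
#' d <- enumerate_directions()
#' nrow(d)            # 13
#' table(round(d$length^2))  # 3 of length 1, 6 of sqrt(2), 4 of sqrt(3)
#' @export
enumerate_directions <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  # keep one representative per {d, -d} pair: last non-zero component positive
  keep <- with(g, dz > 0 | (dz == 0 & dy > 0) | (dz == 0 & dy == 0 & dx > 0))
  d <- g[keep, , drop = FALSE]
  d$length <- sqrt(d$dx^2 + d$dy^2 + d$dz^2)
  d <- d[order(d$length, d$dz, d$dy, d$dx), ]
  rownames(d) <- NULL
  stopifnot(nrow(d) == 13L)
  d
}
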