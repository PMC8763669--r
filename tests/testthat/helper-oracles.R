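# Independent oracles: plain triple-loop implementations used only to verify
# the vectorized texture engine on tiny lattices.

# Exhaustive-pair GLCM oracle: count every ordered in-mask voxel pair at
# offset +d and -d, then normalize. Voxel-by-voxel, no vectorization.
oracle_glcm <- function(levels, offset, n_levels) {
  dm <- dim(levels)
  C <- matrix(0, n_levels, n_levels)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- levels[x, y, z]
    if (a == 0L) next
    for (s in c(1L, -1L)) {
      p <- c(x, y, z) + s * offset
      if (any(p < 1L) || any(p > dm)) next
      b <- levels[p[1], p[2], p[3]]
      if (b > 0L) C[a, b] <- C[a, b] + 1
    }
  }
  if (sum(C) == 0) stop("no pairs")
  C / sum(C)
}

# Run-scanning oracle: walk every voxel; a run starts where the predecessor
# along d is outside the volume, outside the mask, or a different level.
oracle_glrlm <- function(levels, offset, n_levels, max_len) {
  dm <- dim(levels)
  R <- matrix(0, n_levels, max_len)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- levels[x, y, z]
    if (a == 0L) next
    prev <- c(x, y, z) - offset
    prev_same <- all(prev >= 1L) && all(prev <= dm) &&
      levels[prev[1], prev[2], prev[3]] == a
    if (prev_same) next               # not a run start
    len <- 1L
    nxt <- c(x, y, z) + offset
    while (all(nxt >= 1L) && all(nxt <= dm) &&
           levels[nxt[1], nxt[2], nxt[3]] == a) {
      len <- len + 1L
      nxt <- nxt + offset
    }
    R[a, len] <- R[a, len] + 1
  }
  R
}

# Random quantized region on a tiny lattice (levels 0 = out of mask)
random_region <- function(max_dim = 4L, n_levels = 4L, p_mask = 0.75) {
  dm <- sample(2:max_dim, 3L, replace = TRUE)
  lev <- array(sample(0:n_levels, prod(dm), replace = TRUE,
                      prob = c(1 - p_mask, rep(p_mask / n_levels, n_levels))),
               dim = dm)
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 n_voxels = sum(lev > 0L), range = c(0, 1)),
            class = "quantized_region")
}

# The 48 symmetries of the cube lattice: axis permutations x axis flips,
# applied to a 3D array.
apply_symmetry <- function(a, perm, flips) {
  a <- aperm(a, perm)
  idx <- lapply(1:3, function(ax)
    if (flips[ax]) rev(seq_len(dim(a)[ax])) else seq_len(dim(a)[ax]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

all_symmetries <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  flips <- expand.grid(x = c(FALSE, TRUE), y = c(FALSE, TRUE),
                       z = c(FALSE, TRUE))
  out <- list()
  for (p in perms) for (r in seq_len(nrow(flips)))
    out[[length(out) + 1L]] <- list(perm = p,
                                    flips = unlist(flips[r, ]))
  out
}

# A small random masked volume shared by rotation-invariance checks
random_masked_volume <- function(dm = c(7L, 7L, 7L), seed = 1L) {
  set.seed(seed)
  v <- volume_grid(array(stats::rnorm(prod(dm), 100, 25), dm),
                   spacing = c(1, 1, 1), modality = "CT")
  ctr <- (dm + 1) / 2
  g <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3]))
  inside <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <=
    (min(dm) / 2 - 0.2)^2
  m <- label_mask(array(as.integer(inside), dm))
  list(volume = v, mask = m)
}

# Lazily generated toy cohort shared across pipeline tests
toy_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- cohort_config(n_patients = 6L, levels_per_patient = 4L,
                           volume_shape = c(14L, 14L, 12L), seed = 42L)
      dir <- file.path(tempdir(), "toy_cohort")
      sim <- generate_cohort(cfg, dir)
      memo <<- list(config = cfg, sim = sim, dir = dir)
    }
    memo
  }
})
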