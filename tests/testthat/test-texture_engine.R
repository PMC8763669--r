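test_that("the 26-neighborhood collapses to 13 direction classes with the right lengths", {
  d <- enumerate_directions()
  expect_equal(nrow(d), 13L)
  # no two offsets are negatives of each other
  offs <- as.matrix(d[, c("dx", "dy", "dz")])
  for (i in seq_len(nrow(offs)))
    for (j in seq_len(nrow(offs)))
      if (i != j) expect_false(all(offs[i, ] == -offs[j, ]))
  # underlying neighbor count: each class stands for d and -d
  expect_equal(2L * nrow(d), 26L)
  expect_equal(sort(round(d$length^2)), c(rep(1, 3), rep(2, 6), rep(3, 4)))
})

test_that("quantization bins by in-mask range with a closed top bin", {
  m <- label_mask(array(c(rep(1L, 4), rep(0L, 4)), c(2, 2, 2)))
  v <- volume_grid(array(c(0, 1, 2, 3, 9, 9, 9, 9), c(2, 2, 2)))
  q <- quantize(v, m, 2)
  expect_equal(as.integer(q$levels[q$levels > 0]), c(1L, 1L, 2L, 2L))
  expect_equal(q$n_voxels, 4L)
  # constant region collapses to level 1
  vc <- volume_grid(array(5, c(2, 2, 2)))
  expect_true(all(quantize(vc, m, 8)$levels[unclass(m) == 1L] == 1L))
  # affine rescaling leaves the level map unchanged
  v2 <- volume_grid(array(3.5 * c(0, 1, 2, 3, 9, 9, 9, 9) - 11, c(2, 2, 2)))
  expect_identical(quantize(v2, m, 2)$levels, q$levels)
  expect_error(quantize(v, m, 1), "n_levels")
})

test_that("single-offset GLCM matches hand-worked examples", {
  # constant 2x2x2 region: all mass at (1,1)
  qc <- quantize(volume_grid(array(1, c(2, 2, 2))),
                 label_mask(array(1L, c(2, 2, 2))), 4)
  g <- build_glcm(qc, c(1, 0, 0))
  expect_equal(g$P[1, 1], 1)
  expect_equal(sum(g$P), 1)
  # alternating columns: pure off-diagonal
  lev <- array(0L, c(2, 2, 2)); lev[, , 1] <- matrix(c(1L, 2L, 1L, 2L), 2)
  q <- structure(list(levels = lev, n_levels = 2L, n_voxels = 4L,
                      range = c(1, 2)), class = "quantized_region")
  g2 <- build_glcm(q, c(1, 0, 0))
  expect_equal(g2$P, matrix(c(0, .5, .5, 0), 2))
  # single-voxel mask has no pair
  lone <- array(0L, c(3, 3, 3)); lone[2, 2, 2] <- 1L
  ql <- structure(list(levels = lone, n_levels = 2L, n_voxels = 1L,
                       range = c(0, 1)), class = "quantized_region")
  expect_error(build_glcm(ql, c(1, 0, 0)), "no in-mask voxel pair")
})

test_that("GLCM equals the exhaustive-pair oracle on random tiny lattices", {
  set.seed(7)
  dirs <- enumerate_directions()
  n_done <- 0L
  while (n_done < 60L) {
    q <- random_region()
    for (k in seq_len(nrow(dirs))) {
      d <- c(dirs$dx[k], dirs$dy[k], dirs$dz[k])
      ours <- tryCatch(build_glcm(q, d), error = function(e) NULL)
      ref <- tryCatch(oracle_glcm(q$levels, d, q$n_levels),
                      error = function(e) NULL)
      expect_equal(is.null(ours), is.null(ref))
      if (!is.null(ours)) expect_equal(ours$P, ref)
    }
    n_done <- n_done + 1L
  }
})

test_that("direction averaging is a renormalized 1/length-weighted mean", {
  dirs <- enumerate_directions()
  P0 <- matrix(c(.5, .25, .25, 0), 2)
  same <- replicate(13, list(P = P0, n_pairs = 4), simplify = FALSE)
  for (lw in c(TRUE, FALSE))
    expect_equal(average_glcm(same, dirs, lw)$P, P0)
  # two-direction toy with lengths 1 and sqrt(2)
  P1 <- matrix(c(1, 0, 0, 0), 2); P2 <- matrix(c(0, .5, .5, 0), 2)
  two <- list(list(P = P1, n_pairs = 1), list(P = P2, n_pairs = 1))
  d2 <- dirs[c(1, 4), ]
  w <- 1 / d2$length
  expect_equal(average_glcm(two, d2, TRUE)$P,
               (w[1] * P1 + w[2] * P2) / sum(w))
  set.seed(1)
  rand <- lapply(1:13, function(i) {
    A <- matrix(stats::runif(16), 4); A <- A + t(A); list(P = A / sum(A))
  })
  avg <- average_glcm(rand, dirs, TRUE)$P
  expect_equal(sum(avg), 1)
  expect_equal(avg, t(avg))
})

test_that("GLCM features match closed-form values", {
  point <- list(P = {
    P <- matrix(0, 3, 3); P[2, 2] <- 1; P
  })
  f <- glcm_features(point)
  expect_equal(f[["Energy"]], 1)
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Homogeneity"]], 1)
  expect_equal(f[["Dissimilarity"]], 0)
  expect_equal(f[["Correlation"]], 0)  # degenerate marginal convention

  off <- list(P = matrix(c(0, .5, .5, 0), 2))
  f2 <- glcm_features(off)
  expect_equal(unname(f2[c("Energy", "Contrast", "Entropy", "Homogeneity",
                           "Correlation", "SumAverage", "Dissimilarity")]),
               c(0.5, 1, 1, 0.5, -1, 3, 1))

  ng <- 5
  unif <- list(P = matrix(1 / ng^2, ng, ng))
  expect_equal(glcm_features(unif)[["Energy"]], 1 / ng^2)
  expect_error(glcm_features(list(P = matrix(1, 2, 2))), "not normalized")
})

test_that("GLRLM matches hand-worked runs and the run-scanning oracle", {
  one_dir <- data.frame(dx = 1, dy = 0, dz = 0, length = 1)
  # constant 2x2x2 cube, single direction: four runs of length 2
  qc <- quantize(volume_grid(array(1, c(2, 2, 2))),
                 label_mask(array(1L, c(2, 2, 2))), 4)
  r <- build_glrlm(qc, one_dir, length_weighting = FALSE)
  expect_equal(r$n_runs, 4)
  expect_equal(r$R[1, 2], 4)
  # alternating columns: four runs of length 1
  lev <- array(0L, c(2, 2, 2)); lev[, , 1] <- matrix(c(1L, 2L, 1L, 2L), 2)
  q <- structure(list(levels = lev, n_levels = 2L, n_voxels = 4L,
                      range = c(1, 2)), class = "quantized_region")
  r2 <- build_glrlm(q, one_dir, length_weighting = FALSE)
  expect_equal(r2$R[, 1], c(2, 2))

  set.seed(11)
  dirs <- enumerate_directions()
  for (rep in 1:40) {
    qq <- random_region()
    if (qq$n_voxels == 0L) next
    merged_ref <- matrix(0, qq$n_levels, max(dim(qq$levels)))
    for (k in seq_len(nrow(dirs))) {
      d <- c(dirs$dx[k], dirs$dy[k], dirs$dz[k])
      Rd <- oracle_glrlm(qq$levels, d, qq$n_levels, max(dim(qq$levels)))
      # per single direction, run lengths account for every masked voxel
      expect_equal(sum(Rd %*% seq_len(ncol(Rd))), qq$n_voxels)
      merged_ref <- merged_ref + Rd
    }
    ours <- build_glrlm(qq, dirs, length_weighting = FALSE)
    expect_equal(unname(ours$R),
                 unname(merged_ref[, seq_len(ncol(ours$R)), drop = FALSE]))
    if (ncol(merged_ref) > ncol(ours$R))
      expect_true(all(merged_ref[, -seq_len(ncol(ours$R))] == 0))
  }
})

test_that("GLRLM features match closed forms and respect their bounds", {
  one_dir <- data.frame(dx = 1, dy = 0, dz = 0, length = 1)
  qc <- quantize(volume_grid(array(1, c(2, 2, 2))),
                 label_mask(array(1L, c(2, 2, 2))), 4)
  f <- glrlm_features(build_glrlm(qc, one_dir, length_weighting = FALSE))
  expect_equal(unname(f[c("SRE", "LRE", "RP", "GLV", "RLV")]),
               c(0.25, 4, 0.5, 0, 0))
  # all runs of length 1
  f2 <- glrlm_features(
    build_glrlm(structure(list(levels = array(c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L),
                                              c(2, 2, 2)),
                               n_levels = 2L, n_voxels = 8L, range = c(1, 2)),
                          class = "quantized_region"),
                one_dir, length_weighting = FALSE))
  expect_equal(unname(f2[c("SRE", "LRE", "RLV")]), c(1, 1, 0))

  set.seed(3)
  for (rep in 1:25) {
    q <- random_region()
    r <- tryCatch(build_glrlm(q), error = function(e) NULL)
    if (is.null(r) || r$n_runs == 0) next
    f <- glrlm_features(r)
    expect_true(f[["SRE"]] > 0 && f[["SRE"]] <= 1)
    expect_true(f[["LRE"]] >= 1)
    expect_true(f[["RP"]] > 0 && f[["RP"]] <= 1)
    expect_true(f[["GLV"]] >= 0)
    expect_true(all(is.finite(f)))
  }
})

test_that("global histogram features use population moments with the zero-spread convention", {
  m <- label_mask(array(c(rep(1L, 4), rep(0L, 4)), c(2, 2, 2)))
  v <- volume_grid(array(c(0, 0, 100, 100, 7, 7, 7, 7), c(2, 2, 2)))
  f <- global_features(v, m)
  expect_equal(unname(f), c(2500, 0, -2))
  vc <- volume_grid(array(42, c(2, 2, 2)))
  expect_equal(unname(global_features(vc, m)), c(0, 0, 0))
  # symmetric distribution has zero skewness
  set.seed(5)
  x <- stats::rnorm(500)
  sym <- array(c(x, -x, rep(0, 1000 - 2 * length(x)))[1:1000], c(10, 10, 10))
  fs <- global_features(volume_grid(sym), array(TRUE, c(10, 10, 10)))
  expect_lt(abs(fs[["Skewness"]]), 1e-12)
})

test_that("the assembled feature vector has the modality-specific menu and recomposes from parts", {
  rmv <- random_masked_volume(seed = 9)
  ct <- extract_feature_vector(rmv$volume, rmv$mask, "CT", n_levels = 8)
  pdff <- extract_feature_vector(rmv$volume, rmv$mask, "PDFF", n_levels = 8)
  expect_named(ct, feature_names("CT"))
  expect_length(ct, 24L)
  expect_named(pdff, feature_names("PDFF"))
  expect_length(pdff, 11L)
  # deterministic
  expect_identical(ct, extract_feature_vector(rmv$volume, rmv$mask, "CT",
                                              n_levels = 8))
  # recomposition from the component operations
  dirs <- enumerate_directions()
  q <- quantize(rmv$volume, rmv$mask, 8)
  per_dir <- lapply(seq_len(13), function(k)
    build_glcm(q, c(dirs$dx[k], dirs$dy[k], dirs$dz[k])))
  manual <- c(global_features(rmv$volume, rmv$mask),
              glcm_features(average_glcm(per_dir, dirs, TRUE)),
              glrlm_features(build_glrlm(q, dirs, TRUE)))
  expect_equal(unname(ct), unname(manual))
  # GLCM features invariant under affine intensity rescaling
  v2 <- volume_grid(unclass(rmv$volume) * 2.7 + 31, attr(rmv$volume, "spacing"),
                    "CT")
  ct2 <- extract_feature_vector(v2, rmv$mask, "CT", n_levels = 8)
  glcm_names <- paste0("CT_", c("Energy", "Contrast", "Entropy", "Homogeneity",
                                "Correlation", "SumAverage", "Variance",
                                "Dissimilarity"))
  expect_equal(ct2[glcm_names], ct[glcm_names])
  # per-direction feature averaging is a supported alternative mode
  alt <- extract_feature_vector(rmv$volume, rmv$mask, "CT", n_levels = 8,
                                glcm_mode = "average_features")
  expect_length(alt, 24L)
  expect_false(isTRUE(all.equal(alt, ct)))
})

test_that("features are invariant under axis permutations of volume and mask", {
  rmv <- random_masked_volume(seed = 21)
  base <- extract_feature_vector(rmv$volume, rmv$mask, "CT", n_levels = 6)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    v <- volume_grid(aperm(unclass(rmv$volume), perm), modality = "CT")
    m <- label_mask(aperm(unclass(rmv$mask), perm))
    expect_equal(extract_feature_vector(v, m, "CT", n_levels = 6), base,
                 tolerance = 1e-12)
  }
})
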