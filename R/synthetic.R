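#' Configuration of the synthetic vertebral cohort
#'
#' Defines the statistical structure of the simulated cohort: two patient
#' groups (with / without prevalent vertebral fracture) that differ in mean
#' volumetric BMD, marrow fat fraction, T2*, and texture heterogeneity.
#' Defaults emulate a thoracolumbar two-group cohort: 26 patients with a
#' fracture prevalence of 11/26, group integral vBMD means of 153.1 and
#' 218.5 mg/cm^3 (fracture vs control), higher marrow PDFF and longer T2* in
#' the fracture group, and a more heterogeneous trabecular texture in the
#' fracture group.
#'
#' @param n_patients number of patients.
#' @param fracture_fraction probability a patient carries a fracture.
#' @param levels_per_patient vertebrae simulated per patient.
#' @param volume_shape integer voxel triple per vertebra volume (each >= 3).
#' @param voxel_spacing_mm voxel size in mm.
#' @param mean_vbmd_by_group mg/cm^3, `c(fracture, control)`.
#' @param mean_pdff_by_group percent, `c(fracture, control)`.
#' @param mean_t2star_by_group ms, `c(fracture, control)`.
#' @param texture_sd_by_group HU, `c(fracture, control)`; standard deviation
#'   of the spatially correlated texture field on the CT volume. The same
#'   field drives PDFF heterogeneity scaled by `pdff_texture_scale`.
#' @param correlation_length_mm Gaussian correlation length of the texture
#'   field.
#' @param hu_calibration `c(slope, intercept)`: vBMD = slope * HU +
#'   intercept, slope non-zero.
#' @param noise_sd white (voxelwise independent) noise sd on the CT volume,
#'   HU.
#' @param pdff_texture_scale percent PDFF per HU of texture sd (fixed design
#'   constant mapping the shared heterogeneity field into the fat-fraction
#'   map).
#' @param patient_sd,vertebra_sd between-patient and between-vertebra sd of
#'   true mean vBMD within a group, mg/cm^3.
#' @param pdff_patient_sd,pdff_vertebra_sd within-group spread of true mean
#'   PDFF, percent points, at patient and vertebra level.
#' @param t2star_patient_sd,t2star_vertebra_sd within-group spread of true
#'   mean T2*, ms.
#' @param seed integer master seed; all randomness derives from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 26L,
                          fracture_fraction = 11 / 26,
                          levels_per_patient = 7L,
                          volume_shape = c(18L, 18L, 14L),
                          voxel_spacing_mm = c(1.8, 1.8, 1.8),
                          mean_vbmd_by_group = c(153.1, 218.5),
                          mean_pdff_by_group = c(55, 40),
                          mean_t2star_by_group = c(18, 14),
                          texture_sd_by_group = c(45, 25),
                          correlation_length_mm = 4,
                          hu_calibration = c(slope = 0.8, intercept = 0),
                          noise_sd = 10,
                          pdff_texture_scale = 0.1,
                          patient_sd = 40,
                          vertebra_sd = 15,
                          pdff_patient_sd = 8,
                          pdff_vertebra_sd = 3,
                          t2star_patient_sd = 3,
                          t2star_vertebra_sd = 1.5,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              fracture_fraction = fracture_fraction,
              levels_per_patient = as.integer(levels_per_patient),
              volume_shape = as.integer(volume_shape),
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              mean_vbmd_by_group = as.numeric(mean_vbmd_by_group),
              mean_pdff_by_group = as.numeric(mean_pdff_by_group),
              mean_t2star_by_group = as.numeric(mean_t2star_by_group),
              texture_sd_by_group = as.numeric(texture_sd_by_group),
              correlation_length_mm = correlation_length_mm,
              hu_calibration = c(slope = unname(hu_calibration[1]),
                                 intercept = unname(hu_calibration[2])),
              noise_sd = noise_sd,
              pdff_texture_scale = pdff_texture_scale,
              patient_sd = patient_sd,
              vertebra_sd = vertebra_sd,
              pdff_patient_sd = pdff_patient_sd,
              pdff_vertebra_sd = pdff_vertebra_sd,
              t2star_patient_sd = t2star_patient_sd,
              t2star_vertebra_sd = t2star_vertebra_sd,
              seed = as.integer(seed))
  if (cfg$fracture_fraction < 0 || cfg$fracture_fraction > 1)
    stop("fracture_fraction must be in [0, 1]")
  if (cfg$n_patients < 1L || cfg$levels_per_patient < 1L)
    stop("counts must be >= 1")
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 3L))
    stop("volume_shape must have >= 3 voxels on every axis")
  if (any(cfg$texture_sd_by_group < 0)) stop("texture_sd must be >= 0")
  if (cfg$hu_calibration[["slope"]] == 0) stop("calibration slope must be non-zero")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(cfg, class = "cohort_config")
}

# Stationary Gaussian random field: white noise smoothed by a separable
# Gaussian kernel (sigma in voxels per axis), then centered and scaled to
# unit sd over the reference voxels. Edge effects are absorbed by
# renormalized kernel rows.
gaussian_random_field <- function(dm, sigma_vox, ref = NULL) {
  f <- array(stats::rnorm(prod(dm)), dim = dm)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dm[ax]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * s^2)))
    K[abs(row(K) - col(K)) > ceiling(4 * s)] <- 0
    K <- K / rowSums(K)
    m <- aperm(f, c(ax, setdiff(1:3, ax)))       # axis `ax` first
    m <- K %*% matrix(m, nrow = n)
    f <- aperm(array(m, dim = dm[c(ax, setdiff(1:3, ax))]),
               order(c(ax, setdiff(1:3, ax))))
  }
  if (is.null(ref)) ref <- array(TRUE, dm)
  mu <- mean(f[ref]); sd_ <- stats::sd(f[ref])
  if (sd_ > 0) (f - mu) / sd_ else f * 0
}

# 6-connected binary erosion of a 3D logical array, `iter` times
erode3d <- function(sel, iter = 1L) {
  dm <- dim(sel)
  for (it in seq_len(iter)) {
    out <- sel
    pad_shift <- function(d) {
      s <- array(FALSE, dm)
      xs <- src_range(dm[1], d[1]); ys <- src_range(dm[2], d[2])
      zs <- src_range(dm[3], d[3])
      s[xs, ys, zs] <- sel[xs + d[1], ys + d[2], zs + d[3]]
      s
    }
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
      out <- out & pad_shift(d)
    sel <- out
  }
  sel
}

# Ellipsoidal vertebral-body phantom mask: label 1 = integral shell,
# label 2 = trabecular interior (morphological interior of the body label).
phantom_mask <- function(dm, spacing) {
  ctr <- (dm + 1) / 2
  ax <- (dm - 3) / 2  # semi-axes leave a >=1-voxel border to the volume edge
  g <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3]))
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  integral <- array(inside, dim = dm)
  trab <- erode3d(integral, 2L)
  lab <- array(0L, dim = dm)
  lab[integral] <- 1L
  lab[trab] <- 2L
  label_mask(lab, spacing = spacing)
}

#' Generate a synthetic vertebral cohort on disk
#'
#' For each vertebra of each patient, writes co-registered NIfTI volumes —
#' a CT-like HU volume, water and fat signal volumes constructed so that
#' `100 * fat / (fat + water)` reproduces the simulated PDFF field, a T2*
#' map — and a label mask with integral (1) and trabecular (2) compartment
#' codes. Each scalar field is (group mean + patient and vertebra effects) +
#' a stationary correlated Gaussian texture field with the group's sd +
#' voxelwise white noise; the texture field is centered within the mask so
#' the vertebra's true mean is exact. Fracture status is a patient-level
#' Bernoulli draw and all of a patient's vertebrae inherit the group's field
#' parameters. Identical configurations (including seed) reproduce
#' byte-identical outputs.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with `truth` (one row per vertebra: patient,
#'   level, group, true means, texture sd), `manifest` (patient id, level,
#'   fracture status, age, sex, file paths), and `dir`. Both tables are also
#'   written as CSV, and the configuration is echoed as JSON.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  dm <- config$volume_shape
  sp <- config$voxel_spacing_mm
  sigma_vox <- config$correlation_length_mm / sp
  mask <- phantom_mask(dm, sp)
  write_mask(mask, file.path(out_dir, "mask.nii.gz"))
  sel <- mask_select(mask, "integral")

  # patient-level draws (substream: master seed)
  set.seed(config$seed %% .Machine$integer.max)
  frac <- stats::rbinom(config$n_patients, 1L, config$fracture_fraction)
  age <- round(stats::runif(config$n_patients, 55, 85))
  sex <- stats::rbinom(config$n_patients, 1L, 0.5)
  pat_eff <- stats::rnorm(config$n_patients, 0, config$patient_sd)
  pat_pdff <- stats::rnorm(config$n_patients, 0, config$pdff_patient_sd)
  pat_t2 <- stats::rnorm(config$n_patients, 0, config$t2star_patient_sd)

  slope <- config$hu_calibration[["slope"]]
  icpt <- config$hu_calibration[["intercept"]]
  truth <- list(); manifest <- list()
  for (p in seq_len(config$n_patients)) {
    grp <- if (frac[p] == 1L) 1L else 2L  # index into *_by_group pairs
    tex_sd <- config$texture_sd_by_group[grp]
    for (lv in seq_len(config$levels_per_patient)) {
      # per-vertebra substream, stable under cohort-size changes
      set.seed((config$seed + 7919L * p + 104729L * lv) %% .Machine$integer.max)
      vb_true <- config$mean_vbmd_by_group[grp] + pat_eff[p] +
        stats::rnorm(1, 0, config$vertebra_sd)
      pd_true <- min(max(config$mean_pdff_by_group[grp] + pat_pdff[p] +
                           stats::rnorm(1, 0, config$pdff_vertebra_sd), 1), 99)
      t2_true <- max(config$mean_t2star_by_group[grp] + pat_t2[p] +
                       stats::rnorm(1, 0, config$t2star_vertebra_sd), 1)

      hu_mean <- (vb_true - icpt) / slope
      grf_ct <- gaussian_random_field(dm, sigma_vox, ref = sel)
      grf_pd <- gaussian_random_field(dm, sigma_vox, ref = sel)
      grf_t2 <- gaussian_random_field(dm, sigma_vox, ref = sel)

      ct <- hu_mean + tex_sd * grf_ct +
        array(stats::rnorm(prod(dm), 0, config$noise_sd), dim = dm)
      pdff <- pd_true + config$pdff_texture_scale * tex_sd * grf_pd +
        array(stats::rnorm(prod(dm), 0,
                           config$pdff_texture_scale * config$noise_sd),
              dim = dm)
      pdff <- pmin(pmax(pdff, 0), 100)
      t2 <- pmax(t2_true + 0.05 * tex_sd * grf_t2 +
                   array(stats::rnorm(prod(dm), 0, 0.3), dim = dm), 0.1)
      total <- 1000
      fat <- total * pdff / 100
      water <- total - fat

      stem <- sprintf("p%03d_L%02d", p, lv)
      paths <- c(ct = file.path(out_dir, paste0(stem, "_ct.nii.gz")),
                 water = file.path(out_dir, paste0(stem, "_water.nii.gz")),
                 fat = file.path(out_dir, paste0(stem, "_fat.nii.gz")),
                 t2star = file.path(out_dir, paste0(stem, "_t2star.nii.gz")),
                 mask = file.path(out_dir, "mask.nii.gz"))
      write_volume(volume_grid(array(ct, dm), sp, "CT"), paths[["ct"]])
      write_volume(volume_grid(array(water, dm), sp, "water"), paths[["water"]])
      write_volume(volume_grid(array(fat, dm), sp, "fat"), paths[["fat"]])
      write_volume(volume_grid(array(t2, dm), sp, "T2star"), paths[["t2star"]])

      truth[[stem]] <- data.frame(
        patient_id = p, level = lv,
        group = if (grp == 1L) "fracture" else "control",
        true_vbmd = vb_true, true_pdff = pd_true, true_t2star = t2_true,
        texture_sd = tex_sd)
      manifest[[stem]] <- data.frame(
        patient_id = p, level = lv, fracture_status = frac[p],
        age = age[p], sex = sex[p],
        ct = paths[["ct"]], water = paths[["water"]], fat = paths[["fat"]],
        t2star = paths[["t2star"]], mask = paths[["mask"]])
    }
  }
  truth <- do.call(rbind, c(truth, make.row.names = FALSE))
  manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  cfg_json <- unclass(config)
  cfg_json$hu_calibration <- as.list(cfg_json$hu_calibration)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, manifest = manifest, dir = out_dir))
}
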