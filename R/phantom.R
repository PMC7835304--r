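#' Schematic mouse-brain atlas phantom
#'
#' Builds the digital atlas used by the synthetic cohorts: an ellipsoidal
#' brain partitioned into the six analysed regions (neocortex,
#' caudate/putamen, hippocampus, thalamus, cerebellum, brainstem) plus
#' background, together with the six skull-fixed fiducial landmarks (eyes,
#' mandibular condyles, cochleae) lying outside the brain. The geometry is
#' deliberately schematic — nested ellipsoids and axis splits scaled to the
#' grid — because the quantification pipeline needs labels and contrasts, not
#' anatomy. The atlas plays the role of a single fixed public reference
#' atlas, so its geometry is deterministic; `seed` is accepted for interface
#' symmetry with the other generators.
#'
#' @param grid_shape integer length-3 grid size in voxels (minimum 16 per
#'   axis so that every region receives voxels).
#' @param voxel_size_mm voxel edge length(s), mm.
#' @param seed integer; unused by the deterministic geometry but kept so all
#'   generators share one calling convention.
#' @return an `atlas_phantom`: list with `labels` (integer [volume3d()]),
#'   `region_names` (named code vector) and `landmarks` (a [landmark_set()]).
#' @examples
#' atl <- generate_atlas(c(48, 48, 48), 0.25)
#' table(atl$labels$data)[1:3]
#' @export
generate_atlas <- function(grid_shape = c(64, 64, 64),
                           voxel_size_mm = c(0.25, 0.25, 0.25),
                           seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape < 16L))
    stop("grid too small to place all regions: need at least 16 voxels per axis")
  vol <- volume3d(array(0L, grid_shape), voxel_size = voxel_size_mm)
  w <- grid_world_coords(vol)
  half <- grid_shape * rep_len(voxel_size_mm, 3L) / 2
  # brain semi-axes: generous fractions of the grid half-extent so every
  # region is thick relative to the PET point-spread function (keeps VOI
  # means robust to partial-volume dilution) while leaving a rim for the
  # inter-session misalignment
  a <- c(0.90, 0.86, 0.80) * half

  ell <- function(centre, semi) {
    ((w[, 1] - centre[1]) / semi[1])^2 +
      ((w[, 2] - centre[2]) / semi[2])^2 +
      ((w[, 3] - centre[3]) / semi[3])^2 <= 1
  }
  brain <- ell(c(0, 0, 0), a)
  hind <- brain & w[, 2] < -0.25 * a[2]
  fore <- brain & !hind

  lab <- integer(nrow(w))
  lab[fore] <- 1L                                          # neocortex (rest)
  caud <- (ell(c(0.44 * a[1], 0.30 * a[2], 0), c(0.23, 0.28, 0.35) * a) |
             ell(c(-0.44 * a[1], 0.30 * a[2], 0), c(0.23, 0.28, 0.35) * a))
  hipp <- ell(c(0, -0.02 * a[2], 0.44 * a[3]), c(0.50, 0.24, 0.24) * a)
  thal <- ell(c(0, 0, -0.09 * a[3]), c(0.31, 0.24, 0.32) * a)
  lab[fore & thal] <- 4L
  lab[fore & hipp] <- 3L
  lab[fore & caud] <- 2L
  lab[hind & w[, 3] >= -0.05 * a[3]] <- 5L                 # cerebellum
  lab[hind & w[, 3] < -0.05 * a[3]] <- 6L                  # brainstem

  codes <- c(background = 0L, neocortex = 1L, caudate_putamen = 2L,
             hippocampus = 3L, thalamus = 4L, cerebellum = 5L, brainstem = 6L)
  counts <- tabulate(lab, nbins = 6L)
  if (any(counts == 0L))
    stop("grid too small to place all regions: empty region(s) ",
         paste(names(codes)[-1][counts == 0L], collapse = ", "))

  lms <- landmark_set(
    c("eye_L", "eye_R", "condyle_L", "condyle_R", "cochlea_L", "cochlea_R"),
    rbind(c(-0.35, 0.95, 0.10), c(0.35, 0.95, 0.10),
          c(-0.75, 0.35, -0.65), c(0.75, 0.35, -0.65),
          c(-0.52, -0.88, -0.18), c(0.52, -0.88, -0.18)) *
      matrix(a, 6, 3, byrow = TRUE))

  vol$data <- array(lab, grid_shape)
  vol$units <- "label"
  structure(list(labels = vol, region_names = codes, landmarks = lms),
            class = "atlas_phantom")
}

#' @export
print.atlas_phantom <- function(x, ...) {
  cat("<atlas_phantom>\n")
  print(x$labels)
  counts <- vapply(region_names(x), function(r) sum(x$labels$data == x$region_names[[r]]), 0)
  cat("  regions:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

#' Analysed region names of an atlas (background excluded)
#' @param atlas an `atlas_phantom`.
#' @return character vector of the six region names.
#' @export
region_names <- function(atlas) {
  setdiff(names(atlas$region_names), "background")
}

#' Logical mask of one atlas region
#' @param atlas an `atlas_phantom`.
#' @param region region name.
#' @return logical 3D array.
#' @export
region_mask <- function(atlas, region) {
  code <- atlas$region_names[region]
  if (is.na(code)) stop("unknown region: ", region)
  atlas$labels$data == unname(code)
}

#' Dynamic PET study container
#'
#' Ordered, timed activity frames plus the injection metadata needed for SUV
#' conversion.
#'
#' @param frames 4D array (x, y, z, frame) of activity concentration,
#'   MBq/cm^3.
#' @param affine 4x4 voxel-to-world matrix shared by all frames.
#' @param frame_times data frame with `start_min` and `end_min` columns,
#'   minutes post-injection; intervals must be increasing and
#'   non-overlapping.
#' @param dose_MBq injected dose, MBq (> 0).
#' @param weight_g body weight, g (> 0).
#' @return an object of class `dynamic_pet`.
#' @export
dynamic_pet <- function(frames, affine, frame_times, dose_MBq, weight_g) {
  stopifnot(length(dim(frames)) == 4L)
  if (nrow(frame_times) != dim(frames)[4])
    stop("one timing row per frame required")
  if (any(frame_times$end_min <= frame_times$start_min))
    stop("frame intervals must have positive duration")
  if (nrow(frame_times) > 1 &&
      any(frame_times$start_min[-1] < frame_times$end_min[-nrow(frame_times)]))
    stop("frame intervals must be increasing and non-overlapping")
  if (dose_MBq <= 0 || weight_g <= 0)
    stop("dose_MBq and weight_g must be positive")
  structure(list(frames = frames, affine = as.matrix(affine),
                 frame_times = frame_times, dose_MBq = dose_MBq,
                 weight_g = weight_g),
            class = "dynamic_pet")
}

#' @export
print.dynamic_pet <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dynamic_pet> %d frames of %d x %d x %d, %g-%g min, dose %.2f MBq, weight %.1f g\n",
              d[4], d[1], d[2], d[3], min(x$frame_times$start_min),
              max(x$frame_times$end_min), x$dose_MBq, x$weight_g))
  invisible(x)
}

#' Simulate a dynamic TSPO-PET study on an atlas phantom
#'
#' Each region's activity is the reference (neocortex) activity times its
#' configured uptake ratio; frames are blurred by an isotropic Gaussian
#' point-spread function and degraded with additive Gaussian noise
#' (post-reconstruction PET noise is approximately Gaussian on activity).
#' Uptake is stationary across frames: the analysis window of a late-phase
#' TSPO scan is treated as being at equilibrium, so no kinetics are
#' modelled.
#'
#' @param atlas an `atlas_phantom`.
#' @param suvr_profile named numeric vector/list: uptake ratio per region
#'   (every atlas region must be present; the reference region `neocortex`
#'   must have ratio 1).
#' @param reference_suv SUV of the reference region, sets the activity scale
#'   (activity = SUV x dose/weight).
#' @param dose_MBq,weight_g injection metadata stored for SUV conversion.
#' @param psf_fwhm_mm scanner point-spread function FWHM, mm (0 disables).
#' @param noise_sd additive frame noise, as a fraction of the reference
#'   activity (0.05 = 5%).
#' @param n_frames,frame_len_min,t_start_min frame sequence (defaults: 6
#'   frames of 5 min starting 20 min post-injection).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `pet` (a [dynamic_pet()]) and `truth` (list with
#'   `true_suvr`, the configured profile).
#' @export
generate_pet <- function(atlas, suvr_profile, reference_suv = 0.21,
                         dose_MBq = 6.0, weight_g = 18.0,
                         psf_fwhm_mm = 0.9, noise_sd = 0.05,
                         n_frames = 6L, frame_len_min = 5,
                         t_start_min = 20, seed = NULL) {
  prof <- unlist(suvr_profile)
  missing <- setdiff(region_names(atlas), names(prof))
  if (length(missing))
    stop("suvr_profile is missing region(s): ", paste(missing, collapse = ", "))
  if (abs(prof[["neocortex"]] - 1) > 1e-9)
    stop("the reference region (neocortex) must have ratio 1 in suvr_profile")
  maybe_with_seed(seed, {
    ref_act <- reference_suv * dose_MBq / weight_g
    base <- numeric(length(atlas$labels$data))
    for (r in region_names(atlas))
      base[atlas$labels$data == atlas$region_names[[r]]] <- ref_act * prof[[r]]
    base <- array(base, dim(atlas$labels$data))
    sigma_vox <- (psf_fwhm_mm / 2.354820045) / vox_size(atlas$labels)
    if (psf_fwhm_mm > 0) base <- gauss_blur3(base, sigma_vox)
    frames <- array(0, c(dim(base), n_frames))
    for (f in seq_len(n_frames)) {
      fr <- base
      if (noise_sd > 0)
        fr <- fr + stats::rnorm(length(fr), sd = noise_sd * ref_act)
      frames[, , , f] <- fr
    }
    times <- data.frame(start_min = t_start_min + (seq_len(n_frames) - 1) * frame_len_min,
                        end_min = t_start_min + seq_len(n_frames) * frame_len_min)
    list(pet = dynamic_pet(frames, atlas$labels$affine, times, dose_MBq, weight_g),
         truth = list(true_suvr = prof[region_names(atlas)]))
  })
}

#' Simulate a SPIO T2*-weighted MRI volume with punctate hypointense lesions
#'
#' Punctate SPIO uptake sites are modelled as spherical clusters (radius 1-3
#' voxels), rejection-sampled wholly inside their target region on the atlas
#' grid until the requested fractional volume is reached; the realized
#' fraction is recorded exactly. The MRI is synthesised directly on its own
#' acquisition grid, whose world frame differs from the atlas/PET frame by
#' the given rigid misalignment: each MRI voxel centre is mapped through the
#' misalignment into atlas space and assigned crisp tissue/lesion membership
#' (as a scanner samples the object on its own grid). A smooth multiplicative
#' receiver-coil bias field — the exponential of a random second-order 3D
#' polynomial, mean 1 over the brain with peak deviation `bias_amplitude` —
#' multiplies the whole image.
#'
#' @param atlas an `atlas_phantom`.
#' @param lesion_fraction named numeric: requested percent fractional volume
#'   per region (regions not named get no lesions).
#' @param lesion_contrast lesion signal drop as a fraction of tissue
#'   intensity, in (0, 1): lesion voxels have intensity
#'   `mu_tissue * (1 - lesion_contrast)`.
#' @param bias_amplitude peak relative deviation of the bias field (0.2 =
#'   20%); 0 disables.
#' @param noise_sd voxel noise as a fraction of `mu_tissue`.
#' @param misalignment a [rigid_transform()] mapping MRI world coordinates to
#'   atlas/PET world coordinates (the unknown animal repositioning between
#'   sessions).
#' @param mu_tissue mean tissue intensity (arbitrary units).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `mri` (a [volume3d()] in the misaligned frame),
#'   `landmarks_mri` (atlas fiducials expressed in the MRI frame) and `truth`
#'   (list: `true_lesion_mask` on the atlas grid, `true_lesion_fraction` in
#'   percent (exact recomputation from the mask), `true_bias_field`,
#'   `misalignment`).
#' @export
generate_spio_mri <- function(atlas, lesion_fraction, lesion_contrast = 0.7,
                              bias_amplitude = 0.2, noise_sd = 0.05,
                              misalignment = identity_transform(),
                              mu_tissue = 100, seed = NULL) {
  if (lesion_contrast <= 0 || lesion_contrast >= 1)
    stop("lesion_contrast must lie in (0, 1)")
  unknown <- setdiff(names(lesion_fraction), region_names(atlas))
  if (length(unknown))
    stop("lesion_fraction names unknown region(s): ", paste(unknown, collapse = ", "))
  maybe_with_seed(seed, {
    d <- dim(atlas$labels$data)
    lesion <- array(FALSE, d)
    for (r in names(lesion_fraction))
      lesion <- lesion | place_lesions(atlas, r, lesion_fraction[[r]])
    realized <- vapply(region_names(atlas), function(r) {
      m <- region_mask(atlas, r)
      100 * sum(lesion & m) / sum(m)
    }, 0)

    # sample anatomy on the (misaligned) MRI grid by nearest-neighbour lookup
    mri_vol <- volume3d(array(0, d), affine = atlas$labels$affine)
    w_mri <- grid_world_coords(mri_vol)
    p_atlas <- apply_transform(misalignment, w_mri)
    vox <- world_to_voxel(atlas$labels, p_atlas)
    lab_s <- interp3(atlas$labels$data, vox, "nearest")
    les_s <- interp3(lesion + 0, vox, "nearest") > 0.5
    inten <- numeric(length(lab_s))
    inten[lab_s > 0] <- mu_tissue
    inten[les_s & lab_s > 0] <- mu_tissue * (1 - lesion_contrast)
    if (noise_sd > 0)
      inten <- inten + stats::rnorm(length(inten), sd = noise_sd * mu_tissue)
    # magnitude images are non-negative; folding emulates the Rician floor
    inten <- abs(inten)
    inten <- array(inten, d)

    brain_mri <- array(lab_s > 0, d)
    field <- make_bias_field(mri_vol, brain_mri, bias_amplitude, order = 2L)
    mri_vol$data <- inten * field$data
    mri_vol$units <- "a.u."

    lms_mri <- apply_transform(invert_transform(misalignment), atlas$landmarks)
    truth <- list(
      true_lesion_mask = volume3d(lesion + 0L, affine = atlas$labels$affine,
                                  units = "mask"),
      true_lesion_fraction = realized,
      true_bias_field = field,
      misalignment = misalignment)
    list(mri = mri_vol, landmarks_mri = lms_mri, truth = truth)
  })
}

# rejection-sample spherical lesion clusters wholly inside `region` until the
# requested percent volume is met as closely as punctate clusters allow
place_lesions <- function(atlas, region, percent_requested) {
  m <- region_mask(atlas, region)
  # keep clusters one voxel clear of the brain surface (uptake sites are
  # parenchymal/perivascular, and surface notches would defeat the
  # hole-filling step of brain extraction)
  m_ok <- m & erode6(atlas$labels$data > 0)
  n_region <- sum(m)
  target <- round(percent_requested / 100 * n_region)
  lesion <- array(FALSE, dim(m))
  if (target <= 0) return(lesion)
  d <- dim(m)
  idx_region <- which(m_ok)
  ijk_region <- arrayInd(idx_region, d)
  radii <- c(3, 2, 1)                     # voxel radii; ~123, 33, 7 voxels
  placed <- 0L
  for (r in radii) {
    off <- sphere_offsets(r)
    size_r <- nrow(off)
    fails <- 0L
    while (target - placed >= size_r && fails < 200L) {
      c_ijk <- ijk_region[sample.int(nrow(ijk_region), 1L), ]
      pts <- sweep(off, 2, c_ijk, "+")
      if (any(pts < 1) || any(pts[, 1] > d[1]) || any(pts[, 2] > d[2]) ||
          any(pts[, 3] > d[3])) { fails <- fails + 1L; next }
      lin <- pts[, 1] + (pts[, 2] - 1) * d[1] + (pts[, 3] - 1) * d[1] * d[2]
      if (!all(m_ok[lin]) || any(lesion[lin])) { fails <- fails + 1L; next }
      lesion[lin] <- TRUE
      placed <- placed + size_r
    }
  }
  lesion
}

# voxel offsets of a digital ball of the given radius (in voxels)
sphere_offsets <- function(r) {
  s <- seq(-r, r)
  g <- as.matrix(expand.grid(i = s, j = s, k = s))
  g[rowSums(g^2) <= r^2 + 1e-9, , drop = FALSE]
}

# multiplicative bias field: exp of a random centred 2nd-order polynomial,
# scaled so the peak relative deviation over the mask equals `amplitude`,
# then normalised to mean 1 over the mask
make_bias_field <- function(vol, mask, amplitude, order = 2L) {
  d <- dim(vol$data)
  if (amplitude <= 0)
    return(volume3d(array(1, d), affine = vol$affine, units = "bias"))
  B <- poly_basis3(vol, order)[, -1, drop = FALSE]   # drop intercept
  coef <- stats::rnorm(ncol(B))
  p <- drop(B %*% coef)
  p <- p - mean(p[mask])
  peak <- max(abs(p[mask]))
  if (peak > 0) p <- p * log1p(amplitude) / peak
  f <- array(exp(p), d)
  f <- f / mean(f[mask])
  volume3d(f, affine = vol$affine, units = "bias")
}

# 3D polynomial design matrix over the voxel grid, coordinates normalised to
# [-1, 1] per axis; column 1 is the intercept
poly_basis3 <- function(vol, order = 2L) {
  d <- dim(vol$data)
  u <- lapply(1:3, function(ax) {
    x <- seq_len(d[ax])
    2 * (x - 1) / max(d[ax] - 1, 1) - 1
  })
  U <- cbind(rep(u[[1]], times = d[2] * d[3]),
             rep(rep(u[[2]], each = d[1]), times = d[3]),
             rep(u[[3]], each = d[1] * d[2]))
  pows <- as.matrix(expand.grid(i = 0:order, j = 0:order, k = 0:order))
  pows <- pows[rowSums(pows) <= order, , drop = FALSE]
  pows <- pows[order(rowSums(pows), pows[, 1], pows[, 2], pows[, 3]), ,
               drop = FALSE]
  B <- matrix(1, nrow(U), nrow(pows))
  for (t in seq_len(nrow(pows)))
    B[, t] <- U[, 1]^pows[t, 1] * U[, 2]^pows[t, 2] * U[, 3]^pows[t, 3]
  B
}

#' Draw a random rigid transform
#'
#' Uniform random rotation axis, rotation angle and translation bounded by
#' the given magnitudes; used for the unknown inter-session misalignment.
#'
#' @param max_rot_deg maximum rotation angle, degrees.
#' @param max_trans_mm maximum translation per axis, mm.
#' @return a [rigid_transform()].
#' @export
random_rigid <- function(max_rot_deg = 5, max_trans_mm = 1) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, stats::runif(3, -max_trans_mm, max_trans_mm))
}

#' Simulate a two-channel fluorescence field with known co-expression
#'
#' Round cell blobs are placed without overlap; a fraction `frac_double` is
#' positive in both channels (the TSPO and Iba1 analogues), the remainder is
#' split between single-positive cells. A vessel band provides the geometry
#' for perivascular distance measurements (Euclidean distance transform from
#' the vessel border, in micrometres).
#'
#' @param field_size image size in pixels (length 2).
#' @param n_cells number of cells to place.
#' @param frac_double fraction of cells positive in both channels, in
#'   `[0, 1]`.
#' @param vessel list with `x_px` (band centre column) and `width_px`.
#' @param pixel_size_um pixel pitch, micrometres.
#' @param cell_radius_px cell blob radius, pixels.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `image` (a `fluor_image`: channels `a`, `b`,
#'   `pixel_size_um`), `cells` (data frame: cell_id, row, col, positive_a,
#'   positive_b, distance_to_vessel_um) and `vessel_mask`.
#' @export
generate_fluorescence <- function(field_size = c(256, 256), n_cells = 50L,
                                  frac_double = 0.4,
                                  vessel = list(x_px = 40, width_px = 12),
                                  pixel_size_um = 1, cell_radius_px = 4L,
                                  seed = NULL) {
  if (frac_double < 0 || frac_double > 1)
    stop("frac_double must lie in [0, 1]")
  maybe_with_seed(seed, {
    nr <- field_size[1]; nc <- field_size[2]
    vmask <- matrix(FALSE, nr, nc)
    vmask[, abs(seq_len(nc) - vessel$x_px) <= vessel$width_px / 2] <- TRUE
    dist_um <- as.matrix(EBImage::distmap(1 - vmask)) * pixel_size_um

    r <- cell_radius_px
    centres <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centres) < n_cells && tries < 50L * n_cells) {
      cand <- c(stats::runif(1, r + 1, nr - r), stats::runif(1, r + 1, nc - r))
      tries <- tries + 1L
      if (vmask[round(cand[1]), round(cand[2])]) next
      if (nrow(centres) &&
          min(sqrt(rowSums(sweep(centres, 2, cand)^2))) < 2 * r + 2) next
      centres <- rbind(centres, cand)
    }
    n <- nrow(centres)
    n_double <- round(frac_double * n)
    n_a_only <- floor((n - n_double) / 2)
    kind <- sample(c(rep("both", n_double), rep("a", n_a_only),
                     rep("b", n - n_double - n_a_only)))
    cha <- matrix(pmax(stats::rnorm(nr * nc, 5, 2), 0), nr, nc)
    chb <- matrix(pmax(stats::rnorm(nr * nc, 5, 2), 0), nr, nc)
    off <- as.matrix(expand.grid(i = -r:r, j = -r:r))
    off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
    for (ci in seq_len(n)) {
      pix <- sweep(off, 2, round(centres[ci, ]), "+")
      lin <- pix[, 1] + (pix[, 2] - 1) * nr
      amp <- stats::runif(1, 150, 250)
      if (kind[ci] %in% c("both", "a")) cha[lin] <- amp
      if (kind[ci] %in% c("both", "b")) chb[lin] <- amp
    }
    cells <- data.frame(
      cell_id = seq_len(n),
      row = centres[, 1], col = centres[, 2],
      positive_a = kind %in% c("both", "a"),
      positive_b = kind %in% c("both", "b"),
      distance_to_vessel_um = dist_um[cbind(round(centres[, 1]),
                                            round(centres[, 2]))])
    list(image = fluor_image(cha, chb, pixel_size_um), cells = cells,
         vessel_mask = vmask)
  })
}

#' Two-channel fluorescence image
#' @param a,b 2D intensity matrices of identical shape (channel A = TSPO
#'   analogue, channel B = Iba1/F4-80 analogue); intensities must be >= 0.
#' @param pixel_size_um pixel pitch, micrometres.
#' @return object of class `fluor_image`.
#' @export
fluor_image <- function(a, b, pixel_size_um = 1) {
  if (!all(dim(a) == dim(b))) stop("channels must share shape")
  if (min(a) < 0 || min(b) < 0) stop("intensities must be non-negative")
  structure(list(a = a, b = b, pixel_size_um = pixel_size_um),
            class = "fluor_image")
}
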