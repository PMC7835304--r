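#' Default EAE / control effect profile
#'
#' Per-region group means and SDs of SUVR and SPIO-Vol used by the cohort
#' generator as realistic settings for a symptomatic-EAE vs control contrast
#' (neocortex is the SUVR reference, so its ratio is 1 with zero spread in
#' both groups; its SPIO load is small and similar between groups).
#'
#' @return data frame with columns `region`, `suvr_eae_mean`, `suvr_eae_sd`,
#'   `suvr_ctr_mean`, `suvr_ctr_sd`, `spio_eae_mean`, `spio_eae_sd`,
#'   `spio_ctr_mean`, `spio_ctr_sd`.
#' @export
default_effect_profile <- function() {
  data.frame(
    region        = c("caudate_putamen", "hippocampus", "thalamus",
                      "cerebellum", "brainstem", "neocortex"),
    suvr_eae_mean = c(1.2, 1.6, 1.5, 2.4, 2.0, 1.0),
    suvr_eae_sd   = c(0.1, 0.1, 0.2, 0.2, 0.3, 0.0),
    suvr_ctr_mean = c(1.0, 1.3, 1.1, 1.9, 1.4, 1.0),
    suvr_ctr_sd   = c(0.1, 0.1, 0.1, 0.3, 0.1, 0.0),
    spio_eae_mean = c(5.4, 5.7, 7.3, 14.5, 9.0, 0.5),
    spio_eae_sd   = c(4.5, 2.6, 5.5, 7.5, 8.1, 0.5),
    spio_ctr_mean = c(0.6, 1.7, 1.6, 3.9, 0.5, 0.3),
    spio_ctr_sd   = c(1.1, 1.5, 1.7, 2.8, 0.5, 0.3))
}

#' Default monotone lesion-burden to clinical-score link
#'
#' Increasing affine map from mean lesion burden (percent) to the 0-4
#' clinical score, quantised to the 0.5-step scale. Controls are
#' sham-immunised and asymptomatic, so the link applies to EAE animals only.
#'
#' @param burden mean SPIO lesion fraction across regions, percent.
#' @return clinical score on the `{0, 0.5, ..., 4}` scale.
#' @export
default_cs_link <- function(burden) {
  quantize_cs(0.8 + 0.22 * burden)
}

#' Generate a complete synthetic EAE / control cohort
#'
#' Draws per-animal uptake ratios and lesion fractions from the effect
#' profile, with a shared latent severity factor so that SUVR elevation,
#' lesion burden and clinical score rise together (giving the pipeline a
#' recoverable correlation structure). SUVR values are drawn with normal
#' marginals (ratios with small coefficients of variation); SPIO lesion
#' fractions with gamma marginals matched to the profile's mean and SD
#' through a Gaussian copula on the severity factor, since burdens are
#' non-negative with SDs comparable to their means. When `images = TRUE` the
#' generator additionally
#' synthesises the full imaging bundle per animal: dynamic PET, misaligned
#' SPIO-MRI with bias field, jittered fiducial landmarks and recorded ground
#' truth. With `images = FALSE` only the ground-truth measurements and
#' metadata are produced, which is what the statistical simulation studies
#' need.
#'
#' @param n_eae,n_ctr group sizes (both at least 2; defaults 7 vs 5).
#' @param effect_profile data frame as [default_effect_profile()]; `NULL`
#'   gives a null cohort (EAE distribution identical to control, for type-I
#'   error studies).
#' @param cs_link monotone function mapping mean lesion burden (percent) to
#'   clinical score; applied to EAE animals (controls score 0).
#' @param seed integer seed controlling all randomness.
#' @param images synthesise image volumes (TRUE) or ground-truth
#'   measurements only (FALSE).
#' @param atlas optional pre-built `atlas_phantom` (built from `grid_shape`
#'   and `voxel_size_mm` when NULL).
#' @param grid_shape,voxel_size_mm atlas grid (when `atlas` is NULL).
#' @param psf_fwhm_mm,pet_noise_sd PET point-spread FWHM (mm) and frame noise
#'   fraction.
#' @param mri_noise_sd,bias_amplitude,lesion_contrast MRI noise fraction,
#'   bias-field peak deviation, lesion signal drop.
#' @param landmark_jitter_mm fiducial identification error SD, mm.
#' @param misalign_rot_deg,misalign_trans_mm bounds of the random rigid
#'   inter-session misalignment.
#' @param severity_loading share of per-region variance carried by the
#'   common severity factor, in `[0, 1)`.
#' @return list with `atlas` (when `images = TRUE`), `animals` (list of
#'   per-animal bundles) and `cohort` (metadata data frame: `animal_id`,
#'   `group`, `dose_MBq`, `weight_g`, `cs`, `day_post_immunization`).
#' @export
generate_cohort <- function(n_eae = 7L, n_ctr = 5L,
                            effect_profile = default_effect_profile(),
                            cs_link = default_cs_link,
                            seed = 1L, images = TRUE, atlas = NULL,
                            grid_shape = c(64, 64, 64), voxel_size_mm = 0.25,
                            psf_fwhm_mm = 0.9, pet_noise_sd = 0.05,
                            mri_noise_sd = 0.05, bias_amplitude = 0.2,
                            lesion_contrast = 0.7,
                            landmark_jitter_mm = 0.05,
                            misalign_rot_deg = 3, misalign_trans_mm = 0.5,
                            severity_loading = 0.8) {
  if (n_eae < 2 || n_ctr < 2)
    stop("n_eae and n_ctr must both be at least 2")
  if (severity_loading < 0 || severity_loading >= 1)
    stop("severity_loading must lie in [0, 1)")
  prof <- if (is.null(effect_profile)) {
    p <- default_effect_profile()
    p$suvr_eae_mean <- p$suvr_ctr_mean; p$suvr_eae_sd <- p$suvr_ctr_sd
    p$spio_eae_mean <- p$spio_ctr_mean; p$spio_eae_sd <- p$spio_ctr_sd
    p
  } else effect_profile
  if (images && is.null(atlas))
    atlas <- generate_atlas(grid_shape, voxel_size_mm)

  maybe_with_seed(seed, {
    groups <- c(rep("EAE", n_eae), rep("CTR", n_ctr))
    ids <- c(sprintf("EAE%02d", seq_len(n_eae)), sprintf("CTR%02d", seq_len(n_ctr)))
    lam <- severity_loading
    animals <- vector("list", length(ids))
    meta <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      g <- groups[i]
      s <- stats::rnorm(1)
      e <- stats::rnorm(nrow(prof))
      mix <- lam * s + sqrt(1 - lam^2) * e
      if (g == "EAE") {
        suvr <- prof$suvr_eae_mean + prof$suvr_eae_sd * mix
        spio <- gamma_from_gaussian(mix, prof$spio_eae_mean, prof$spio_eae_sd)
        weight <- stats::rnorm(1, 17.14, 1.69)
        day <- sample(11:14, 1)
      } else {
        suvr <- prof$suvr_ctr_mean + prof$suvr_ctr_sd * mix
        spio <- gamma_from_gaussian(mix, prof$spio_ctr_mean, prof$spio_ctr_sd)
        weight <- stats::rnorm(1, 19.63, 0.83)
        day <- sample(11:13, 1)
      }
      suvr <- pmax(suvr, 0.1); names(suvr) <- prof$region
      suvr[["neocortex"]] <- 1
      names(spio) <- prof$region
      dose <- stats::runif(1, 5.55, 7.0)
      bundle <- list(animal_id = ids[i],
                     truth = list(true_suvr = suvr, true_spio = spio,
                                  severity = s))
      if (images) {
        mis <- random_rigid(misalign_rot_deg, misalign_trans_mm)
        petg <- generate_pet(atlas, suvr, reference_suv = max(stats::rnorm(1, 0.21, 0.09), 0.05),
                             dose_MBq = dose, weight_g = max(weight, 10),
                             psf_fwhm_mm = psf_fwhm_mm, noise_sd = pet_noise_sd,
                             seed = NULL)
        mrig <- generate_spio_mri(atlas, spio, lesion_contrast = lesion_contrast,
                                  bias_amplitude = bias_amplitude,
                                  noise_sd = mri_noise_sd, misalignment = mis,
                                  seed = NULL)
        jit <- function(lms) landmark_set(
          lms$name,
          as.matrix(lms[, c("x", "y", "z")]) +
            matrix(stats::rnorm(3 * nrow(lms), sd = landmark_jitter_mm),
                   ncol = 3))
        bundle$pet <- petg$pet
        bundle$mri <- mrig$mri
        bundle$landmarks_pet <- jit(atlas$landmarks)
        bundle$landmarks_mri <- jit(mrig$landmarks_mri)
        bundle$truth <- c(bundle$truth, mrig$truth)
        burden <- mean(mrig$truth$true_lesion_fraction)
      } else {
        burden <- mean(spio)
      }
      cs <- if (g == "EAE") cs_link(burden) else 0
      bundle$record <- list(animal_id = ids[i], group = g, dose_MBq = dose,
                            weight_g = weight, cs = cs,
                            day_post_immunization = day)
      animals[[i]] <- bundle
      meta[[i]] <- as.data.frame(bundle$record)
    }
    out <- list(animals = animals, cohort = do.call(rbind, meta))
    if (images) out$atlas <- atlas
    out
  })
}

# map a standard-normal draw to a gamma marginal with the given mean and SD
# (Gaussian copula): lesion burdens are non-negative with SDs on the order of
# their means, which a normal marginal cannot represent
gamma_from_gaussian <- function(z, mu, sd) {
  out <- numeric(length(z))
  for (i in seq_along(z)) {
    if (mu[i] <= 0) { out[i] <- 0; next }
    if (sd[i] <= 0) { out[i] <- mu[i]; next }
    shape <- (mu[i] / sd[i])^2
    out[i] <- stats::qgamma(stats::pnorm(z[i]), shape = shape,
                            scale = sd[i]^2 / mu[i])
  }
  out
}

#' Ground-truth measurement tables of a cohort
#'
#' Flattens the per-animal true SUVR and SPIO fraction values into the tidy
#' region-table format, bypassing the imaging arm; used for statistical
#' simulation at scale.
#'
#' @param cohort result of [generate_cohort()].
#' @return data frame (`animal_id`, `region`, `metric`, `value`) with
#'   metrics `SUVR` and `SPIO_Vol_pct`.
#' @export
cohort_truth_tables <- function(cohort) {
  do.call(rbind, lapply(cohort$animals, function(a) {
    rbind(
      data.frame(animal_id = a$animal_id, region = names(a$truth$true_suvr),
                 metric = "SUVR", value = unname(a$truth$true_suvr)),
      data.frame(animal_id = a$animal_id, region = names(a$truth$true_spio),
                 metric = "SPIO_Vol_pct", value = unname(a$truth$true_spio)))
  }))
}
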