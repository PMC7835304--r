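#' Build a validated pipeline run configuration
#'
#' @param seed integer seed controlling every random draw of the run.
#' @param n_eae,n_ctr cohort sizes (at least 2 each).
#' @param grid_shape,voxel_size_mm atlas grid.
#' @param psf_fwhm_mm,pet_noise_sd PET simulation settings.
#' @param mri_noise_sd,bias_amplitude,lesion_contrast MRI simulation
#'   settings.
#' @param spio_k,spio_min_cluster SPIO labelling parameters (lower cut in
#'   robust sigmas; minimum cluster size in voxels).
#' @param reference_region SUVR reference region.
#' @param landmark_jitter_mm,misalign_rot_deg,misalign_trans_mm registration
#'   challenge settings.
#' @param out_dir run directory.
#' @param save_images also write per-animal NIfTI volumes and transform JSON
#'   files (larger, slower; off by default).
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed = 1L, n_eae = 7L, n_ctr = 5L,
                       grid_shape = c(64, 64, 64), voxel_size_mm = 0.25,
                       psf_fwhm_mm = 0.9, pet_noise_sd = 0.05,
                       mri_noise_sd = 0.05, bias_amplitude = 0.2,
                       lesion_contrast = 0.7, spio_k = 3.0,
                       spio_min_cluster = 2L, reference_region = "neocortex",
                       landmark_jitter_mm = 0.05, misalign_rot_deg = 3,
                       misalign_trans_mm = 0.5, out_dir = tempfile("petspio_run_"),
                       save_images = FALSE) {
  cfg <- list(seed = as.integer(seed), n_eae = as.integer(n_eae),
              n_ctr = as.integer(n_ctr), grid_shape = as.integer(rep_len(grid_shape, 3)),
              voxel_size_mm = as.numeric(voxel_size_mm),
              psf_fwhm_mm = psf_fwhm_mm, pet_noise_sd = pet_noise_sd,
              mri_noise_sd = mri_noise_sd, bias_amplitude = bias_amplitude,
              lesion_contrast = lesion_contrast, spio_k = spio_k,
              spio_min_cluster = as.integer(spio_min_cluster),
              reference_region = reference_region,
              landmark_jitter_mm = landmark_jitter_mm,
              misalign_rot_deg = misalign_rot_deg,
              misalign_trans_mm = misalign_trans_mm,
              out_dir = out_dir, save_images = isTRUE(save_images))
  if (is.na(cfg$seed)) stop("config error: seed must be an integer")
  if (cfg$n_eae < 2 || cfg$n_ctr < 2)
    stop("config error: n_eae and n_ctr must both be at least 2")
  if (any(cfg$grid_shape < 16))
    stop("config error: grid_shape must be at least 16 voxels per axis")
  if (cfg$lesion_contrast <= 0 || cfg$lesion_contrast >= 1)
    stop("config error: lesion_contrast must lie in (0, 1)")
  if (cfg$spio_k <= 0) stop("config error: spio_k must be positive")
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full phantom-to-report pipeline
#'
#' Orchestrates one reproducible end-to-end run: synthetic cohort generation,
#' landmark rigid MRI-to-PET co-registration composed with affine
#' normalisation to atlas space, MRI resampling, PET SUV / windowed-sum /
#' SUVR quantification, SPIO brain extraction, bias correction, histogram
#' thresholding and fractional volumes, and the group/correlation report.
#' When an animal shows labelled SPIO voxels inside the reference region,
#' those voxels are excluded from the reference SUV (the
#' "unaffected neocortex" rule). All outputs, the configuration, and a
#' manifest with per-file checksums are written to the run directory; the
#' run is deterministic for a fixed seed. A stage failure aborts with the
#' stage name; outputs of completed stages remain on disk.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @return invisibly, a list with `run_dir`, `results` (the
#'   `results_report`), `suvr`, `spiovol`, `registration` and `cohort`
#'   tables.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("phantom", generate_cohort(
    n_eae = config$n_eae, n_ctr = config$n_ctr, seed = config$seed,
    images = TRUE, grid_shape = config$grid_shape,
    voxel_size_mm = config$voxel_size_mm, psf_fwhm_mm = config$psf_fwhm_mm,
    pet_noise_sd = config$pet_noise_sd, mri_noise_sd = config$mri_noise_sd,
    bias_amplitude = config$bias_amplitude,
    lesion_contrast = config$lesion_contrast,
    landmark_jitter_mm = config$landmark_jitter_mm,
    misalign_rot_deg = config$misalign_rot_deg,
    misalign_trans_mm = config$misalign_trans_mm))
  atlas <- cohort$atlas

  suvr_rows <- list(); spio_rows <- list(); reg_rows <- list()
  img_dir <- file.path(config$out_dir, "images")
  if (config$save_images) dir.create(img_dir, showWarnings = FALSE)

  for (an in cohort$animals) {
    id <- an$animal_id
    rigid <- stage(paste0("coreg:", id),
                   estimate_rigid(an$landmarks_mri, an$landmarks_pet))
    affine <- stage(paste0("normalize:", id),
                    estimate_affine(an$landmarks_pet, atlas$landmarks))
    total <- compose_transforms(affine$transform, rigid$transform)
    reg_rows[[id]] <- data.frame(animal_id = id, rigid_rms_mm = rigid$rms_mm,
                                 affine_rms_mm = affine$rms_mm)

    # segment in native MRI space (crisp intensities), then propagate the
    # binary labels to atlas space with nearest-neighbour for VOI accounting
    sp <- stage(paste0("spio:", id), {
      brain <- extract_brain(an$mri)
      bc <- correct_bias(an$mri, brain)
      label_spio(bc$corrected, brain, k = config$spio_k,
                 min_cluster_vox = config$spio_min_cluster)
    })
    labels_atlas <- stage(paste0("resample:", id),
                          resample(sp$labels, total, atlas$labels, "nearest"))
    spio_rows[[id]] <- spio_vol_table(labels_atlas, atlas, id)

    pt <- stage(paste0("pet:", id), {
      summed <- sum_window(an$pet)
      suv <- compute_suv(summed, an$pet$dose_MBq, an$pet$weight_g)
      ref_lesions <- labels_atlas$data > 0 & region_mask(atlas, config$reference_region)
      compute_suvr(suv, atlas, animal_id = id,
                   reference = config$reference_region,
                   exclude_mask = if (any(ref_lesions)) ref_lesions)
    })
    suvr_rows[[id]] <- pt

    if (config$save_images) {
      mri_atlas <- resample(an$mri, total, atlas$labels, "trilinear")
      write_volume(mri_atlas, file.path(img_dir, paste0(id, "_mri_atlas.nii.gz")))
      write_volume(labels_atlas, file.path(img_dir, paste0(id, "_spio_labels_atlas.nii.gz")))
      write_transform_json(total, file.path(img_dir, paste0(id, "_to_atlas.json")))
    }
  }

  suvr <- do.call(rbind, unname(suvr_rows))
  spiovol <- do.call(rbind, unname(spio_rows))
  registration <- do.call(rbind, unname(reg_rows))
  results <- stage("report", build_results(suvr, spiovol, cohort$cohort))

  wr <- function(d, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    p
  }
  paths <- c(wr(cohort$cohort, "cohort.csv"), wr(suvr, "suvr.csv"),
             wr(spiovol, "spiovol.csv"), wr(registration, "registration.csv"),
             write_results(results, config$out_dir), cfg_path)
  manifest <- list(
    package = "petspio",
    version = as.character(utils::packageVersion("petspio")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    checksums = as.list(tools::md5sum(sort(paths))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(run_dir = config$out_dir, results = results, suvr = suvr,
                 spiovol = spiovol, registration = registration,
                 cohort = cohort$cohort))
}
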