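#' Convert an activity image to standardized uptake values
#'
#' SUV = tissue activity (MBq/cm^3) / (injected dose (MBq) / body weight
#' (g)); voxelwise and linear in activity.
#'
#' @param activity a [volume3d()] (or 3D array) of activity concentration,
#'   MBq/cm^3.
#' @param dose_MBq injected dose, MBq (> 0).
#' @param weight_g body weight, g (> 0).
#' @return a [volume3d()] of dimensionless SUV.
#' @examples
#' v <- volume3d(array(0.2, c(4, 4, 4)))
#' compute_suv(v, dose_MBq = 5, weight_g = 20)$data[1]   # 0.8
#' @export
compute_suv <- function(activity, dose_MBq, weight_g) {
  if (dose_MBq <= 0 || weight_g <= 0)
    stop("dose_MBq and weight_g must be positive")
  if (!inherits(activity, "volume3d"))
    activity <- volume3d(activity)
  volume3d(activity$data / (dose_MBq / weight_g), affine = activity$affine,
           units = "SUV")
}

#' Sum (duration-weighted average) the PET frames of an analysis window
#'
#' Averages the frames whose intervals lie within `[t0_min, t1_min)`,
#' weighting by frame duration. For equal-length frames this equals the plain
#' frame mean; the duration weighting makes the result robust to unequal
#' frames, and downstream SUVR is invariant to the overall scale either way.
#'
#' @param pet a [dynamic_pet()].
#' @param t0_min,t1_min analysis window, minutes post-injection (defaults
#'   20-50 min, the late-phase window of a 6 x 5 min acquisition).
#' @return a [volume3d()] of windowed activity.
#' @export
sum_window <- function(pet, t0_min = 20, t1_min = 50) {
  ft <- pet$frame_times
  use <- ft$start_min >= t0_min & ft$end_min <= t1_min + 1e-9
  if (!any(use))
    stop(sprintf("window [%g, %g] min outside acquisition; frames cover [%g, %g] min",
                 t0_min, t1_min, min(ft$start_min), max(ft$end_min)))
  w <- (ft$end_min - ft$start_min)[use]
  idx <- which(use)
  acc <- array(0, dim(pet$frames)[1:3])
  for (i in seq_along(idx))
    acc <- acc + pet$frames[, , , idx[i]] * w[i]
  volume3d(acc / sum(w), affine = pet$affine, units = "MBq/cm3")
}

#' Mean value of a volume over one atlas region (VOI mean)
#'
#' @param volume a [volume3d()] on the atlas grid.
#' @param atlas an `atlas_phantom` on the same grid.
#' @param region region name.
#' @return arithmetic mean over the region's voxels; an empty region is an
#'   error, never a silent `NaN`.
#' @export
voi_mean <- function(volume, atlas, region) {
  if (!all(dim(volume$data) == dim(atlas$labels$data)))
    stop("volume and atlas must share a grid")
  m <- region_mask(atlas, region)
  if (!any(m)) stop("region '", region, "' has no voxels")
  mean(volume$data[m])
}

#' Per-region SUV and reference-normalised SUVR table
#'
#' Computes VOI mean SUVs and divides by the reference-region SUV (neocortex
#' by default). When a mouse shows evidence of cortical lesions, an
#' `exclude_mask` restricts the reference mean to the unaffected neocortex
#' voxels — the mask is an explicit input (typically derived from the SPIO
#' labels), not an automatic detector.
#'
#' @param suv a [volume3d()] of SUV on the atlas grid.
#' @param atlas an `atlas_phantom`.
#' @param animal_id identifier carried into the output table.
#' @param reference reference region name.
#' @param exclude_mask optional logical 3D array (or binary [volume3d()]) of
#'   voxels to exclude from the reference mean.
#' @return a data frame (`animal_id`, `region`, `metric`, `value`) with
#'   metrics `SUV` and `SUVR`; the reference region's SUVR is 1 by
#'   construction (when no mask is given).
#' @export
compute_suvr <- function(suv, atlas, animal_id = "animal",
                         reference = "neocortex", exclude_mask = NULL) {
  regions <- region_names(atlas)
  if (!reference %in% regions) stop("unknown reference region: ", reference)
  suvs <- vapply(regions, function(r) voi_mean(suv, atlas, r), 0)
  ref_m <- region_mask(atlas, reference)
  if (!is.null(exclude_mask)) {
    if (inherits(exclude_mask, "volume3d")) exclude_mask <- exclude_mask$data > 0
    ref_m <- ref_m & !exclude_mask
    if (!any(ref_m)) stop("exclude_mask removes the whole reference region")
  }
  ref_suv <- mean(suv$data[ref_m])
  if (ref_suv <= 0) stop("reference SUV is not positive")
  rbind(
    data.frame(animal_id = animal_id, region = regions, metric = "SUV",
               value = unname(suvs)),
    data.frame(animal_id = animal_id, region = regions, metric = "SUVR",
               value = unname(suvs) / ref_suv))
}
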