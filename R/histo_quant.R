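#' Normalise fluorescence intensities to the control-group mean
#'
#' Each value is expressed as a percentage of the averaged control value for
#' the same region, so the control group itself maps to mean 100. The
#' normalisation is scale-equivariant: rescaling all inputs by a constant
#' leaves the percentages unchanged.
#'
#' @param eae_values numeric intensities in the diseased group.
#' @param ctr_values numeric intensities in the control group (mean must be
#'   positive).
#' @return `eae_values * 100 / mean(ctr_values)`.
#' @examples
#' normalize_to_control(c(100), c(40, 60))   # 200
#' @export
normalize_to_control <- function(eae_values, ctr_values) {
  m <- mean(ctr_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  eae_values * 100 / m
}

#' Pixelwise two-channel co-localization percentage
#'
#' Thresholds each channel to its positive signal, then reports
#' `100 * |A+ and B+| / |B+|`: the extent of channel-A (TSPO) expression
#' within channel-B (Iba1) positive pixels. The denominator is exposed
#' because the convention is not universal.
#'
#' @param img a [fluor_image()].
#' @param threshold_method `"otsu"` (per-channel Otsu; channels must be
#'   non-constant) or `"fixed"` (supply `thresholds`).
#' @param thresholds length-2 numeric `(A, B)` used when
#'   `threshold_method = "fixed"`.
#' @param denominator positive-pixel set used as the denominator:
#'   channel B (default), channel A, or their union.
#' @return list with `percent` (NA and `flagged = TRUE` when the denominator
#'   set is empty — undefined, not 0), `mask_a`, `mask_b`, `threshold_a`,
#'   `threshold_b`, `flagged`.
#' @export
coloc_percent <- function(img, threshold_method = c("otsu", "fixed"),
                          thresholds = NULL,
                          denominator = c("channel_b", "channel_a", "union")) {
  threshold_method <- match.arg(threshold_method)
  denominator <- match.arg(denominator)
  if (threshold_method == "otsu") {
    if (diff(range(img$a)) == 0 || diff(range(img$b)) == 0)
      stop("otsu thresholding requires non-constant channels")
    ta <- EBImage::otsu(img$a, range = range(img$a))
    tb <- EBImage::otsu(img$b, range = range(img$b))
  } else {
    if (is.null(thresholds) || length(thresholds) != 2)
      stop("fixed thresholding requires `thresholds` of length 2")
    ta <- thresholds[1]; tb <- thresholds[2]
  }
  ma <- img$a > ta
  mb <- img$b > tb
  den <- switch(denominator, channel_b = mb, channel_a = ma, union = ma | mb)
  n_den <- sum(den)
  if (n_den == 0)
    return(list(percent = NA_real_, mask_a = ma, mask_b = mb,
                threshold_a = ta, threshold_b = tb, flagged = TRUE))
  list(percent = 100 * sum(ma & mb & den) / n_den,
       mask_a = ma, mask_b = mb, threshold_a = ta, threshold_b = tb,
       flagged = FALSE)
}

#' Perivascular co-expression percentages
#'
#' Restricts a cell table to cells within `max_dist_um` of the vessel border
#' (the manual-counting criterion applied algorithmically via the recorded
#' distances) and reports the percentage of iron-positive cells that
#' co-express the microglia/macrophage marker, and vice versa.
#'
#' @param cells data frame with logical columns `positive_iron`,
#'   `positive_marker` and numeric `distance_to_vessel_um`.
#' @param max_dist_um perivascular distance cut, micrometres (default 60).
#' @return list with `pct_iron_with_marker`, `pct_marker_with_iron`,
#'   `n_in_range`, and `flagged` (TRUE with NA percentages when no
#'   iron-positive — resp. marker-positive — cell lies in range: undefined,
#'   not 0).
#' @export
perivascular_coexpression <- function(cells, max_dist_um = 60) {
  need <- c("positive_iron", "positive_marker", "distance_to_vessel_um")
  if (!all(need %in% names(cells)))
    stop("cells table must have columns: ", paste(need, collapse = ", "))
  sub <- cells[cells$distance_to_vessel_um <= max_dist_um, , drop = FALSE]
  n_iron <- sum(sub$positive_iron)
  n_marker <- sum(sub$positive_marker)
  both <- sum(sub$positive_iron & sub$positive_marker)
  list(
    pct_iron_with_marker = if (n_iron) 100 * both / n_iron else NA_real_,
    pct_marker_with_iron = if (n_marker) 100 * both / n_marker else NA_real_,
    n_in_range = nrow(sub),
    flagged = n_iron == 0 || n_marker == 0)
}
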