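#' Fixed-SUV-threshold tumor segmentation
#'
#' Segments the metabolic tumor inside a user-drawn VOI by keeping voxels
#' with SUV strictly above a fixed threshold (default 2.5 g/mL, the common
#' choice in head-and-neck FDG-PET). The strict inequality makes tie
#' handling at the threshold reproducible: a voxel at exactly 2.5 is
#' excluded.
#'
#' @param volume An `image_volume` with modality `"PET_SUV"`.
#' @param voi A `voi_mask` delimiting the region drawn around the tumor.
#' @param threshold SUV threshold (g/mL); voxels kept iff SUV > threshold.
#' @param keep_largest If `TRUE` (default) retain only the largest
#'   26-connected component, guarding against disjoint physiologic-uptake
#'   specks inside a generous VOI.
#' @return A `voi_mask` of the segmented tumor. If no voxel exceeds the
#'   threshold an empty mask is returned with a warning.
#' @export
segment_fixed_threshold <- function(volume, voi, threshold = 2.5,
                                    keep_largest = TRUE) {
  stopifnot(inherits(volume, "image_volume"), inherits(voi, "voi_mask"))
  if (volume$modality != "PET_SUV")
    stop("fixed-threshold segmentation requires a PET_SUV volume, got ",
         volume$modality)
  check_grid(volume, voi)
  if (!any(voi$data)) stop("VOI mask is empty")
  m <- voi$data & (volume$data > threshold)
  if (!any(m)) {
    warning("no voxel exceeds SUV threshold ", threshold, "; empty mask")
    return(voi_mask(m))
  }
  if (keep_largest) m <- largest_component_26(m)
  voi_mask(m)
}

#' Background uptake from a reference sphere
#'
#' Mean SUV over a small spherical VOI (default diameter 10 mm) placed in a
#' lesion-free region, e.g. the lower neck; used as the reference level for
#' adaptive-threshold segmentation.
#'
#' @param volume An `image_volume`.
#' @param center Voxel coordinates of the sphere center (1-based).
#' @param diameter_mm Sphere diameter in mm.
#' @return Mean SUV (scalar) over voxels whose centers lie within
#'   `diameter_mm / 2` of the center.
#' @export
estimate_background <- function(volume, center, diameter_mm = 10) {
  stopifnot(inherits(volume, "image_volume"), length(center) == 3L,
            diameter_mm > 0)
  r <- diameter_mm / 2
  d <- dim(volume$data)
  # the sphere must fit inside the grid (voxel-center extent)
  lo <- center - r / volume$spacing_mm
  hi <- center + r / volume$spacing_mm
  if (any(lo < 1) || any(hi > d))
    stop("background sphere extends beyond the grid (center ",
         paste(center, collapse = ","), ", radius ", r, " mm)")
  sph <- sphere_mask(d, volume$spacing_mm, center, r)
  mean(volume$data[sph])
}

#' Adaptive-threshold tumor segmentation
#'
#' Background-referenced adaptive segmentation: the threshold is placed a
#' fraction of the way from the background uptake to the VOI's SUVmax,
#' \deqn{T = b + f (SUV_{max} - b),} and voxels with SUV > T inside the VOI
#' are kept. With `fraction = 0.5` this is the familiar "background + 50%
#' of (max - background)" rule.
#'
#' @inheritParams segment_fixed_threshold
#' @param background Background SUV, typically from [estimate_background()].
#' @param fraction Fraction in (0, 1) of the background-to-max range.
#' @return A `voi_mask`; the threshold used is attached as attribute
#'   `"threshold"` and the rule is recorded in attribute `"rule"`.
#' @export
segment_adaptive <- function(volume, voi, background, fraction = 0.5,
                             keep_largest = TRUE) {
  stopifnot(inherits(volume, "image_volume"), inherits(voi, "voi_mask"),
            is.numeric(background), length(background) == 1L)
  if (volume$modality != "PET_SUV")
    stop("adaptive segmentation requires a PET_SUV volume, got ",
         volume$modality)
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  check_grid(volume, voi)
  if (!any(voi$data)) stop("VOI mask is empty")
  suv_max <- max(volume$data[voi$data])
  if (suv_max <= background)
    stop("SUVmax within the VOI (", signif(suv_max, 4),
         ") does not exceed the background (", signif(background, 4),
         "): no lesion contrast")
  thr <- background + fraction * (suv_max - background)
  m <- voi$data & (volume$data > thr)
  if (any(m) && keep_largest) m <- largest_component_26(m)
  out <- voi_mask(m)
  attr(out, "threshold") <- thr
  attr(out, "rule") <- sprintf(
    "background + %.3g * (SUVmax - background), background = %.4g", fraction,
    background)
  out
}

#' Conventional PET metabolic parameters
#'
#' SUVmax, SUVmean, metabolic tumor volume (MTV, mL) and total lesion
#' glycolysis (TLG = SUVmean x MTV, g/mL x mL) over a segmented tumor mask.
#'
#' @param volume An `image_volume` in SUV units.
#' @param tumor_mask A nonempty `voi_mask` from one of the segmentation
#'   functions.
#' @return A list of class `conventional_pet_features` with elements
#'   `suv_max`, `suv_mean`, `mtv_ml`, `tlg`.
#' @examples
#' vol <- image_volume(array(4, c(2, 2, 2)), c(4, 4, 4), "PET_SUV")
#' conventional_features(vol, voi_mask(array(TRUE, c(2, 2, 2))))
#' @export
conventional_features <- function(volume, tumor_mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(tumor_mask, "voi_mask"))
  check_grid(volume, tumor_mask)
  if (!any(tumor_mask$data)) stop("tumor mask is empty")
  vals <- volume$data[tumor_mask$data]
  voxel_ml <- prod(volume$spacing_mm) / 1000
  mtv <- length(vals) * voxel_ml
  out <- list(suv_max = max(vals), suv_mean = mean(vals),
              mtv_ml = mtv, tlg = mean(vals) * mtv)
  class(out) <- "conventional_pet_features"
  out
}

#' @export
print.conventional_pet_features <- function(x, ...) {
  cat(sprintf("SUVmax %.4g g/mL  SUVmean %.4g g/mL  MTV %.4g mL  TLG %.4g g/mL*mL\n",
              x$suv_max, x$suv_mean, x$mtv_ml, x$tlg))
  invisible(x)
}
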