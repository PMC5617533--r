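#' Apparent diffusion coefficient from a two-b-value acquisition
#'
#' \deqn{ADC = \ln(S_0 / S_b) / b,} reported in units of
#' \eqn{10^{-3}} mm^2/s. The acquisition pairs a b = 0 volume with a
#' diffusion-weighted volume at b = 800 s/mm^2.
#'
#' @param s0_vol b = 0 volume: an `image_volume` or a numeric array/vector.
#' @param sb_vol Diffusion-weighted volume on the same grid.
#' @param b Diffusion weighting (s/mm^2), > 0.
#' @return ADC map (same shape as input) in 1e-3 mm^2/s. Voxels with
#'   non-positive signal are `NA`; voxels where `Sb > S0` produce negative
#'   ADC values. Both index sets are reported in attributes
#'   `"flagged_signal"` and `"flagged_negative"`.
#' @examples
#' compute_adc(1000, 1000 * exp(-0.8), b = 800)  # 1.0
#' @export
compute_adc <- function(s0_vol, sb_vol, b = 800) {
  if (b <= 0) stop("'b' must be positive")
  s0 <- if (inherits(s0_vol, "image_volume")) s0_vol$data else s0_vol
  sb <- if (inherits(sb_vol, "image_volume")) sb_vol$data else sb_vol
  if (!identical(dim(s0), dim(sb)) || length(s0) != length(sb))
    stop("b0 and diffusion-weighted volumes are on different grids")
  bad <- !(s0 > 0 & sb > 0)
  adc <- rep(NA_real_, length(s0))
  adc[!bad] <- log(s0[!bad] / sb[!bad]) / b * 1000
  if (!is.null(dim(s0))) adc <- array(adc, dim(s0))
  attr(adc, "flagged_signal") <- which(bad)
  attr(adc, "flagged_negative") <- which(!bad & sb > s0)
  adc
}

#' ROI summary of a parameter map
#'
#' Summarizes a voxel-wise map (ADC, K^trans, ...) over a region of
#' interest. Non-finite (flagged) voxels are excluded; per-lesion reporting
#' uses the mean by default.
#'
#' @param map Numeric array (or `image_volume`).
#' @param mask Logical array or `voi_mask`, same grid.
#' @param statistic Summary function (default `mean`); applied to the
#'   finite in-mask values.
#' @return Scalar summary. Errors if the mask is empty or retains no finite
#'   voxel.
#' @export
roi_summarize <- function(map, mask, statistic = mean) {
  if (inherits(map, "image_volume")) map <- map$data
  if (inherits(mask, "voi_mask")) mask <- mask$data
  if (!identical(dim(map), dim(mask)))
    stop("map and mask are on different grids")
  if (!any(mask)) stop("mask is empty")
  vals <- map[mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no finite in-mask values to summarize")
  statistic(vals)
}
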