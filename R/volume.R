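#' Image volume container
#'
#' A light container for a 3D scalar field on a regular grid: the voxel data,
#' the voxel spacing in millimetres, and a modality tag. PET volumes are
#' expected in standardized uptake value (SUV, g/mL) units.
#'
#' @param data Numeric 3D array of voxel values.
#' @param spacing_mm Numeric length-3 vector of voxel spacing (mm), all > 0.
#' @param modality One of `"PET_SUV"`, `"MR"`, `"DWI"`.
#' @return An object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(1, c(4, 4, 4)), spacing_mm = c(2, 2, 2),
#'                     modality = "PET_SUV")
#' dim(vol$data)
#' @export
image_volume <- function(data, spacing_mm, modality = c("PET_SUV", "MR", "DWI")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive finite numbers")
  if (any(!is.finite(data)))
    stop("'data' contains non-finite values")
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels  spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Volume-of-interest mask
#'
#' A binary 3D mask on the same grid as its parent volume, marking the region
#' inside which the analysis (segmentation, texture, ROI summaries) runs.
#'
#' @param data Logical 3D array (numeric input is coerced with `!= 0`).
#' @param volume Optional `image_volume` to validate the grid against.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(data, volume = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (!is.logical(data)) data <- array(data != 0, dim(data))
  if (!is.null(volume)) {
    stopifnot(inherits(volume, "image_volume"))
    if (!identical(dim(data), dim(volume$data)))
      stop("mask shape does not match volume shape")
  }
  structure(list(data = data), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voi_mask> %d x %d x %d voxels, %d set\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

n_voxels <- function(mask) sum(mask$data)

check_grid <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("volume and mask are on different grids")
  invisible(TRUE)
}

#' Spherical voxel-membership mask
#'
#' Marks voxels whose centers lie within `radius_mm` of a center voxel.
#' Voxel-center geometry is used everywhere in this package so that sphere
#' volumes are exactly countable.
#'
#' @param shape Integer length-3 grid shape.
#' @param spacing_mm Voxel spacing (mm).
#' @param center Voxel coordinates (1-based, may be fractional).
#' @param radius_mm Sphere radius (mm).
#' @return Logical 3D array.
#' @export
sphere_mask <- function(shape, spacing_mm, center, radius_mm) {
  stopifnot(length(shape) == 3L, length(center) == 3L, radius_mm >= 0)
  dx <- (seq_len(shape[1]) - center[1]) * spacing_mm[1]
  dy <- (seq_len(shape[2]) - center[2]) * spacing_mm[2]
  dz <- (seq_len(shape[3]) - center[3]) * spacing_mm[3]
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  array(d2 <= radius_mm^2, shape)
}

# The 26 offsets of the 3D Moore neighbourhood (Chebyshev distance 1).
neighbour_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# The 13 unique direction offsets (one per +/- pair).
direction_offsets_13 <- function() {
  g <- neighbour_offsets_26()
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[keep, , drop = FALSE]
}

# Label 26-connected components of a logical 3D array; returns an integer
# array (0 = background). Breadth-first flood fill on linear indices.
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- neighbour_offsets_26()
  idx_all <- which(mask)
  if (length(idx_all) == 0L) return(lab)
  coord <- arrayInd(idx_all, d)
  pos <- integer(prod(d)); pos[idx_all] <- seq_along(idx_all)
  comp <- 0L
  for (start in seq_along(idx_all)) {
    if (lab[idx_all[start]] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[idx_all[start]] <- comp
    while (length(queue)) {
      cur <- coord[queue, , drop = FALSE]
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nb <- cbind(cur[, 1] + offs[k, 1], cur[, 2] + offs[k, 2],
                    cur[, 3] + offs[k, 3])
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
        lin <- lin[mask[lin] & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- comp
          nxt <- c(nxt, pos[lin])
        }
      }
      queue <- unique(nxt)
    }
  }
  lab
}

# Keep the largest 26-connected component of a logical array.
largest_component_26 <- function(mask) {
  lab <- label_components_26(mask)
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that carry voxel spacing and the
#' modality tag between disk and the in-memory containers.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param modality Modality tag to attach on read.
#' @return `read_volume` returns an `image_volume`; `write_volume` returns
#'   the path invisibly.
#' @export
read_volume <- function(path, modality = c("PET_SUV", "MR", "DWI")) {
  modality <- match.arg(modality)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim(img)[1:3]), spacing, modality)
}

#' @rdname read_volume
#' @param volume An `image_volume` to write.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param mask A `voi_mask` to write (stored as 0/1).
#' @param spacing_mm Spacing recorded in the mask header.
#' @export
write_mask <- function(mask, path, spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(mask, "voi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  voi_mask(array(as.numeric(img) != 0, dim(img)[1:3]))
}
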