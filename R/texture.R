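#' Fixed-bin-number intensity resampling
#'
#' Resamples voxel intensities inside the segmented tumor onto a fixed
#' number of gray levels (32 or 64 in the standard analysis), the
#' discretization used by both co-occurrence and gray-tone-difference
#' features. The minimum in-mask intensity maps to level 1 and the maximum
#' to level `bins`:
#' \deqn{L = 1 + \lfloor B (I - I_{min}) / (I_{max} - I_{min}) \rfloor,}
#' with the top value clamped so that \eqn{I_{max}} receives level B.
#'
#' @param volume An `image_volume`.
#' @param mask A nonempty `voi_mask` (the segmented tumor).
#' @param bins Number of gray levels (any integer >= 2; 32 and 64 are the
#'   conventional choices).
#' @return A `label_volume`: integer labels in `[1, bins]` inside the mask,
#'   `NA` outside.
#' @export
resample_intensities <- function(volume, mask, bins = 32) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "voi_mask"))
  check_grid(volume, mask)
  bins <- as.integer(bins)
  if (bins < 2L) stop("'bins' must be at least 2")
  if (!any(mask$data)) stop("mask is empty")
  vals <- volume$data[mask$data]
  mn <- min(vals); mx <- max(vals)
  if (mx <= mn)
    stop("constant intensity inside the mask: resampling range undefined")
  lab <- array(NA_integer_, dim(volume$data))
  l <- 1L + as.integer(floor(bins * (vals - mn) / (mx - mn)))
  l[l > bins] <- bins
  lab[mask$data] <- l
  label_volume(lab, bins, mask$data)
}

#' Label volume constructor
#'
#' Wraps an already-discretized integer label array (levels `1..bins`
#' inside the mask) for the texture operations, e.g. when the
#' discretization was done outside [resample_intensities()].
#'
#' @param data Integer 3D array; values inside the mask must lie in
#'   `[1, bins]`.
#' @param bins Number of gray levels.
#' @param mask Logical 3D array of analysed voxels.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, bins, mask) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            identical(dim(mask), dim(data)))
  v <- data[mask]
  if (any(is.na(v)) || any(v < 1L) || any(v > bins))
    stop("in-mask labels must lie in [1, bins]")
  structure(list(data = data, bins = as.integer(bins), mask = mask),
            class = "label_volume")
}

# Directional pair counts for one offset; returns a bins x bins count matrix
# with both offset senses accumulated (symmetric).
.shift_range <- function(d, off) {
  lo <- max(1L, 1L - off); hi <- min(d, d - off)
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

.pair_counts <- function(lab, msk, off, bins) {
  d <- dim(lab)
  i1 <- .shift_range(d[1], off[1])
  i2 <- .shift_range(d[2], off[2])
  i3 <- .shift_range(d[3], off[3])
  if (!length(i1) || !length(i2) || !length(i3))
    return(matrix(0, bins, bins))
  a <- lab[i1, i2, i3, drop = FALSE]
  b <- lab[i1 + off[1], i2 + off[2], i3 + off[3], drop = FALSE]
  ok <- msk[i1, i2, i3, drop = FALSE] &
        msk[i1 + off[1], i2 + off[2], i3 + off[3], drop = FALSE]
  a <- a[ok]; b <- b[ok]
  if (!length(a)) return(matrix(0, bins, bins))
  cnt <- tabulate(a + (b - 1L) * bins, nbins = bins * bins) +
         tabulate(b + (a - 1L) * bins, nbins = bins * bins)
  matrix(cnt, bins, bins)
}

#' Normalized gray-level co-occurrence matrix (3D, 13 directions)
#'
#' Counts how often a voxel of resampled level i neighbours a voxel of level
#' j, over the 13 unique space directions at Chebyshev distance 1 (both
#' senses of each direction, so every matrix is symmetric). Each directional
#' matrix is normalized to sum 1 and the matrices are averaged over the
#' directions that contain at least one in-mask pair, giving an
#' orientation-invariant NGLCM.
#'
#' @param labels A `label_volume` from [resample_intensities()].
#' @return An object of class `nglcm` with elements `matrix` (bins x bins,
#'   entries summing to 1), `bins`, `n_directions` (directions with pairs)
#'   and `directional` (the per-direction normalized matrices).
#' @export
compute_nglcm <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  bins <- labels$bins
  offs <- direction_offsets_13()
  directional <- vector("list", nrow(offs))
  used <- logical(nrow(offs))
  for (k in seq_len(nrow(offs))) {
    cnt <- .pair_counts(labels$data, labels$mask, offs[k, ], bins)
    tot <- sum(cnt)
    if (tot > 0) {
      directional[[k]] <- cnt / tot
      used[k] <- TRUE
    }
  }
  if (!any(used))
    stop("no in-mask neighbour pairs in any direction; NGLCM undefined")
  directional <- directional[used]
  avg <- Reduce(`+`, directional) / length(directional)
  structure(list(matrix = avg, bins = bins, n_directions = length(directional),
                 directional = directional),
            class = "nglcm")
}

#' Second-order (NGLCM) heterogeneity parameters
#'
#' The seven Haralick-type features of the analysis: uniformity (the sum of
#' squared matrix entries, also called energy; high values mean a
#' homogeneous tumor), entropy (base-2 log), dissimilarity, contrast,
#' homogeneity, inverse difference moment, and correlation.
#'
#' @param m An `nglcm` object or a normalized co-occurrence matrix.
#' @return Named numeric vector of the seven features. For a degenerate
#'   matrix with zero gray-level variance, correlation is 0 by convention.
#' @export
nglcm_features <- function(m) {
  p <- if (inherits(m, "nglcm")) m$matrix else as.matrix(m)
  b <- nrow(p)
  lv <- seq_len(b)
  di <- matrix(lv, b, b) - matrix(lv, b, b, byrow = TRUE)  # i - j
  pos <- p > 0
  px <- rowSums(p)
  mu <- sum(lv * px)
  sig2 <- sum((lv - mu)^2 * px)
  corr <- if (sig2 <= .Machine$double.eps) 0 else
    sum(outer(lv - mu, lv - mu) * p) / sig2
  c(uniformity  = sum(p^2),
    entropy     = -sum(p[pos] * log2(p[pos])),
    dissimilarity = sum(abs(di) * p),
    contrast    = sum(di^2 * p),
    homogeneity = sum(p / (1 + abs(di))),
    inverse_difference_moment = sum(p / (1 + di^2)),
    correlation = corr)
}

#' Neighborhood gray-tone difference matrix
#'
#' For every in-mask voxel with at least one in-mask neighbour in its
#' 26-neighbourhood (the adjacent voxels within and across image planes),
#' accumulates the absolute difference between the voxel's level and the
#' mean level of its in-mask neighbours. Voxels without any in-mask
#' neighbour are excluded from the valid count.
#'
#' @param labels A `label_volume` from [resample_intensities()].
#' @return A list of class `ngtdm` with `p` (level occupancy probabilities,
#'   length `bins`, summing to 1), `s` (summed absolute neighbour
#'   differences per level), `n_valid` (number of contributing voxels) and
#'   `bins`.
#' @export
compute_ngtdm <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$data)
  bins <- labels$bins
  msk <- labels$mask
  lab0 <- labels$data
  lab0[!msk] <- 0L
  nb_sum <- array(0, d)
  nb_cnt <- array(0L, d)
  offs <- neighbour_offsets_26()
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    i1 <- .shift_range(d[1], off[1])
    i2 <- .shift_range(d[2], off[2])
    i3 <- .shift_range(d[3], off[3])
    if (!length(i1) || !length(i2) || !length(i3)) next
    j1 <- i1 + off[1]; j2 <- i2 + off[2]; j3 <- i3 + off[3]
    nb_sum[i1, i2, i3] <- nb_sum[i1, i2, i3] + lab0[j1, j2, j3]
    nb_cnt[i1, i2, i3] <- nb_cnt[i1, i2, i3] + msk[j1, j2, j3]
  }
  valid <- msk & nb_cnt > 0L
  n_valid <- sum(valid)
  if (n_valid == 0L) stop("no in-mask voxel has an in-mask neighbour")
  lv <- lab0[valid]
  dev <- abs(lv - nb_sum[valid] / nb_cnt[valid])
  s <- vapply(seq_len(bins), function(i) sum(dev[lv == i]), numeric(1))
  cnt <- tabulate(lv, nbins = bins)
  structure(list(p = cnt / n_valid, s = s, n_valid = n_valid, bins = bins),
            class = "ngtdm")
}

#' Higher-order (NGTDM) heterogeneity parameters
#'
#' Coarseness, contrast, busyness, complexity and strength in the
#' Amadasun-King form, computed over the occupied gray levels. A small
#' \eqn{\epsilon = 10^{-6}} regularizes the coarseness and strength
#' denominators so a perfectly flat image has finite (large) coarseness;
#' contrast and busyness are 0 by convention when fewer than two levels are
#' occupied.
#'
#' @param ngtdm An `ngtdm` object (or `p`); when `p` is a bare vector, `s`,
#'   `n_valid` must be supplied.
#' @param s,n_valid See [compute_ngtdm()].
#' @param eps Regularization constant.
#' @return Named numeric vector: coarseness, contrast, busyness, complexity,
#'   strength.
#' @export
ngtdm_features <- function(ngtdm, s = NULL, n_valid = NULL, eps = 1e-6) {
  if (inherits(ngtdm, "ngtdm")) {
    p <- ngtdm$p; s <- ngtdm$s; n_valid <- ngtdm$n_valid
  } else p <- ngtdm
  stopifnot(length(p) == length(s), n_valid > 0)
  occ <- which(p > 0)
  ng <- length(occ)
  pi_ <- p[occ]; si <- s[occ]; ii <- occ
  psum <- sum(pi_ * si)
  coarseness <- 1 / (eps + psum)
  if (ng < 2) {
    contrast <- 0; busyness <- 0; complexity <- 0
    strength <- 0
  } else {
    dij2 <- outer(ii, ii, `-`)^2
    pij <- outer(pi_, pi_)
    contrast <- sum(pij * dij2) / (ng * (ng - 1)) * sum(si) / n_valid
    bden <- sum(abs(outer(ii * pi_, ii * pi_, `-`)))
    busyness <- if (bden == 0) 0 else psum / bden
    psi <- pi_ * si
    complexity <- sum(abs(outer(ii, ii, `-`)) * outer(psi, psi, `+`) /
                        (n_valid * outer(pi_, pi_, `+`)))
    strength <- sum(outer(pi_, pi_, `+`) * dij2) / (eps + sum(si))
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' All heterogeneity parameters at 32 and 64 gray levels
#'
#' One-pass convenience wrapper: resamples the tumor intensities at each
#' requested bin count and returns the seven NGLCM and five NGTDM features,
#' named with a bin suffix (e.g. `uniformity_32`), matching the reporting
#' convention of the underlying analysis.
#'
#' @param volume An `image_volume` (PET SUV).
#' @param mask The segmented tumor `voi_mask`.
#' @param bins Integer vector of bin counts (default `c(32, 64)`).
#' @param average How to aggregate the 13 directions for NGLCM features:
#'   `"matrix"` averages the directional matrices and evaluates the features
#'   on the average (default); `"features"` evaluates the features per
#'   direction and averages the feature values.
#' @return Named numeric vector of `12 * length(bins)` features. The entropy
#'   log base (2) and the averaging mode are recorded as attributes.
#' @export
texture_features <- function(volume, mask, bins = c(32, 64),
                             average = c("matrix", "features")) {
  average <- match.arg(average)
  out <- numeric(0)
  for (b in bins) {
    lab <- resample_intensities(volume, mask, b)
    g <- compute_nglcm(lab)
    fg <- if (average == "matrix") nglcm_features(g) else
      rowMeans(vapply(g$directional, nglcm_features, numeric(7)))
    ft <- ngtdm_features(compute_ngtdm(lab))
    names(fg) <- paste0("nglcm_", names(fg), "_", b)
    names(ft) <- paste0("ngtdm_", names(ft), "_", b)
    out <- c(out, fg, ft)
  }
  attr(out, "entropy_log_base") <- 2
  attr(out, "direction_averaging") <- average
  out
}
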