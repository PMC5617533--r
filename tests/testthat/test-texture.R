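lab_from <- function(vals, dim3, bins, mask = NULL) {
  vol <- image_volume(array(vals, dim3), c(1, 1, 1), "PET_SUV")
  if (is.null(mask)) mask <- array(TRUE, dim3)
  resample_intensities(vol, voi_mask(mask), bins)
}

test_that("fixed-bin-number resampling maps the range onto 1..bins", {
  lab <- lab_from(0:31, c(32, 1, 1), 32)
  expect_identical(sort(unique(as.integer(lab$data))), 1:32)
  expect_identical(as.integer(lab$data), 1:32)  # bijective, order-preserving
  lab2 <- lab_from(c(2.5, 7.1, 9.9), c(3, 1, 1), 64)
  expect_identical(lab2$data[1, 1, 1], 1L)    # minimum -> level 1
  expect_identical(lab2$data[3, 1, 1], 64L)   # maximum -> level bins
  expect_error(lab_from(rep(3, 8), c(2, 2, 2), 32), "constant")
})

test_that("NGLCM of a constant region is a one-hot matrix", {
  lab <- label_volume(array(1L, c(3, 3, 3)), 2,
                      array(c(rep(TRUE, 26), FALSE), c(3, 3, 3)))
  g <- compute_nglcm(lab)
  expect_equal(g$matrix[1, 1], 1)
  expect_equal(sum(g$matrix), 1)
})

test_that("NGLCM of an alternating line matches the hand-enumerated matrix", {
  lab <- lab_from(c(1, 2, 1, 2), c(1, 1, 4), 2)
  g <- compute_nglcm(lab)
  expect_equal(g$n_directions, 1)  # only the in-line direction has pairs
  expect_equal(g$matrix, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("NGLCM entries always sum to one and stay symmetric", {
  for (s in 1:10) {
    ph <- random_label_phantom(s)
    g <- compute_nglcm(as_label_volume(ph))
    expect_equal(sum(g$matrix), 1, tolerance = 1e-9)
    expect_equal(g$matrix, t(g$matrix), tolerance = 1e-12)
  }
})

test_that("NGLCM features reproduce hand-evaluated matrices", {
  one_hot <- matrix(0, 3, 3); one_hot[2, 2] <- 1
  f <- nglcm_features(one_hot)
  expect_equal(f[["uniformity"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  expect_equal(f[["correlation"]], 0)   # sigma = 0 convention
  f2 <- nglcm_features(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(f2[["uniformity"]], 0.5)
  expect_equal(f2[["contrast"]], 1)
  expect_equal(f2[["dissimilarity"]], 1)
  expect_equal(f2[["entropy"]], 1)
  for (b in c(4, 32)) {
    fu <- nglcm_features(matrix(1 / b^2, b, b))
    expect_equal(fu[["entropy"]], 2 * log2(b))
    expect_equal(fu[["uniformity"]], 1 / b^2)
  }
})

test_that("NGTDM accumulators match hand enumeration on a 3-voxel line", {
  lab <- lab_from(c(1, 2, 1), c(1, 1, 3), 2)
  nt <- compute_ngtdm(lab)
  expect_equal(nt$s[1], 2)          # the two end voxels deviate by 1 each
  expect_equal(nt$s[2], 1)          # the center deviates by 1
  expect_equal(nt$n_valid, 3)
  expect_equal(sum(nt$p), 1)
  expect_equal(nt$p, c(2, 1) / 3)
})

test_that("flat regions give zero gray-tone differences and 1/eps coarseness", {
  msk <- array(c(rep(TRUE, 26), FALSE), c(3, 3, 3))
  lab <- label_volume(array(2L, c(3, 3, 3)), 4, msk)
  nt <- compute_ngtdm(lab)
  expect_true(all(nt$s == 0))
  f <- ngtdm_features(nt)
  expect_equal(f[["coarseness"]], 1e6)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["busyness"]], 0)
})

test_that("NGTDM features match independent substitution for the 3-voxel line", {
  lab <- lab_from(c(1, 2, 1), c(1, 1, 3), 2)
  f <- ngtdm_features(compute_ngtdm(lab))
  # direct substitution: p = (2/3, 1/3), s = (2, 1), n = 3, Ng = 2
  p <- c(2 / 3, 1 / 3); s <- c(2, 1); n <- 3
  psum <- sum(p * s)
  expect_equal(f[["coarseness"]], 1 / (1e-6 + psum))
  expect_equal(f[["contrast"]],
               (2 * p[1] * p[2] * 1) / (2 * 1) * sum(s) / n)
  # i * p_i is 2/3 for both levels, so the busyness denominator vanishes
  # and the documented 0-convention applies
  expect_equal(f[["busyness"]], 0)
  expect_equal(f[["complexity"]],
               2 * (1 / (n * (p[1] + p[2]))) * (p[1] * s[1] + p[2] * s[2]))
  expect_equal(f[["strength"]], 2 * (p[1] + p[2]) * 1 / (1e-6 + sum(s)))
})

test_that("NGLCM and NGTDM agree exactly with brute-force enumeration", {
  for (s in 1:60) {
    ph <- random_label_phantom(s)
    lab <- as_label_volume(ph)
    g <- tryCatch(compute_nglcm(lab), error = function(e) NULL)
    bf <- tryCatch(bf_nglcm(ph$lab, ph$mask, ph$bins),
                   error = function(e) NULL)
    expect_identical(is.null(g), is.null(bf))
    if (!is.null(g)) expect_equal(g$matrix, bf, tolerance = 1e-12)
    nt <- tryCatch(compute_ngtdm(lab), error = function(e) NULL)
    bt <- tryCatch(bf_ngtdm(ph$lab, ph$mask, ph$bins),
                   error = function(e) NULL)
    expect_identical(is.null(nt), is.null(bt))
    if (!is.null(nt)) {
      expect_equal(nt$p, bt$p, tolerance = 1e-12)
      expect_equal(nt$s, bt$s, tolerance = 1e-12)
      expect_identical(nt$n_valid, as.integer(bt$n_valid))
    }
  }
})

test_that("sharper checkerboards are measured as more heterogeneous", {
  # fixed-bin-number resampling is scale invariant, so widening the level
  # separation is expressed directly on the label scale: checkers at
  # levels 16 -/+ k for growing k
  d <- c(8, 8, 8)
  co <- arrayInd(1:prod(d), d)
  parity <- (co[, 1] + co[, 2] + co[, 3]) %% 2 == 0
  msk <- array(TRUE, d)
  unif <- c(); contr <- c()
  for (k in c(1, 3, 7, 15)) {
    labs <- array(ifelse(parity, 16L + k, 16L - k), d)
    tfg <- nglcm_features(compute_nglcm(label_volume(labs, 32, msk)))
    unif <- c(unif, tfg[["uniformity"]])
    contr <- c(contr, tfg[["contrast"]])
  }
  expect_true(all(diff(unif) <= 1e-12))
  expect_true(all(diff(contr) > 0))
})

test_that("feature vectors carry both bin counts with declared metadata", {
  ph <- generate_pet_phantom(
    lesion_spec(c(12, 12, 12), 8, texture = "gaussian-random-field",
                sd = 0.6, seed = 3),
    c(24, 24, 24), c(2, 2, 2))
  tf <- texture_features(ph$volume, ph$lesion_mask)
  expect_length(tf, 24)
  expect_true(all(c("nglcm_uniformity_32", "nglcm_uniformity_64",
                    "ngtdm_strength_32", "ngtdm_strength_64") %in%
                    names(tf)))
  expect_identical(attr(tf, "entropy_log_base"), 2)
  tf2 <- texture_features(ph$volume, ph$lesion_mask, average = "features")
  expect_identical(attr(tf2, "direction_averaging"), "features")
  expect_false(identical(tf[["nglcm_entropy_32"]],
                         tf2[["nglcm_entropy_32"]]))
})
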