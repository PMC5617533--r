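#' Lesion specification for PET phantoms
#'
#' Describes a spherical lesion embedded in a low-uptake background: its
#' center, radius, mean uptake, and the intratumoural texture used to
#' emulate metabolic heterogeneity.
#'
#' @param center Voxel coordinates (1-based) of the lesion center.
#' @param radius_mm Lesion radius (mm), > 0.
#' @param background_suv Background SUV (g/mL).
#' @param lesion_suv_mean Mean lesion SUV, must exceed the background.
#' @param texture One of `"constant"`, `"two-level-checker"` (alternating
#'   `lesion_suv_mean - delta` / `+ delta` by voxel parity), or
#'   `"gaussian-random-field"` (correlated Gaussian texture of standard
#'   deviation `sd` and correlation length `correlation_length_mm`).
#' @param delta Half level-separation of the checker texture (SUV).
#' @param sd Marginal standard deviation of the random-field texture (SUV).
#' @param correlation_length_mm Gaussian correlation length of the
#'   random-field texture (mm).
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius_mm, background_suv = 1,
                        lesion_suv_mean = 4,
                        texture = c("constant", "two-level-checker",
                                    "gaussian-random-field"),
                        delta = 1, sd = 0.5, correlation_length_mm = 2,
                        seed = 1L) {
  texture <- match.arg(texture)
  if (radius_mm <= 0) stop("'radius_mm' must be positive")
  if (lesion_suv_mean <= background_suv)
    stop("'lesion_suv_mean' must exceed 'background_suv'")
  structure(list(center = center, radius_mm = radius_mm,
                 background_suv = background_suv,
                 lesion_suv_mean = lesion_suv_mean, texture = texture,
                 delta = delta, sd = sd,
                 correlation_length_mm = correlation_length_mm,
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

# Correlated Gaussian field with unit marginal variance: white noise
# convolved with a Gaussian kernel, scaled by the kernel's l2 norm.
.gaussian_random_field <- function(shape, spacing_mm, corr_mm) {
  z <- array(stats::rnorm(prod(shape)), shape)
  if (corr_mm <= 0) return(z)
  sm <- z
  norm2 <- 1
  for (ax in 1:3) {
    sig_vox <- corr_mm / spacing_mm[ax]
    half <- max(1L, ceiling(3 * sig_vox))
    k <- exp(-0.5 * ((-half:half) / sig_vox)^2)
    norm2 <- norm2 * sum(k^2)
    sm <- .convolve_axis(sm, k, ax)
  }
  sm / sqrt(norm2)
}

# Same-size 1D convolution along one axis with zero padding.
.convolve_axis <- function(x, k, axis) {
  d <- dim(x)
  half <- (length(k) - 1L) / 2L
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, dp[1], dp[2] * dp[3])
  pad <- matrix(0, half, ncol(m))
  mp <- rbind(pad, m, pad)
  out <- matrix(0, dp[1], ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * mp[i:(i + dp[1] - 1L), , drop = FALSE]
  aperm(array(out, dp), order(perm))
}

#' Generate a PET phantom with a textured spherical lesion
#'
#' Builds an SUV volume containing one spherical lesion (voxel membership
#' by voxel-center distance) inside a uniform low-uptake background, plus a
#' generous VOI enclosing the lesion with a margin, emulating the manually
#' drawn tumor boundary. The ground-truth lesion mask is returned so
#' segmentation and volume estimates can be checked against known truth.
#'
#' @param spec A [lesion_spec()].
#' @param shape Grid shape (3 integers).
#' @param spacing_mm Voxel spacing (mm).
#' @param voi_margin_mm Margin added to the lesion radius for the VOI.
#' @return List with `volume` (`image_volume`), `voi` (`voi_mask`),
#'   `lesion_mask` (`voi_mask`, ground truth) and `spec`.
#' @export
generate_pet_phantom <- function(spec, shape = c(48, 48, 48),
                                 spacing_mm = c(2, 2, 2),
                                 voi_margin_mm = 6) {
  stopifnot(inherits(spec, "lesion_spec"))
  r_vox <- spec$radius_mm / spacing_mm
  lo <- spec$center - r_vox
  hi <- spec$center + r_vox
  if (any(lo < 1) || any(hi > shape))
    stop("lesion extent [", paste(signif(lo, 4), collapse = ","), "] - [",
         paste(signif(hi, 4), collapse = ","),
         "] exceeds the grid [1,1,1] - [", paste(shape, collapse = ","), "]")
  set.seed(spec$seed)
  lesion <- sphere_mask(shape, spacing_mm, spec$center, spec$radius_mm)
  vol <- array(spec$background_suv, shape)
  nles <- sum(lesion)
  vals <- switch(spec$texture,
    "constant" = rep(spec$lesion_suv_mean, nles),
    "two-level-checker" = {
      co <- arrayInd(which(lesion), shape)
      spec$lesion_suv_mean +
        ifelse((co[, 1] + co[, 2] + co[, 3]) %% 2 == 0, spec$delta,
               -spec$delta)
    },
    "gaussian-random-field" = {
      f <- .gaussian_random_field(shape, spacing_mm,
                                  spec$correlation_length_mm)
      spec$lesion_suv_mean + spec$sd * f[lesion]
    })
  vol[lesion] <- vals
  voi <- sphere_mask(shape, spacing_mm, spec$center,
                     spec$radius_mm + voi_margin_mm)
  list(volume = image_volume(vol, spacing_mm, "PET_SUV"),
       voi = voi_mask(voi), lesion_mask = voi_mask(lesion), spec = spec)
}

#' Generate a synthetic DCE-MRI acquisition
#'
#' Forward-simulates the full acquisition the pharmacokinetic pipeline
#' inverts: per-voxel extended-Kety tissue concentration from ground-truth
#' parameter maps, conversion to T1 via the relaxivity model, spoiled
#' gradient-echo dynamic signals at the dynamic flip angle, plus the
#' multi-flip-angle baseline volumes used for T1_0 mapping. The default
#' grid matches the acquisition protocol being emulated: 80 frames at
#' 3.3 s, flip angles 4/8/15/25 degrees, TR 3.5 ms, with 4 pre-bolus
#' baseline frames.
#'
#' @param ktrans_map,ve_map,vp_map 3D ground-truth parameter maps
#'   (min^-1 / dimensionless); `ve`, `vp` must lie in `[0, 1]`.
#' @param aif An `aif_curve` sampled on the frame times.
#' @param t10_map 3D baseline T1 map (ms), all > 0.
#' @param m0 Equilibrium magnetization (scalar or 3D map).
#' @param tr_ms Repetition time (ms).
#' @param flip_dyn_deg Dynamic-series flip angle (degrees).
#' @param flip_vfa_deg Baseline variable flip angles (degrees).
#' @param r1 Relaxivity (s^-1 mM^-1); default 3.6 (Gd-DTPA at 3 T).
#' @param noise_sd Additive Gaussian noise on the magnitude signal.
#' @param seed Integer seed for the noise.
#' @return List with `dynamic` (4D signal array), `vfa` (list of
#'   `signals` 3D arrays and `flip_angles_deg`), `times_s`, `aif` and the
#'   acquisition constants.
#' @export
generate_dce_series <- function(ktrans_map, ve_map, vp_map, aif, t10_map,
                                m0 = 1000, tr_ms = 3.5, flip_dyn_deg = 15,
                                flip_vfa_deg = c(4, 8, 15, 25), r1 = 3.6,
                                noise_sd = 0, seed = 1L) {
  stopifnot(inherits(aif, "aif_curve"))
  d <- dim(ktrans_map)
  stopifnot(identical(dim(ve_map), d), identical(dim(vp_map), d),
            identical(dim(t10_map), d))
  if (any(ve_map < 0 | ve_map > 1) || any(vp_map < 0 | vp_map > 1))
    stop("'ve' and 'vp' maps must lie in [0, 1]")
  if (any(ktrans_map > 0 & ve_map <= 0))
    stop("'ve' must be positive wherever ktrans > 0")
  if (any(t10_map <= 0)) stop("non-positive T1 in 't10_map'")
  nt <- length(aif$times_s)
  if (length(m0) == 1L) m0 <- array(m0, d)
  nvox <- prod(d)
  dyn <- matrix(0, nvox, nt)
  for (i in seq_len(nvox)) {
    ct <- kety_forward(ktrans_map[i], max(ve_map[i], 1e-6), vp_map[i], aif)
    r1_t <- 1000 / t10_map[i] + r1 * ct           # s^-1
    dyn[i, ] <- spgr_signal(m0[i], 1000 / r1_t, tr_ms, flip_dyn_deg)
  }
  vfa_signals <- lapply(flip_vfa_deg, function(a)
    array(spgr_signal(as.numeric(m0), as.numeric(t10_map), tr_ms, a), d))
  if (noise_sd > 0) {
    set.seed(seed)
    dyn <- dyn + stats::rnorm(length(dyn), sd = noise_sd)
    vfa_signals <- lapply(vfa_signals, function(v)
      v + array(stats::rnorm(length(v), sd = noise_sd), d))
  }
  list(dynamic = array(dyn, c(d, nt)),
       vfa = list(signals = vfa_signals, flip_angles_deg = flip_vfa_deg),
       times_s = aif$times_s, aif = aif,
       acquisition = list(tr_ms = tr_ms, flip_dyn_deg = flip_dyn_deg,
                          r1 = r1, n_baseline = sum(aif$cp_mM == 0)),
       truth = list(ktrans = ktrans_map, ve = ve_map, vp = vp_map,
                    t10_ms = t10_map))
}

#' Generate a two-b-value DWI pair from a known ADC field
#'
#' \deqn{S_b = S_0 e^{-b \cdot ADC} + \epsilon,} with ADC supplied in
#' 1e-3 mm^2/s and b in s/mm^2 (800 in the emulated protocol).
#'
#' @param adc_map ADC field in 1e-3 mm^2/s (array or scalar), >= 0.
#' @param s0 Unweighted signal (scalar or array).
#' @param b Diffusion weighting (s/mm^2), > 0.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return List with `b0` and `bw` arrays (unweighted / weighted) and `b`.
#' @export
generate_dwi_pair <- function(adc_map, s0 = 1000, b = 800, noise_sd = 0,
                              seed = 1L) {
  if (b <= 0) stop("'b' must be positive")
  if (any(adc_map < 0)) stop("'adc_map' must be non-negative")
  b0 <- s0 + 0 * adc_map
  bw <- s0 * exp(-b * adc_map * 1e-3)
  if (noise_sd > 0) {
    set.seed(seed)
    b0 <- b0 + stats::rnorm(length(b0), sd = noise_sd)
    bw <- bw + stats::rnorm(length(bw), sd = noise_sd)
    if (!is.null(dim(adc_map))) {
      b0 <- array(b0, dim(adc_map)); bw <- array(bw, dim(adc_map))
    }
  }
  list(b0 = b0, bw = bw, b = b)
}

#' Cohort specification for survival simulation
#'
#' Parameters of a synthetic patient cohort whose hazard increases
#' multiplicatively with the number of risk factors carried, emulating a
#' composite 0-4 prognostic score with administrative censoring.
#'
#' @param n Number of patients, >= 1.
#' @param score_probs Probability vector over scores 0..4 (sums to 1).
#' @param baseline_hazard Event hazard at score 0 (1/month).
#' @param hazard_ratio_per_point Hazard multiplier per score point, >= 1.
#' @param censor_time Administrative censoring time (months).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 124, score_probs = c(0, 0.09, 0.42, 0.38, 0.11),
                        baseline_hazard = 0.0012,
                        hazard_ratio_per_point = 2.5,
                        censor_time = 58, seed = 1L) {
  if (n < 1) stop("'n' must be at least 1")
  if (length(score_probs) != 5L || abs(sum(score_probs) - 1) > 1e-8)
    stop("'score_probs' must be 5 probabilities summing to 1")
  if (hazard_ratio_per_point < 1)
    stop("'hazard_ratio_per_point' must be >= 1")
  structure(list(n = as.integer(n), score_probs = score_probs,
                 baseline_hazard = baseline_hazard,
                 hazard_ratio_per_point = hazard_ratio_per_point,
                 censor_time = censor_time, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic survival cohort
#'
#' Draws a 0-4 score for each patient, sets binary risk-factor indicators
#' and continuous marker values consistent with that score (each satisfied
#' factor places its marker on the risky side of the standard cutoffs), and
#' simulates exponential overall-survival and recurrence-free-survival
#' times with hazard `baseline_hazard * hazard_ratio_per_point^score`,
#' censored administratively at `censor_time`.
#'
#' The four OS-type factors realized are smoking, low K^trans
#' (<= 0.5512 min^-1), low K_ep (<= 0.8872 min^-1) and low NGLCM
#' uniformity (<= 0.00381); subsite, alcohol and SUV are also generated so
#' that alternative risk definitions are evaluable on the same table.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame (one row per patient) with columns `id`, `score`,
#'   `smoking`, `alcohol`, `subsite`, `ktrans`, `kep`, `ve`, `uniformity`,
#'   `suv`, `adc`, `os_months`, `os_event`, `rfs_months`, `rfs_event`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  score <- sample(0:4, n, replace = TRUE, prob = spec$score_probs)
  # which of the four factors are "present", uniformly among subsets of
  # the right size
  flags <- t(vapply(score, function(s) {
    f <- rep(FALSE, 4)
    if (s > 0) f[sample.int(4, s)] <- TRUE
    f
  }, logical(4)))
  colnames(flags) <- c("smoking", "ktrans_low", "kep_low", "uniformity_low")
  rside <- function(risk, cutoff, lo, hi) # risky side is "<= cutoff"
    ifelse(risk, stats::runif(n, lo, cutoff), stats::runif(n, cutoff, hi))
  ktrans <- rside(flags[, "ktrans_low"], 0.5512, 0.05, 1.5)
  kep <- rside(flags[, "kep_low"], 0.8872, 0.1, 2.5)
  uniformity <- rside(flags[, "uniformity_low"], 0.00381, 0.001, 0.02)
  haz <- spec$baseline_hazard * spec$hazard_ratio_per_point^score
  draw_outcome <- function() {
    tt <- stats::rexp(n, rate = haz)
    ev <- tt <= spec$censor_time
    list(time = pmin(tt, spec$censor_time), event = as.integer(ev))
  }
  os <- draw_outcome(); rfs <- draw_outcome()
  data.frame(id = sprintf("P%03d", seq_len(n)), score = score,
             smoking = flags[, "smoking"],
             alcohol = stats::runif(n) < 0.65,
             subsite = sample(c("oropharynx", "hypopharynx"), n,
                              replace = TRUE),
             ktrans = ktrans, kep = kep, ve = ktrans / kep,
             uniformity = uniformity,
             suv = stats::rlnorm(n, log(13), 0.4),
             adc = stats::rnorm(n, 1.1, 0.2),
             os_months = os$time, os_event = os$event,
             rfs_months = rfs$time, rfs_event = rfs$event,
             stringsAsFactors = FALSE)
}

#' Read / write a cohort table
#'
#' CSV round trip for the per-patient table (one row per patient: id,
#' score, risk-factor flags, marker values, survival times and event
#' flags).
#'
#' @param cohort Data frame as returned by [generate_cohort()].
#' @param path CSV file path.
#' @return `write_cohort` returns the path invisibly; `read_cohort` the
#'   data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
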