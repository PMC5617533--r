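#' Spoiled gradient-echo steady-state signal
#'
#' \deqn{S = M_0 \sin\alpha (1 - E) / (1 - E \cos\alpha), \quad
#'       E = e^{-TR/T_1}.}
#' The TE-dependent T2* weighting is omitted (at TE ~ 1 ms it is a common
#' multiplicative factor that cancels throughout the analysis).
#'
#' @param m0 Equilibrium magnetization (signal units).
#' @param t1_ms Longitudinal relaxation time (ms), > 0.
#' @param tr_ms Repetition time (ms), > 0.
#' @param alpha_deg Flip angle (degrees).
#' @return Signal in the units of `m0`; vectorized over all arguments.
#' @export
spgr_signal <- function(m0, t1_ms, tr_ms, alpha_deg) {
  if (any(t1_ms <= 0)) stop("'t1_ms' must be positive")
  if (any(tr_ms <= 0)) stop("'tr_ms' must be positive")
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Baseline T1 mapping from variable flip angles (DESPOT1)
#'
#' Estimates T1_0 and M0 from spoiled gradient-echo signals acquired at two
#' or more flip angles (the acquisition uses 4, 8, 15 and 25 degrees) by
#' the linearized regression of \eqn{S/\sin\alpha} on \eqn{S/\tan\alpha}:
#' the slope equals \eqn{E_1 = e^{-TR/T_1}} and the intercept
#' \eqn{M_0 (1 - E_1)}.
#'
#' @param signals Numeric vector of signals, one per flip angle.
#' @param flip_angles_deg Flip angles (degrees), same length as `signals`.
#' @param tr_ms Repetition time (ms).
#' @return List with `t10_ms` and `m0`.
#' @export
fit_t10_vfa <- function(signals, flip_angles_deg, tr_ms) {
  if (length(signals) != length(flip_angles_deg))
    stop("'signals' and 'flip_angles_deg' lengths differ")
  if (length(unique(flip_angles_deg)) < 2L)
    stop("at least two distinct flip angles are required")
  if (any(signals <= 0)) stop("signals must be positive")
  a <- flip_angles_deg * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  if (!is.finite(slope) || slope <= 0 || slope >= 1)
    stop("VFA regression slope ", signif(slope, 4),
         " outside (0, 1): non-physical T1")
  list(t10_ms = as.numeric(-tr_ms / log(slope)),
       m0 = as.numeric(intercept / (1 - slope)))
}

#' Dynamic signal to contrast-agent concentration
#'
#' Converts a dynamic spoiled-gradient-echo signal time course to tissue
#' gadolinium concentration. The pre-bolus baseline (mean of the first
#' `n_baseline` frames, 4 in the acquisition) together with the baseline T1
#' fixes the effective M0; each dynamic sample is then inverted for T1(t)
#' and converted with the linear relaxivity model
#' \eqn{1/T_1(t) = 1/T_{1,0} + r_1 C(t)}.
#'
#' @param dyn_signal Numeric vector, dynamic signal over time for one voxel
#'   or ROI.
#' @param t10_ms Baseline T1 (ms).
#' @param tr_ms Repetition time (ms).
#' @param alpha_deg Dynamic flip angle (degrees; 15 in the acquisition).
#' @param r1 Longitudinal relaxivity (s^-1 mM^-1).
#' @param n_baseline Number of pre-bolus frames averaged for the baseline.
#' @return Numeric vector of concentrations (mM). Samples whose signal
#'   implies a non-physical T1 are returned as `NA` and their indices
#'   reported in attribute `"flagged"`.
#' @export
signal_to_concentration <- function(dyn_signal, t10_ms, tr_ms, alpha_deg,
                                    r1 = 3.6, n_baseline = 4) {
  stopifnot(t10_ms > 0, tr_ms > 0, r1 > 0, n_baseline >= 1,
            length(dyn_signal) > n_baseline)
  a <- alpha_deg * pi / 180
  s0 <- mean(dyn_signal[seq_len(n_baseline)])
  e10 <- exp(-tr_ms / t10_ms)
  # effective M0 from the baseline signal and T1_0
  m0 <- s0 * (1 - e10 * cos(a)) / (sin(a) * (1 - e10))
  ms <- m0 * sin(a)
  e1 <- (ms - dyn_signal) / (ms - dyn_signal * cos(a))
  bad <- !is.finite(e1) | e1 <= 0 | e1 >= 1
  r1_t <- rep(NA_real_, length(dyn_signal))
  r1_t[!bad] <- -log(e1[!bad]) / (tr_ms / 1000)   # s^-1
  conc <- (r1_t - 1000 / t10_ms) / r1
  conc[!bad & abs(conc) < 1e-12] <- 0
  attr(conc, "flagged") <- which(bad)
  conc
}

#' Arterial input function containers and a population curve
#'
#' `aif_curve()` packages a sampled plasma-concentration curve;
#' `aif_population()` evaluates a bi-exponential population input function
#' (Weinmann-type amplitudes with a short exponential rise) suitable when a
#' measured AIF is unavailable:
#' \deqn{C_p(t) = D [a_1 e^{-m_1 \tau} + a_2 e^{-m_2 \tau}]
#'       (1 - e^{-\tau/\tau_r}), \quad \tau = t - t_0,}
#' zero before the bolus arrival `t0_s`. Defaults: a1 = 3.99, a2 = 4.78
#' kg/L, m1 = 0.144, m2 = 0.0111 min^-1, dose 0.1 mmol/kg, rise constant
#' 5 s.
#'
#' @param times_s Sample times (s), strictly increasing.
#' @param cp_mM Plasma concentration (mM) at each time, >= 0.
#' @return An object of class `aif_curve` with `times_s` and `cp_mM`.
#' @export
aif_curve <- function(times_s, cp_mM) {
  if (length(times_s) != length(cp_mM)) stop("length mismatch")
  if (any(diff(times_s) <= 0)) stop("'times_s' must be strictly increasing")
  if (any(cp_mM < 0)) stop("negative plasma concentration")
  structure(list(times_s = as.numeric(times_s), cp_mM = as.numeric(cp_mM)),
            class = "aif_curve")
}

#' @rdname aif_curve
#' @param t0_s Bolus arrival time (s).
#' @param dose_mmol_kg Contrast dose (mmol per kg body weight).
#' @param a1,a2 Compartment amplitudes (kg/L).
#' @param m1,m2 Decay rates (min^-1).
#' @param rise_s Exponential rise time constant (s).
#' @export
aif_population <- function(times_s, t0_s = 13.2, dose_mmol_kg = 0.1,
                           a1 = 3.99, a2 = 4.78, m1 = 0.144, m2 = 0.0111,
                           rise_s = 5) {
  tau_min <- pmax(times_s - t0_s, 0) / 60
  tau_s <- pmax(times_s - t0_s, 0)
  cp <- dose_mmol_kg * (a1 * exp(-m1 * tau_min) + a2 * exp(-m2 * tau_min)) *
    (1 - exp(-tau_s / rise_s))
  cp[times_s <= t0_s] <- 0
  aif_curve(times_s, cp)
}

#' Extended Tofts-Kety forward model
#'
#' Tissue concentration from plasma concentration:
#' \deqn{C_t(t) = v_p C_p(t) +
#'   K^{trans} \int_0^t C_p(\tau) e^{-k_{ep}(t-\tau)} d\tau,}
#' with \eqn{k_{ep} = K^{trans}/v_e}. The convolution is evaluated exactly
#' for a piecewise-linear interpolation of the AIF against the exponential
#' kernel (no quadrature error beyond the AIF sampling itself). Rates are
#' in min^-1; the time grid is in seconds, converted internally.
#'
#' @param ktrans Volume transfer constant (min^-1), >= 0.
#' @param ve Fractional extravascular-extracellular volume, in (0, 1]
#'   (ignored when `ktrans = 0`).
#' @param vp Fractional plasma volume, in `[0, 1]`.
#' @param aif An `aif_curve`.
#' @return Tissue concentration (mM) on the AIF time grid.
#' @export
kety_forward <- function(ktrans, ve, vp, aif) {
  stopifnot(inherits(aif, "aif_curve"), ktrans >= 0, vp >= 0, vp <= 1)
  tt <- aif$times_s / 60      # minutes
  cp <- aif$cp_mM
  n <- length(tt)
  if (ktrans == 0) return(vp * cp)
  if (ve <= 0 || ve > 1) stop("'ve' must be in (0, 1]")
  kep <- ktrans / ve
  conv <- numeric(n)
  for (k in 2:n) {
    dt <- tt[k] - tt[k - 1]
    a <- cp[k - 1]
    b <- (cp[k] - cp[k - 1]) / dt
    ekd <- exp(-kep * dt)
    if (kep * dt < 1e-10) {
      seg <- a * dt + b * dt^2 / 2
    } else {
      seg <- a * (1 - ekd) / kep + b * (dt / kep - (1 - ekd) / kep^2)
    }
    conv[k] <- conv[k - 1] * ekd + seg
  }
  vp * cp + ktrans * conv
}

#' Fit the extended Tofts-Kety model to a tissue concentration curve
#'
#' Bounded Levenberg-Marquardt least squares over (K^trans, v_e, v_p), with
#' k_ep derived as K^trans / v_e. Default bounds: K^trans in [0, 5] min^-1,
#' v_e in [1e-3, 1], v_p in [0, 0.5]. Up to `n_starts` restarts from
#' dispersed initial values are tried when the first fit converges poorly;
#' a voxel that still fails is returned flagged with diagnostics rather
#' than raising an error, so map fitting can proceed.
#'
#' @param ct Tissue concentration (mM) over time.
#' @param aif An `aif_curve` on the same time grid.
#' @param init Optional numeric `c(ktrans, ve, vp)` starting point.
#' @param lower,upper Bounds on `c(ktrans, ve, vp)`.
#' @param n_starts Maximum number of starting points.
#' @return List of class `kety_fit`: `ktrans`, `ve`, `vp`, `kep`,
#'   `rss` (residual sum of squares), `converged`, `flagged`, `message`.
#' @export
fit_extended_kety <- function(ct, aif, init = c(0.1, 0.2, 0.05),
                              lower = c(0, 1e-3, 0), upper = c(5, 1, 0.5),
                              n_starts = 3) {
  stopifnot(inherits(aif, "aif_curve"), length(ct) == length(aif$times_s))
  if (length(ct) < 10) stop("at least 10 time points are required")
  if (max(abs(ct)) < 1e-12)
    return(structure(list(ktrans = 0, ve = lower[2], vp = 0, kep = 0,
                          rss = sum(ct^2), converged = TRUE, flagged = TRUE,
                          message = "no enhancement: parameters at bounds"),
                     class = "kety_fit"))
  resid_fn <- function(p) kety_forward(p[1], p[2], p[3], aif) - ct
  starts <- list(init, c(0.5, 0.5, 0.01), c(0.02, 0.1, 0.1))[seq_len(n_starts)]
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(par = fit$par, rss = rss, info = fit$info,
                   message = fit$message)
    if (!is.null(best) && best$rss <= 1e-10 * max(sum(ct^2), 1)) break
  }
  if (is.null(best))
    return(structure(list(ktrans = NA_real_, ve = NA_real_, vp = NA_real_,
                          kep = NA_real_, rss = NA_real_, converged = FALSE,
                          flagged = TRUE, message = "all starts failed"),
                     class = "kety_fit"))
  p <- best$par
  converged <- best$info %in% 1:3
  structure(list(ktrans = p[1], ve = p[2], vp = p[3], kep = p[1] / p[2],
                 rss = best$rss, converged = converged,
                 flagged = !converged, message = best$message),
            class = "kety_fit")
}

#' @export
print.kety_fit <- function(x, ...) {
  cat(sprintf("Ktrans %.4g /min  ve %.4g  vp %.4g  kep %.4g /min  rss %.3g%s\n",
              x$ktrans, x$ve, x$vp, x$kep, x$rss,
              if (isTRUE(x$flagged)) "  [flagged]" else ""))
  invisible(x)
}

#' Voxel-wise extended-Kety map fitting
#'
#' Applies [signal_to_concentration()] and [fit_extended_kety()] to every
#' in-mask voxel of a dynamic series, using per-voxel baseline T1 from a
#' supplied map or from multi-flip-angle baseline volumes.
#'
#' @param dynamic 4D array (x, y, z, time) of dynamic signal.
#' @param aif An `aif_curve` on the frame time grid.
#' @param mask Logical 3D array or `voi_mask` of voxels to fit.
#' @param t10_map 3D array of baseline T1 (ms); alternatively supply `vfa`.
#' @param vfa Optional list with `signals` (list of 3D arrays, one per flip
#'   angle) and `flip_angles_deg`; used to fit `t10_map` when not given.
#' @param tr_ms,alpha_deg,r1,n_baseline Acquisition constants as in
#'   [signal_to_concentration()].
#' @param ... Passed to [fit_extended_kety()].
#' @return List of 3D maps `ktrans`, `ve`, `vp`, `kep`, `rss`, logical
#'   `flagged`, plus `t10_ms` (the map used).
#' @export
fit_kety_map <- function(dynamic, aif, mask, t10_map = NULL, vfa = NULL,
                         tr_ms = 3.5, alpha_deg = 15, r1 = 3.6,
                         n_baseline = 4, ...) {
  if (inherits(mask, "voi_mask")) mask <- mask$data
  d <- dim(dynamic)
  stopifnot(length(d) == 4L, identical(dim(mask), d[1:3]))
  if (is.null(t10_map)) {
    if (is.null(vfa)) stop("supply either 't10_map' or 'vfa'")
    t10_map <- array(NA_real_, d[1:3])
    idx <- which(mask)
    sigs <- vapply(vfa$signals, function(v) v[idx], numeric(length(idx)))
    for (i in seq_along(idx))
      t10_map[idx[i]] <- fit_t10_vfa(sigs[i, ], vfa$flip_angles_deg,
                                     tr_ms)$t10_ms
  }
  maps <- list(ktrans = array(NA_real_, d[1:3]), ve = array(NA_real_, d[1:3]),
               vp = array(NA_real_, d[1:3]), kep = array(NA_real_, d[1:3]),
               rss = array(NA_real_, d[1:3]))
  flagged <- array(FALSE, d[1:3])
  idx <- which(mask)
  dyn_mat <- matrix(dynamic, prod(d[1:3]), d[4])
  for (i in idx) {
    conc <- signal_to_concentration(dyn_mat[i, ], t10_map[i], tr_ms,
                                    alpha_deg, r1, n_baseline)
    if (length(attr(conc, "flagged"))) { flagged[i] <- TRUE; next }
    f <- fit_extended_kety(as.numeric(conc), aif, ...)
    maps$ktrans[i] <- f$ktrans; maps$ve[i] <- f$ve; maps$vp[i] <- f$vp
    maps$kep[i] <- f$kep; maps$rss[i] <- f$rss
    flagged[i] <- isTRUE(f$flagged)
  }
  c(maps, list(flagged = flagged, t10_ms = t10_map))
}
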