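#' Per-point fluorescence drift slopes
#'
#' During a titration the intrinsic fluorescence can drift slowly with time;
#' at every titration point a short fluorescence-vs-time trace is recorded and
#' a straight line is fitted. The slopes, rescaled to per-interval units
#' (interval = time between successive titration points), feed
#' [drift_correct()].
#'
#' @param time_series A list, one element per titration point, each a
#'   data.frame/list with columns `t` (minutes) and `F` (signal). At least two
#'   samples per point.
#' @param interval Time between titration points, minutes (default 1).
#' @return A `drift_record`: list with `slopes` (signal per interval) and
#'   `interval`.
#' @export
fit_drift_slopes <- function(time_series, interval = 1) {
  slopes <- vapply(time_series, function(ts) {
    t <- as.numeric(ts$t); F <- as.numeric(ts$F)
    if (length(t) < 2L) stop("need >= 2 time samples per titration point")
    stats::cov(t, F) / stats::var(t)
  }, numeric(1))
  structure(list(slopes = slopes * interval, interval = interval),
            class = "drift_record")
}

#' Cumulative time-drift correction
#'
#' Corrects titration point `n` by the accumulated per-interval drift slopes:
#' \deqn{F^{cor}_n = F_n + s \sum_{m=1}^{n} a_m}
#' with `s = drift_sign`. The conventional form adds the slopes as fitted
#' (`drift_sign = +1`); because quenching drift has negative slopes, undoing an
#' accumulated downward drift requires `drift_sign = -1`. Both conventions are
#' available; the synthetic round-trip tests pin the self-consistent choice.
#'
#' @param F Observed signals, one per titration point.
#' @param drift A `drift_record` from [fit_drift_slopes()] (or a numeric
#'   vector of per-interval slopes).
#' @param drift_sign `+1` (add the slopes as fitted) or `-1` (invert an accumulated drift).
#' @return Corrected signal vector.
#' @export
drift_correct <- function(F, drift, drift_sign = 1) {
  slopes <- if (inherits(drift, "drift_record")) drift$slopes else as.numeric(drift)
  if (length(F) != length(slopes))
    stop("need exactly one drift slope per titration point")
  if (!drift_sign %in% c(-1, 1)) stop("drift_sign must be +1 or -1")
  F + drift_sign * cumsum(slopes)
}

#' Ionic strength of a phosphate titration point
#'
#' Phosphate near neutral pH is a mono-/di-basic mixture (pKa 7.2). With
#' dibasic fraction \eqn{f_2 = 1/(1 + 10^{pKa - pH})} and monovalent
#' counterions at electroneutrality, the ionic strength contribution of
#' `c_phosphate` is
#' \deqn{I = \tfrac12 c (4 f_2 + (1 - f_2)) + \tfrac12 c (1 + f_2).}
#'
#' @param c_phosphate Total phosphate concentration, mM. Vectorised.
#' @param pH Solution pH.
#' @param pKa Second phosphate pKa (default 7.2).
#' @return Ionic strength, mM.
#' @examples
#' phosphate_ionic_strength(10, pH = 7.6)  # ~24.3 mM
#' @export
phosphate_ionic_strength <- function(c_phosphate, pH, pKa = 7.2) {
  if (any(c_phosphate < 0)) stop("c_phosphate must be >= 0")
  f2 <- 1 / (1 + 10^(pKa - pH))
  0.5 * c_phosphate * (4 * f2 + (1 - f2)) + 0.5 * c_phosphate * (1 + f2)
}

#' Ionic-strength reference model from a NaCl titration
#'
#' @param I Ionic strengths of the reference (NaCl) titration, mM, strictly
#'   increasing.
#' @param F Reference fluorescence at each `I`, > 0.
#' @param normalization_I Ionic strength at which the reference is scaled to 1
#'   (default: the smallest reference `I`); choose the ionic strength of the
#'   first titration point so that point is correction-neutral.
#' @return An `ionic_strength_model` with a monotone piecewise-cubic
#'   interpolator.
#' @export
ionic_strength_model <- function(I, F, normalization_I = min(I)) {
  I <- as.numeric(I); F <- as.numeric(F)
  if (any(diff(I) <= 0)) stop("reference I must be strictly increasing")
  if (any(F <= 0)) stop("reference F must be > 0")
  if (normalization_I < min(I) || normalization_I > max(I))
    stop("normalization_I outside the reference range")
  fun <- stats::splinefun(I, F, method = "monoH.FC")
  structure(list(I = I, F = F, normalization_I = normalization_I,
                 interp = fun, F_norm = fun(normalization_I)),
            class = "ionic_strength_model")
}

#' Divide out the ionic-strength quench
#'
#' \deqn{F^{bind}_n = F^{obs}_n / \hat F(I_n)}
#' with \eqn{\hat F} the reference curve normalised to 1 at the model's
#' `normalization_I`. Both the observed and the reference series must be
#' drift-corrected first. Extrapolation beyond the reference range is refused.
#'
#' @param F_obs Drift-corrected observed signals.
#' @param model An [ionic_strength_model()].
#' @param I_of_point Ionic strength at each titration point, mM.
#' @return Binding-only signal vector.
#' @export
ionic_strength_correct <- function(F_obs, model, I_of_point) {
  if (length(F_obs) != length(I_of_point))
    stop("F_obs and I_of_point lengths differ")
  out_of_range <- I_of_point < min(model$I) | I_of_point > max(model$I)
  if (any(out_of_range))
    stop(sprintf(paste0("ionic strength %g mM outside the reference range ",
                        "[%g, %g] mM; refusing to extrapolate"),
                 I_of_point[which(out_of_range)[1]], min(model$I), max(model$I)))
  F_obs / (model$interp(I_of_point) / model$F_norm)
}

#' Spectrum container
#'
#' @param wavelength_nm Strictly increasing, uniformly spaced wavelength grid.
#' @param value Signal (ellipticity or fluorescence) per wavelength.
#' @return A `spectrum_1d`.
#' @export
spectrum_1d <- function(wavelength_nm, value) {
  w <- as.numeric(wavelength_nm); v <- as.numeric(value)
  if (length(w) != length(v)) stop("grid and value lengths differ")
  if (length(w) < 2L || any(diff(w) <= 0)) stop("grid must be strictly increasing")
  steps <- diff(w)
  if (diff(range(steps)) > 1e-8 * mean(steps)) stop("grid must be uniform")
  structure(list(wavelength_nm = w, value = v), class = "spectrum_1d")
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Local least-squares polynomial smoothing; the defaults (4th-degree
#' polynomial, 11-point window) preserve near-UV CD band shapes while
#' suppressing photometric noise. Endpoints use one-sided polynomial fits.
#'
#' @param spec A [spectrum_1d()].
#' @param poly_order Polynomial degree (default 4).
#' @param window Window length, odd, > `poly_order` (default 11).
#' @return Smoothed `spectrum_1d`.
#' @export
sg_smooth <- function(spec, poly_order = 4, window = 11) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= poly_order) stop("window must exceed poly_order")
  if (length(spec$value) < window)
    stop("spectrum shorter than the smoothing window")
  spectrum_1d(spec$wavelength_nm,
              signal::sgolayfilt(spec$value, p = poly_order, n = window))
}

#' Differential spectrum and wavelength selection
#'
#' Computes `complex - apo` and returns the `k` wavelengths of largest
#' absolute difference, enforcing a minimum spacing of one smoothing window so
#' the picks track distinct spectral features. These wavelengths are where
#' titration cross-sections carry the most binding signal.
#'
#' @param spec_complex,spec_apo [spectrum_1d()] objects on identical grids.
#' @param k Number of wavelengths to select.
#' @param window Minimum spacing between picks, in grid points (default 11,
#'   matching the smoothing window).
#' @return List with `diff` (a `spectrum_1d`) and `wavelengths` (nm, in
#'   decreasing order of |difference|).
#' @export
differential_and_select <- function(spec_complex, spec_apo, k, window = 11) {
  if (!isTRUE(all.equal(spec_complex$wavelength_nm, spec_apo$wavelength_nm)))
    stop("spectra are on different wavelength grids")
  d <- spec_complex$value - spec_apo$value
  diff_spec <- spectrum_1d(spec_apo$wavelength_nm, d)
  if (max(abs(d)) <= .Machine$double.eps * max(1, max(abs(spec_apo$value))))
    stop("differential spectrum is identically zero; nothing to select")
  ord <- order(abs(d), decreasing = TRUE)
  picks <- integer(0)
  for (i in ord) {
    if (length(picks) == k) break
    if (all(abs(i - picks) >= window)) picks <- c(picks, i)
  }
  if (length(picks) < k)
    warning("only ", length(picks), " wavelengths satisfy the spacing rule")
  list(diff = diff_spec, wavelengths = spec_apo$wavelength_nm[picks])
}

#' Stitch two-range titration curves
#'
#' MST designs spanning nM to hundreds of mM need two ligand-concentration
#' ranges with 3-4 overlapping points. The high-range curve is mapped onto the
#' low-range curve by least-squares affine alignment (scale + offset) over the
#' overlap -- affine, not scale-only, because capillary batches shift the
#' baseline -- then merged, deduplicated (overlap points averaged) and sorted.
#'
#' @param curve_low,curve_high [titration_curve()] objects of the same
#'   modality and `p_total`.
#' @param n_overlap Minimum required overlapping `l_total` points (default 3).
#' @param rel_tol Relative tolerance for matching overlap concentrations.
#' @return A merged `titration_curve` with attribute `"stitch"` = list(scale,
#'   offset, rms) describing the alignment.
#' @export
stitch_ranges <- function(curve_low, curve_high, n_overlap = 3,
                          rel_tol = 1e-6) {
  match_idx <- outer(curve_low$l_total, curve_high$l_total,
                     function(a, b) abs(a - b) <= rel_tol * pmax(a, b))
  pairs <- which(match_idx, arr.ind = TRUE)
  if (nrow(pairs) < n_overlap)
    stop("need at least ", n_overlap, " overlapping points, found ",
         nrow(pairs))
  y_low <- curve_low$signal[pairs[, 1]]
  y_high <- curve_high$signal[pairs[, 2]]
  A <- cbind(y_high, 1)
  coefs <- qr.solve(A, y_low)
  aligned <- coefs[1] * curve_high$signal + coefs[2]
  rms <- sqrt(mean((coefs[1] * y_high + coefs[2] - y_low)^2))

  keep_high <- setdiff(seq_along(curve_high$l_total), pairs[, 2])
  l_all <- c(curve_low$l_total, curve_high$l_total[keep_high])
  s_all <- c(curve_low$signal, aligned[keep_high])
  s_all[pairs[, 1]] <- (y_low + (coefs[1] * y_high + coefs[2])) / 2
  ord <- order(l_all)
  out <- titration_curve(l_all[ord], s_all[ord], curve_low$modality,
                         curve_low$p_total, metadata = curve_low$metadata)
  attr(out, "stitch") <- list(scale = unname(coefs[1]),
                              offset = unname(coefs[2]), rms = rms)
  out
}
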