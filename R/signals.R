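#' Titration curve container
#'
#' One measured or simulated titration series: a design (total-ligand grid,
#' modality, binding-unit protein concentration) plus the observed signal.
#'
#' @param l_total Total ligand concentrations, uM, non-decreasing, >= 4 points.
#' @param signal Observed signal, same length as `l_total`.
#' @param modality One of `"fluorescence"`, `"cd"`, `"mst"`, `"itc"`.
#' @param p_total Binding-unit protein concentration, uM, > 0.
#' @param weights Optional per-point sigma (signal units); defaults to 1.
#' @param metadata Optional named list (excitation/emission wavelengths, CD
#'   wavelength, MST laser power, ...).
#' @return A `titration_curve`.
#' @export
titration_curve <- function(l_total, signal, modality, p_total,
                            weights = NULL, metadata = list()) {
  modality <- match.arg(modality, c("fluorescence", "cd", "mst", "itc"))
  l_total <- as.numeric(l_total); signal <- as.numeric(signal)
  if (length(l_total) != length(signal))
    stop("l_total and signal lengths differ")
  if (length(l_total) < 4L) stop("a titration curve needs at least 4 points")
  if (any(diff(l_total) < 0)) stop("l_total must be non-decreasing")
  if (any(l_total < 0)) stop("l_total must be >= 0")
  if (!is.finite(p_total) || p_total <= 0) stop("p_total must be > 0")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(signal) || any(weights <= 0))
      stop("weights must be positive, one per point")
  }
  structure(list(l_total = l_total, signal = signal, modality = modality,
                 p_total = p_total, weights = weights, metadata = metadata),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve [%s]: %d points, L_tot %g - %g uM, P_tot %g uM\n",
              x$modality, length(x$l_total), min(x$l_total), max(x$l_total),
              x$p_total))
  invisible(x)
}

#' Per-species response coefficients
#'
#' The observable of each modality is modelled as a linear combination of the
#' ligation-state concentrations: every species P, PL, PLL, PLLL contributes
#' its own molar response coefficient. Responses are normalised per uM of
#' species, so coefficients are comparable across curves measured at different
#' protein concentrations.
#'
#' @param r Numeric vector of length `n_steps + 1`: responses for P, PL, ...
#'   (signal units per uM of species).
#' @param offset Constant instrumental offset (signal units). Note that with a
#'   constant `p_total` the species concentrations sum to `p_total`, so an
#'   offset is only identifiable against an independent constraint; fitting
#'   absorbs it into the responses.
#' @return A `response_set`.
#' @export
response_set <- function(r, offset = 0) {
  r <- as.numeric(r)
  if (length(r) < 2L || length(r) > 4L) stop("need 2-4 response coefficients")
  if (any(!is.finite(r)) || !is.finite(offset)) stop("responses must be finite")
  structure(list(r = r, offset = offset), class = "response_set")
}

#' Predicted optical signal for a titration
#'
#' Computes the model signal \eqn{offset + \sum_s r_s [s]} at each total-ligand
#' concentration, after exact speciation. Used for fluorescence, CD and MST
#' alike; for MST the convention is fractional responses (see `fraction`),
#' since the labelled-protein concentration is fixed and the normalised
#' thermophoresis signal is intensive.
#'
#' @param scheme A [binding_scheme()].
#' @param responses A [response_set()] with `n_steps + 1` coefficients.
#' @param p_total Binding-unit protein concentration, uM.
#' @param l_totals Total ligand concentrations, uM.
#' @param fraction If `TRUE`, responses multiply species *fractions*
#'   (concentration / p_total) instead of concentrations.
#' @return Numeric vector of predicted signals.
#' @export
optical_signal <- function(scheme, responses, p_total, l_totals,
                           fraction = FALSE) {
  scheme <- as_scheme(scheme)
  if (length(responses$r) != scheme$n_steps + 1L)
    stop("need ", scheme$n_steps + 1L, " response coefficients for this scheme")
  st <- solve_speciation(scheme, p_total, l_totals)
  sp <- if (inherits(st, "species_state")) matrix(st$species, nrow = 1L) else st$species
  X <- sp[, seq_len(scheme$n_steps + 1L), drop = FALSE]
  if (fraction) X <- X / p_total
  drop(X %*% responses$r) + responses$offset
}

#' ITC experiment geometry
#'
#' @param cell_volume Calorimeter cell volume, uL.
#' @param injection_volumes Per-injection syringe volumes, uL.
#' @param syringe_ligand Ligand concentration in the syringe, uM.
#' @param cell_protein Binding-unit protein concentration in the cell, uM.
#' @param dH Molar enthalpy per binding step, kcal/mol; length = `n_steps` of
#'   the scheme the experiment is modelled with.
#' @param q_dilution Constant per-injection blank (dilution) heat, kcal.
#' @return An `itc_experiment`.
#' @export
itc_experiment <- function(cell_volume, injection_volumes, syringe_ligand,
                           cell_protein, dH, q_dilution = 0) {
  if (cell_volume <= 0 || any(injection_volumes <= 0))
    stop("volumes must be > 0")
  if (any(injection_volumes >= cell_volume))
    stop("injection volume must be smaller than the cell volume")
  if (syringe_ligand < 0 || cell_protein < 0) stop("concentrations must be >= 0")
  structure(list(cell_volume = cell_volume,
                 injection_volumes = as.numeric(injection_volumes),
                 syringe_ligand = syringe_ligand,
                 cell_protein = cell_protein,
                 dH = as.numeric(dH),
                 q_dilution = q_dilution),
            class = "itc_experiment")
}

#' Per-injection heats for a sequential binding scheme
#'
#' Standard perfusion-cell bookkeeping: each injection of volume `v` displaces
#' a fraction `v/V0` of the current cell contents, so totals are diluted by
#' `1 - v/V0` before the new ligand is added. The heat of injection `n` is
#' \deqn{q_n = V_0 \sum_i \Delta H_i \, \Delta [PL_{\ge i}]_n + q_{dil}}
#' where \eqn{[PL_{\ge i}] = \sum_{j \ge i} [PL_j]} is the concentration of
#' ligand bound at step `i` and the change is taken against the
#' displacement-corrected previous contents.
#'
#' @param exp An [itc_experiment()]; `length(exp$dH)` must equal
#'   `scheme$n_steps`.
#' @param scheme A [binding_scheme()].
#' @param displacement If `FALSE`, skip the displacement dilution (then the
#'   heats telescope exactly to the final bound enthalpy; used as an internal
#'   consistency check).
#' @return Numeric vector of per-injection heats, kcal.
#' @export
itc_injection_heats <- function(exp, scheme, displacement = TRUE) {
  scheme <- as_scheme(scheme)
  if (length(exp$dH) != scheme$n_steps)
    stop("length(dH) must equal the number of binding steps")
  V0 <- exp$cell_volume
  P <- exp$cell_protein; Ltot <- 0
  bound_ge <- bound_ge_concentrations(scheme, P, Ltot)
  heats <- numeric(length(exp$injection_volumes))
  for (n in seq_along(exp$injection_volumes)) {
    v <- exp$injection_volumes[n]
    d <- if (displacement) 1 - v / V0 else 1
    P <- P * d
    Ltot <- Ltot * d + exp$syringe_ligand * v / V0
    prev <- bound_ge * d
    bound_ge <- bound_ge_concentrations(scheme, P, Ltot)
    # uM * uL = 1e-12 mol; dH kcal/mol -> heat in kcal
    heats[n] <- 1e-12 * V0 * sum(exp$dH * (bound_ge - prev)) + exp$q_dilution
  }
  heats
}

# concentration of ligand bound at step >= i, i = 1..n_steps
bound_ge_concentrations <- function(scheme, p_total, l_total) {
  if (p_total <= 0 || l_total <= 0) return(numeric(scheme$n_steps))
  st <- solve_speciation(scheme, p_total, l_total)
  pl <- st$species[2:(scheme$n_steps + 1L)]
  rev(cumsum(rev(pl)))
}
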