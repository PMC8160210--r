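---
title: "Deciding how many binding-site classes a hexameric enzyme exposes"
author: "hexabind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding how many binding-site classes a hexameric enzyme exposes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexabind)
```

## The problem

Homohexameric purine nucleoside phosphorylase (PNP) binds its substrates —
phosphate and purine nucleosides — at six chemically identical active sites.
Whether those sites behave identically in solution is the question this
package's machinery answers. Crystal structures of ligand complexes mostly
show a broken three-fold symmetry: two dimers adopt an open–closed
conformation while the third stays open–open, suggesting *three* classes of
sites rather than one or two. Titration experiments probe this directly: if
sites are non-equivalent (or cooperative), a model with more stepwise
dissociation constants is needed to describe the binding curves.

`hexabind` implements the full inference chain for that decision: exact
speciation for sequential binding schemes, observation models for four
titration modalities (intrinsic fluorescence, near-UV CD, microscale
thermophoresis, isothermal titration calorimetry), the pre-fit signal
corrections those modalities need, global multi-curve fitting, and a
model-discrimination procedure combining a residual runs test, Akaike
weights and profile-likelihood 3σ intervals. Seeded generators emulate
every modality so the whole pipeline is testable without instrument data.

## Sequential binding model

A binding unit `P` (see below for what "unit" means) binds up to three
ligands in steps characterised by macroscopic stepwise dissociation
constants:

$$P + L \rightleftharpoons PL\ (K_{d1}),\quad
  PL + L \rightleftharpoons PLL\ (K_{d2}),\quad
  PLL + L \rightleftharpoons PLLL\ (K_{d3}).$$

With $\beta_i = \prod_{j\le i} 1/K_{dj}$, the binding polynomial
$Q(L) = 1 + \sum_i \beta_i L^i$ is the partition function over ligation
states; species fractions are its terms divided by $Q$, and the average
number of bound ligands per unit is $B/Q$ with $B = \sum_i i\beta_i L^i$.

Free ligand is never approximated by total ligand: protein (0.5–2 µM
monomer in fluorescence work) is comparable to the tightest $K_d$ (a few
µM), so `solve_speciation()` solves the depleted mass balance
$L + P_{tot} B(L)/Q(L) = L_{tot}$ with a bracketed, vectorised Newton
iteration (relative tolerance $10^{-12}$; bisection safeguard on
$[0, L_{tot}]$, where the left side is strictly increasing). The test suite
cross-checks it against exhaustive enumeration of the roots of the
degree-$(n{+}1)$ mass-balance polynomial.

**No-cooperativity references.** For $n$ identical independent sites the
constants are forced by site counting alone: $K_{di} = k\,i/(n-i+1)$, hence
$K_{d2} = 4K_{d1}$ for two sites and $K_{d2} = 3K_{d1}$, $K_{d3} = 9K_{d1}$
for three. Fitted constants deviating from these ratios are evidence of
non-equivalence or cooperativity; `statistical_scheme()` builds the
reference.

**Binding-unit basis.** Experimental concentrations are quoted per monomer,
but the schemes are written per *binding unit* — the assembly carrying one
set of sequential sites. The package defaults to 2 monomers per unit
(`binding_units()`): the catalytic unit of this enzyme family is the dimer,
and a hexamer with three dimer-level site classes has two monomers per
class. Analysing the whole hexamer as a single three-site unit (divisor 6)
changes only the response scale, not the fitted constants, so the divisor
is exposed rather than hard-coded.

## Observation models

Every optical modality is modelled as a linear species-response map,
$y(L_{tot}) = \sum_s r_s\,[s]$, with one molar coefficient per ligation
state. Because $\sum_s [s] = P_{tot}$ is constant in the no-dilution
design, a separate instrumental offset is exactly collinear with the
responses and is absorbed into them — this gauge is fixed everywhere, and a
titration series whose responses are all equal is reported as
*unidentifiable* (infinite SDs), never silently fitted.

MST differs only in normalisation: the labelled-protein concentration is
fixed, so responses multiply species *fractions*. Each heating-laser power
gets its own response set; the constants are shared across powers.

ITC is modelled at the injection level (integrated heats in, never raw
thermograms). Standard perfusion bookkeeping retains a fraction
$1 - v/V_0$ of the cell contents at each injection; the heat of injection
$n$ is $V_0 \sum_i \Delta H_i\, \Delta[PL_{\ge i}]_n + q_{dil}$. With the
displacement correction disabled the heats telescope exactly to the final
bound enthalpy, which the tests use as an identity.

## Pre-fit corrections

*Time drift.* Intrinsic fluorescence of the tryptophan-bearing mutant
decays slowly; a line is fitted to each titration point's short
fluorescence–time trace and the correction accumulates the per-interval
slopes: $F^{cor}_n = F_n + s\sum_{m\le n} a_m$. The conventional form adds the
slopes as fitted; since quenching drift has negative slopes, *undoing* an
accumulated downward drift needs $s = -1$. Both conventions are exposed
(`drift_sign`), the synthetic round trip pins the self-consistent one, and
the default follows the conventional algebra.

*Ionic strength.* Phosphate at pH 7.6 is mostly dibasic (pKa 7.2), so its
titration raises ionic strength steeply
(`phosphate_ionic_strength()`; ~2.43 mM ionic strength per mM phosphate at
pH 7.6). A NaCl reference titration gives $F(I)$, interpolated with a
monotone piecewise-cubic spline — monotonicity prevents spurious wiggles
between reference nodes, and extrapolation beyond the reference range is an
error, never silent. The reference is normalised to 1 at the ionic strength
of the first titration point, making that point correction-neutral (existing
practice leaves the normalisation point a free choice; this one is
the least invasive). Drift is removed *before* the quench is divided out,
on both series; the order is enforced and the tests show the wrong order
leaves a bias well above the noise.

*CD spectra.* Savitzky–Golay smoothing (4th-degree, 11-point window, via
`signal::sgolayfilt`, whose startup rows are one-sided polynomial fits)
precedes differential-spectrum wavelength selection; cross-sections at the
selected wavelengths become ordinary titration curves. Selection enforces a
minimum spacing of one smoothing window so the picks track distinct bands.
The number of cross-sections is user-set (default 5, the low end of the
five-to-seven used in practice).

*MST two-range stitching.* Covering 3.5 nM–750 mM needs two 16-point
ranges; they are merged by least-squares *affine* alignment over the 3–4
overlapping points (scale and offset — capillary batches shift baselines,
so scale-only alignment is not enough).

## Global fitting and uncertainty

`global_fit()` minimises the weighted SSR over all curves jointly. The
constants are optimised as log10 values with the ordering
$K_{d1}\le K_{d2}\le K_{d3}$ (spacings bounded below by zero), which
removes label switching; for any trial constants the responses enter
linearly and are profiled out exactly by per-curve weighted least squares
(variable projection). The nonlinear search therefore runs over at most
three parameters, restarted from a quantile-based heuristic plus seeded
log-normal perturbations (default 10 starts; the seeded studies in the test
suite use 4–6 starts, which the warm-started, separable objective makes
sufficient). The objective is normalised to O(1) so optimiser tolerances
behave identically for fluorescence counts and kcal-scale heats. Nested
fits are warm-started from the simpler model, which keeps
$SSR(1) \ge SSR(2) \ge SSR(3)$ up to optimiser tolerance.

Per-curve weights default to 1 (the source analyses do not state their
weighting); a per-point σ can be attached to any curve.

SDs come from the singular-value decomposition of the weighted Jacobian
over *all* parameters at the optimum; directions hitting singular values
below $10^{-8}$ of the largest are flagged and the affected SDs set to
infinity. `ci3` intervals are Wald ±3 SD in log10 space;
`profile_ci_3sigma()` replaces them with profile-likelihood intervals at
the $\alpha^* = 0.0027$ level, i.e. where
$SSR \le SSR_{min}(1 + F(\alpha^*; 1, n-k)/(n-k))$. When the lower crossing
falls below the smallest ligand concentration titrated, the bound is
reported *open* with that concentration as the censoring value and
rendered as `(< 0.07–2.12)*` style by `write_report()` — the data cannot
distinguish "very tight" from "tighter still".

## Model discrimination

`discriminate()` climbs the ladder 1 → 2 → 3 sites, always starting from
the simplest model. The step criterion is the Wald–Wolfowitz runs test on
the pooled residual signs: a one-sided *too-few-runs* p below 0.05 (run
count below expectation) flags systematic misfit. The run-count null
distribution is enumerated exactly (closed-form PMF) up to $n_1+n_2 = 200$
and approximated normally beyond; exact zeros are dropped before counting.
Two p-value conventions are returned: the one-sided lower-tail **mid-p**
(the default the ladder uses — on the discrete run-count lattice the mid-p
is the convention whose null distribution is closest to uniform, which the
calibration tests verify) and the classical two-sided
$2\min(\text{tails})$ p, which is conservative on a lattice. The normal
approximation uses a continuity correction for the two-sided p and none
for the mid-p, matching what each approximates.

AICc weights (small-sample corrected, since individual curves carry only
16–30 points; a flag restores plain AIC) are computed across all fitted
models. The ladder verdict is final; when the AICc winner disagrees, both
are reported and the disagreement flagged — with real data the two criteria
can genuinely conflict, and the package surfaces that rather than
arbitrating silently.

The generators include the instructive failure case: a thermophoresis
response pattern in which the first transition raises the signal, the last
lowers it, and the middle step produces no net change. Data simulated from
a true three-site scheme with this pattern are *correctly* assigned two
sites by the ladder — the middle constant is hidden in the observable, not
absent from the chemistry. This is the mechanism by which a middle constant
can be undetectable in one modality yet solid in another.

## Enzyme kinetics

Three rate laws cover the catalytic side: Michaelis–Menten
($v_0 = V_{max1}c_0/(c_0+K_{M1})$); a two-site allosteric law with
$K_{M2} = aK_{M1}$, $V_{max2} = bV_{max1}$,

$$v_0 = \frac{2V_{max1}c_0/K_{M1} + 2V_{max2}c_0^2/K_{M2}^2}
            {1 + 2c_0/K_{M1} + c_0^2/(aK_{M1}^2)};$$

and competitive inhibition
$v_0 = V_{max1}c_0/(c_0 + K_M(1 + c_i/K_i))$. The commonly used form of the allosteric law mixes $K_{M2}^2$ in the numerator with
$aK_{M1}^2 = K_{M1}K_{M2}$ in the denominator; for $a \ne 1$ these are
different saturation scales. Both that form (default) and the
self-consistent $2V_{max2}c_0^2/(K_{M1}K_{M2})$ numerator are implemented
behind `variant`; at $a=b=1$ both reduce exactly to Michaelis–Menten with
doubled $V_{max}$, which the tests assert to $10^{-12}$. Fitting is
Levenberg–Marquardt with positivity bounds and five seeded log-perturbed
starts; the competitive model is fitted globally across inhibitor levels.
Nested rate laws are compared by the F-test at 95%.

A calibration note: the F ratio has its nominal null distribution under
homoscedastic Gaussian noise, and the package's null-calibration study runs
under exactly that sampling model (`noise_type = "absolute"` in
`simulate_kinetics()`), where the measured type-I error sits at the nominal
5%. Initial-rate data whose error is proportional to the rate (the
generator's default, and common in practice) make the *unweighted* F-test
over-reject — we measure roughly 10% at 2% relative noise — so such data
should be fitted with the matching `1/v^2`-style weights before model
comparison.

## What the generators emulate — and what they do not

Defaults reproduce the study conditions the analysis is built for:
three-site truths at 4.4/84/1770 µM (phosphate-like) and 6.75/148.9/655 µM
(nucleoside-analogue-like), seven fluorescence curves per series with
distinct mixed-sign response vectors, 2% relative Gaussian noise, drift
slopes decaying with ligand (signal stabilisation), a quench knee near
100 mM ionic strength, four MST laser powers over 3.5 nM–750 mM, ITC series
over 300 µM–1.3 mM monomer with 8–12× ligand stocks and optional small
first injections (noise 0.1 µcal absolute), and near-UV CD spectra
(230–300 nm, 0.25 nm step) at 10 µM binding units. Noise is Gaussian —
relative for optical and kinetic signals, absolute for heats — and
independent across points.

Real data are harsher in ways the generators deliberately omit:
photobleaching kinetics, capillary adsorption, injection backlash, shot
noise, correlated baseline wander, and buffer speciation beyond the
single-pKa phosphate model. Passing recovery tests therefore demonstrates
that the *inference machinery* is correct and calibrated under the stated
statistical structure, not that any particular instrument will achieve the
same precision.

Problem sizes in the seeded studies (100 seeds for recovery and
discrimination rates, 200 for the coverage band, 1000 draws for the null
calibrations, 10⁴ instances for the speciation oracle) were chosen as the
smallest giving stable rates; all are deterministic given the seed.

## Numerical choices and limitations

- Concentration unit is µM throughout; converters live at the I/O boundary
  (`read_titration_csv()` honours a `# units:` header).
- Speciation brackets on $[0, L_{tot}]$ and never leaves it; non-convergence
  raises an error with the offending load, never a silent value.
- The profile walker steps in 0.05-decade increments and interpolates the
  threshold crossing linearly in SSR; a profile flat to ±8 decades is
  reported open on that side.
- Degenerate inputs: zero protein gives free ligand = total ligand;
  all-one-sign residuals make the runs test explicitly degenerate;
  identical spectra make wavelength selection an error rather than an
  arbitrary pick.
- Site-specific (microscopic) models, time-resolved binding, Bayesian
  posteriors and model averaging beyond Akaike weights are out of scope.
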