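#' Sequential binding scheme
#'
#' A `binding_scheme` describes a sequential (stepwise) ligand-binding model
#' \deqn{P + L \rightleftharpoons PL \; (K_{d1}), \quad
#'       PL + L \rightleftharpoons PLL \; (K_{d2}), \quad
#'       PLL + L \rightleftharpoons PLLL \; (K_{d3})}
#' with 1, 2 or 3 steps. The constants are *macroscopic* stepwise dissociation
#' constants: each aggregates all microscopic site configurations with the same
#' number of bound ligands.
#'
#' @param kd Numeric vector of 1-3 stepwise dissociation constants, in uM,
#'   ordered K_d1, K_d2, ... All must be finite and positive.
#' @return An object of class `binding_scheme` with fields `n_steps` and `kd`.
#' @examples
#' binding_scheme(c(4.4, 84, 1770))   # three non-equivalent site classes
#' @export
binding_scheme <- function(kd) {
  kd <- as.numeric(kd)
  if (length(kd) < 1L || length(kd) > 3L)
    stop("a binding scheme has 1, 2 or 3 steps, got ", length(kd))
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("all dissociation constants must be finite and > 0")
  structure(list(n_steps = length(kd), kd = kd), class = "binding_scheme")
}

#' @export
print.binding_scheme <- function(x, ...) {
  cat(sprintf("Sequential binding scheme, %d step(s)\n", x$n_steps))
  cat("  K_d [uM]:", paste(signif(x$kd, 4), collapse = ", "), "\n")
  invisible(x)
}

as_scheme <- function(x) {
  if (inherits(x, "binding_scheme")) x else binding_scheme(x)
}

# Overall association constants beta_i = prod_{j<=i} 1/K_dj  [uM^-i]
scheme_beta <- function(scheme) cumprod(1 / scheme$kd)

#' Binding polynomial and its bound-ligand moment
#'
#' Evaluates the binding polynomial (partition function over ligation states)
#' \deqn{Q(L) = 1 + \sum_i \beta_i L^i, \qquad \beta_i = \prod_{j \le i} 1/K_{dj}}
#' and the first moment \eqn{B(L) = \sum_i i \beta_i L^i}, so that the average
#' number of ligands bound per binding unit is `B/Q`.
#'
#' @param scheme A [binding_scheme()].
#' @param free_ligand Free-ligand concentration(s), uM, >= 0. Vectorised.
#' @return A list with numeric vectors `Q` and `bound_moment` (same length as
#'   `free_ligand`).
#' @examples
#' s <- binding_scheme(c(1, 3, 9))
#' binding_polynomial(s, 3)$Q  # 1 + 3 + 3 + 1 = 8
#' @export
binding_polynomial <- function(scheme, free_ligand) {
  scheme <- as_scheme(scheme)
  L <- as.numeric(free_ligand)
  if (any(!is.finite(L)) || any(L < 0))
    stop("free_ligand must be finite and >= 0")
  beta <- scheme_beta(scheme)
  Q <- rep(1, length(L)); B <- numeric(length(L))
  for (i in seq_len(scheme$n_steps)) {
    term <- beta[i] * L^i
    Q <- Q + term
    B <- B + i * term
  }
  list(Q = Q, bound_moment = B)
}

#' Statistical (no-cooperativity) reference scheme
#'
#' Stepwise macroscopic constants for `n_sites` identical and independent sites
#' with microscopic dissociation constant `k_micro`:
#' \deqn{K_{di} = k_{micro} \cdot i / (n - i + 1).}
#' For two sites this forces the ratio \eqn{K_{d2}/K_{d1} = 4}; for three sites
#' \eqn{K_{d2}/K_{d1} = 3} and \eqn{K_{d3}/K_{d1} = 9}. Fitted constants that
#' deviate from these ratios indicate site non-equivalence or cooperativity.
#'
#' @param n_sites Number of identical sites, 1, 2 or 3.
#' @param k_micro Microscopic (per-site) dissociation constant, uM.
#' @return A [binding_scheme()].
#' @examples
#' statistical_scheme(3, 12)$kd / 12   # 1/3, 1, 3
#' @export
statistical_scheme <- function(n_sites, k_micro) {
  if (length(n_sites) != 1L || !(n_sites %in% 1:3))
    stop("n_sites must be 1, 2 or 3")
  if (length(k_micro) != 1L || !is.finite(k_micro) || k_micro <= 0)
    stop("k_micro must be a single positive number")
  i <- seq_len(n_sites)
  binding_scheme(k_micro * i / (n_sites - i + 1))
}

#' Monomer concentration to binding-unit concentration
#'
#' Titration models here count *binding units*: the protein assembly carrying
#' one set of `n_steps` sequential sites. Protein concentrations are usually
#' reported per monomer; the divisor converts them. For a hexamer analysed as
#' three dimer-level units (the default reading) the divisor is 2; analysing
#' the whole hexamer as one 3-site unit would use 6.
#'
#' @param monomer_uM Protein concentration expressed per monomer, uM.
#' @param units_per_site_group Monomers per binding unit (default 2).
#' @return Binding-unit concentration, uM.
#' @export
binding_units <- function(monomer_uM, units_per_site_group = 2) {
  if (units_per_site_group <= 0) stop("units_per_site_group must be > 0")
  monomer_uM / units_per_site_group
}
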