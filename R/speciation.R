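#' Exact equilibrium speciation with ligand depletion
#'
#' Solves the ligand mass balance
#' \deqn{L + P_{tot} \, B(L)/Q(L) = L_{tot}}
#' for the free-ligand concentration \eqn{L} on \eqn{[0, L_{tot}]}, where
#' \eqn{Q} is the binding polynomial and \eqn{B} its bound-ligand moment.
#' The left-hand side is strictly increasing in \eqn{L}, so the root is unique;
#' it is found by a bracketed, vectorised Newton iteration with bisection
#' safeguard, to relative tolerance 1e-12. No free-ligand approximation is
#' made: in these titrations the protein (0.5-2 uM monomer) is comparable to
#' the tightest K_d, so depletion is material.
#'
#' @param scheme A [binding_scheme()].
#' @param p_total Binding-unit concentration, uM, >= 0 (scalar).
#' @param l_total Total ligand concentration(s), uM, >= 0. Vectorised.
#' @return For scalar `l_total`, a `species_state`: list with `free_ligand`,
#'   `species` (named concentrations of P, PL, PLL, PLLL; entries beyond
#'   `n_steps` zero), `p_total`, `l_total`. For vector `l_total`, a
#'   `species_table`: list of vectors `free_ligand` and matrix `species`
#'   (rows = points).
#' @examples
#' s <- binding_scheme(4.4)
#' solve_speciation(s, p_total = 1, l_total = 10)$free_ligand  # ~9.32 uM
#' @export
solve_speciation <- function(scheme, p_total, l_total) {
  scheme <- as_scheme(scheme)
  if (length(p_total) != 1L || !is.finite(p_total) || p_total < 0)
    stop("p_total must be a single finite number >= 0")
  l_total <- as.numeric(l_total)
  if (any(!is.finite(l_total)) || any(l_total < 0))
    stop("l_total must be finite and >= 0")
  scalar <- length(l_total) == 1L

  L <- speciation_free_ligand(scheme, p_total, l_total)
  sp <- species_concentrations(scheme, p_total, L)

  if (scalar) {
    structure(list(free_ligand = L,
                   species = sp[1L, ],
                   p_total = p_total,
                   l_total = l_total),
              class = "species_state")
  } else {
    structure(list(free_ligand = L,
                   species = sp,
                   p_total = p_total,
                   l_total = l_total),
              class = "species_table")
  }
}

# concentrations of P, PL, PLL, PLLL at given free ligand; matrix, one row per L
species_concentrations <- function(scheme, p_total, L) {
  beta <- scheme_beta(scheme)
  bp <- binding_polynomial(scheme, L)
  sp <- matrix(0, nrow = length(L), ncol = 4L,
               dimnames = list(NULL, c("P", "PL", "PLL", "PLLL")))
  sp[, 1L] <- p_total / bp$Q
  for (i in seq_len(scheme$n_steps)) sp[, i + 1L] <- p_total * beta[i] * L^i / bp$Q
  sp
}

# Vectorised safeguarded Newton for the unique root of
# f(L) = L + P*B(L)/Q(L) - Ltot on [0, Ltot].
speciation_free_ligand <- function(scheme, p_total, l_total, tol = 1e-12,
                                   max_iter = 200L) {
  n <- length(l_total)
  beta <- scheme_beta(scheme)
  ns <- scheme$n_steps

  fval <- function(L) {
    Q <- rep(1, length(L)); B <- numeric(length(L)); Bp <- numeric(length(L))
    for (i in seq_len(ns)) {
      t1 <- beta[i] * L^i
      Q <- Q + t1; B <- B + i * t1
      Bp <- Bp + i * i * beta[i] * L^(i - 1)
    }
    Qp <- ifelse(L > 0, B / L, beta[1])
    f <- L + p_total * B / Q - l_total
    fp <- 1 + p_total * (Bp * Q - B * Qp) / Q^2
    list(f = f, fp = fp)
  }

  lo <- numeric(n); hi <- l_total
  x <- pmin(l_total, l_total / (1 + p_total * ns / (l_total + scheme$kd[1])))
  x[l_total == 0] <- 0
  active <- l_total > 0 & p_total > 0
  if (p_total == 0) return(l_total)

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    ev <- fval(x)
    f <- ev$f; fp <- ev$fp
    neg <- f < 0
    lo[active & neg] <- x[active & neg]
    hi[active & !neg] <- x[active & !neg]
    xn <- x - f / fp
    bad <- !is.finite(xn) | xn <= lo | xn >= hi
    xn[bad] <- (lo[bad] + hi[bad]) / 2
    conv <- abs(xn - x) <= tol * pmax(xn, .Machine$double.xmin) | (hi - lo) <= tol * pmax(hi, .Machine$double.xmin)
    x[active] <- xn[active]
    active <- active & !conv
  }
  if (any(active)) {
    idx <- which(active)[1]
    stop(sprintf(paste0("speciation solver did not converge: l_total = %g, ",
                        "p_total = %g, bracket [%g, %g]"),
                 l_total[idx], p_total, lo[idx], hi[idx]))
  }
  x
}

#' @export
print.species_state <- function(x, ...) {
  cat(sprintf("Species state: P_tot = %g uM, L_tot = %g uM, free L = %g uM\n",
              x$p_total, x$l_total, x$free_ligand))
  print(signif(x$species, 6))
  invisible(x)
}

#' Fractional saturation of the binding sites
#'
#' The occupied fraction of all sites, \eqn{\sum_i i [PL_i] / (n \, P_{tot})}.
#' Runs from 0 (no ligand) to 1 (all steps saturated).
#'
#' @param scheme A [binding_scheme()].
#' @param state A `species_state` from [solve_speciation()].
#' @return Saturation fraction in `[0, 1]`.
#' @export
saturation_fraction <- function(scheme, state) {
  scheme <- as_scheme(scheme)
  if (state$p_total <= 0)
    stop("saturation fraction is undefined for p_total = 0")
  bound <- sum(seq_len(3) * state$species[2:4])
  bound / (scheme$n_steps * state$p_total)
}
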