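#' Michaelis-Menten rate law
#'
#' \deqn{v_0 = V_{max1} c_0 / (c_0 + K_{M1})}
#'
#' @param p Named list/vector with `vmax1` (U/mg) and `km1` (uM).
#' @param c0 Initial substrate concentration(s), uM, >= 0.
#' @return Initial rate(s), U/mg.
#' @export
mm_rate <- function(p, c0) {
  check_kinetic_params(p, c("vmax1", "km1"))
  if (any(c0 < 0)) stop("c0 must be >= 0")
  p$vmax1 * c0 / (c0 + p$km1)
}

#' Two-site allosteric rate law
#'
#' Rate law for a dimeric enzyme whose second active site changes once the
#' first is occupied: with \eqn{K_{M2} = a K_{M1}} and
#' \eqn{V_{max2} = b V_{max1}},
#' \deqn{v_0 = \frac{2 V_{max1} c_0 / K_{M1} + 2 V_{max2} c_0^2 / K_{M2}^2}
#'             {1 + 2 c_0 / K_{M1} + c_0^2 / (a K_{M1}^2)}.}
#' `a` and `b` express the degree of cooperation between the two subunits;
#' `a = b = 1` collapses to Michaelis-Menten with `V_max = 2 V_max1`.
#'
#' The printed form mixes \eqn{K_{M2}^2} in the numerator with
#' \eqn{a K_{M1}^2 = K_{M1} K_{M2}} in the denominator; for `a != 1` these are
#' not the same saturation scale. `variant = "consistent"` replaces the
#' numerator's second term by \eqn{2 V_{max2} c_0^2 / (K_{M1} K_{M2})},
#' matching the denominator. Default is the printed form.
#'
#' @param p Named list/vector with `vmax1`, `km1`, `a`, `b`.
#' @param c0 Substrate concentration(s), uM.
#' @param variant `"printed"` (default) or `"consistent"`.
#' @return Initial rate(s), U/mg.
#' @export
allosteric_rate <- function(p, c0, variant = c("printed", "consistent")) {
  variant <- match.arg(variant)
  check_kinetic_params(p, c("vmax1", "km1", "a", "b"))
  if (any(c0 < 0)) stop("c0 must be >= 0")
  km2 <- p$a * p$km1
  vmax2 <- p$b * p$vmax1
  num2 <- if (variant == "printed") 2 * vmax2 * c0^2 / km2^2
          else                      2 * vmax2 * c0^2 / (p$km1 * km2)
  num <- 2 * p$vmax1 * c0 / p$km1 + num2
  den <- 1 + 2 * c0 / p$km1 + c0^2 / (p$a * p$km1^2)
  num / den
}

#' Competitive inhibition rate law
#'
#' \deqn{v_0 = V_{max1} c_0 / (c_0 + K_M (1 + c_i/K_i))}
#'
#' @param p Named list/vector with `vmax1`, `km1`, `ki` (uM).
#' @param c0 Substrate concentration(s), uM.
#' @param ci Inhibitor concentration(s), uM (recycled against `c0`).
#' @return Initial rate(s), U/mg.
#' @export
competitive_rate <- function(p, c0, ci) {
  check_kinetic_params(p, c("vmax1", "km1", "ki"))
  if (any(c0 < 0) || any(ci < 0)) stop("concentrations must be >= 0")
  p$vmax1 * c0 / (c0 + p$km1 * (1 + ci / p$ki))
}

check_kinetic_params <- function(p, needed) {
  missing <- setdiff(needed, names(p))
  if (length(missing)) stop("missing kinetic parameter(s): ",
                            paste(missing, collapse = ", "))
  vals <- unlist(p[needed])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("kinetic parameters must be finite and > 0")
  invisible(TRUE)
}

#' Kinetic dataset container
#'
#' @param c0 Substrate concentrations, uM, > 0.
#' @param v0 Initial rates, U/mg, >= 0.
#' @param ci Optional inhibitor concentrations, uM (one per row).
#' @param weights Optional per-point sigma.
#' @return A `kinetic_dataset` (data.frame subclass).
#' @export
kinetic_dataset <- function(c0, v0, ci = NULL, weights = NULL) {
  if (any(c0 <= 0)) stop("c0 must be > 0")
  if (any(v0 < 0)) stop("v0 must be >= 0")
  d <- data.frame(c0 = c0, v0 = v0)
  if (!is.null(ci)) {
    if (any(ci < 0)) stop("ci must be >= 0")
    d$ci <- ci
  }
  if (!is.null(weights)) d$weights <- weights
  class(d) <- c("kinetic_dataset", "data.frame")
  d
}

#' Fit a rate law to initial-rate data
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt, multi-start). For the
#' competitive model a single (V_max, K_M, K_i) set is fitted globally across
#' all inhibitor concentrations. Starting values follow the usual heuristics
#' (V_max from the largest rate, K_M from the half-max concentration,
#' a = b = 1, K_i from the median inhibitor concentration), plus seeded
#' log-perturbed restarts to dodge local minima.
#'
#' @param data A [kinetic_dataset()].
#' @param model `"mm"`, `"allosteric"` or `"competitive"`.
#' @param variant Passed to [allosteric_rate()].
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Seed for the start perturbations.
#' @return A `kinetic_fit`: list with `params`, `sd`, `ssr`, `residuals`,
#'   `n_obs`, `n_params`, `model`, `fitted`, `converged`.
#' @export
fit_kinetics <- function(data, model = c("mm", "allosteric", "competitive"),
                         variant = "printed", n_starts = 5, seed = 1) {
  model <- match.arg(model)
  pnames <- switch(model,
    mm = c("vmax1", "km1"),
    allosteric = c("vmax1", "km1", "a", "b"),
    competitive = c("vmax1", "km1", "ki"))
  if (model == "competitive" && is.null(data$ci))
    stop("competitive model needs inhibitor concentrations (ci)")
  if (nrow(data) < length(pnames) + 2L)
    stop("need at least n_params + 2 data points")
  w <- if (!is.null(data$weights)) 1 / data$weights^2 else rep(1, nrow(data))

  predict_fun <- function(pars) {
    p <- as.list(pars)
    switch(model,
      mm = mm_rate(p, data$c0),
      allosteric = allosteric_rate(p, data$c0, variant = variant),
      competitive = competitive_rate(p, data$c0, data$ci))
  }
  resid_fun <- function(pars) sqrt(w) * (data$v0 - predict_fun(pars))

  half <- data$c0[which.min(abs(data$v0 - max(data$v0) / 2))]
  start0 <- c(vmax1 = max(data$v0), km1 = half, a = 1, b = 1,
              ki = if (!is.null(data$ci)) max(stats::median(data$ci[data$ci > 0], na.rm = TRUE), 1) else 1)
  start0 <- start0[pnames]

  starts <- list(start0)
  if (n_starts > 1) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- start0 * 10^stats::rnorm(length(start0), 0, 0.3)
  }

  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = resid_fun,
      lower = rep(1e-12, length(st)),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("kinetic fit failed to converge from any start; model = ", model)

  pars <- best$par
  ssr <- best$deviance
  dof <- nrow(data) - length(pars)
  covm <- try(solve(best$hessian) * ssr / max(dof, 1), silent = TRUE)
  sds <- if (inherits(covm, "try-error")) rep(NA_real_, length(pars))
         else sqrt(pmax(diag(covm), 0))
  names(sds) <- names(pars)
  structure(list(params = pars, sd = sds, ssr = ssr,
                 residuals = data$v0 - predict_fun(pars),
                 fitted = predict_fun(pars),
                 n_obs = nrow(data), n_params = length(pars),
                 model = model, converged = best$info %in% 1:4),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit [%s]: SSR = %.4g, n = %d\n", x$model, x$ssr, x$n_obs))
  est <- cbind(estimate = x$params, sd = x$sd)
  print(signif(est, 4))
  invisible(x)
}

#' F-test between nested kinetic fits
#'
#' \deqn{F = \frac{(SSR_s - SSR_c)/(k_c - k_s)}{SSR_c/(n - k_c)}}
#' The more complex model is retained only when the drop in the residual sum
#' of squares is significant at the given level (default 95%).
#'
#' @param fit_simple,fit_complex `kinetic_fit` objects on the same data with
#'   `n_params(complex) > n_params(simple)`.
#' @param alpha Significance level (default 0.05).
#' @return List with `F`, `df1`, `df2`, `p`, and `choice` (`"simple"` or
#'   `"complex"`).
#' @export
select_kinetic_model <- function(fit_simple, fit_complex, alpha = 0.05) {
  if (fit_simple$n_obs != fit_complex$n_obs)
    stop("fits are not on the same data (different n)")
  df1 <- fit_complex$n_params - fit_simple$n_params
  df2 <- fit_complex$n_obs - fit_complex$n_params
  if (df1 <= 0 || df2 <= 0) stop("models are not nested with positive df")
  ssr_s <- fit_simple$ssr; ssr_c <- fit_complex$ssr
  if (ssr_c == 0) {
    Fst <- Inf; p <- 0
  } else {
    Fst <- max(0, (ssr_s - ssr_c) / df1) / (ssr_c / df2)
    p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  }
  list(F = Fst, df1 = df1, df2 = df2, p = p,
       choice = if (p < alpha) "complex" else "simple")
}
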