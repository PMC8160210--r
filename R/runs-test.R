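#' Wald-Wolfowitz runs test on residual signs
#'
#' Counts runs in the sign sequence of the residuals (exact zeros are dropped)
#' and compares the observed count with its null distribution under random
#' sign arrangement:
#' \deqn{E[R] = \frac{2 n_1 n_2}{n_1 + n_2} + 1, \qquad
#'  Var[R] = \frac{2 n_1 n_2 (2 n_1 n_2 - n_1 - n_2)}
#'                {(n_1+n_2)^2 (n_1+n_2-1)}.}
#' Too few runs indicate systematic lack of fit; too many indicate
#' over-fitting or negative correlation.
#'
#' Two p-values are reported. `p_one_sided` is the lower-tail (too-few-runs)
#' mid-p, the calibrated default used by the model-discrimination ladder:
#' exact enumeration of the run-count distribution when `n1 + n2 <= 200`,
#' normal approximation beyond. `p_two_sided` is the classical
#' `2 * min(tails)` p (exact for small samples, normal with continuity
#' correction otherwise); it is conservative on the discrete lattice.
#'
#' @param residuals Numeric residual vector; needs >= 8 nonzero values.
#' @param exact_limit Largest `n1 + n2` for which the exact distribution is
#'   enumerated (default 200).
#' @return A `runs_test_result`: list with `n_pos`, `n_neg`, `runs_observed`,
#'   `runs_expected`, `variance`, `p_one_sided`, `p_two_sided`, `direction`
#'   (`"below"`/`"above"` expectation), `degenerate` (all one sign).
#' @examples
#' runs_test(c(1, 2, 1.5, 0.5, -1, -2, -0.3, -0.8, 1, -1))
#' @export
runs_test <- function(residuals, exact_limit = 200) {
  sg <- sign(residuals[residuals != 0])
  n1 <- sum(sg > 0); n2 <- sum(sg < 0); n <- n1 + n2
  if (n < 8) stop("need at least 8 nonzero residuals, got ", n)
  if (n1 == 0 || n2 == 0) {
    return(structure(list(n_pos = n1, n_neg = n2, runs_observed = 1L,
                          runs_expected = NA_real_, variance = NA_real_,
                          p_one_sided = NA_real_, p_two_sided = NA_real_,
                          direction = NA_character_, degenerate = TRUE),
                     class = "runs_test_result"))
  }
  r <- 1L + sum(diff(sg) != 0)
  ER <- 2 * n1 * n2 / n + 1
  VR <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) / (n^2 * (n - 1))

  if (n <= exact_limit) {
    pmf <- runs_pmf(n1, n2)
    rs <- as.integer(names(pmf))
    below <- sum(pmf[rs < r]); at <- sum(pmf[rs == r]); above <- sum(pmf[rs > r])
    p1 <- below + 0.5 * at
    p2 <- min(1, 2 * min(below + at, above + at))
  } else {
    z1 <- (r - ER) / sqrt(VR)
    p1 <- stats::pnorm(z1)
    zl <- (r + 0.5 - ER) / sqrt(VR); zu <- (r - 0.5 - ER) / sqrt(VR)
    p2 <- min(1, 2 * min(stats::pnorm(zl), stats::pnorm(zu, lower.tail = FALSE)))
  }
  structure(list(n_pos = n1, n_neg = n2, runs_observed = r,
                 runs_expected = ER, variance = VR,
                 p_one_sided = p1, p_two_sided = p2,
                 direction = if (r < ER) "below" else "above",
                 degenerate = FALSE),
            class = "runs_test_result")
}

#' @export
print.runs_test_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Runs test: degenerate (all residuals one sign)\n")
    return(invisible(x))
  }
  cat(sprintf("Runs test: R = %d (%s expected %.2f), n+ = %d, n- = %d\n",
              x$runs_observed, x$direction, x$runs_expected, x$n_pos, x$n_neg))
  cat(sprintf("  p (one-sided, too few runs) = %.4g; p (two-sided) = %.4g\n",
              x$p_one_sided, x$p_two_sided))
  invisible(x)
}

# Exact null PMF of the number of runs for n1 positive and n2 negative signs.
runs_pmf <- function(n1, n2) {
  lC <- function(n, k) ifelse(k < 0 | k > n, -Inf, lchoose(n, k))
  rs <- 2:(n1 + n2)
  den <- lchoose(n1 + n2, n1)
  p <- vapply(rs, function(r) {
    if (r %% 2 == 0) {
      k <- r / 2
      exp(log(2) + lC(n1 - 1, k - 1) + lC(n2 - 1, k - 1) - den)
    } else {
      k <- (r - 1) / 2
      a <- lC(n1 - 1, k) + lC(n2 - 1, k - 1)
      b <- lC(n1 - 1, k - 1) + lC(n2 - 1, k)
      exp(a - den) + exp(b - den)
    }
  }, numeric(1))
  names(p) <- rs
  p[is.nan(p)] <- 0
  p
}

#' Akaike comparison of fits on the same data
#'
#' Least-squares AIC \eqn{n \ln(SSR/n) + 2k}, small-sample corrected (AICc,
#' adds \eqn{2k(k+1)/(n-k-1)}) by default since titration curves carry only
#' 16-30 points each. Akaike weights are
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#'
#' @param fits List of fit objects, each with `ssr`, `n_obs`, `n_params`
#'   (e.g. [global_fit()] or [fit_kinetics()] results), all on the same data.
#' @param corrected Use AICc (default `TRUE`).
#' @return data.frame with columns `model`, `k`, `aic`, `delta`, `weight`.
#' @export
aic_and_weights <- function(fits, corrected = TRUE) {
  ns <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("fits compare different data (n differs)")
  n <- ns[1]
  k <- vapply(fits, function(f) f$n_params, numeric(1))
  ssr <- vapply(fits, function(f) f$ssr, numeric(1))
  aic <- n * log(ssr / n) + 2 * k
  if (corrected) {
    denom <- n - k - 1
    aic <- aic + ifelse(denom > 0, 2 * k * (k + 1) / denom, Inf)
  }
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  labels <- vapply(seq_along(fits), function(i) {
    ml <- fits[[i]]$model_label
    if (is.null(ml)) ml <- fits[[i]]$model
    if (is.null(ml)) ml <- paste0("model", i)
    ml
  }, character(1))
  data.frame(model = labels, k = k, aic = aic, delta = delta, weight = w,
             row.names = NULL)
}
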