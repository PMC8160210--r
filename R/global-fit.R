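#' Global multi-curve fit of a sequential binding scheme
#'
#' Fits one set of stepwise dissociation constants jointly to several
#' titration curves, each with its own per-species response coefficients.
#' The objective is the weighted residual sum of squares over all curves.
#'
#' Parameterisation: K_d's are optimised as log10 values with the ordering
#' constraint \eqn{K_{d1} \le K_{d2} \le K_{d3}} (log-spacings bounded below
#' by zero), which removes label switching. For any trial K_d set the
#' responses enter the model linearly, so they are profiled out exactly by
#' per-curve weighted linear least squares (variable projection); the
#' nonlinear search runs only over the `n_sites` log-constants and is
#' restarted from `n_starts` seeded perturbations of a quantile-based
#' heuristic start. Because species concentrations sum to `p_total`, a
#' constant instrumental offset is not separately identifiable and is
#' absorbed into the responses.
#'
#' @param curves List of [titration_curve()] objects sharing the same
#'   ligand/protein system. MST curves use fractional responses
#'   automatically.
#' @param n_sites Number of sequential binding steps to fit (1, 2 or 3).
#' @param n_starts Optimiser starts (default 10, seeded).
#' @param seed Seed for start perturbations.
#' @param warm_from Optional `binding_fit` with fewer sites; its constants
#'   seed extra starts (keeps nested SSRs monotone).
#' @param kd_bounds Optional log10 bounds (length 2) for K_d1.
#' @return A `binding_fit`: list with `params` (named: `log10_kd*` and
#'   per-curve responses), `sd`, `ci3` (Wald +/- 3 SD with open-bound flags),
#'   `ssr`, `n_obs`, `n_params`, `residuals` and `fitted` (per curve),
#'   `runs` (per curve and pooled), `aic` (AICc), `scheme`, `model_label`,
#'   `identifiable`, `converged`.
#' @export
global_fit <- function(curves, n_sites, n_starts = 10, seed = 1,
                       warm_from = NULL, kd_bounds = NULL) {
  stopifnot(n_sites %in% 1:3)
  if (!length(curves)) stop("no curves supplied")
  if (inherits(curves, "titration_curve")) curves <- list(curves)
  for (cv in curves) if (!inherits(cv, "titration_curve"))
    stop("curves must be titration_curve objects")

  blocks <- lapply(curves, function(cv) {
    sigma <- if (is.null(cv$weights)) rep(1, length(cv$signal)) else cv$weights
    list(l = cv$l_total, y = cv$signal, w = 1 / sigma^2,
         p_total = cv$p_total, fraction = identical(cv$modality, "mst"))
  })
  design <- function(kd, b) {
    scheme <- binding_scheme(kd)
    L <- speciation_free_ligand(scheme, b$p_total, b$l)
    X <- species_concentrations(scheme, b$p_total, L)[, seq_len(n_sites + 1L),
                                                      drop = FALSE]
    if (b$fraction) X / b$p_total else X
  }
  # curves of one series usually share design (same grid, same p_total):
  # compute each unique design once per trial kd
  keys <- vapply(blocks, function(b)
    paste(b$p_total, b$fraction, paste(b$l, collapse = ","), sep = "|"),
    character(1))
  group_of <- match(keys, unique(keys))
  group_rep <- match(unique(keys), keys)
  eval_ssr <- function(kd) {
    Xs <- lapply(group_rep, function(i) design(kd, blocks[[i]]))
    ssr <- 0
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      fit <- stats::lm.wfit(Xs[[group_of[i]]], b$y, b$w)
      ssr <- ssr + sum(b$w * fit$residuals^2)
    }
    if (!is.finite(ssr)) 1e300 else ssr
  }

  lpos <- unlist(lapply(blocks, function(b) b$l[b$l > 0]))
  if (!length(lpos)) stop("curves contain no positive ligand concentrations")
  lr <- log10(range(lpos))
  if (is.null(kd_bounds)) kd_bounds <- c(lr[1] - 4, lr[2] + 4)

  starts <- vp_starts(n_sites, lr, n_starts, seed, warm_from)
  opt <- vp_optimize(eval_ssr, n_sites, starts, kd_bounds)
  vp_assemble(opt, design, blocks, curves, n_sites,
              label = paste0(n_sites, "-site"))
}

# quantile heuristic + seeded log-perturbations (+ warm-started insertions)
vp_starts <- function(n_sites, lr, n_starts, seed, warm_from = NULL) {
  probs <- (seq_len(n_sites) - 0.5) / n_sites
  base <- lr[1] + probs * (lr[2] - lr[1])
  starts <- list(base)
  if (!is.null(warm_from)) {
    prev <- warm_from$params[grep("^log10_kd", names(warm_from$params))]
    if (length(prev) < n_sites) {
      for (extra in c(max(prev) + 1.5, max(prev) + 3, min(prev) - 1.5))
        starts[[length(starts) + 1]] <- sort(c(unname(prev), extra))[1:n_sites]
    }
  }
  old <- local_seed(seed); on.exit(restore_seed(old))
  while (length(starts) < n_starts)
    starts[[length(starts) + 1]] <- sort(base + stats::rnorm(n_sites, 0, 0.7))
  starts
}

kd_from_theta <- function(theta) 10^cumsum(theta)
theta_from_logkd <- function(lk) c(lk[1], diff(lk))

# nonlinear search over theta = (log10 kd1, spacings >= 0); the objective is
# normalised to O(1) so the optimiser's tolerances behave the same whether
# the signals are fluorescence counts or kcal-scale heats
vp_optimize <- function(eval_ssr, n_sites, starts, kd_bounds) {
  lower <- c(kd_bounds[1], rep(0, n_sites - 1))
  upper <- c(kd_bounds[2], rep(12, n_sites - 1))
  th1 <- pmin(pmax(theta_from_logkd(starts[[1]]), lower), upper)
  ssr0 <- eval_ssr(kd_from_theta(th1))
  scale <- 1 / max(ssr0, .Machine$double.xmin)
  objective <- function(theta) {
    v <- eval_ssr(kd_from_theta(theta)) * scale
    if (!is.finite(v)) 1e300 else v
  }
  best <- NULL; diagnostics <- character(0)
  for (st in starts) {
    th0 <- pmin(pmax(theta_from_logkd(st), lower), upper)
    res <- try(stats::nlminb(th0, objective, lower = lower, upper = upper,
                             control = list(rel.tol = 1e-12, x.tol = 1e-10,
                                            eval.max = 600, iter.max = 400)),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      diagnostics <- c(diagnostics, as.character(res))
      next
    }
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("global fit failed from every start:\n",
         paste(diagnostics, collapse = "\n"))
  best$objective <- best$objective / scale
  best$converged <- best$convergence == 0
  best
}

# full parameter vector, covariance, residual diagnostics
vp_assemble <- function(opt, design, blocks, curves, n_sites, label) {
  kd <- kd_from_theta(opt$par)
  log10_kd <- log10(kd)

  coefs <- vector("list", length(blocks))
  fitted <- residuals <- vector("list", length(blocks))
  ssr <- 0
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    X <- design(kd, b)
    fit <- stats::lm.wfit(X, b$y, b$w)
    cf <- fit$coefficients; cf[is.na(cf)] <- 0
    coefs[[i]] <- cf
    fitted[[i]] <- drop(X %*% cf)
    residuals[[i]] <- b$y - fitted[[i]]
    ssr <- ssr + sum(b$w * residuals[[i]]^2)
  }

  pnames <- c(paste0("log10_kd", seq_len(n_sites)),
              unlist(lapply(seq_along(blocks), function(i)
                paste0("curve", i, "_r", seq_len(n_sites + 1L) - 1L))))
  params <- c(log10_kd, unlist(coefs))
  names(params) <- pnames
  n_obs <- sum(vapply(blocks, function(b) length(b$y), numeric(1)))
  n_params <- length(params)

  # weighted Jacobian over (log10 kds, responses)
  J <- matrix(0, n_obs, n_params)
  row0 <- 0
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    m <- length(b$y); rows <- row0 + seq_len(m)
    X <- design(kd, b)
    sw <- sqrt(b$w)
    for (j in seq_len(n_sites)) {
      h <- 1e-5
      kd_p <- 10^(log10_kd + h * (seq_len(n_sites) == j))
      kd_m <- 10^(log10_kd - h * (seq_len(n_sites) == j))
      dX <- (design(cummax(kd_p), b) %*% coefs[[i]] -
             design(cummax(kd_m), b) %*% coefs[[i]]) / (2 * h)
      J[rows, j] <- sw * drop(dX)
    }
    cols <- n_sites + (i - 1) * (n_sites + 1L) + seq_len(n_sites + 1L)
    J[rows, cols] <- sw * X
    row0 <- row0 + m
  }
  dof <- n_obs - n_params
  s2 <- if (dof > 0) ssr / dof else NA_real_
  sv <- svd(J)
  tol <- max(sv$d) * 1e-8
  ok <- sv$d > tol
  identifiable <- all(ok)
  inv_d2 <- ifelse(ok, 1 / sv$d^2, Inf)
  var_p <- rowSums(sweep(sv$v^2, 2, inv_d2, `*`)) * s2
  null_hit <- if (identifiable) rep(FALSE, n_params)
              else rowSums(abs(sv$v[, !ok, drop = FALSE])) > 1e-6
  sd <- sqrt(var_p)
  sd[null_hit] <- Inf
  names(sd) <- pnames

  ci3 <- cbind(lower = params - 3 * sd, upper = params + 3 * sd)
  open <- !is.finite(sd)

  runs_per_curve <- lapply(residuals, function(r)
    if (sum(r != 0) >= 8) try(runs_test(r), silent = TRUE) else NULL)
  pooled <- try(runs_test(unlist(residuals)), silent = TRUE)

  aicc <- n_obs * log(ssr / n_obs) + 2 * n_params +
    if (n_obs - n_params - 1 > 0) 2 * n_params * (n_params + 1) / (n_obs - n_params - 1) else Inf

  structure(list(params = params, sd = sd,
                 ci3 = ci3, ci3_open = cbind(lower = open, upper = open),
                 ssr = ssr, n_obs = n_obs, n_params = n_params,
                 residuals = residuals, fitted = fitted,
                 runs = list(per_curve = runs_per_curve,
                             pooled = if (inherits(pooled, "try-error")) NULL else pooled),
                 aic = aicc, scheme = binding_scheme(kd),
                 model_label = label, theta = opt$par,
                 identifiable = identifiable, converged = isTRUE(opt$converged),
                 curves = curves, n_sites = n_sites),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Global binding fit [%s]: %d curves, n = %d, SSR = %.5g\n",
              x$model_label, length(x$curves), x$n_obs, x$ssr))
  kd_i <- grep("^log10_kd", names(x$params))
  tab <- cbind(`Kd [uM]` = 10^x$params[kd_i],
               `log10 est` = x$params[kd_i],
               `log10 SD` = x$sd[kd_i])
  print(signif(tab, 4))
  if (!x$identifiable)
    cat("warning: some parameters are unidentifiable (SD = Inf)\n")
  if (!is.null(x$runs$pooled)) {
    cat("pooled ")
    print(x$runs$pooled)
  }
  invisible(x)
}

#' Profile-likelihood 3-sigma confidence interval
#'
#' Steps one log10 K_d over a grid, re-optimising all other constants (the
#' responses are profiled out exactly), and reports the interval where
#' \deqn{SSR(\theta) \le SSR_{min} (1 + F(\alpha^*; 1, n-k)/(n-k))}
#' with \eqn{\alpha^* = 0.0027} (the 3-sigma level). If the lower crossing
#' falls below the smallest positive ligand concentration used in the
#' titrations, the bound is reported as *open* with that concentration as the
#' censoring value -- the data do not probe tighter binding. A profile that
#' never rises to the threshold on a side leaves that bound open as well.
#'
#' @param fit A `binding_fit` from [global_fit()].
#' @param param Which constant to profile: index 1..n_sites or name
#'   `"kd2"`/`"log10_kd2"`.
#' @param step Profile step, decades (default 0.05).
#' @param max_span Maximum distance walked from the estimate, decades.
#' @param alpha Interval level (default 0.0027, i.e. 3 sigma).
#' @return List with `estimate` (uM), `lower`, `upper` (uM), `open_lower`,
#'   `open_upper`, `censor_lower` (uM, smallest tested concentration) and
#'   `ssr_threshold`.
#' @export
profile_ci_3sigma <- function(fit, param, step = 0.05, max_span = 8,
                              alpha = 0.0027) {
  n_sites <- fit$n_sites
  j <- if (is.character(param)) as.integer(sub("^(log10_)?kd", "", param)) else as.integer(param)
  if (is.na(j) || j < 1 || j > n_sites) stop("param must identify one of the fitted constants")

  blocks <- lapply(fit$curves, function(cv) {
    sigma <- if (is.null(cv$weights)) rep(1, length(cv$signal)) else cv$weights
    list(l = cv$l_total, y = cv$signal, w = 1 / sigma^2,
         p_total = cv$p_total, fraction = identical(cv$modality, "mst"))
  })
  design <- function(kd, b) {
    scheme <- binding_scheme(sort(kd))
    L <- speciation_free_ligand(scheme, b$p_total, b$l)
    X <- species_concentrations(scheme, b$p_total, L)[, seq_len(n_sites + 1L),
                                                      drop = FALSE]
    if (b$fraction) X / b$p_total else X
  }
  keys <- vapply(blocks, function(b)
    paste(b$p_total, b$fraction, paste(b$l, collapse = ","), sep = "|"),
    character(1))
  group_of <- match(keys, unique(keys))
  group_rep <- match(unique(keys), keys)
  ssr_at <- function(lk) {  # full log10 kd vector
    kd <- 10^lk
    Xs <- lapply(group_rep, function(i) design(kd, blocks[[i]]))
    ssr <- 0
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      f <- stats::lm.wfit(Xs[[group_of[i]]], b$y, b$w)
      ssr <- ssr + sum(b$w * f$residuals^2)
    }
    ssr
  }
  lk_hat <- fit$params[grep("^log10_kd", names(fit$params))]
  scale <- 1 / max(fit$ssr, .Machine$double.xmin)
  profile_ssr <- function(lkj) {
    if (n_sites == 1L) return(ssr_at(lkj))
    others0 <- lk_hat[-j]
    obj <- function(o) { lk <- numeric(n_sites); lk[j] <- lkj; lk[-j] <- o
                         ssr_at(lk) * scale }
    res <- stats::nlminb(others0, obj,
                         control = list(rel.tol = 1e-11, eval.max = 400))
    res$objective / scale
  }

  dof <- fit$n_obs - fit$n_params
  if (dof <= 0) stop("no residual degrees of freedom for profiling")
  crit <- fit$ssr * (1 + stats::qf(1 - alpha, 1, dof) / dof)

  walk <- function(dir) {
    prev_lk <- lk_hat[j]; prev_ssr <- fit$ssr
    for (s in seq(step, max_span, by = step)) {
      lk <- lk_hat[j] + dir * s
      cur <- profile_ssr(lk)
      if (cur >= crit) {
        frac <- (crit - prev_ssr) / (cur - prev_ssr)
        return(list(bound = prev_lk + dir * step * frac, open = FALSE,
                    trace = c(lk, cur)))
      }
      prev_lk <- lk; prev_ssr <- cur
    }
    list(bound = dir * Inf, open = TRUE, trace = c(prev_lk, prev_ssr))
  }
  lo <- walk(-1); hi <- walk(+1)

  lmin <- min(unlist(lapply(fit$curves, function(cv) cv$l_total[cv$l_total > 0])))
  open_lower <- lo$open
  lower <- 10^lo$bound
  if (!lo$open && lower < lmin) { open_lower <- TRUE; lower <- lmin }
  if (lo$open) lower <- lmin

  list(estimate = 10^lk_hat[[j]],
       lower = unname(lower), upper = unname(10^hi$bound),
       open_lower = open_lower, open_upper = hi$open,
       censor_lower = lmin,
       ssr_threshold = crit)
}

#' Model-discrimination ladder for binding curves
#'
#' Implements the 1 -> 2 -> 3-site discrimination procedure: fit the
#' one-site model first; only when the pooled residual runs test flags
#' systematic misfit (one-sided p below `alpha` with the run count *below*
#' expectation) move to the two-site model, and by the same rule to the
#' three-site model. AICc weights are computed across all fitted models. The
#' ladder verdict is final unless the Akaike best model disagrees, in which
#' case both verdicts are reported and the disagreement flagged -- mirroring
#' situations where the two criteria genuinely conflict.
#'
#' @param curves List of [titration_curve()] objects.
#' @param max_sites Deepest model to consider (default 3).
#' @param alpha Runs-test level for climbing the ladder (default 0.05).
#' @param n_starts,seed Passed to [global_fit()].
#' @return A `model_comparison`: list with `fits` (by model), `aic` table,
#'   `ladder_choice`, `aic_choice`, `final` (sites chosen), `agreement`.
#' @export
discriminate <- function(curves, max_sites = 3, alpha = 0.05,
                         n_starts = 10, seed = 1) {
  fits <- list()
  choice <- NA_integer_
  warm <- NULL
  for (k in seq_len(max_sites)) {
    fits[[k]] <- global_fit(curves, k, n_starts = n_starts, seed = seed + k,
                            warm_from = warm)
    warm <- fits[[k]]
    pooled <- fits[[k]]$runs$pooled
    reject <- !is.null(pooled) && !pooled$degenerate &&
      !is.na(pooled$p_one_sided) && pooled$p_one_sided < alpha &&
      identical(pooled$direction, "below")
    if (!reject) { choice <- k; break }
    if (k == max_sites) choice <- k
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  aic_tab <- aic_and_weights(fits)
  aic_choice <- as.integer(sub("-site", "", aic_tab$model[which.max(aic_tab$weight)]))
  structure(list(fits = stats::setNames(fits, vapply(fits, `[[`, "", "model_label")),
                 aic = aic_tab,
                 ladder_choice = choice,
                 aic_choice = aic_choice,
                 final = choice,
                 agreement = choice == aic_choice),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model discrimination: ladder -> %d site(s), AICc -> %d site(s)%s\n",
              x$ladder_choice, x$aic_choice,
              if (x$agreement) "" else "  [criteria disagree]"))
  print(transform(x$aic, aic = signif(aic, 6), delta = signif(delta, 4),
                  weight = signif(weight, 4)))
  invisible(x)
}
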