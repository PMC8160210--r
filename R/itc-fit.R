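#' Global fit of ITC injection-heat series
#'
#' Fits one set of stepwise dissociation constants jointly to several
#' calorimetric titrations run at different cell concentrations. For a trial
#' K_d set the per-injection heats are linear in the step enthalpies and the
#' constant dilution heat, so (dH_1..dH_n, q_dil) are profiled out exactly per
#' experiment; the nonlinear search runs over the shared log10 K_d's, exactly
#' as in [global_fit()].
#'
#' @param experiments List of [itc_experiment()] objects (their `dH` and
#'   `q_dilution` entries are ignored; both are fitted).
#' @param heats List of per-injection heat vectors (kcal), parallel to
#'   `experiments`.
#' @param n_sites Number of binding steps (1, 2 or 3).
#' @param n_starts,seed As in [global_fit()].
#' @param fit_dilution Estimate a per-experiment constant dilution heat
#'   (default `TRUE`).
#' @return A `binding_fit` with `params` = log10 K_d's plus per-experiment
#'   `dH` (kcal/mol) and dilution heats.
#' @export
global_fit_itc <- function(experiments, heats, n_sites, n_starts = 10,
                           seed = 1, fit_dilution = TRUE) {
  stopifnot(n_sites %in% 1:3)
  if (length(experiments) != length(heats))
    stop("experiments and heats lengths differ")
  blocks <- lapply(seq_along(experiments), function(i) {
    ex <- experiments[[i]]
    y <- as.numeric(heats[[i]])
    if (length(y) != length(ex$injection_volumes))
      stop("heat vector length must match injections (experiment ", i, ")")
    list(exper = ex, y = y, w = rep(1, length(y)))
  })
  design <- function(kd, b) itc_design_matrix(binding_scheme(kd), b$exper,
                                              fit_dilution)
  # K_d starts span the ligand concentrations actually visited in the cell
  lt_cell <- unlist(lapply(blocks, function(b) {
    ex <- b$exper
    cumsum(ex$syringe_ligand * ex$injection_volumes / ex$cell_volume)
  }))
  lr <- log10(range(lt_cell[lt_cell > 0])) + c(-1.5, 0.5)

  eval_ssr <- function(kd) {
    ssr <- 0
    for (b in blocks) {
      X <- design(kd, b)
      f <- stats::lm.wfit(X, b$y, b$w)
      ssr <- ssr + sum(b$w * f$residuals^2)
    }
    if (!is.finite(ssr)) 1e300 else ssr
  }
  starts <- vp_starts(n_sites, lr, n_starts, seed)
  opt <- vp_optimize(eval_ssr, n_sites, starts,
                     kd_bounds = c(lr[1] - 3, lr[2] + 3))
  vp_assemble_itc(opt, design, blocks, n_sites, fit_dilution)
}

# columns: heat per unit dH_i (kcal per kcal/mol), optionally intercept
itc_design_matrix <- function(scheme, ex, fit_dilution) {
  V0 <- ex$cell_volume
  P <- ex$cell_protein; Ltot <- 0
  bound_ge <- bound_ge_concentrations(scheme, P, Ltot)
  n_inj <- length(ex$injection_volumes)
  X <- matrix(0, n_inj, scheme$n_steps)
  for (n in seq_len(n_inj)) {
    v <- ex$injection_volumes[n]
    d <- 1 - v / V0
    P <- P * d
    Ltot <- Ltot * d + ex$syringe_ligand * v / V0
    prev <- bound_ge * d
    bound_ge <- bound_ge_concentrations(scheme, P, Ltot)
    X[n, ] <- 1e-12 * V0 * (bound_ge - prev)
  }
  if (fit_dilution) cbind(X, q_dil = 1) else X
}

vp_assemble_itc <- function(opt, design, blocks, n_sites, fit_dilution) {
  kd <- kd_from_theta(opt$par)
  log10_kd <- log10(kd)
  ncol_b <- n_sites + as.integer(fit_dilution)

  coefs <- fitted <- residuals <- vector("list", length(blocks))
  ssr <- 0
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    X <- design(kd, b)
    f <- stats::lm.wfit(X, b$y, b$w)
    cf <- f$coefficients; cf[is.na(cf)] <- 0
    coefs[[i]] <- cf
    fitted[[i]] <- drop(X %*% cf)
    residuals[[i]] <- b$y - fitted[[i]]
    ssr <- ssr + sum(b$w * residuals[[i]]^2)
  }
  cnames <- unlist(lapply(seq_along(blocks), function(i) {
    nm <- paste0("exp", i, "_dH", seq_len(n_sites))
    if (fit_dilution) nm <- c(nm, paste0("exp", i, "_qdil"))
    nm
  }))
  params <- c(log10_kd, unlist(coefs))
  names(params) <- c(paste0("log10_kd", seq_len(n_sites)), cnames)
  n_obs <- sum(vapply(blocks, function(b) length(b$y), numeric(1)))
  n_params <- length(params)

  J <- matrix(0, n_obs, n_params)
  row0 <- 0
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    m <- length(b$y); rows <- row0 + seq_len(m)
    X <- design(kd, b)
    for (j in seq_len(n_sites)) {
      h <- 1e-5
      kd_p <- cummax(10^(log10_kd + h * (seq_len(n_sites) == j)))
      kd_m <- cummax(10^(log10_kd - h * (seq_len(n_sites) == j)))
      J[rows, j] <- drop((design(kd_p, b) - design(kd_m, b)) %*% coefs[[i]]) / (2 * h)
    }
    cols <- n_sites + (i - 1) * ncol_b + seq_len(ncol_b)
    J[rows, cols] <- X
    row0 <- row0 + m
  }
  dof <- n_obs - n_params
  s2 <- if (dof > 0) ssr / dof else NA_real_
  sv <- svd(J)
  ok <- sv$d > max(sv$d) * 1e-8
  identifiable <- all(ok)
  inv_d2 <- ifelse(ok, 1 / sv$d^2, Inf)
  sd <- sqrt(rowSums(sweep(sv$v^2, 2, inv_d2, `*`)) * s2)
  if (!identifiable)
    sd[rowSums(abs(sv$v[, !ok, drop = FALSE])) > 1e-6] <- Inf
  names(sd) <- names(params)

  aicc <- n_obs * log(ssr / n_obs) + 2 * n_params +
    if (n_obs - n_params - 1 > 0) 2 * n_params * (n_params + 1) / (n_obs - n_params - 1) else Inf
  pooled <- if (sum(unlist(residuals) != 0) >= 8)
    try(runs_test(unlist(residuals)), silent = TRUE) else NULL

  structure(list(params = params, sd = sd,
                 ci3 = cbind(lower = params - 3 * sd, upper = params + 3 * sd),
                 ci3_open = cbind(lower = !is.finite(sd), upper = !is.finite(sd)),
                 ssr = ssr, n_obs = n_obs, n_params = n_params,
                 residuals = residuals, fitted = fitted,
                 runs = list(per_curve = NULL,
                             pooled = if (inherits(pooled, "try-error")) NULL else pooled),
                 aic = aicc, scheme = binding_scheme(kd),
                 model_label = paste0(n_sites, "-site"),
                 theta = opt$par, identifiable = identifiable,
                 converged = isTRUE(opt$converged), curves = NULL,
                 n_sites = n_sites),
            class = "binding_fit")
}
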