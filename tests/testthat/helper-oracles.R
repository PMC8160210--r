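# Independent oracles used across tests.

# Free-ligand by exhaustive enumeration of all roots of the degree-(n+1)
# mass-balance polynomial L*Q(L) + P*B(L) - Ltot*Q(L) = 0; the unique real
# root in [0, Ltot] is selected. Independent of the package's Newton solver.
oracle_free_ligand <- function(kd, p_total, l_total) {
  beta <- cumprod(1 / kd)
  n <- length(kd)
  # coefficients by ascending power of L
  co <- numeric(n + 2)
  co[1] <- -l_total
  co[2] <- 1 + p_total * beta[1] - l_total * beta[1]
  if (n >= 2) co[3] <- beta[1] + 2 * p_total * beta[2] - l_total * beta[2]
  if (n >= 3) co[4] <- beta[2] + 3 * p_total * beta[3] - l_total * beta[3]
  co[n + 2] <- beta[n]
  # scale for conditioning
  rts <- polyroot(co)
  real <- Re(rts)[abs(Im(rts)) <= 1e-8 * (1 + abs(Re(rts)))]
  cand <- real[real >= -1e-9 * max(1, l_total) &
               real <= l_total * (1 + 1e-9)]
  if (!length(cand)) stop("oracle found no admissible root")
  max(min(cand, l_total), 0)
}

# quadratic closed form for the 1-step scheme
oracle_free_ligand_1step <- function(kd, p_total, l_total) {
  b <- kd + p_total - l_total
  (-b + sqrt(b^2 + 4 * kd * l_total)) / 2
}

# brute-force partition function for n identical independent sites with
# microscopic constant k: Q(L) = sum over subsets = sum_i C(n,i) (L/k)^i
oracle_statistical_kds <- function(n, k) {
  beta <- choose(n, seq_len(n)) / k^seq_len(n)
  beta_prev <- c(1, beta[-n])
  beta_prev / beta   # stepwise K_di = beta_{i-1} / beta_i
}

# Savitzky-Golay projection weights from first principles (Vandermonde LSQ)
oracle_sg_central_weights <- function(poly_order, window) {
  half <- (window - 1) / 2
  x <- -half:half
  V <- outer(x, 0:poly_order, `^`)
  H <- V %*% solve(crossprod(V)) %*% t(V)
  H[half + 1, ]
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)), tol)
}
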