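test_that("runs test matches enumeration and the normal approximation", {
  # + + + - - -: two runs, E[R] = 4, exact lower-tail P(R <= 2) = 2/C(6,3)
  r <- runs_test(c(1, 2, 0.5, -1, -0.5, -2, 1, -1, 2, -2))
  expect_s3_class(r, "runs_test_result")

  expect_error(runs_test(c(1, 1, 1, -1, -1, -1)), "at least 8")

  x <- c(3, 2, 1, -1, -2, -3, 4, -4)  # 4 runs with n1 = n2 = 4
  rt <- runs_test(x)
  expect_equal(rt$n_pos, 4)
  expect_equal(rt$runs_observed, 4)
  expect_equal(rt$runs_expected, 2 * 4 * 4 / 8 + 1)

  # full PMF oracle at n1 = n2 = 3 embedded in an 8-residual vector is not
  # possible; check the distribution function directly instead
  pmf <- hexabind:::runs_pmf(3, 3)
  expect_equal(sum(pmf), 1)
  expect_equal(unname(pmf["2"]), 2 / choose(6, 3))
  expect_equal(unname(sum(pmf[c("2")])), 0.1)

  # perfectly alternating signs: R = n, direction above
  alt <- rep(c(1, -1), 8)
  ra <- runs_test(alt)
  expect_equal(ra$runs_observed, 16)
  expect_equal(ra$direction, "above")
  expect_gt(ra$p_one_sided, 0.99)

  # degenerate: one sign only
  rd <- runs_test(rep(1, 10))
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p_two_sided))

  # zeros are dropped
  rz <- runs_test(c(x, 0, 0))
  expect_equal(rz$n_pos + rz$n_neg, 8)

  # exact and normal approximations agree at n1 + n2 = 20
  set.seed(2)
  for (i in 1:50) {
    sg <- sample(c(rep(1, 10), rep(-1, 10)))
    ex <- runs_test(sg, exact_limit = 200)
    no <- runs_test(sg, exact_limit = 0)
    expect_lt(abs(ex$p_two_sided - no$p_two_sided), 0.02)
  }
})

test_that("Akaike weights follow the closed form", {
  mk <- function(ssr, k, n = 40, label = "m")
    list(ssr = ssr, n_obs = n, n_params = k, model_label = label)

  # equal AIC: equal weights
  eq <- aic_and_weights(list(mk(10, 3, label = "a"), mk(10, 3, label = "b")))
  expect_equal(eq$weight, c(0.5, 0.5))
  expect_equal(sum(eq$weight), 1, tolerance = 1e-12)

  # delta = (0, 2): weights 0.731 / 0.269
  n <- 50
  ssr2 <- 10 * exp(2 / n)  # same k, AIC difference exactly 2
  w <- aic_and_weights(list(mk(10, 3, n), mk(ssr2, 3, n)))
  expect_equal(round(w$weight, 3), c(0.731, 0.269))

  # an overwhelmingly worse model gets weight 0
  w3 <- aic_and_weights(list(mk(1, 3), mk(1e9, 3), mk(1e9, 3)))
  expect_equal(w3$weight, c(1, 0, 0), tolerance = 1e-12)

  expect_error(aic_and_weights(list(mk(1, 2, 30), mk(1, 2, 40))),
               "different data")
})

test_that("global fit recovers a noise-free three-site series exactly", {
  s <- binding_scheme(c(4.4, 84, 1770))
  lt <- 10^seq(log10(0.007), log10(4e4), length.out = 25)
  resp <- rbind(c(100, 80, 60, 40),
                c(100, 130, 90, 110),
                c(100, 60, 80, 130))
  curves <- lapply(1:3, function(i)
    titration_curve(lt, optical_signal(s, response_set(resp[i, ]), 0.5, lt),
                    "fluorescence", 0.5))
  fit <- global_fit(curves, 3, n_starts = 6, seed = 2)
  expect_equal(10^fit$params[paste0("log10_kd", 1:3)],
               c(log10_kd1 = 4.4, log10_kd2 = 84, log10_kd3 = 1770),
               tolerance = 1e-6)
  expect_lt(fit$ssr, 1e-12)
  # responses recovered too
  expect_equal(unname(fit$params[paste0("curve1_r", 0:3)]), resp[1, ],
               tolerance = 1e-5)
})

test_that("a flat curve leaves the constants unidentifiable, not wrong", {
  s <- binding_scheme(10)
  lt <- 10^seq(-1, 3, length.out = 12)
  flat <- titration_curve(lt, rep(50, 12), "fluorescence", 1)
  fit <- global_fit(list(flat), 1, n_starts = 3, seed = 1)
  expect_false(fit$identifiable)
  expect_true(any(!is.finite(fit$sd)))
})

test_that("nested fits have monotone SSR and sane Akaike weights", {
  sim <- simulate_fluorescence_series(seed = 12)
  curves <- correct_fluorescence_series(sim)
  f1 <- global_fit(curves, 1, n_starts = 4, seed = 3)
  f2 <- global_fit(curves, 2, n_starts = 4, seed = 3, warm_from = f1)
  f3 <- global_fit(curves, 3, n_starts = 4, seed = 3, warm_from = f2)
  expect_gte(f1$ssr * (1 + 1e-6), f2$ssr)
  expect_gte(f2$ssr * (1 + 1e-6), f3$ssr)
  tab <- aic_and_weights(list(f1, f2, f3))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$model[which.max(tab$weight)], "3-site")
})

test_that("statistical-scheme data return the site-counting ratios", {
  s <- statistical_scheme(3, 30)   # 10, 30, 90 uM
  lt <- 10^seq(-1, 4, length.out = 25)
  resp <- rbind(c(100, 85, 65, 40), c(100, 120, 145, 170),
                c(100, 70, 115, 55))
  set.seed(9)
  curves <- lapply(1:3, function(i) {
    y <- optical_signal(s, response_set(resp[i, ]), 0.5, lt)
    titration_curve(lt, y + rnorm(length(y), 0, 0.01 * mean(abs(y))),
                    "fluorescence", 0.5)
  })
  fit <- global_fit(curves, 3, n_starts = 6, seed = 4)
  lk <- fit$params[paste0("log10_kd", 1:3)]
  sdk <- fit$sd[paste0("log10_kd", 1:3)]
  # ratios Kd2/Kd1 = 3 and Kd3/Kd1 = 9 within 3 sigma (in log10)
  expect_lt(abs((lk[2] - lk[1]) - log10(3)), 3 * sqrt(sdk[1]^2 + sdk[2]^2))
  expect_lt(abs((lk[3] - lk[1]) - log10(9)), 3 * sqrt(sdk[1]^2 + sdk[3]^2))
})

test_that("three-sigma intervals cover the truth at the nominal rate", {
  # reduced coverage study: one-site truth, 200 seeded repetitions
  s <- binding_scheme(25)
  lt <- 10^seq(-1, 4, length.out = 18)
  resp <- c(100, 60)
  covered <- logical(200)
  for (i in seq_len(200)) {
    set.seed(4000 + i)
    y0 <- optical_signal(s, response_set(resp), 0.5, lt)
    curves <- list(titration_curve(lt, y0 + rnorm(18, 0, 0.8),
                                   "fluorescence", 0.5))
    fit <- global_fit(curves, 1, n_starts = 2, seed = i)
    covered[i] <- abs(fit$params["log10_kd1"] - log10(25)) <=
      3 * fit$sd["log10_kd1"]
  }
  expect_gte(mean(covered), 0.97)
})

test_that("ITC global fit recovers constants and enthalpies", {
  sim <- simulate_itc_series(noise_sd = 0, seed = 21)
  fit <- global_fit_itc(sim$experiments, sim$heats, 3, n_starts = 6, seed = 2)
  expect_equal(10^unname(fit$params[paste0("log10_kd", 1:3)]),
               c(6.75, 148.9, 655), tolerance = 1e-4)
  expect_equal(unname(fit$params[paste0("exp1_dH", 1:3)]),
               c(-3.5, -2.0, -4.5), tolerance = 1e-4)

  simn <- simulate_itc_series(seed = 22)
  fitn <- global_fit_itc(simn$experiments, simn$heats, 3, n_starts = 6,
                         seed = 2)
  lk <- fitn$params[paste0("log10_kd", 1:3)]
  expect_true(all(abs(lk - log10(c(6.75, 148.9, 655))) <=
                    3 * fitn$sd[paste0("log10_kd", 1:3)]))
})

test_that("profile interval reports an open lower bound on weak data", {
  # CD-like regime: protein 10 uM binding units vs Kd1 = 0.58 uM -- the
  # tightest constant sits below the depletion floor
  sim <- simulate_cd_titration(seed = 41)
  curves <- cd_cross_sections(sim, k = 5)
  fit <- global_fit(curves, 3, n_starts = 6, seed = 5)
  pr <- profile_ci_3sigma(fit, 1, step = 0.1, max_span = 5)
  expect_true(pr$open_lower)
  expect_equal(pr$censor_lower, min(sim$l_total))
  txt <- write_report(fit, profiles = list(
    pr, profile_ci_3sigma(fit, 2, step = 0.2, max_span = 3),
    profile_ci_3sigma(fit, 3, step = 0.2, max_span = 3)))
  expect_true(any(grepl("< ", txt, fixed = TRUE)))
})
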