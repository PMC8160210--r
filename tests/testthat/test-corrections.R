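test_that("drift slopes are recovered and applied cumulatively", {
  # exact line: F = 100 - 0.5 t
  ts <- list(data.frame(t = 0:4, F = 100 - 0.5 * (0:4)),
             data.frame(t = 0:4, F = rep(3, 5)))
  dr <- fit_drift_slopes(ts)
  expect_equal(dr$slopes, c(-0.5, 0), tolerance = 1e-12)

  expect_error(fit_drift_slopes(list(data.frame(t = 1, F = 2))), ">= 2")

  # printed form: F_n^cor = F_n + sum of slopes
  expect_equal(drift_correct(c(100, 98), c(0.5, 0.5)), c(100.5, 99.0))
  expect_equal(drift_correct(c(5, 6, 7), c(0, 0, 0)), c(5, 6, 7))
  expect_equal(drift_correct(c(100, 98), c(0.5, 0.5), drift_sign = -1),
               c(99.5, 97.0))
  expect_error(drift_correct(1:3, 1:2), "one drift slope per")

  # noisy line: OLS slope within 3 standard errors
  set.seed(11)
  t <- seq(0, 2, by = 0.25)
  reps <- lapply(1:50, function(i)
    data.frame(t = t, F = 50 - 1.2 * t + rnorm(length(t), 0, 0.3)))
  sl <- fit_drift_slopes(reps)$slopes
  se <- 0.3 / sqrt(sum((t - mean(t))^2))
  expect_true(mean(abs(sl - (-1.2)) <= 3 * se) > 0.95)
})

test_that("phosphate ionic strength follows the dibasic speciation", {
  expect_equal(phosphate_ionic_strength(0, pH = 7.6), 0)
  # Henderson-Hasselbalch midpoint
  f2_mid <- 1 / (1 + 10^(7.2 - 7.2))
  expect_equal(f2_mid, 0.5)
  I_mid <- phosphate_ionic_strength(10, pH = 7.2)
  expect_equal(I_mid, 0.5 * 10 * (4 * 0.5 + 0.5) + 0.5 * 10 * 1.5)
  # formula arithmetic at pH 7.6
  f2 <- 1 / (1 + 10^(7.2 - 7.6))
  expect_equal(round(f2, 3), 0.715)
  expect_equal(phosphate_ionic_strength(10, pH = 7.6),
               0.5 * 10 * (4 * f2 + (1 - f2)) + 0.5 * 10 * (1 + f2))
  expect_equal(round(phosphate_ionic_strength(10, pH = 7.6), 1), 24.3)
  # linear in concentration at fixed pH
  expect_equal(phosphate_ionic_strength(c(1, 2, 4), pH = 7.6),
               phosphate_ionic_strength(1, pH = 7.6) * c(1, 2, 4))
})

test_that("ionic-strength correction divides out the reference quench", {
  # flat reference: identity up to the constant
  ism <- ionic_strength_model(seq(10, 200, by = 10), rep(80, 20),
                              normalization_I = 10)
  F <- c(5, 7, 9)
  expect_equal(ionic_strength_correct(F, ism, c(20, 90, 150)), F)

  # known quench shape is inverted exactly at the reference nodes
  I <- seq(10, 300, by = 5)
  q <- 1 / (1 + (pmax(I - 100, 0) / 60)^2)
  ism <- ionic_strength_model(I, 100 * q, normalization_I = 10)
  truth <- rep(42, 6)
  I_pts <- c(10, 50, 100, 150, 200, 300)
  obs <- truth * (q[match(I_pts, I)] / q[1])
  expect_equal(ionic_strength_correct(obs, ism, I_pts), truth,
               tolerance = 1e-9)

  expect_error(ionic_strength_correct(1, ism, 400), "extrapolate")
  expect_error(ionic_strength_model(c(1, 1, 2), c(1, 1, 1)), "increasing")
})

test_that("correction order matters on drifting, quenched data", {
  # extend the grid into the strong-quench region so the order of the two
  # corrections is material
  sim <- simulate_fluorescence_series(
    l_total = 10^seq(log10(0.007), log10(2e5), length.out = 25),
    noise_sd = 0.002, seed = 31)
  good <- correct_fluorescence_series(sim)

  # wrong order: quench divided out before the drift is removed
  ism <- ionic_strength_model(sim$nacl_reference$I, sim$nacl_reference$F,
                              normalization_I = sim$I_of_point[1])
  i <- 1
  dr <- fit_drift_slopes(sim$time_series[[i]])
  wrong <- drift_correct(
    ionic_strength_correct(sim$curves[[i]]$signal, ism, sim$I_of_point),
    dr, drift_sign = -1)
  truth <- sim$truth$clean[[i]]
  err_good <- sqrt(mean((good[[i]]$signal - truth)^2))
  err_wrong <- sqrt(mean((wrong - truth)^2))
  expect_gt(err_wrong, 2 * err_good)
})

test_that("Savitzky-Golay smoothing is exact for quartics and denoises", {
  w <- seq(230, 300, by = 0.25)
  x <- (w - 265) / 35
  quart <- spectrum_1d(w, 3 - 2 * x + x^2 - 0.5 * x^3 + 2 * x^4)
  sm <- sg_smooth(quart)
  expect_equal(sm$value, quart$value, tolerance = 1e-9)

  flat <- spectrum_1d(w, rep(2.5, length(w)))
  expect_equal(sg_smooth(flat)$value, flat$value, tolerance = 1e-12)

  expect_error(sg_smooth(spectrum_1d(w[1:8], rep(1, 8))), "shorter")
  expect_error(sg_smooth(quart, window = 10), "odd")

  # white-noise variance reduced by the central-weight gain, from a
  # first-principles projection-matrix oracle
  gain <- sum(oracle_sg_central_weights(4, 11)^2)
  set.seed(5)
  ratios <- replicate(100, {
    noise <- rnorm(length(w))
    sm <- sg_smooth(spectrum_1d(w, noise))
    interior <- 6:(length(w) - 5)
    var(sm$value[interior]) / var(noise)
  })
  expect_equal(mean(ratios), gain, tolerance = 0.1)
})

test_that("differential spectra locate the largest changes", {
  w <- seq(230, 300, by = 0.25)
  g <- function(mu, s, a) a * exp(-0.5 * ((w - mu) / s)^2)
  apo <- spectrum_1d(w, g(260, 8, -5))

  expect_error(differential_and_select(apo, apo, k = 2), "identically zero")

  one <- spectrum_1d(w, apo$value + g(275, 3, 2))
  sel <- differential_and_select(one, apo, k = 1)
  expect_equal(sel$wavelengths, 275, tolerance = 0.3)

  two <- spectrum_1d(w, apo$value + g(245, 3, 1.5) + g(280, 3, -3))
  sel2 <- differential_and_select(two, apo, k = 2)
  expect_equal(sel2$wavelengths, c(280, 245), tolerance = 0.3)
})

test_that("two-range curves stitch by affine alignment", {
  l_low <- 10^seq(-2, 2, length.out = 12)
  l_high <- c(tail(l_low, 3), 10^seq(2.4, 5, length.out = 9))  # 3-point overlap
  f <- function(l) 10 + 5 * l / (l + 50)
  shared <- tail(l_low, 3)

  low <- titration_curve(l_low, f(l_low), "mst", 0.1)
  high <- titration_curve(l_high, 2 * f(l_high) + 7, "mst", 0.1)
  merged <- stitch_ranges(low, high)
  st <- attr(merged, "stitch")
  expect_equal(st$scale, 0.5, tolerance = 1e-9)
  expect_equal(st$offset, -3.5, tolerance = 1e-8)
  expect_equal(merged$signal, f(merged$l_total), tolerance = 1e-8)
  expect_equal(length(merged$l_total),
               length(l_low) + length(l_high) - length(shared))

  # identical curves: identity alignment
  same <- stitch_ranges(low, low)
  expect_equal(attr(same, "stitch")$scale, 1, tolerance = 1e-9)
  expect_equal(attr(same, "stitch")$offset, 0, tolerance = 1e-9)

  expect_error(stitch_ranges(low, titration_curve(l_high * 1.7, f(l_high),
                                                  "mst", 0.1)),
               "overlapping")
})
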