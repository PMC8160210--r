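test_that("generators are bit-reproducible given the seed", {
  a <- simulate_fluorescence_series(seed = 99)
  b <- simulate_fluorescence_series(seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$curves[[1]]$signal,
                         simulate_fluorescence_series(seed = 100)$curves[[1]]$signal))

  m1 <- simulate_mst_series(seed = 7)
  m2 <- simulate_mst_series(seed = 7)
  expect_identical(m1, m2)

  expect_error(simulate_fluorescence_series(), "seed")
})

test_that("zero-noise fluorescence degradations invert exactly", {
  sim <- simulate_fluorescence_series(noise_sd = 0, drift = FALSE,
                                      quench = FALSE, seed = 1)
  for (i in seq_along(sim$curves))
    expect_equal(sim$curves[[i]]$signal, sim$truth$clean[[i]],
                 tolerance = 1e-12)

  # drift-only: correction with the true slopes is an exact round trip
  simd <- simulate_fluorescence_series(noise_sd = 0, drift = TRUE,
                                       quench = FALSE, seed = 2)
  for (i in seq_along(simd$curves)) {
    rec <- drift_correct(simd$curves[[i]]$signal,
                         simd$truth$drift_slopes[[i]], drift_sign = -1)
    expect_equal(rec, simd$truth$clean[[i]], tolerance = 1e-10)
  }

  # full pipeline at zero noise recovers the clean curves to interpolation
  # accuracy of the reference quench
  simq <- simulate_fluorescence_series(noise_sd = 0, seed = 3)
  cc <- correct_fluorescence_series(simq)
  for (i in seq_along(cc))
    expect_lt(max(abs(cc[[i]]$signal - simq$truth$clean[[i]])) /
                mean(abs(simq$truth$clean[[i]])), 1e-3)
})

test_that("end-to-end fluorescence recovery lands within 3 sigma", {
  sim <- simulate_fluorescence_series(seed = 314)
  curves <- correct_fluorescence_series(sim)
  fit <- global_fit(curves, 3, n_starts = 6, seed = 314)
  lk <- fit$params[paste0("log10_kd", 1:3)]
  expect_true(all(abs(lk - log10(c(4.4, 84, 1770))) <=
                    3 * fit$sd[paste0("log10_kd", 1:3)]))
})

test_that("MST generator supports powers, stitching and replicates", {
  # zero noise, single range: global MST fit recovers the truth
  sim <- simulate_mst_series(noise_sd = 0, seed = 4)
  fit <- global_fit(sim$curves, 3, n_starts = 6, seed = 4)
  expect_equal(10^unname(fit$params[paste0("log10_kd", 1:3)]),
               c(4.4, 84, 1770), tolerance = 1e-5)

  # two ranges: stitching restores one consistent curve per power
  sim2 <- simulate_mst_series(noise_sd = 0, two_ranges = TRUE, seed = 5)
  stitched <- lapply(sim2$curves, function(pair)
    stitch_ranges(pair$low, pair$high))
  st <- attr(stitched[[1]], "stitch")
  expect_equal(st$scale, 1 / 1.06, tolerance = 1e-6)
  fit2 <- global_fit(stitched, 3, n_starts = 6, seed = 5)
  expect_equal(10^unname(fit2$params[paste0("log10_kd", 1:3)]),
               c(4.4, 84, 1770), tolerance = 1e-4)

  # seven replicates shrink the noise by about sqrt(7)
  sd1 <- sapply(1:40, function(i) {
    s <- simulate_mst_series(n_powers = 1, seed = 600 + i)
    sd(s$curves[[1]]$signal - (simulate_mst_series(n_powers = 1, noise_sd = 0,
                                                   seed = 1)$curves[[1]]$signal))
  })
  sd7 <- sapply(1:40, function(i) {
    s <- simulate_mst_series(n_powers = 1, n_replicates = 7, seed = 700 + i)
    sd(s$curves[[1]]$signal - (simulate_mst_series(n_powers = 1, noise_sd = 0,
                                                   seed = 1)$curves[[1]]$signal))
  })
  expect_equal(mean(sd1) / mean(sd7), sqrt(7), tolerance = 0.2)
})

test_that("CD generator feeds the spectral pipeline", {
  sim <- simulate_cd_titration(noise_sd = 0, seed = 6)
  # zero noise: selected wavelengths sit at extrema of the difference
  # templates actually populated at the last titration point
  sel <- cd_cross_sections(sim, k = 3)
  expect_length(sel, 3)
  picked <- vapply(sel, function(cv) cv$metadata$cd_wavelength_nm, numeric(1))
  st <- solve_speciation(sim$truth$scheme, sim$p_total, max(sim$l_total))
  total_diff <- drop(st$species[2:4] %*% sim$truth$templates)
  peaks <- sim$spectra[[1]]$wavelength_nm[order(abs(total_diff),
                                                decreasing = TRUE)][1]
  expect_lt(min(abs(picked - peaks)), 1)

  # 5 cross-section curves at mild noise recover the loose constants within
  # 3 sigma (the tightest is depletion-limited; see the profile tests)
  simn <- simulate_cd_titration(seed = 8)
  fit <- global_fit(cd_cross_sections(simn, k = 5), 3, n_starts = 6, seed = 8)
  lk <- fit$params[paste0("log10_kd", 2:3)]
  expect_true(all(abs(lk - log10(c(100, 1030))) <=
                    3 * fit$sd[paste0("log10_kd", 2:3)]))
})

test_that("kinetic generator honours its design", {
  d <- simulate_kinetics(list(vmax1 = 10, km1 = 50), "mm", noise_sd = 0,
                         seed = 8)
  expect_equal(d$v0, mm_rate(list(vmax1 = 10, km1 = 50), d$c0),
               tolerance = 1e-12)
  dc <- simulate_kinetics(list(vmax1 = 10, km1 = 50, ki = 20), "competitive",
                          seed = 9)
  expect_setequal(unique(dc$ci), c(0, 50, 150))
})

test_that("recovery suite summarises bias, coverage and discrimination", {
  mk_sim <- function(noise) function(seed) {
    s <- binding_scheme(25)
    lt <- 10^seq(-1, 4, length.out = 16)
    set.seed(seed)
    y <- optical_signal(s, response_set(c(100, 60)), 0.5, lt) +
      rnorm(16, 0, noise)
    list(curves = list(titration_curve(lt, y, "fluorescence", 0.5)),
         truth_log10_kd = log10(25))
  }
  out <- recovery_suite(list(lo = list(simulate = mk_sim(0.4), n_sites = 1),
                             hi = list(simulate = mk_sim(1.6), n_sites = 1)),
                        n_seeds = 12, seed = 5, n_starts = 2)
  expect_equal(nrow(out), 2)
  # noiseless-ish scenario: small bias; quadrupling noise raises the RMSE
  expect_gt(out$mean_rmse[2], out$mean_rmse[1])
  expect_true(all(out$coverage >= 0.8))
})
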