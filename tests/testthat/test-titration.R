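test_that("fluorescence ratio reads interpolated band intensities", {
  wl <- seq(540, 650, by = 1)
  flat <- emission_spectrum(wl, rep(2, length(wl)))
  expect_equal(fluorescence_ratio(flat), 1)
  free <- emission_spectrum(wl, exp(-(wl - 564)^2 / 200))
  expect_gt(fluorescence_ratio(free), 1)
  bound <- emission_spectrum(wl, exp(-(wl - 575)^2 / 200))
  expect_lt(fluorescence_ratio(bound), 1)
  narrow <- emission_spectrum(seq(560, 570, 1), rep(1, 11))
  expect_error(fluorescence_ratio(narrow), "outside")
})

test_that("the spectral ratio tracks the bound fraction monotonically", {
  specs <- gen_spectra_series(ratios = seq(5, 50, by = 5), n_sat = 25,
                              quench_depth = 0.4, seed = 221)
  ratios <- vapply(specs, fluorescence_ratio, numeric(1))
  fb <- pmin(1, 25 / seq(5, 50, by = 5))
  # bound fraction decreases along the grid, so F564/F575 increases
  expect_true(all(diff(fb) <= 0))
  expect_true(all(diff(ratios[!duplicated(fb)]) > 0))
  # 50/50 mixture of equal-width bands is symmetric: ratio exactly 1
  half <- gen_spectra_series(ratios = 2 * 27, n_sat = 27, seed = 222)
  expect_equal(fluorescence_ratio(half[[1]]), 1, tolerance = 1e-9)
})

test_that("peak wavelength finds the free and bound band limits", {
  free <- gen_spectra_series(ratios = 1000, n_sat = 1e-6, seed = 231)[[1]]
  expect_equal(peak_wavelength(free), 564, tolerance = 1)
  bound <- gen_spectra_series(ratios = 1, n_sat = 50, seed = 232)[[1]]
  expect_equal(peak_wavelength(bound), 575, tolerance = 1)
  spike <- emission_spectrum(c(560, 570, 580), c(0, 5, 0))
  expect_equal(peak_wavelength(spike), 570)
  plateau <- emission_spectrum(560:565, c(0, 1, 1, 1, 1, 0))
  pw <- peak_wavelength(plateau)
  expect_equal(as.numeric(pw), 562.5)
  expect_true(attr(pw, "plateau"))
  expect_error(peak_wavelength(emission_spectrum(1:6, rep(1, 6))), "flat")
})

test_that("noiseless two-segment curves are recovered exactly for any breakpoint", {
  for (n_true in c(5L, 17L, 27L, 38L, 50L)) {
    x <- 1:55
    y <- ifelse(x <= n_true, -2 * (x - n_true), 0) - 30
    est <- job_stoichiometry(titration_series(x, y, kind = "zeta"))
    expect_equal(est$n, n_true, tolerance = 1e-9)
    expect_false(est$degenerate)
  }
  # non-integer breakpoints recovered via midpoint candidates
  y <- ifelse(1:50 <= 27.5, -1.3 * (1:50 - 27.5), 0) + 10
  est <- job_stoichiometry(titration_series(1:50, y, kind = "zeta"))
  expect_equal(est$n, 27.5, tolerance = 1e-9)
})

test_that("the estimate is invariant under affine rescaling of the response", {
  s <- gen_titration(23, noise_sd = 1.2, seed = 241)
  n1 <- job_stoichiometry(s)$n
  s2 <- titration_series(s$x, 0.01 * s$y + 7, kind = "fluorescence")
  expect_equal(job_stoichiometry(s2)$n, n1, tolerance = 1e-9)
})

test_that("estimator bias shrinks as noise shrinks", {
  truth <- 26
  err <- vapply(c(2.0, 0.5, 0.05), function(sd_noise) {
    e <- vapply(1:40, function(s)
      job_stoichiometry(gen_titration(truth, noise_sd = sd_noise,
                                      seed = 3000 + s))$n - truth,
      numeric(1))
    median(abs(e))
  }, numeric(1))
  expect_true(all(diff(err) <= 0))
  expect_lt(err[3], 0.1)
})

test_that("strictly linear data is flagged degenerate, not estimated", {
  s <- titration_series(1:20, 5 - 0.7 * (1:20), kind = "zeta")
  est <- job_stoichiometry(s)
  expect_true(est$degenerate)
  expect_true(is.na(est$n))
  # label rounding is half-up
  e2 <- job_stoichiometry(gen_titration(26.5, noise_sd = 0, seed = 1))
  expect_equal(e2$label, "1:27")
})

test_that("zeta saturation recovers the plateau level", {
  s <- gen_titration(21, initial = 40, plateau = -30, noise_sd = 1,
                     seed = 251)
  expect_equal(zeta_saturation(s), -30, tolerance = 1)
  flat <- titration_series(1:10, rep(40, 10), kind = "zeta")
  expect_equal(zeta_saturation(flat), 40)
  falling <- titration_series(1:10, 40 - 3 * (1:10), kind = "zeta")
  expect_error(zeta_saturation(falling), "plateau")
})

test_that("fluorescence- and zeta-based estimates agree on a shared truth", {
  truth <- 30
  nz <- vapply(1:25, function(s)
    job_stoichiometry(gen_titration(truth, noise_sd = 1.4,
                                    seed = 4000 + s))$n, numeric(1))
  nf <- vapply(1:25, function(s)
    job_stoichiometry(gen_titration(truth, initial = 4.4, plateau = 0.8,
                                    noise_sd = 0.072,
                                    kind = "fluorescence",
                                    seed = 5000 + s))$n, numeric(1))
  expect_lt(abs(median(nz) - median(nf)), 1)
  expect_lt(abs(median(nz) - truth), 1)
})

test_that("singlet-oxygen slopes are reported as percent of control", {
  t <- 0:5
  ctrl <- 10 + 2 * t
  expect_equal(singlet_oxygen_rate(t, ctrl, t, ctrl), 100)
  expect_equal(singlet_oxygen_rate(t, 1 + 6 * t, t, ctrl), 300)
  expect_equal(singlet_oxygen_rate(t, rep(3, 6), t, ctrl), 0)
  expect_error(singlet_oxygen_rate(t, ctrl, t, rep(1, 6)), "control slope")
  expect_error(singlet_oxygen_rate(t, ctrl, t + 100, ctrl), "overlap")
})

test_that("titration CSVs round-trip through the reader", {
  s <- gen_titration(24, seed = 261)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(ratio = s$x, response = s$y), path,
            row.names = FALSE)
  back <- read_titration_csv(path, kind = "zeta")
  expect_equal(back$x, s$x)
  expect_equal(back$y, s$y)
  expect_equal(job_stoichiometry(back)$n, job_stoichiometry(s)$n)
})
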