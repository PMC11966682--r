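test_that("Nernst fraction hits its closed-form anchors and is strictly decreasing", {
  m <- titration_model(E_m = -450, n_e = 1, T = 298.15)
  expect_equal(nernst_fraction(-450, m), 0.5, tolerance = 1e-12)
  expect_equal(nernst_fraction(-509, m), 0.909, tolerance = 1e-3)
  expect_equal(nernst_fraction(-1e6, m), 1, tolerance = 1e-12)
  expect_equal(nernst_fraction(1e6, m), 0, tolerance = 1e-12)
  E <- seq(-600, -300, by = 10)
  expect_true(all(diff(nernst_fraction(E, m)) < 0))
  # two-electron couple steepens the transition
  m2 <- titration_model(-450, n_e = 2)
  expect_gt(abs(nernst_fraction(-460, m2) - 0.5),
            abs(nernst_fraction(-460, m) - 0.5))
  expect_error(titration_model(-450, n_e = 0), "positive integer")
})

test_that("pH fraction follows the Hill sigmoid with configurable plateaus", {
  m <- ph_model(pKa = 6.8, n_H = 1, f_low = 1, f_high = 0)
  expect_equal(ph_fraction(6.8, m), 0.5, tolerance = 1e-12)
  expect_equal(ph_fraction(6.5, m), 0.666, tolerance = 1e-3)
  expect_lt(ph_fraction(9, m), 0.01)
  pH <- seq(5, 10, by = 0.25)
  expect_true(all(diff(ph_fraction(pH, m)) < 0))
  # direction set by the plateaus
  up <- ph_model(7, f_low = 0.1, f_high = 0.9)
  expect_true(all(diff(ph_fraction(pH, up)) > 0))
  # Hill limit: large n_H approaches a step at pKa
  steep <- ph_model(6.8, n_H = 50)
  expect_gt(ph_fraction(6.7, steep), 0.99)
  expect_lt(ph_fraction(6.9, steep), 0.01)
})

test_that("two-species fractions conserve to one at every condition", {
  m <- titration_model(-420)
  E <- seq(-550, -300, length.out = 11)
  fR <- nernst_fraction(E, m)
  expect_equal(fR + (1 - fR), rep(1, 11), tolerance = 1e-12)
  p <- ph_model(6.8)
  pH <- seq(5, 10, length.out = 11)
  expect_equal(ph_fraction(pH, p) + (1 - ph_fraction(pH, p)), rep(1, 11),
               tolerance = 1e-12)
})

test_that("midpoint potential is recovered within 5 mV on noisy synthetic titrations", {
  truth <- titration_model(E_m = -420)
  E <- seq(-540, -300, length.out = 7)
  est <- numeric(100)
  for (k in seq_len(100)) {
    set.seed(5000 + k)
    w <- pmin(pmax(nernst_fraction(E, truth) + rnorm(7, 0, 0.03), 0), 1)
    est[k] <- fit_midpoint(condition_series(E, w))$E_m
  }
  expect_lt(abs(mean(est) + 420), 5)
  # noiseless series recovers the midpoint to solver tolerance
  exact <- fit_midpoint(condition_series(E, nernst_fraction(E, truth)))
  expect_lt(abs(exact$E_m + 420), 1e-6)
  expect_true(exact$identifiable)
})

test_that("plateau-only titration series are flagged non-identifiable", {
  E <- seq(-700, -650, length.out = 5)
  w <- nernst_fraction(E, titration_model(-420))  # all ~1
  expect_warning(f <- fit_midpoint(condition_series(E, w)), "plateau")
  expect_false(f$identifiable)
  expect_true(is.na(f$E_m))
})

test_that("pKa is recovered within 0.1 on noisy synthetic pH series", {
  truth <- ph_model(pKa = 7.0)
  pH <- seq(5.5, 9, length.out = 6)
  est <- numeric(100)
  for (k in seq_len(100)) {
    set.seed(7000 + k)
    w <- pmin(pmax(ph_fraction(pH, truth) + rnorm(6, 0, 0.03), 0), 1)
    est[k] <- fit_pka(condition_series(pH, w, kind = "ph"))$pKa
  }
  expect_lt(abs(mean(est) - 7.0), 0.1)
  exact <- fit_pka(condition_series(pH, ph_fraction(pH, truth),
                                    kind = "ph"))
  expect_lt(abs(exact$pKa - 7.0), 1e-5)
})

test_that("under-determined pH series are flagged", {
  expect_warning(
    f <- fit_pka(condition_series(c(6, 9), c(0.8, 0.1), kind = "ph")),
    "too few")
  expect_false(f$identifiable)
  expect_identical(f$flags, "under_determined")
})

test_that("condition series validate their inputs", {
  expect_error(condition_series(c(1, 2), c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(condition_series(c(1, 1), c(0.5, 0.6)), "distinct")
  expect_error(condition_series(c(1, 2), c(0.5, 0.6), sigma = c(0, 1)),
               "> 0")
})

test_that("planted midpoint survives the full spectral pipeline at SNR 20", {
  A <- fx_axial(); R <- fx_rhombic()
  truth <- titration_model(E_m = -420)
  E <- seq(-540, -300, length.out = 7)
  ds <- generate_condition_series(list(A, R), E, truth, fx_qband(),
                                  noise = noise_model(snr = 20, seed = 99),
                                  n_orient = 576)
  wR <- vapply(ds$spectra, function(s)
    unname(fit_weights(s[[1]], list(A, R),
                       n_orient = 576)$weights_normalized["4Fe-R"]),
    numeric(1))
  fm <- fit_midpoint(condition_series(E, wR))
  expect_lt(abs(fm$E_m + 420), 10)
})
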