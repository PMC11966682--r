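test_that("simulate_mixture is an exact linear combination of species spectra", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband()
  sA <- powder_spectrum(A, q)
  one <- simulate_mixture(list(A), 1, instrument_config(
    q$mw_frequency, q$field_start, q$field_stop, q$n_points))
  expect_equal(one$intensity, sA$intensity, tolerance = 1e-12)
  half <- simulate_mixture(list(A, R), c(0.5, 0.5), q)
  iA <- simulate_mixture(list(A), 1, q)
  iR <- simulate_mixture(list(R), 1, q)
  expect_equal(half$intensity, 0.5 * (iA$intensity + iR$intensity),
               tolerance = 1e-10)
  zero <- simulate_mixture(list(A, R), c(0, 0), q)
  expect_true(all(zero$intensity == 0))
  expect_error(simulate_mixture(list(A, R), 1, q), "one weight per")
  expect_error(simulate_mixture(list(A), -1, q), ">= 0")
})

test_that("noiseless two-species mixtures are decomposed to the planted weights", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband()
  tgt <- simulate_mixture(list(A, R), c(1, 2) / 3, q)
  f <- fit_weights(tgt, list(A, R))
  expect_equal(unname(f$weights_normalized), c(1, 2) / 3, tolerance = 0.01)
  expect_lt(f$residual_norm, 1e-8)
  # pure-A target with both species offered: rhombic weight vanishes
  pure <- simulate_mixture(list(A), 1, q)
  fp <- fit_weights(pure, list(A, R))
  expect_lt(fp$weights_normalized["4Fe-R"], 0.01)
})

test_that("fitted weights are always non-negative and match the lattice-search oracle", {
  A <- fx_axial(); R <- fx_rhombic()
  third <- species_preset("qband_fid", name = "third")
  q <- fx_qband()
  X <- cbind(simulate_mixture(list(A), 1, q)$intensity,
             simulate_mixture(list(R), 1, q)$intensity,
             simulate_mixture(list(third), 1, q)$intensity)
  set.seed(42)
  for (truth in list(c(0.35, 0.65, 0), c(0.2, 0.45, 0.3), c(0, 0, 0.9))) {
    y <- as.numeric(X %*% truth) +
      rnorm(nrow(X), sd = 0.002 * max(abs(X %*% truth)))
    fld <- simulate_mixture(list(A), 1, q)$field
    tgt <- epr_spectrum(fld, y, q)
    f <- fit_weights(tgt, list(A, R, third), baseline_order = NULL)
    expect_true(all(f$weights >= 0))
    oracle <- lattice_search_weights(y, X, by = 0.05)
    expect_true(all(abs(unname(f$weights) - oracle) <= 0.05 + 1e-9))
  }
})

test_that("weight recovery at SNR 20 is unbiased within 0.05 over repeated noise draws", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband()
  w <- matrix(NA_real_, 100, 2)
  for (k in seq_len(100)) {
    tgt <- generate_spectrum(list(A, R), c(1, 2) / 3, q,
                             noise = noise_model(snr = 20, seed = 1000 + k),
                             n_orient = 576)
    w[k, ] <- fit_weights(tgt, list(A, R), n_orient = 576)$weights_normalized
  }
  expect_lt(abs(mean(w[, 1]) - 1 / 3), 0.05)
  expect_lt(abs(mean(w[, 2]) - 2 / 3), 0.05)
  # per-seed scatter stays physical
  expect_true(all(w >= 0 & w <= 1))
})

test_that("masking a region without species intensity leaves weights unchanged", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband(n_points = 1024)
  tgt <- simulate_mixture(list(A, R), c(0.4, 0.6), q)
  f0 <- fit_weights(tgt, list(A, R))
  # 1150-1160 mT sits below every resonance of both species
  fm <- fit_weights(tgt, list(A, R), mask = list(c(1150, 1160)))
  expect_lt(max(abs(f0$weights - fm$weights)), 1e-6)
  expect_error(fit_weights(tgt, list(A, R), mask = list(c(1000, 2000))),
               "mask excludes")
})

test_that("scaling the target scales raw weights and leaves normalized weights fixed", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband()
  tgt <- simulate_mixture(list(A, R), c(0.3, 0.7), q)
  f1 <- fit_weights(tgt, list(A, R))
  tgt2 <- tgt; tgt2$intensity <- 3.7 * tgt$intensity
  f2 <- fit_weights(tgt2, list(A, R))
  expect_equal(unname(f2$weights), 3.7 * unname(f1$weights),
               tolerance = 1e-8)
  expect_equal(f2$weights_normalized, f1$weights_normalized,
               tolerance = 1e-9)
})

test_that("collinear species designs are flagged, not silently resolved", {
  A <- fx_axial()
  A2 <- fx_axial(name = "copy")
  q <- fx_qband()
  tgt <- simulate_mixture(list(A), 1, q)
  expect_warning(f <- fit_weights(tgt, list(A, A2)), "collinear")
  expect_true(f$collinear)
  expect_true(all(f$weights >= 0))
})

test_that("model selection residual is monotone in K and drops sharply at the true count", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband()
  pool <- list(A, R, species_preset("qband_fid", name = "extra"))
  tgt <- generate_spectrum(list(A, R), c(0.5, 0.5), q,
                           noise = noise_model(snr = 50, seed = 3))
  tab <- model_selection(tgt, pool, k_max = 3)
  expect_equal(tab$k, 1:3)
  expect_true(all(diff(tab$residual_norm) <= 1e-9))
  # adding the true second species explains far more than adding a third
  drop12 <- tab$residual_norm[1] - tab$residual_norm[2]
  drop23 <- tab$residual_norm[2] - tab$residual_norm[3]
  expect_gt(drop12, 10 * drop23)
  expect_error(model_selection(tgt, list()), "at least one")
})
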