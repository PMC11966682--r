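# Nonlinear refinement tests run at reduced simulation sizes
# (512 field points, ~576 orientation knots, 2 starts) to stay fast;
# the tolerances checked are the ones the full pipeline must meet.

test_that("refinement recovers g-values of a noiseless single species from a perturbed start", {
  truth <- species_model("S", g_tensor(2.045, 1.926, 1.896),
                         g_strain = 0.004, linewidth = 1.2)
  x <- fx_xband()
  tgt <- simulate_mixture(truth, 1, x, n_orient = 576)
  init <- truth
  init$g <- g_tensor(2.045 + 0.01, 1.926 - 0.01, 1.896 + 0.01, sort = FALSE)
  f <- refine_species(tgt, init, multistart = 2, n_orient = 576,
                      fit_linewidth = FALSE)
  expect_true(f$converged)
  expect_false(f$at_boundary)
  expect_true(all(abs(as.numeric(f$species[[1]]$g) -
                        c(2.045, 1.926, 1.896)) < 1e-3))
})

test_that("starting at the truth converges immediately with near-zero residual", {
  truth <- fx_rhombic()
  q <- fx_qband()
  tgt <- simulate_mixture(truth, 1, q, n_orient = 576)
  f <- refine_species(tgt, truth, multistart = 1, n_orient = 576)
  expect_true(f$converged)
  expect_lt(f$residual_norm / max(abs(tgt$intensity)), 1e-6)
})

test_that("bounds excluding the truth give a best-on-boundary solution with a flag", {
  truth <- species_model("S", g_tensor(2.045, 1.926, 1.896),
                         g_strain = 0.004, linewidth = 1.2)
  x <- fx_xband()
  tgt <- simulate_mixture(truth, 1, x, n_orient = 576)
  init <- truth
  init$g <- g_tensor(2.060, 1.940, 1.910, sort = FALSE)
  # boxes of half-width 0.005 around the (wrong) init exclude the truth
  f <- refine_species(tgt, init, g_window = 0.005, multistart = 1,
                      n_orient = 576, fit_linewidth = FALSE)
  expect_true(f$at_boundary)
  # the optimum is pushed toward the truth, i.e. onto the lower box edges
  expect_true(any(abs(as.numeric(f$species[[1]]$g) -
                        c(2.055, 1.935, 1.905)) < 1e-6))
})

test_that("initial parameters outside the bounds are rejected", {
  truth <- fx_axial()
  q <- fx_qband()
  tgt <- simulate_mixture(truth, 1, q, n_orient = 576)
  expect_error(refine_species(tgt, truth, lower = rep(0, 4),
                              upper = rep(1, 4)),
               "inside the bounds")
})

test_that("global fit recovers shared g-values from matched X- and Q-band spectra", {
  truth <- species_model("S", g_tensor(2.040, 1.910, 1.910),
                         g_strain = 0.004, linewidth = 1.2)
  tx <- simulate_mixture(truth, 1, fx_xband(), n_orient = 576)
  tq <- simulate_mixture(truth, 1, fx_qband(), n_orient = 576)
  init <- truth
  init$g <- g_tensor(2.047, 1.904, 1.915, sort = FALSE)
  gf <- global_fit(list(tx, tq), init, multistart = 2, n_orient = 576,
                   fit_linewidth = FALSE)
  expect_true(gf$converged)
  expect_true(all(abs(as.numeric(gf$species[[1]]$g) -
                        c(2.040, 1.910, 1.910)) < 1e-3))
  # per-spectrum weights are reported for every member of the dataset
  expect_length(gf$fits, 2)
})

test_that("a single-spectrum dataset reduces to the plain weight fit", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband()
  tgt <- simulate_mixture(list(A, R), c(0.3, 0.7), q, n_orient = 576)
  gf <- global_fit(list(tgt), list(A, R), refine = FALSE, n_orient = 576)
  f <- fit_weights(tgt, list(A, R), n_orient = 576)
  expect_equal(gf$fits[[1]]$weights_normalized, f$weights_normalized,
               tolerance = 1e-12)
  expect_equal(gf$residual_norm, f$residual_norm, tolerance = 1e-12)
})

test_that("two conditions with different compositions are both recovered in a joint fit", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband()
  t1 <- generate_spectrum(list(A, R), c(0.5, 0.5), q,
                          noise = noise_model(snr = 50, seed = 11),
                          n_orient = 576)
  t2 <- generate_spectrum(list(A, R), c(0.9, 0.1), q,
                          noise = noise_model(snr = 50, seed = 12),
                          n_orient = 576)
  gf <- global_fit(list(t1, t2), list(A, R), refine = FALSE, n_orient = 576)
  w1 <- gf$fits[[1]]$weights_normalized
  w2 <- gf$fits[[2]]$weights_normalized
  expect_lt(max(abs(w1 - c(0.5, 0.5))), 0.03)
  expect_lt(max(abs(w2 - c(0.9, 0.1))), 0.03)
})
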