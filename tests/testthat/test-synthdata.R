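test_that("preset library ships the four literature g-sets verbatim", {
  lib <- preset_library()
  row <- function(p) lib[lib$preset == p, ]
  expect_equal(unlist(row("xband_cw")[c("g1", "g2", "g3")], use.names = FALSE),
               c(2.040, 1.910, 1.910))
  expect_equal(unlist(row("qband_fid")[c("g1", "g2", "g3")], use.names = FALSE),
               c(2.045, 1.926, 1.896))
  expect_equal(unlist(row("qband_ese_2010s")[c("g1", "g2", "g3")],
                      use.names = FALSE),
               c(2.050, 1.915, 1.852))
  expect_equal(unlist(row("qband_ese_2014")[c("g1", "g2", "g3")],
                      use.names = FALSE),
               c(2.054, 1.921, 1.848))
  expect_identical(row("xband_cw")$symmetry, "axial")
  expect_identical(row("qband_ese_2014")$symmetry, "rhombic")
  # templates are editable species models
  sp <- species_preset("rhombic_template", linewidth = 2)
  expect_s3_class(sp, "species_model")
  expect_equal(sp$linewidth, 2)
  expect_error(species_preset("nope"), "unknown preset")
})

test_that("generation is bit-reproducible from the seed and exact when noise is off", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband()
  s1 <- generate_spectrum(list(A, R), c(1, 2), q,
                          noise = noise_model(snr = 15, seed = 77),
                          n_orient = 576)
  s2 <- generate_spectrum(list(A, R), c(1, 2), q,
                          noise = noise_model(snr = 15, seed = 77),
                          n_orient = 576)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- generate_spectrum(list(A, R), c(1, 2), q,
                          noise = noise_model(snr = 15, seed = 78),
                          n_orient = 576)
  expect_false(identical(s1$intensity, s3$intensity))
  # infinite SNR equals the clean mixture exactly
  clean <- generate_spectrum(list(A, R), c(1, 2), q, n_orient = 576)
  mix <- simulate_mixture(list(A, R), c(1, 2), q, n_orient = 576)
  expect_identical(clean$intensity, mix$intensity)
  expect_identical(clean$provenance, "synthetic")
  # the ground truth rides along
  expect_equal(s1$meta$ground_truth$weights, c(1, 2))
  # generating with noise but no seed is refused
  expect_error(noise_model(snr = 10), "seed")
})

test_that("realized noise standard deviation matches the requested SNR", {
  A <- fx_axial(); R <- fx_rhombic()
  q <- fx_qband(n_points = 2048)
  clean <- simulate_mixture(list(A, R), c(0.5, 0.5), q, n_orient = 576)
  noisy <- generate_spectrum(list(A, R), c(0.5, 0.5), q,
                             noise = noise_model(snr = 20, seed = 5),
                             n_orient = 576)
  target_sd <- diff(range(clean$intensity)) / 20
  realized <- sd(noisy$intensity - clean$intensity)
  expect_lt(abs(realized - target_sd) / target_sd, 0.05)
})

test_that("the radical artifact adds a narrow line at its isotropic g position", {
  A <- fx_axial()
  x <- instrument_config(9.7, 320, 400, 1024,
                         detection_mode = "absorption")
  plain <- generate_spectrum(list(A), 1, x, n_orient = 576)
  rad <- generate_spectrum(list(A), 1, x, n_orient = 576,
                           radical = radical_artifact(g_iso = 2.004,
                                                      linewidth = 0.8,
                                                      amplitude = 2))
  extra <- rad$intensity - plain$intensity
  B0 <- resonance_field(2.004, 9.7)
  expect_equal(B0, 345.8, tolerance = 2e-4)
  expect_lt(abs(rad$field[which.max(extra)] - B0), 0.2)
  expect_error(radical_artifact(linewidth = -1), "> 0")
})

test_that("polynomial baselines are reproducible and recorded in the truth", {
  A <- fx_axial()
  x <- fx_xband()
  s <- generate_spectrum(list(A), 1, x,
                         noise = noise_model(snr = Inf, baseline_order = 1,
                                             baseline_scale = 0.1,
                                             seed = 31),
                         n_orient = 576)
  gt <- s$meta$ground_truth
  expect_length(gt$baseline_coeffs, 2)
  clean <- simulate_mixture(list(A), 1, x, n_orient = 576)
  drift <- s$intensity - clean$intensity
  # pure linear drift, no noise
  expect_gt(max(abs(drift)), 0)
  expect_lt(max(abs(residuals(lm(drift ~ s$field)))), 1e-12)
})

test_that("potential series weights are Nernst-monotone and pH series match the plateau model", {
  A <- fx_axial(); R <- fx_rhombic()
  E <- seq(-540, -300, length.out = 7)
  ds <- generate_condition_series(list(A, R), E, titration_model(-420),
                                  fx_qband(), n_orient = 576)
  expect_true(all(diff(ds$truth$fraction) < 0))
  pH <- c(6, 6.5, 7, 8, 9)
  dp <- generate_condition_series(list(A, R), pH, ph_model(6.8),
                                  fx_qband(), n_orient = 576)
  expect_equal(dp$truth$fraction[pH == 6.5], 2 / 3, tolerance = 2e-3)
  expect_lt(dp$truth$fraction[pH == 9], 0.01)
  # tracked + untracked fractions conserve
  expect_equal(dp$truth$w_first + dp$truth$w_second, rep(1, 5),
               tolerance = 1e-12)
})

test_that("dual-frequency generation shares identical truth weights per condition", {
  A <- fx_axial(); R <- fx_rhombic()
  ds <- generate_condition_series(
    list(A, R), c(-500, -400), titration_model(-420),
    list(fx_xband(), fx_qband()),
    noise = noise_model(snr = 30, seed = 2), n_orient = 576)
  expect_length(ds$spectra, 2)
  expect_length(ds$spectra[[1]], 2)
  gt_x <- ds$spectra[[1]][[1]]$meta$ground_truth$weights
  gt_q <- ds$spectra[[1]][[2]]$meta$ground_truth$weights
  expect_identical(gt_x, gt_q)
  expect_error(generate_condition_series(list(A, R), -500,
                                         titration_model(-420), fx_qband()),
               "at least 2")
})
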