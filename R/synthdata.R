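# Synthetic spectra and condition series with known ground truth.
# Emulates the structure of multi-frequency pulsed-EPR measurements on a
# reduced [4Fe4S]1+ cluster: weighted axial + rhombic S = 1/2 powder
# patterns, white noise at a stated SNR, a low-order polynomial baseline
# and an interfering narrow isotropic radical line near g = 2.

#' Literature g-value presets and species templates
#'
#' Ships the four literature g-tensor sets reported for the reduced
#' \[4Fe4S\]1+ cluster of the apo-hydrogenase, labelled by the method they
#' were obtained with, plus editable axial (`"axial_template"`) and
#' rhombic (`"rhombic_template"`) species templates for 4Fe-A / 4Fe-R
#' style simulations.
#'
#' @return A data.frame with columns `preset`, `g1`, `g2`, `g3`,
#'   `symmetry`, `method`.
#' @seealso [species_preset()] to turn a row into a [species_model()].
#' @export
preset_library <- function() {
  df <- data.frame(
    preset = c("xband_cw", "qband_fid", "qband_ese_2010s",
               "qband_ese_2014", "axial_template", "rhombic_template"),
    g1 = c(2.040, 2.045, 2.050, 2.054, 2.040, 2.054),
    g2 = c(1.910, 1.926, 1.915, 1.921, 1.910, 1.921),
    g3 = c(1.910, 1.896, 1.852, 1.848, 1.910, 1.848),
    method = c("X-band cw EPR", "Q-band FID-detected EPR",
               "Q-band ESE-detected EPR", "Q-band ESE-detected EPR",
               "editable axial template (4Fe-A style)",
               "editable rhombic template (4Fe-R style)"),
    stringsAsFactors = FALSE)
  df$symmetry <- vapply(seq_len(nrow(df)), function(i)
    classify_symmetry(g_tensor(df$g1[i], df$g2[i], df$g3[i])), "")
  df[c("preset", "g1", "g2", "g3", "symmetry", "method")]
}

#' Build a species model from a preset
#'
#' @param preset A `preset` name from [preset_library()].
#' @param name Species label (defaults to the preset name).
#' @param g_strain,linewidth,lineshape Overridable broadening parameters;
#'   defaults (per-axis strain 0.004, residual FWHM 1.2 mT Gaussian) give
#'   realistic protein FeS-cluster linewidths at both X- and Q-band.
#' @return A [species_model()].
#' @examples
#' species_preset("xband_cw")$g  # (2.040, 1.910, 1.910)
#' @export
species_preset <- function(preset, name = preset, g_strain = 0.004,
                           linewidth = 1.2, lineshape = "gaussian") {
  lib <- preset_library()
  row <- lib[lib$preset == preset, ]
  if (nrow(row) != 1L)
    stop("unknown preset '", preset, "'; see preset_library()")
  species_model(name, g_tensor(row$g1, row$g2, row$g3),
                g_strain = g_strain, linewidth = linewidth,
                lineshape = lineshape)
}

#' Instrument presets for the two-frequency experiment
#'
#' `"xband"`: 9.7 GHz, 320-400 mT, 1.4 mT pseudo-modulation.
#' `"qband"`: 34 GHz, 1150-1350 mT, 4 mT pseudo-modulation.
#'
#' @param band `"xband"` or `"qband"`.
#' @param n_points Field points (default 1024).
#' @param detection_mode Detection mode (default pseudo-modulated).
#' @param temperature,condition Passed to [instrument_config()].
#' @return An [instrument_config()].
#' @export
instrument_preset <- function(band = c("xband", "qband"), n_points = 1024,
                              detection_mode = "pseudo_modulated",
                              temperature = 10, condition = list()) {
  band <- match.arg(band)
  if (band == "xband")
    instrument_config(9.7, 320, 400, n_points,
                      modulation_amplitude = 1.4,
                      detection_mode = detection_mode,
                      temperature = temperature, condition = condition)
  else
    instrument_config(34, 1150, 1350, n_points,
                      modulation_amplitude = 4,
                      detection_mode = detection_mode,
                      temperature = temperature, condition = condition)
}

#' Noise model for synthetic spectra
#'
#' @param snr Ratio of the peak-to-peak amplitude of the noiseless signal
#'   (in the final detection mode) to the noise standard deviation;
#'   `Inf` disables noise. Default 20, the level at which weight-recovery
#'   performance is characterised.
#' @param baseline_order Polynomial order of the drifting baseline
#'   (`-1` disables it).
#' @param baseline_scale Baseline amplitude as a fraction of the signal
#'   peak-to-peak amplitude.
#' @param seed Integer seed; mandatory for any stochastic output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(snr = 20, baseline_order = -1, baseline_scale = 0.05,
                        seed = NULL) {
  if (snr <= 0) stop("snr must be > 0")
  stochastic <- is.finite(snr) || baseline_order >= 0
  if (stochastic && is.null(seed))
    stop("a seed is mandatory for stochastic output")
  structure(list(snr = snr, baseline_order = as.integer(baseline_order),
                 baseline_scale = baseline_scale,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "noise_model")
}

#' Narrow isotropic radical artifact
#'
#' An interfering organic-radical line near g = 2 of the kind commonly
#' superimposed on reduced-cluster spectra, modelled as an isotropic
#' Gaussian absorption.
#'
#' @param g_iso Isotropic g-value (default 2.004).
#' @param linewidth FWHM in mT, > 0.
#' @param amplitude Peak absorption relative to the peak of the cluster
#'   mixture absorption.
#' @return An object of class `radical_artifact`.
#' @export
radical_artifact <- function(g_iso = 2.004, linewidth = 1, amplitude = 0.5) {
  if (linewidth <= 0) stop("linewidth must be > 0")
  structure(list(g_iso = g_iso, linewidth = linewidth,
                 amplitude = amplitude),
            class = "radical_artifact")
}

# run fn() under a local RNG state seeded with `seed`
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate one synthetic spectrum with known ground truth
#'
#' Simulates the requested mixture, optionally adds a narrow isotropic
#' radical line (in absorption, before the detection transform), applies
#' the instrument's detection mode, then adds a polynomial baseline and
#' white Gaussian noise at the stated SNR. Fully reproducible from the
#' noise model's seed.
#'
#' @param species List of [species_model()] objects.
#' @param weights Non-negative mixture weights.
#' @param instrument An [instrument_config()].
#' @param noise A [noise_model()].
#' @param radical Optional [radical_artifact()].
#' @param n_orient Orientation knots per species.
#' @return An [epr_spectrum()] with provenance `"synthetic"`; the ground
#'   truth (species, weights, noise parameters, realized noise sd) is
#'   stored in `$meta$ground_truth`.
#' @export
generate_spectrum <- function(species, weights, instrument,
                              noise = noise_model(snr = Inf),
                              radical = NULL, n_orient = 2048) {
  stopifnot(inherits(noise, "noise_model"))
  if (inherits(species, "species_model")) species <- list(species)
  clean <- simulate_mixture(species, weights, instrument,
                            n_orient = n_orient)
  if (!is.null(radical)) {
    stopifnot(inherits(radical, "radical_artifact"))
    B <- clean$field
    # rebuild: radical belongs in absorption space, before detection
    absn <- simulate_mixture(
      species, weights,
      instrument_config(instrument$mw_frequency, instrument$field_start,
                        instrument$field_stop, instrument$n_points,
                        detection_mode = "absorption",
                        temperature = instrument$temperature,
                        condition = instrument$condition),
      n_orient = n_orient)
    B0 <- resonance_field(radical$g_iso, instrument$mw_frequency)
    sig <- radical$linewidth / .fwhm_gauss
    line <- exp(-0.5 * ((B - B0) / sig)^2)
    absn$intensity <- absn$intensity +
      radical$amplitude * max(absn$intensity) * line
    absn$instrument <- instrument
    clean <- apply_detection(absn)
  }
  y <- clean$intensity
  pp <- diff(range(y))
  sd_noise <- if (is.finite(noise$snr)) pp / noise$snr else 0
  out <- clean
  gt <- list(species = species, weights = weights,
             noise = unclass(noise), radical = if (!is.null(radical))
               unclass(radical) else NULL,
             sd_noise = sd_noise)
  if (is.finite(noise$snr) || noise$baseline_order >= 0) {
    out$intensity <- with_seed(noise$seed, function() {
      yy <- y
      if (noise$baseline_order >= 0) {
        P <- baseline_design(clean$field, noise$baseline_order)
        coef <- stats::runif(ncol(P), -1, 1) * noise$baseline_scale * pp
        yy <- yy + as.numeric(P %*% coef)
        gt$baseline_coeffs <<- coef
      }
      yy + stats::rnorm(length(yy), sd = sd_noise)
    })
  }
  out$provenance <- "synthetic"
  out$meta <- list(ground_truth = gt)
  out
}

#' Generate a condition series of synthetic spectra
#'
#' Computes per-condition weights of a two-species (axial/rhombic style)
#' system from a titration or pH model and generates one spectrum per
#' condition (and per instrument, when several are given, e.g. matched X-
#' and Q-band acquisitions sharing identical truth weights).
#'
#' @param species List of exactly 2 [species_model()] objects; the second
#'   is the condition-tracked species (the reduced / protonation-linked
#'   form whose fraction follows the model).
#' @param conditions Numeric condition grid (mV vs SHE or pH), >= 2 values.
#' @param model A [titration_model()] or [ph_model()].
#' @param instruments One [instrument_config()] or a list of them.
#' @param noise A [noise_model()]; per-spectrum sub-seeds are derived
#'   deterministically from its seed.
#' @param radical Optional [radical_artifact()] added to every spectrum.
#' @param n_orient Orientation knots per species.
#' @return A list with `spectra` (list of lists: one entry per condition,
#'   one spectrum per instrument), `truth` (data.frame of condition and
#'   tracked-species fraction) and `model`.
#' @export
generate_condition_series <- function(species, conditions, model,
                                      instruments,
                                      noise = noise_model(snr = Inf),
                                      radical = NULL, n_orient = 2048) {
  if (length(species) != 2L)
    stop("condition series are generated for exactly two species")
  if (length(conditions) < 2L) stop("need at least 2 conditions")
  if (inherits(instruments, "instrument_config"))
    instruments <- list(instruments)
  frac <- if (inherits(model, "titration_model"))
    nernst_fraction(conditions, model)
  else if (inherits(model, "ph_model"))
    ph_fraction(conditions, model)
  else stop("model must be a titration_model or ph_model")

  spectra <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    w <- c(1 - frac[i], frac[i])
    spectra[[i]] <- lapply(seq_along(instruments), function(j) {
      ni <- noise
      if (!is.na(ni$seed))
        ni$seed <- (ni$seed + 7919L * i + 104729L * j) %% 2147483647L
      inst <- instruments[[j]]
      inst$condition <- c(inst$condition, list(value = conditions[i]))
      generate_spectrum(species, w, inst, noise = ni, radical = radical,
                        n_orient = n_orient)
    })
  }
  list(spectra = spectra,
       truth = data.frame(condition = conditions, fraction = frac,
                          w_first = 1 - frac, w_second = frac),
       model = model)
}
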