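#' Spectroscopic model of one paramagnetic species
#'
#' Bundles everything needed to simulate the powder pattern of a single
#' S = 1/2 species: principal g-values, per-axis Gaussian g-strain widths,
#' a residual field-domain linewidth and the residual lineshape. Only
#' S = 1/2 is supported; reduced [4Fe4S]+ clusters with higher-spin ground
#' states are out of scope.
#'
#' @param name Species label (e.g. `"4Fe-A"`).
#' @param g A [g_tensor()] or numeric length-3 vector of principal g-values.
#' @param g_strain Per-principal-axis Gaussian standard deviations of the
#'   g-value distribution (dimensionless, length 3 or scalar recycled,
#'   all >= 0). Strain broadening scales with field and hence with
#'   microwave frequency.
#' @param linewidth Residual (frequency-independent) linewidth, full width
#'   at half maximum in mT, >= 0.
#' @param lineshape Residual lineshape: `"gaussian"`, `"lorentzian"` or
#'   `"voigt"` (residual width split equally between a Gaussian and a
#'   Lorentzian part).
#' @return An object of class `species_model`.
#' @examples
#' species_model("4Fe-A", g_tensor(2.040, 1.910, 1.910),
#'               g_strain = 0.004, linewidth = 1.2)
#' @export
species_model <- function(name, g, g_strain = 0, linewidth = 1,
                          lineshape = c("gaussian", "lorentzian", "voigt")) {
  if (!inherits(g, "g_tensor")) g <- g_tensor(g)
  lineshape <- match.arg(lineshape)
  g_strain <- rep_len(as.numeric(g_strain), 3L)
  if (any(g_strain < 0)) stop("g_strain widths must be >= 0")
  if (!is.numeric(linewidth) || length(linewidth) != 1L || linewidth < 0)
    stop("linewidth must be a single value >= 0 (FWHM, mT)")
  if (linewidth == 0 && all(g_strain == 0))
    stop("species needs a non-zero linewidth or g-strain")
  structure(list(name = as.character(name), g = g, g_strain = g_strain,
                 linewidth = linewidth, lineshape = lineshape, spin = 0.5),
            class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf(
    "<species_model> %s: g = (%.4f, %.4f, %.4f) [%s], strain = (%.4g, %.4g, %.4g), lw = %.3g mT %s\n",
    x$name, x$g[1], x$g[2], x$g[3], classify_symmetry(x$g),
    x$g_strain[1], x$g_strain[2], x$g_strain[3], x$linewidth, x$lineshape))
  invisible(x)
}

#' Acquisition settings of a field-swept EPR experiment
#'
#' @param mw_frequency Microwave frequency in GHz, > 0.
#' @param field_start,field_stop Sweep limits in mT, `field_stop >
#'   field_start`.
#' @param n_points Number of field points (>= 2).
#' @param modulation_amplitude Pseudo-modulation amplitude in mT (half the
#'   sinusoidal field excursion); 0 means plain absorption detection.
#' @param detection_mode `"absorption"` (echo-detected field sweep),
#'   `"pseudo_modulated"` (absorption followed by numerical field
#'   modulation) or `"derivative"` (exact first derivative, the small
#'   modulation limit of cw detection).
#' @param temperature Sample temperature in K. A condition label only:
#'   no relaxation physics is attached to it.
#' @param condition Free-form named list of condition labels (applied
#'   potential in mV vs SHE, pH, buffer, ...).
#' @return An object of class `instrument_config`.
#' @examples
#' instrument_config(9.7, 320, 400, 1024, modulation_amplitude = 1.4,
#'                   detection_mode = "pseudo_modulated")
#' @export
instrument_config <- function(mw_frequency, field_start, field_stop,
                              n_points = 1024,
                              modulation_amplitude = 0,
                              detection_mode = c("absorption",
                                                 "pseudo_modulated",
                                                 "derivative"),
                              temperature = 10,
                              condition = list()) {
  detection_mode <- match.arg(detection_mode)
  if (mw_frequency <= 0) stop("mw_frequency must be > 0 (GHz)")
  if (field_stop <= field_start) stop("field_stop must exceed field_start")
  if (n_points < 2) stop("n_points must be >= 2")
  if (modulation_amplitude < 0) stop("modulation_amplitude must be >= 0")
  if (detection_mode == "pseudo_modulated" && modulation_amplitude == 0)
    stop("pseudo_modulated detection needs modulation_amplitude > 0")
  structure(list(mw_frequency = mw_frequency, field_start = field_start,
                 field_stop = field_stop, n_points = as.integer(n_points),
                 modulation_amplitude = modulation_amplitude,
                 detection_mode = detection_mode, temperature = temperature,
                 condition = condition),
            class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf(
    "<instrument_config> %.6g GHz, %.6g-%.6g mT (%d pts), %s%s, T = %g K\n",
    x$mw_frequency, x$field_start, x$field_stop, x$n_points,
    x$detection_mode,
    if (x$modulation_amplitude > 0)
      sprintf(" (a = %g mT)", x$modulation_amplitude) else "",
    x$temperature))
  invisible(x)
}

# field axis implied by an instrument_config (mT, uniform, ascending)
field_axis <- function(instrument) {
  seq(instrument$field_start, instrument$field_stop,
      length.out = instrument$n_points)
}

#' A field-swept EPR spectrum
#'
#' Couples a strictly increasing, uniformly spaced field axis (mT) with an
#' intensity vector and the acquisition metadata.
#'
#' @param field Field axis in mT, strictly increasing, uniform spacing
#'   (relative tolerance 1e-9).
#' @param intensity Intensity values (arbitrary units), same length as
#'   `field`.
#' @param instrument An [instrument_config()].
#' @param provenance `"measured"`, `"simulated"` or `"synthetic"`.
#' @param meta Optional list of extra metadata (e.g. generator parameters
#'   for synthetic spectra).
#' @return An object of class `epr_spectrum`.
#' @export
epr_spectrum <- function(field, intensity, instrument,
                         provenance = c("simulated", "measured", "synthetic"),
                         meta = list()) {
  provenance <- match.arg(provenance)
  if (length(field) != length(intensity))
    stop("field and intensity must have the same length")
  if (length(field) < 2L) stop("a spectrum needs at least two points")
  d <- diff(field)
  if (any(d <= 0)) stop("field axis must be strictly increasing")
  if (diff(range(d)) > 1e-9 * mean(d) * length(field))
    stop("field axis must be uniformly spaced")
  if (!inherits(instrument, "instrument_config"))
    stop("instrument must be an instrument_config")
  structure(list(field = as.numeric(field), intensity = as.numeric(intensity),
                 instrument = instrument, provenance = provenance,
                 meta = meta),
            class = "epr_spectrum")
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf("<epr_spectrum> %d pts, %.6g-%.6g mT @ %.6g GHz [%s, %s]\n",
              length(x$field), min(x$field), max(x$field),
              x$instrument$mw_frequency, x$instrument$detection_mode,
              x$provenance))
  invisible(x)
}

#' @export
as.data.frame.epr_spectrum <- function(x, ...) {
  data.frame(field_mT = x$field, intensity = x$intensity)
}

# uniform field step of a spectrum
field_step <- function(spec) {
  (spec$field[length(spec$field)] - spec$field[1]) / (length(spec$field) - 1)
}

#' Normalize a spectrum
#'
#' @param spec An [epr_spectrum()].
#' @param method `"area"` (unit absolute integral), `"amplitude"` (unit
#'   maximum absolute intensity) or `"pp"` (unit peak-to-peak amplitude,
#'   the usual choice for derivative-like traces).
#' @return The rescaled spectrum.
#' @export
normalize_spectrum <- function(spec, method = c("area", "amplitude", "pp")) {
  method <- match.arg(method)
  s <- switch(method,
              area = pracma::trapz(spec$field, abs(spec$intensity)),
              amplitude = max(abs(spec$intensity)),
              pp = diff(range(spec$intensity)))
  if (s <= 0) stop("cannot normalize an all-zero spectrum")
  spec$intensity <- spec$intensity / s
  spec
}
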