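# File I/O: two-column ASCII spectra with '#' metadata headers, Bruker
# BES3T (DSC/DTA) import, condition-series CSV and JSON serialization of
# results. Fields are mT end-to-end; Gauss inputs are converted exactly by
# 0.1 at read time and the conversion is recorded.

#' Write a spectrum as two-column ASCII
#'
#' Writes `# key: value` header comments (frequency, modulation amplitude,
#' detection mode, temperature, condition labels, provenance) followed by
#' field (mT) and intensity columns at 12 significant digits, so a
#' write/read cycle is lossless at that precision.
#'
#' @param spec An [epr_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_ascii <- function(spec, path) {
  stopifnot(inherits(spec, "epr_spectrum"))
  inst <- spec$instrument
  hdr <- c(sprintf("# mw_frequency_GHz: %.6f", inst$mw_frequency),
           sprintf("# modulation_amplitude_mT: %g",
                   inst$modulation_amplitude),
           sprintf("# detection_mode: %s", inst$detection_mode),
           sprintf("# temperature_K: %g", inst$temperature),
           sprintf("# provenance: %s", spec$provenance))
  for (nm in names(inst$condition))
    hdr <- c(hdr, sprintf("# condition_%s: %s", nm,
                          format(inst$condition[[nm]])))
  body <- sprintf("%.12g %.12g", spec$field, spec$intensity)
  writeLines(c(hdr, "# field_mT intensity", body), path)
  invisible(path)
}

#' Read a two-column ASCII spectrum
#'
#' Parses `# key: value` header comments into an [instrument_config()]
#' (field range and point count are taken from the data) and the two
#' numeric columns into field (mT) and intensity. Malformed rows raise an
#' error naming the offending line.
#'
#' @param path Input file path.
#' @param gauss Input field axis is in Gauss; convert to mT (exact factor
#'   0.1). Recorded in the returned spectrum's `meta$unit_conversion`.
#' @return An [epr_spectrum()].
#' @export
read_spectrum_ascii <- function(path, gauss = FALSE) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  data_idx <- which(!is_comment & !is_blank)
  if (length(data_idx) < 2) stop("no data rows found in '", path, "'")
  field <- numeric(length(data_idx))
  inten <- numeric(length(data_idx))
  for (i in seq_along(data_idx)) {
    toks <- strsplit(trimws(lines[data_idx[i]]), "[\\s,;]+", perl = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) < 2 || anyNA(vals[1:2]))
      stop("line ", data_idx[i], " of '", path,
           "' is not two numeric columns: '", lines[data_idx[i]], "'")
    field[i] <- vals[1]; inten[i] <- vals[2]
  }
  if (gauss) field <- field * 0.1
  if (any(diff(field) <= 0))
    stop("field axis in '", path, "' is not strictly increasing (first ",
         "violation at data row ",
         which(diff(field) <= 0)[1] + 1, ")")
  nu <- if (!is.null(meta$mw_frequency_GHz))
    as.numeric(meta$mw_frequency_GHz) else 9.7
  amp <- if (!is.null(meta$modulation_amplitude_mT))
    as.numeric(meta$modulation_amplitude_mT) else 0
  mode <- if (!is.null(meta$detection_mode)) meta$detection_mode
          else "absorption"
  temp <- if (!is.null(meta$temperature_K))
    as.numeric(meta$temperature_K) else 10
  cond_keys <- grep("^condition_", names(meta), value = TRUE)
  cond <- stats::setNames(lapply(meta[cond_keys], identity),
                          sub("^condition_", "", cond_keys))
  inst <- instrument_config(nu, min(field), max(field), length(field),
                            modulation_amplitude = amp,
                            detection_mode = mode, temperature = temp,
                            condition = cond)
  prov <- if (!is.null(meta$provenance) &&
              meta$provenance %in% c("measured", "simulated", "synthetic"))
    meta$provenance else "measured"
  sp <- epr_spectrum(field, inten, inst, provenance = prov)
  if (gauss) sp$meta$unit_conversion <- "gauss_to_mT_x0.1"
  sp
}

#' Read a Bruker BES3T (DSC/DTA) spectrum
#'
#' Reconstructs the field axis from the `XMIN`/`XWID`/`XPTS` descriptor
#' keys (endpoint-inclusive: `XMIN + XWID * (0:(XPTS-1))/(XPTS-1)`), reads
#' the binary DTA payload honouring the `IRFMT` (D = float64, F = float32)
#' and `BSEQ` (BIG/LIT endianness, big-endian default) keys, takes the
#' microwave frequency from `MWFQ` (Hz) and converts Gauss axes (`XUNI`)
#' to mT.
#'
#' @param dsc_path Path to the text descriptor (`.DSC`).
#' @param dta_path Path to the binary data (`.DTA`); defaults to
#'   `dsc_path` with its extension swapped.
#' @return An [epr_spectrum()] with provenance `"measured"`.
#' @export
read_bes3t <- function(dsc_path, dta_path = NULL) {
  if (is.null(dta_path))
    dta_path <- sub("\\.[Dd][Ss][Cc]$", ".DTA", dsc_path)
  lines <- readLines(dsc_path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Z0-9]+)\\s+(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  need <- c("XPTS", "XMIN", "XWID")
  missing_keys <- need[!need %in% names(kv)]
  if (length(missing_keys) > 0)
    stop("DSC descriptor '", dsc_path, "' is missing required key(s): ",
         paste(missing_keys, collapse = ", "))
  npts <- as.integer(kv$XPTS)
  xmin <- as.numeric(kv$XMIN)
  xwid <- as.numeric(kv$XWID)
  irfmt <- toupper(if (!is.null(kv$IRFMT)) kv$IRFMT else "D")
  endian <- if (!is.null(kv$BSEQ) && toupper(kv$BSEQ) == "LIT")
    "little" else "big"
  size <- if (irfmt == "F") 4L else 8L
  payload <- file.info(dta_path)$size
  if (is.na(payload)) stop("DTA file '", dta_path, "' not found")
  if (payload < npts * size)
    stop("DTA payload (", payload, " bytes) shorter than XPTS = ", npts,
         " values of ", size, " bytes")
  con <- file(dta_path, "rb")
  on.exit(close(con))
  y <- readBin(con, "double", n = npts, size = size, endian = endian)
  field <- xmin + xwid * (0:(npts - 1)) / (npts - 1)
  xuni <- if (!is.null(kv$XUNI)) gsub("'", "", kv$XUNI) else "G"
  gauss <- toupper(xuni) %in% c("G", "GAUSS")
  if (gauss) field <- field * 0.1
  nu <- if (!is.null(kv$MWFQ)) as.numeric(kv$MWFQ) / 1e9 else 9.7
  inst <- instrument_config(nu, min(field), max(field), npts,
                            detection_mode = "absorption")
  sp <- epr_spectrum(field, y, inst, provenance = "measured")
  if (gauss) sp$meta$unit_conversion <- "gauss_to_mT_x0.1"
  sp
}

#' Read/write a condition series as CSV
#'
#' CSV with columns `condition`, `weight` and optional `sigma`.
#'
#' @param path CSV path.
#' @param kind `"potential"` or `"ph"`.
#' @return A [condition_series()].
#' @export
read_condition_series <- function(path, kind = c("potential", "ph")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (!all(c("condition", "weight") %in% names(df)))
    stop("CSV must have 'condition' and 'weight' columns")
  condition_series(df$condition, df$weight,
                   sigma = if ("sigma" %in% names(df)) df$sigma else NULL,
                   kind = kind)
}

#' @rdname read_condition_series
#' @param series A [condition_series()].
#' @export
write_condition_series <- function(series, path) {
  stopifnot(inherits(series, "condition_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a spin-population table from CSV
#'
#' CSV with columns `site`, `population` and optionally `conformer`
#' (source label); one classification record per conformer.
#'
#' @param path CSV path.
#' @return A named list of population vectors, one per conformer (a single
#'   unnamed record yields a list of length 1 named `"record"`).
#' @examples
#' recs <- read_spin_populations(system.file("extdata",
#'   "spin_populations_synthetic.csv", package = "eprmix"))
#' classify_valence(recs$A)
#' @export
read_spin_populations <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("site", "population") %in% names(df)))
    stop("CSV must have 'site' and 'population' columns")
  if (!"conformer" %in% names(df)) df$conformer <- "record"
  out <- lapply(split(df, df$conformer), function(d)
    stats::setNames(d$population, d$site))
  out
}

#' Serialize a fit or assignment to JSON
#'
#' @param x An `epr_fit`, `epr_global_fit`, `valence_assignment`,
#'   `titration_fit` or `ph_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  obj <- if (inherits(x, "epr_fit")) {
    list(type = "fit",
         weights = as.list(x$weights),
         weights_normalized = as.list(x$weights_normalized),
         baseline_coeffs = x$baseline_coeffs,
         residual_norm = x$residual_norm,
         collinear = isTRUE(x$collinear),
         species = lapply(x$species, function(sp)
           list(name = sp$name, g = as.numeric(sp$g),
                g_strain = sp$g_strain, linewidth = sp$linewidth,
                lineshape = sp$lineshape)))
  } else if (inherits(x, "epr_global_fit")) {
    list(type = "global_fit",
         residual_norm = x$residual_norm,
         converged = x$converged,
         species = lapply(x$species, function(sp)
           list(name = sp$name, g = as.numeric(sp$g),
                g_strain = sp$g_strain, linewidth = sp$linewidth)),
         weights_normalized = lapply(x$fits, function(f)
           as.list(f$weights_normalized)))
  } else if (inherits(x, "valence_assignment")) {
    list(type = "valence_assignment",
         mixed_valence = x$mixed_valence, ferrous = x$ferrous,
         margin = x$margin, plane_label = x$plane_label)
  } else if (inherits(x, "titration_fit")) {
    list(type = "titration_fit", E_m_mV = x$E_m, E_m_se = x$E_m_se,
         E_m_ci = x$E_m_ci, n_e = x$n_e, n_e_fixed = x$n_e_fixed,
         identifiable = x$identifiable, flags = x$flags)
  } else if (inherits(x, "ph_fit")) {
    list(type = "ph_fit", pKa = x$pKa, pKa_se = x$pKa_se,
         pKa_ci = x$pKa_ci, n_H = x$n_H, n_H_fixed = x$n_H_fixed,
         identifiable = x$identifiable, flags = x$flags)
  } else stop("unsupported object for JSON serialization")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
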