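# Parametric links between experimental condition (applied potential, pH)
# and species fractions, plus estimators for midpoint potential and pKa
# from weight-versus-condition series.

#' One-electron (Nernstian) redox titration model
#'
#' @param E_m Midpoint potential in mV vs SHE.
#' @param n_e Number of electrons transferred (integer >= 1, default 1:
#'   the one-electron \[4Fe4S\]2+/1+ couple).
#' @param T Temperature in K (default 298.15).
#' @return An object of class `titration_model`.
#' @export
titration_model <- function(E_m, n_e = 1L, T = 298.15) {
  if (n_e < 1 || n_e != round(n_e)) stop("n_e must be a positive integer")
  if (T <= 0) stop("temperature must be > 0 K")
  structure(list(E_m = E_m, n_e = as.integer(n_e), T = T),
            class = "titration_model")
}

#' Fraction of the reduced (EPR-visible) form at a given potential
#'
#' Nernst equation for an n-electron couple:
#' `f(E) = 1 / (1 + exp((E - E_m) n_e F / (R T)))`. Strictly decreasing in
#' `E`; `f(E_m) = 1/2`; more negative potentials favour the reduced form.
#'
#' @param E Applied potential(s), mV vs SHE.
#' @param model A [titration_model()].
#' @return Reduced fraction(s) in (0, 1).
#' @examples
#' nernst_fraction(-509, titration_model(E_m = -450))  # ~0.909
#' @export
nernst_fraction <- function(E, model) {
  stopifnot(inherits(model, "titration_model"))
  # E in mV -> volts; F/(RT) in 1/V
  1 / (1 + exp((E - model$E_m) * 1e-3 * model$n_e * .const$F /
                 (.const$R * model$T)))
}

#' Hill-type pH model for a protonation-linked species fraction
#'
#' @param pKa Apparent pKa of the protonation equilibrium.
#' @param n_H Hill coefficient (> 0, default 1).
#' @param f_low,f_high Limiting fractions at very low and very high pH,
#'   both in \[0, 1\]. Non-unit plateaus allow for incomplete conversion.
#' @return An object of class `ph_model`.
#' @export
ph_model <- function(pKa, n_H = 1, f_low = 1, f_high = 0) {
  if (n_H <= 0) stop("n_H must be > 0")
  if (f_low < 0 || f_low > 1 || f_high < 0 || f_high > 1)
    stop("limiting fractions must lie in [0, 1]")
  structure(list(pKa = pKa, n_H = n_H, f_low = f_low, f_high = f_high),
            class = "ph_model")
}

#' Fraction of the protonation-linked species at a given pH
#'
#' `f(pH) = f_high + (f_low - f_high) / (1 + 10^(n_H (pH - pKa)))`:
#' the fraction moves monotonically from `f_low` at low pH to `f_high` at
#' high pH, crossing the midpoint at `pH = pKa`. With the rhombic species
#' as the protonation-linked form this reproduces its dominance at low pH
#' and disappearance at high pH.
#'
#' @param pH pH value(s).
#' @param model A [ph_model()].
#' @return Species fraction(s).
#' @examples
#' ph_fraction(6.5, ph_model(pKa = 6.8))  # ~0.666
#' @export
ph_fraction <- function(pH, model) {
  stopifnot(inherits(model, "ph_model"))
  model$f_high + (model$f_low - model$f_high) /
    (1 + 10^(model$n_H * (pH - model$pKa)))
}

#' A weight-versus-condition series
#'
#' @param condition Condition values (mV vs SHE or pH units).
#' @param weight Normalized weight of the tracked species per condition,
#'   in \[0, 1\].
#' @param sigma Optional per-point uncertainties (> 0).
#' @param kind `"potential"` or `"ph"`.
#' @return A data.frame of class `condition_series`, sorted by condition.
#' @export
condition_series <- function(condition, weight, sigma = NULL,
                             kind = c("potential", "ph")) {
  kind <- match.arg(kind)
  if (length(condition) != length(weight))
    stop("condition and weight must have the same length")
  if (any(weight < -1e-9 | weight > 1 + 1e-9))
    stop("weights must lie in [0, 1]")
  if (anyDuplicated(condition)) stop("condition values must be distinct")
  if (is.null(sigma)) sigma <- rep(NA_real_, length(weight))
  if (any(!is.na(sigma) & sigma <= 0)) stop("sigma must be > 0")
  o <- order(condition)
  structure(data.frame(condition = as.numeric(condition[o]),
                       weight = as.numeric(pmin(pmax(weight[o], 0), 1)),
                       sigma = as.numeric(sigma[o])),
            class = c("condition_series", "data.frame"), kind = kind)
}

# weights for nls: 1/sigma^2 when given, else uniform
.series_weights <- function(series) {
  if (all(is.na(series$sigma))) rep(1, nrow(series))
  else 1 / ifelse(is.na(series$sigma), stats::median(series$sigma,
                                                    na.rm = TRUE),
                  series$sigma)^2
}

#' Estimate a midpoint potential from a titration series
#'
#' Weighted nonlinear least squares of the Nernst sigmoid to a reduced
#' fraction versus potential series. The series should span both sides of
#' the transition; a series sitting entirely on one plateau is flagged
#' non-identifiable.
#'
#' @param series A [condition_series()] (kind `"potential"`).
#' @param n_e Electrons transferred; fixed at this value by default
#'   (reported as fixed), or estimated when `fit_n = TRUE`.
#' @param T Temperature in K.
#' @param fit_n Also estimate `n_e` as a continuous slope parameter.
#' @return A list of class `titration_fit`: `model` ([titration_model()]
#'   with the estimate), `E_m`, `E_m_se`, `E_m_ci` (95 percent),
#'   `n_e`, `n_e_fixed`, `identifiable`, `flags`, and the underlying `fit`.
#' @export
fit_midpoint <- function(series, n_e = 1L, T = 298.15, fit_n = FALSE) {
  stopifnot(inherits(series, "condition_series"))
  flags <- character(0)
  if (nrow(series) < 4) flags <- c(flags, "fewer_than_4_points")
  on_low <- all(series$weight > 0.9)
  on_high <- all(series$weight < 0.1)
  identifiable <- !(on_low || on_high)
  if (!identifiable) {
    flags <- c(flags, "plateau_only_non_identifiable")
    warning("series lies entirely on one plateau; E_m is not identifiable")
    return(structure(list(model = NULL, E_m = NA_real_, E_m_se = NA_real_,
                          E_m_ci = c(NA_real_, NA_real_), n_e = n_e,
                          n_e_fixed = !fit_n, identifiable = FALSE,
                          flags = flags, fit = NULL),
                     class = "titration_fit"))
  }
  if (!(any(series$weight > 0.5) && any(series$weight < 0.5)))
    flags <- c(flags, "transition_poorly_spanned_wide_uncertainty")

  kT <- .const$R * T / (.const$F * 1e-3)  # RT/F in mV
  sw <- sqrt(.series_weights(series))
  E0 <- series$condition[which.min(abs(series$weight - 0.5))]
  model_f <- function(p) {
    ne <- if (fit_n) p[["ne"]] else n_e
    1 / (1 + exp((series$condition - p[["Em"]]) * ne / kT))
  }
  fit <- minpack.lm::nls.lm(
    par = if (fit_n) c(Em = E0, ne = as.numeric(n_e)) else c(Em = E0),
    lower = if (fit_n) c(-Inf, 0.1) else -Inf,
    upper = if (fit_n) c(Inf, 4) else Inf,
    fn = function(p) sw * (series$weight - model_f(p)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  se <- .lm_se(fit)
  Em <- fit$par[["Em"]]
  ne_hat <- if (fit_n) fit$par[["ne"]] else n_e
  structure(list(model = titration_model(Em, max(1L, round(ne_hat)), T),
                 E_m = Em, E_m_se = se[["Em"]],
                 E_m_ci = Em + c(-1, 1) * stats::qt(0.975, nrow(series) -
                                                      length(fit$par)) *
                   se[["Em"]],
                 n_e = ne_hat, n_e_fixed = !fit_n, identifiable = TRUE,
                 flags = flags, fit = fit),
            class = "titration_fit")
}

# standard errors from a nls.lm fit; NA when the curvature is singular
.lm_se <- function(fit) {
  p <- length(fit$par)
  dof <- max(length(fit$fvec) - p, 1)
  V <- tryCatch(solve(fit$hessian) * fit$deviance / dof,
                error = function(e) NULL)
  out <- stats::setNames(rep(NA_real_, p), names(fit$par))
  if (!is.null(V)) out[] <- sqrt(pmax(diag(V), 0))
  out
}

#' Estimate an apparent pKa from a pH series
#'
#' Weighted nonlinear least squares of the Hill sigmoid to a species
#' fraction versus pH series. Plateau fractions `f_low`/`f_high` are
#' co-estimated within \[0, 1\] by default; the Hill coefficient is fixed
#' at `n_H` (reported as fixed) unless `fit_n = TRUE`.
#'
#' @param series A [condition_series()] (kind `"ph"`).
#' @param n_H Hill coefficient, fixed by default.
#' @param fit_n Also estimate `n_H`.
#' @param fit_limits Estimate `f_low`/`f_high` (default `TRUE`); with
#'   `FALSE` they are fixed at 1 and 0.
#' @return A list of class `ph_fit`: `model` ([ph_model()]), `pKa`,
#'   `pKa_se`, `pKa_ci`, `n_H`, `n_H_fixed`, `identifiable`, `flags`,
#'   `fit`.
#' @export
fit_pka <- function(series, n_H = 1, fit_n = FALSE, fit_limits = TRUE) {
  stopifnot(inherits(series, "condition_series"))
  flags <- character(0)
  npar <- 1 + as.integer(fit_n) + 2 * as.integer(fit_limits)
  if (nrow(series) <= npar) {
    warning("series has too few points for the requested parameters")
    return(structure(list(model = NULL, pKa = NA_real_, pKa_se = NA_real_,
                          pKa_ci = c(NA_real_, NA_real_), n_H = n_H,
                          n_H_fixed = !fit_n, identifiable = FALSE,
                          flags = "under_determined", fit = NULL),
                     class = "ph_fit"))
  }
  if (diff(range(series$weight)) < 0.1) {
    flags <- c(flags, "plateau_only_non_identifiable")
    warning("series shows no transition; pKa is not identifiable")
    return(structure(list(model = NULL, pKa = NA_real_, pKa_se = NA_real_,
                          pKa_ci = c(NA_real_, NA_real_), n_H = n_H,
                          n_H_fixed = !fit_n, identifiable = FALSE,
                          flags = flags, fit = NULL),
                     class = "ph_fit"))
  }
  sw <- sqrt(.series_weights(series))
  # start at the observed half-transition point; interpolation through a
  # noisy, non-monotone series is unreliable, the nearest sample is not
  p0 <- series$condition[which.min(abs(series$weight -
                                         mean(range(series$weight))))]
  start <- c(pKa = p0)
  lower <- c(pKa = min(series$condition) - 3)
  upper <- c(pKa = max(series$condition) + 3)
  if (fit_limits) {
    start <- c(start, fl = max(series$weight), fh = min(series$weight))
    lower <- c(lower, fl = 0, fh = 0)
    upper <- c(upper, fl = 1, fh = 1)
  }
  if (fit_n) {
    start <- c(start, nH = n_H)
    lower <- c(lower, nH = 0.2)
    upper <- c(upper, nH = 4)
  }
  model_f <- function(p) {
    nH <- if (fit_n) p[["nH"]] else n_H
    fl <- if (fit_limits) p[["fl"]] else 1
    fh <- if (fit_limits) p[["fh"]] else 0
    fh + (fl - fh) / (1 + 10^(nH * (series$condition - p[["pKa"]])))
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) sw * (series$weight - model_f(p)),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  se <- .lm_se(fit)
  pKa <- fit$par[["pKa"]]
  model <- ph_model(pKa,
                    n_H = if (fit_n) fit$par[["nH"]] else n_H,
                    f_low = if (fit_limits) fit$par[["fl"]] else 1,
                    f_high = if (fit_limits) fit$par[["fh"]] else 0)
  structure(list(model = model, pKa = pKa, pKa_se = se[["pKa"]],
                 pKa_ci = pKa + c(-1, 1) *
                   stats::qt(0.975, nrow(series) - length(fit$par)) *
                   se[["pKa"]],
                 n_H = model$n_H, n_H_fixed = !fit_n, identifiable = TRUE,
                 flags = flags, fit = fit),
            class = "ph_fit")
}
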