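# Spectral decomposition: weighted sums of species powder patterns,
# non-negative least-squares weight fits with optional polynomial baseline,
# bounded variable-projection refinement of g-values, global multi-spectrum
# fits and model-selection tables.

# Apply the detection transform requested by an instrument_config to an
# absorption-mode intensity vector living on that instrument's field axis.
apply_detection <- function(spec) {
  mode <- spec$instrument$detection_mode
  if (mode == "absorption") return(spec)
  if (mode == "derivative") {
    spec$intensity <- .central_diff(spec$intensity, field_step(spec))
    return(spec)
  }
  pseudo_modulate(spec, spec$instrument$modulation_amplitude)
}

# Simulate every species on one instrument (absorption first, detection
# transform last) and return the n_points x n_species design matrix.
species_design <- function(species, instrument, n_orient = 2048) {
  cols <- lapply(species, function(sp) {
    s <- powder_spectrum(sp, instrument, n_orient = n_orient)
    s$instrument <- instrument
    apply_detection(s)$intensity
  })
  do.call(cbind, cols)
}

#' Simulate a weighted mixture of species
#'
#' Exact linear combination of per-species powder spectra, followed by the
#' detection transform the instrument requests (pseudo-modulation or
#' derivative).
#'
#' @param species List of [species_model()] objects.
#' @param weights Non-negative weights, one per species.
#' @param instrument An [instrument_config()].
#' @param n_orient Orientation knots per species (see [powder_spectrum()]).
#' @return An [epr_spectrum()] in the instrument's detection mode.
#' @export
simulate_mixture <- function(species, weights, instrument, n_orient = 2048) {
  if (inherits(species, "species_model")) species <- list(species)
  if (length(weights) != length(species))
    stop("need exactly one weight per species")
  if (any(weights < 0)) stop("weights must be >= 0")
  X <- species_design(species, instrument, n_orient = n_orient)
  epr_spectrum(field_axis(instrument), as.numeric(X %*% weights), instrument,
               provenance = "simulated",
               meta = list(weights = weights,
                           species = vapply(species, `[[`, "", "name")))
}

# rows of the field axis excluded by a mask (list of c(lo, hi) mT ranges)
mask_rows <- function(field, mask) {
  if (is.null(mask) || length(mask) == 0) return(logical(length(field)))
  if (is.numeric(mask) && length(mask) == 2L) mask <- list(mask)
  excl <- logical(length(field))
  for (m in mask) excl <- excl | (field >= min(m) & field <= max(m))
  excl
}

# Chebyshev-like polynomial baseline columns on [-1, 1]
baseline_design <- function(field, order) {
  if (order < 0) return(NULL)
  x <- 2 * (field - min(field)) / (max(field) - min(field)) - 1
  vapply(0:order, function(k) x^k, numeric(length(field)))
}

# NNLS on the species columns with unconstrained baseline columns handled
# by splitting each into a (+, -) non-negative pair.
nnls_mixed <- function(X, P, y) {
  A <- if (is.null(P)) X else cbind(X, P, -P)
  sol <- pracma::lsqnonneg(A, y)
  k <- ncol(X)
  w <- sol$x[seq_len(k)]
  base <- if (is.null(P)) numeric(0)
          else sol$x[k + seq_len(ncol(P))] - sol$x[k + ncol(P) + seq_len(ncol(P))]
  list(weights = w, baseline = base,
       fitted = as.numeric(A %*% sol$x),
       residual = y - as.numeric(A %*% sol$x))
}

#' Fit species weights to a spectrum by non-negative least squares
#'
#' Expresses `target` as a non-negative linear combination of the species'
#' simulated spectra (on the target's own instrument settings) plus an
#' optional unconstrained polynomial baseline. Field regions listed in
#' `mask` (e.g. a narrow organic-radical line near g = 2) are excluded from
#' the fit.
#'
#' @param target An [epr_spectrum()].
#' @param species List of [species_model()] objects, or a single one.
#' @param baseline_order Polynomial baseline order co-fitted in the linear
#'   step; `NULL` or negative disables the baseline. Default 1; orders
#'   above 3 are rejected.
#' @param mask Optional list of `c(lo, hi)` field ranges (mT) to exclude.
#' @param n_orient Orientation knots per species simulation.
#' @return An object of class `epr_fit` with elements `weights` (raw
#'   amplitudes), `weights_normalized` (fractions of the weight sum),
#'   `weight_se` (linear-model standard errors, `NA` for weights pinned at
#'   zero), `baseline_coeffs`, `residual_norm`, `fitted`, `residual`,
#'   `mask` (logical vector of excluded rows), `collinear` flag and the
#'   species list.
#' @export
fit_weights <- function(target, species, baseline_order = 1, mask = NULL,
                        n_orient = 2048) {
  stopifnot(inherits(target, "epr_spectrum"))
  if (inherits(species, "species_model")) species <- list(species)
  if (!is.null(baseline_order) && baseline_order > 3)
    stop("baseline_order above 3 is not supported")
  X <- species_design(species, target$instrument, n_orient = n_orient)
  P <- if (is.null(baseline_order) || baseline_order < 0) NULL
       else baseline_design(target$field, baseline_order)
  excl <- mask_rows(target$field, mask)
  if (all(excl)) stop("mask excludes every field point")
  keep <- !excl

  collinear <- FALSE
  if (ncol(X) > 1) {
    sv <- svd(scale(X[keep, , drop = FALSE], center = FALSE,
                    scale = sqrt(colSums(X[keep, , drop = FALSE]^2))))$d
    if (sv[length(sv)] < 1e-8 * sv[1]) {
      collinear <- TRUE
      warning("species spectra are nearly collinear; the smallest-norm ",
              "non-negative solution is reported")
    }
  }

  sol <- nnls_mixed(X[keep, , drop = FALSE],
                    if (is.null(P)) NULL else P[keep, , drop = FALSE],
                    target$intensity[keep])
  w <- sol$weights
  wn <- if (sum(w) > 0) w / sum(w) else w
  nm <- vapply(species, `[[`, "", "name")
  names(w) <- names(wn) <- nm

  # linear-model covariance on the active (non-zero) columns
  se <- rep(NA_real_, length(w))
  act <- which(w > 0)
  A <- cbind(X, if (is.null(P)) NULL else P)[keep, , drop = FALSE]
  acols <- c(act, if (is.null(P)) integer(0) else ncol(X) + seq_len(ncol(P)))
  dof <- sum(keep) - length(acols)
  if (length(acols) > 0 && dof > 0) {
    s2 <- sum(sol$residual^2) / dof
    V <- tryCatch(solve(crossprod(A[, acols, drop = FALSE])) * s2,
                  error = function(e) NULL)
    if (!is.null(V)) se[act] <- sqrt(pmax(diag(V)[seq_along(act)], 0))
  }
  names(se) <- nm

  structure(list(weights = w, weights_normalized = wn, weight_se = se,
                 baseline_coeffs = sol$baseline,
                 residual_norm = sqrt(sum(sol$residual^2)),
                 fitted = sol$fitted, residual = sol$residual,
                 mask = excl, collinear = collinear, species = species,
                 instrument = target$instrument),
            class = "epr_fit")
}

#' @export
print.epr_fit <- function(x, ...) {
  cat("<epr_fit>\n  normalized weights:\n")
  for (nm in names(x$weights_normalized))
    cat(sprintf("    %-12s %.4f (raw %.4g)\n", nm,
                x$weights_normalized[nm], x$weights[nm]))
  cat(sprintf("  residual norm: %.4g%s\n", x$residual_norm,
              if (isTRUE(x$collinear)) "  [collinear design]" else ""))
  invisible(x)
}

# flatten free species parameters (g-values, optionally linewidth) into a
# vector, and rebuild the species list from such a vector
.pack_species <- function(species, fit_linewidth) {
  unlist(lapply(species, function(sp)
    c(as.numeric(sp$g), if (fit_linewidth) sp$linewidth)))
}
.unpack_species <- function(par, template, fit_linewidth) {
  npar <- 3 + as.integer(fit_linewidth)
  lapply(seq_along(template), function(i) {
    p <- par[(i - 1) * npar + seq_len(npar)]
    sp <- template[[i]]
    sp$g <- g_tensor(p[1], p[2], p[3], sort = FALSE)
    if (fit_linewidth) sp$linewidth <- max(p[4], 1e-3)
    sp
  })
}

# default box bounds: g within +/- g_window of init, linewidth in
# [0.2, 5] x init
.default_bounds <- function(par, template, fit_linewidth, g_window) {
  npar <- 3 + as.integer(fit_linewidth)
  lower <- upper <- numeric(length(par))
  for (i in seq_along(template)) {
    idx <- (i - 1) * npar + 1:3
    lower[idx] <- par[idx] - g_window
    upper[idx] <- par[idx] + g_window
    if (fit_linewidth) {
      lower[idx[3] + 1] <- 0.2 * par[idx[3] + 1]
      upper[idx[3] + 1] <- 5 * par[idx[3] + 1]
    }
  }
  list(lower = lower, upper = upper)
}

#' Refine species parameters against a spectrum
#'
#' Bounded nonlinear least squares over g-values (and optionally residual
#' linewidths) with the mixture weights re-solved by the non-negative
#' linear step at every iteration (variable projection). Multiple jittered
#' starts (deterministic) guard against local minima on broad rhombic
#' features.
#'
#' @param target An [epr_spectrum()].
#' @param init List of [species_model()] initial guesses.
#' @param lower,upper Optional explicit bound vectors in the order
#'   `g1, g2, g3[, linewidth]` per species; defaults are `g +/- g_window`
#'   and linewidth within a factor 5.
#' @param g_window Half-width of the default g-value box (default 0.05).
#' @param fit_linewidth Also refine residual linewidths (default `TRUE`).
#' @param baseline_order,mask,n_orient Passed to the linear step.
#' @param multistart Number of jittered starting points (default 5; the
#'   first start is the unjittered `init`). Jitters are drawn from a fixed
#'   seed so refinement is reproducible.
#' @param maxit Iteration cap per start.
#' @return An `epr_fit` with refined `species`, plus `converged`,
#'   `at_boundary` and `start_used` fields.
#' @export
refine_species <- function(target, init, lower = NULL, upper = NULL,
                           g_window = 0.05, fit_linewidth = TRUE,
                           baseline_order = 1, mask = NULL, n_orient = 2048,
                           multistart = 5, maxit = 200) {
  stopifnot(inherits(target, "epr_spectrum"))
  if (inherits(init, "species_model")) init <- list(init)
  par0 <- .pack_species(init, fit_linewidth)
  bb <- .default_bounds(par0, init, fit_linewidth, g_window)
  if (is.null(lower)) lower <- bb$lower
  if (is.null(upper)) upper <- bb$upper
  if (any(par0 < lower - 1e-12) || any(par0 > upper + 1e-12))
    stop("initial parameters must lie inside the bounds")

  # objective is the residual sum of squares (smooth at a perfect fit,
  # unlike its square root, whose gradient never vanishes)
  obj <- function(par) {
    sp <- .unpack_species(par, init, fit_linewidth)
    f <- fit_weights(target, sp, baseline_order = baseline_order,
                     mask = mask, n_orient = n_orient)
    f$residual_norm^2
  }

  # deterministic jittered starts
  npar <- length(par0)
  starts <- list(par0)
  if (multistart > 1) {
    rs <- .mk_rng(20260101L)
    for (k in seq_len(multistart - 1)) {
      jit <- par0 + (rs(npar) - 0.5) * 0.4 * (upper - lower)
      starts[[k + 1]] <- pmin(pmax(jit, lower), upper)
    }
  }

  best <- NULL
  for (k in seq_along(starts)) {
    opt <- suppressWarnings(
      stats::optim(starts[[k]], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit,
                                  factr = 1e7, pgtol = 1e-10)))
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$start_used <- k
    }
  }
  # an objective at the numerical floor (perfect fit) can abort the line
  # search; that is convergence, not failure
  at_floor <- best$value <= 1e-12 * sum(target$intensity^2)
  if (best$convergence != 0 && !at_floor)
    warning("refinement did not converge (optim code ", best$convergence,
            "): ", best$message)

  refined <- .unpack_species(best$par, init, fit_linewidth)
  # restore descending-order convention on output
  refined <- lapply(refined, function(sp) {
    sp$g <- g_tensor(as.numeric(sp$g))
    sp
  })
  fit <- fit_weights(target, refined, baseline_order = baseline_order,
                     mask = mask, n_orient = n_orient)
  fit$converged <- best$convergence == 0 || at_floor
  fit$at_boundary <- any(abs(best$par - lower) < 1e-8) ||
    any(abs(best$par - upper) < 1e-8)
  fit$start_used <- best$start_used
  fit
}

#' Jointly fit shared species across several spectra
#'
#' One species parameter set is refined against every spectrum in
#' `dataset` simultaneously (pooled sum-of-squares objective); the mixture
#' weights remain free per spectrum. Spectra may differ in microwave
#' frequency, field axis and detection settings — each is simulated on its
#' own instrument, never resampled onto a foreign axis.
#'
#' @param dataset List of [epr_spectrum()] objects (>= 1; a singleton
#'   reduces to [refine_species()] behaviour).
#' @inheritParams refine_species
#' @param refine Refine species parameters (default `TRUE`); with `FALSE`
#'   only per-spectrum weights are fitted for the given species.
#' @return An object of class `epr_global_fit`: shared `species`, list of
#'   per-spectrum `fits`, `residual_norm` (pooled), `converged`.
#' @export
global_fit <- function(dataset, init, lower = NULL, upper = NULL,
                       g_window = 0.05, fit_linewidth = TRUE,
                       baseline_order = 1, mask = NULL, n_orient = 2048,
                       multistart = 3, maxit = 200, refine = TRUE) {
  if (inherits(dataset, "epr_spectrum")) dataset <- list(dataset)
  if (length(dataset) < 1) stop("dataset must contain at least one spectrum")
  if (inherits(init, "species_model")) init <- list(init)

  pooled <- function(sp_list) {
    fits <- lapply(dataset, function(s)
      fit_weights(s, sp_list, baseline_order = baseline_order,
                  mask = mask, n_orient = n_orient))
    rss <- sum(vapply(fits, function(f) f$residual_norm^2, 0))
    list(fits = fits, rss = rss, norm = sqrt(rss))
  }

  if (refine) {
    par0 <- .pack_species(init, fit_linewidth)
    bb <- .default_bounds(par0, init, fit_linewidth, g_window)
    if (is.null(lower)) lower <- bb$lower
    if (is.null(upper)) upper <- bb$upper
    obj <- function(par)
      pooled(.unpack_species(par, init, fit_linewidth))$rss
    starts <- list(par0)
    if (multistart > 1) {
      rs <- .mk_rng(20260102L)
      for (k in seq_len(multistart - 1)) {
        jit <- par0 + (rs(length(par0)) - 0.5) * 0.4 * (upper - lower)
        starts[[k + 1]] <- pmin(pmax(jit, lower), upper)
      }
    }
    best <- NULL
    for (s0 in starts) {
      opt <- suppressWarnings(
        stats::optim(s0, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(maxit = maxit, factr = 1e7)))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    species <- lapply(.unpack_species(best$par, init, fit_linewidth),
                      function(sp) { sp$g <- g_tensor(as.numeric(sp$g)); sp })
    floor_rss <- 1e-12 * sum(vapply(dataset, function(s)
      sum(s$intensity^2), 0))
    converged <- best$convergence == 0 || best$value <= floor_rss
    if (!converged)
      warning("global refinement did not converge (optim code ",
              best$convergence, ")")
  } else {
    species <- init
    converged <- TRUE
  }
  res <- pooled(species)
  structure(list(species = species, fits = res$fits,
                 residual_norm = res$norm, converged = converged),
            class = "epr_global_fit")
}

#' @export
print.epr_global_fit <- function(x, ...) {
  cat(sprintf("<epr_global_fit> %d spectra, pooled residual %.4g\n",
              length(x$fits), x$residual_norm))
  for (sp in x$species)
    cat(sprintf("  %s: g = (%.4f, %.4f, %.4f)\n", sp$name,
                sp$g[1], sp$g[2], sp$g[3]))
  invisible(x)
}

#' Residual and information-criterion table versus species count
#'
#' Fits nested mixtures built from the first `K = 1..k_max` members of a
#' candidate pool and tabulates residual norms with AIC/BIC-style parsimony
#' criteria. The residual is monotone non-increasing in `K` (nested
#' non-negative designs). No model is auto-selected; the table is reported
#' as-is, since residual improvements alone cannot establish a true
#' species count.
#'
#' @param target An [epr_spectrum()].
#' @param candidates List of [species_model()] objects (the pool; order
#'   matters — member `K` is added at step `K`).
#' @param k_max Largest species count to try (default
#'   `min(8, length(candidates))`).
#' @param baseline_order,mask,n_orient Passed to [fit_weights()].
#' @return A data.frame with columns `k`, `residual_norm`, `aic`, `bic`.
#' @export
model_selection <- function(target, candidates,
                            k_max = min(8L, length(candidates)),
                            baseline_order = 1, mask = NULL,
                            n_orient = 2048) {
  if (inherits(candidates, "species_model")) candidates <- list(candidates)
  if (k_max < 1) stop("need at least one candidate species")
  k_max <- min(k_max, length(candidates))
  n <- sum(!mask_rows(target$field, mask))
  rows <- lapply(seq_len(k_max), function(k) {
    f <- fit_weights(target, candidates[seq_len(k)],
                     baseline_order = baseline_order, mask = mask,
                     n_orient = n_orient)
    p <- k + max(0, baseline_order + 1)
    rss <- f$residual_norm^2
    data.frame(k = k, residual_norm = f$residual_norm,
               aic = n * log(rss / n) + 2 * p,
               bic = n * log(rss / n) + log(n) * p)
  })
  do.call(rbind, rows)
}

# small deterministic uniform RNG stream independent of the global seed
.mk_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}
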