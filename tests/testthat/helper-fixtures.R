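# Shared fixtures and independent oracles for the test suite.
# Simulation sizes here are deliberately smaller than the package defaults
# to keep the suite fast; accuracy-critical checks state their own sizes.

fx_axial <- function(name = "4Fe-A")
  species_preset("axial_template", name = name)

fx_rhombic <- function(name = "4Fe-R")
  species_preset("rhombic_template", name = name)

fx_xband <- function(n_points = 512)
  instrument_preset("xband", n_points = n_points)

fx_qband <- function(n_points = 512)
  instrument_preset("qband", n_points = n_points)

# exhaustive lattice search over non-negative weights (step `by`) --
# independent oracle for the NNLS solution on small species sets
lattice_search_weights <- function(y, X, by = 0.05, wmax = 1.5) {
  grid <- seq(0, wmax, by = by)
  k <- ncol(X)
  combos <- as.matrix(expand.grid(rep(list(grid), k)))
  rss <- vapply(seq_len(nrow(combos)), function(i)
    sum((y - X %*% combos[i, ])^2), numeric(1))
  combos[which.min(rss), ]
}

# brute-force valence-partition oracle: minimise within-group sum of
# squares over all 6 equal-size partitions of the 4 sites
brute_force_partition <- function(rho, sites = paste0("Fe", 1:4)) {
  pairs <- utils::combn(4L, 2L)
  best <- NULL; best_ss <- Inf
  for (j in seq_len(ncol(pairs))) {
    mv <- pairs[, j]; fe <- setdiff(1:4, mv)
    ss <- sum((rho[mv] - mean(rho[mv]))^2) + sum((rho[fe] - mean(rho[fe]))^2)
    # the mixed-valence pair must be the more positive group
    if (mean(rho[mv]) < mean(rho[fe])) next
    if (ss < best_ss) { best_ss <- ss; best <- mv }
  }
  list(mixed_valence = sites[best], ferrous = sites[setdiff(1:4, best)])
}

# turning-point fields of a powder pattern: low-field edge (max slope),
# central peak, high-field edge (min slope) -- used to re-read g-values
# from a simulated spectrum
powder_turning_fields <- function(sp, nu, fmin, fmax, n_points = 4096) {
  cfg <- instrument_config(nu, fmin, fmax, n_points)
  s <- suppressWarnings(powder_spectrum(sp, cfg, n_orient = 4096))
  d <- diff(s$intensity)
  mid <- s$field[-1] - diff(s$field) / 2
  c(mid[which.max(d)], s$field[which.max(s$intensity)], mid[which.min(d)])
}

# numerically integrate a spectrum (independent of package internals)
trap_integral <- function(spec) {
  sum(diff(spec$field) * (head(spec$intensity, -1) + tail(spec$intensity, -1)) / 2)
}

# second moment of an absorption spectrum about its centroid
second_moment <- function(spec) {
  w <- spec$intensity / sum(spec$intensity)
  mu <- sum(w * spec$field)
  sum(w * (spec$field - mu)^2)
}
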