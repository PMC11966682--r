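#' Principal g-values of an S = 1/2 species
#'
#' Constructs a g-tensor from its three principal values. Values are stored
#' in descending order (`g1 >= g2 >= g3`), the convention used for
#' iron-sulfur cluster spectra where `g1` is the low-field feature.
#'
#' @param g1,g2,g3 Dimensionless principal g-values, all strictly positive.
#'   A single numeric vector of length 3 may be given as `g1`.
#' @param sort Reorder the values into descending order (default). Internal
#'   fitting code may disable this to keep a continuous parameterisation.
#' @return An object of class `g_tensor`: a named numeric vector
#'   `c(g1, g2, g3)`.
#' @examples
#' g_tensor(1.910, 2.040, 1.910)  # stored as (2.040, 1.910, 1.910)
#' @export
g_tensor <- function(g1, g2 = NULL, g3 = NULL, sort = TRUE) {
  g <- if (is.null(g2)) as.numeric(g1) else c(g1, g2, g3)
  if (length(g) != 3L || anyNA(g) || !is.numeric(g))
    stop("a g-tensor needs exactly three finite principal values")
  if (any(g <= 0)) stop("principal g-values must be > 0")
  if (sort) g <- sort(g, decreasing = TRUE)
  structure(stats::setNames(as.numeric(g), c("g1", "g2", "g3")),
            class = "g_tensor")
}

#' @export
print.g_tensor <- function(x, ...) {
  cat(sprintf("<g_tensor> g1 = %.4f, g2 = %.4f, g3 = %.4f (%s)\n",
              x[1], x[2], x[3], classify_symmetry(x)))
  invisible(x)
}

#' Classify the symmetry of a g-tensor
#'
#' A tensor is isotropic when all three principal values agree within
#' `tol`, axial when exactly one adjacent pair (`g1,g2` or `g2,g3`) is
#' degenerate within `tol`, and rhombic otherwise.
#'
#' @param g A [g_tensor()] (or numeric length-3 vector).
#' @param tol Degeneracy tolerance on the dimensionless g-values. The
#'   default 0.005 is half the smallest g-value difference resolved between
#'   literature parameter sets for the [4Fe4S]+ cluster.
#' @return One of `"isotropic"`, `"axial"`, `"rhombic"`.
#' @examples
#' classify_symmetry(g_tensor(2.040, 1.910, 1.910))  # "axial"
#' classify_symmetry(g_tensor(2.050, 1.915, 1.852))  # "rhombic"
#' @export
classify_symmetry <- function(g, tol = 0.005) {
  if (!inherits(g, "g_tensor")) g <- g_tensor(g)
  stopifnot(tol > 0)
  d12 <- abs(g[1] - g[2]) <= tol
  d23 <- abs(g[2] - g[3]) <= tol
  if (d12 && d23) return("isotropic")
  if (xor(d12, d23)) return("axial")
  "rhombic"
}

#' Effective g-value along an orientation
#'
#' First-order effective Zeeman factor for an anisotropic S = 1/2 species:
#' `g_eff(theta, phi) = sqrt(g1^2 sin^2(theta) cos^2(phi) +
#' g2^2 sin^2(theta) sin^2(phi) + g3^2 cos^2(theta))`, with `theta` the
#' polar angle from the g3 principal axis. Vectorised over `theta`/`phi`.
#'
#' @param g A [g_tensor()].
#' @param theta,phi Orientation angles in radians.
#' @return Effective g-value(s), bounded by `g3 <= g_eff <= g1`.
#' @examples
#' effective_g(g_tensor(2.045, 1.926, 1.896), theta = 0, phi = 0)  # g3
#' @export
effective_g <- function(g, theta, phi) {
  if (!inherits(g, "g_tensor")) g <- g_tensor(g)
  st2 <- sin(theta)^2
  unname(sqrt(g[1]^2 * st2 * cos(phi)^2 + g[2]^2 * st2 * sin(phi)^2 +
                g[3]^2 * cos(theta)^2))
}

#' Resonance field of an S = 1/2 transition
#'
#' First-order resonance condition `B = h nu / (g_eff mu_B)`.
#'
#' @param g_eff Effective g-value(s), > 0.
#' @param nu Microwave frequency in GHz, > 0.
#' @return Resonance field(s) in mT.
#' @examples
#' resonance_field(2.0023, 9.7)   # ~346.1 mT
#' resonance_field(2.045, 34)     # ~1187.9 mT
#' @export
resonance_field <- function(g_eff, nu) {
  if (any(g_eff <= 0)) stop("g_eff must be > 0")
  if (any(nu <= 0)) stop("frequency must be > 0")
  # hv/(g muB) in tesla -> mT
  1e3 * .const$h * (nu * 1e9) / (g_eff * .const$mu_B)
}

#' Field-position to g-value conversion
#'
#' Inverse of [resonance_field()]: `g = h nu / (B mu_B)`.
#'
#' @param B Field in mT, > 0.
#' @param nu Microwave frequency in GHz, > 0.
#' @return Dimensionless g-value(s).
#' @export
field_to_g <- function(B, nu) {
  if (any(B <= 0)) stop("field must be > 0")
  if (any(nu <= 0)) stop("frequency must be > 0")
  .const$h * (nu * 1e9) / (B * 1e-3 * .const$mu_B)
}
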