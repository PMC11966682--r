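#' Physical constants used throughout the package
#'
#' Fixed CODATA 2018 values; the single source of truth for every module
#' (resonance condition, Nernst equation). Returned as an immutable list.
#'
#' @return A named list with elements `h` (Planck constant, J s), `mu_B`
#'   (Bohr magneton, J/T), `F` (Faraday constant, C/mol) and `R` (molar gas
#'   constant, J/mol/K).
#' @examples
#' physical_constants()$h
#' @export
physical_constants <- function() {
  list(
    h    = 6.62607015e-34,    # J s (exact)
    mu_B = 9.2740100783e-24,  # J/T
    F    = 96485.33212,       # C/mol (exact)
    R    = 8.314462618        # J/mol/K (exact)
  )
}

# internal shorthand, avoids rebuilding the list in hot loops
.const <- list(
  h    = 6.62607015e-34,
  mu_B = 9.2740100783e-24,
  F    = 96485.33212,
  R    = 8.314462618
)
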