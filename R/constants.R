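#' Physical constants used throughout the package
#'
#' CODATA 2018 values (the SI redefinition made several of these exact).
#' All electrostatics in the package is done in SI internally; lengths at the
#' user interface are in nanometres and concentrations in mol/L.
#'
#' @return A named list with elements
#'   \describe{
#'     \item{faraday_F}{Faraday constant, C/mol.}
#'     \item{elementary_charge_e}{Elementary charge, C.}
#'     \item{vacuum_permittivity_eps0}{Vacuum permittivity, F/m.}
#'     \item{avogadro_NA}{Avogadro constant, 1/mol.}
#'     \item{boltzmann_kB}{Boltzmann constant, J/K.}
#'   }
#' @examples
#' constants()$faraday_F
#' @export
constants <- function() {
  list(
    faraday_F = 96485.33212,
    elementary_charge_e = 1.602176634e-19,
    vacuum_permittivity_eps0 = 8.8541878128e-12,
    avogadro_NA = 6.02214076e23,
    boltzmann_kB = 1.380649e-23
  )
}

# internal shorthand; avoids repeated list construction in hot loops
.const <- list(
  F = 96485.33212,
  e = 1.602176634e-19,
  eps0 = 8.8541878128e-12,
  NA_ = 6.02214076e23,
  kB = 1.380649e-23
)
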