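## Physical constants in the package-wide unit system: eV, nm, fs, K.

#' Physical constants used throughout the package
#'
#' All internal computations use electronvolts, nanometres and femtoseconds.
#' In these units the electron mass is \eqn{m_e c^2 / c^2} with
#' \eqn{c = 299.792458} nm/fs, the Boltzmann constant is in eV/K, and the
#' Coulomb constant \eqn{e^2/(4\pi\varepsilon_0)} is in eV nm.
#'
#' @format A named list with elements
#' \describe{
#'   \item{m_e}{electron mass, eV fs^2 nm^-2 (5.685630)}
#'   \item{k_B}{Boltzmann constant, eV/K (8.617333e-5)}
#'   \item{k_coulomb}{Coulomb constant e^2/(4 pi eps0), eV nm (1.43996)}
#'   \item{c_light}{speed of light, nm/fs}
#'   \item{n_water}{molecular number density of liquid water at 1 g/cm^3,
#'     nm^-3 (33.43)}
#' }
#' @export
aq_constants <- list(
  m_e       = 510998.95 / 299.792458^2,  # 5.685630 eV fs^2 / nm^2
  k_B       = 8.617333e-5,
  k_coulomb = 1.43996,
  c_light   = 299.792458,
  n_water   = 33.43
)

## speed (nm/fs) of a non-relativistic electron of kinetic energy E (eV)
electron_speed <- function(E) sqrt(2 * E / aq_constants$m_e)
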