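#' Physical constants (CODATA 2018)
#'
#' Exact SI values fixed by the 2019 redefinition, plus derived factors used
#' throughout the package: the Coulomb conversion factor for charges in
#' elementary charge units and distances in angstroms, and the gas constant
#' in kcal units for free-energy arithmetic.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{e}{elementary charge, C}
#'   \item{N_A}{Avogadro constant, mol^-1}
#'   \item{k_B}{Boltzmann constant, J K^-1}
#'   \item{h}{Planck constant, J s}
#'   \item{eps0}{vacuum permittivity, F m^-1}
#'   \item{R_J}{molar gas constant, J mol^-1 K^-1}
#'   \item{R_kcal}{molar gas constant, kcal mol^-1 K^-1}
#'   \item{kJ_per_kcal}{thermochemical calorie conversion, 4.184}
#'   \item{f_coulomb}{Coulomb factor N_A e^2 / (4 pi eps0), in
#'     kJ mol^-1 A e^-2, approx 1389.3546}
#' }
#' @export
physical_constants <- local({
  e    <- 1.602176634e-19    # C (exact)
  N_A  <- 6.02214076e23      # 1/mol (exact)
  k_B  <- 1.380649e-23       # J/K (exact)
  h    <- 6.62607015e-34     # J s (exact)
  eps0 <- 8.8541878128e-12   # F/m (CODATA 2018)
  R_J  <- k_B * N_A
  # N_A e^2/(4 pi eps0): J m / mol -> kJ mol^-1 A e^-2 (x 1e10 / 1e3)
  f_coulomb <- N_A * e^2 / (4 * pi * eps0) * 1e10 / 1e3
  list(e = e, N_A = N_A, k_B = k_B, h = h, eps0 = eps0,
       R_J = R_J, R_kcal = R_J / 4184, kJ_per_kcal = 4.184,
       f_coulomb = f_coulomb)
})
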