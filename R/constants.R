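#' Physical constants used throughout the package
#'
#' CODATA 2018 values for the constants entering the Eyring equation and the
#' thermal-polarization formula, plus gyromagnetic ratios of the nuclei
#' relevant to SABRE.
#'
#' @return A named list with elements
#'   `k_B` (Boltzmann constant, J/K), `h` (Planck constant, J s),
#'   `hbar` (reduced Planck constant, J s), `R_gas` (molar gas constant,
#'   J mol^-1 K^-1), `gamma_1H` and `gamma_15N` (gyromagnetic ratios,
#'   rad s^-1 T^-1; gamma_15N is negative), and `B0_default`
#'   (default magnetic field, T).
#' @examples
#' physical_constants()$k_B
#' @export
physical_constants <- function() {
  list(
    k_B = 1.380649e-23,
    h = 6.62607015e-34,
    hbar = 1.054571817e-34,
    R_gas = 8.314462618,
    gamma_1H = 2.6752218744e8,
    gamma_15N = -2.71261804e7,
    B0_default = 9.4
  )
}
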