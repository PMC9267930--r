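#' Unit conversion constants
#'
#' The engine works internally in Hartree atomic units (length in bohr,
#' energy in hartree, mass in electron masses, time in units of
#' \eqn{\hbar/E_h \approx 24.19} attoseconds), which removes all constants
#' from Coulomb's law.  Configuration and reports use the field's customary
#' units: angstrom, eV, femtoseconds and attoseconds.  This function returns
#' the fixed conversion constants used throughout.
#'
#' @return Named list of conversion constants:
#'   \describe{
#'     \item{bohr_A}{length of 1 bohr in angstrom}
#'     \item{hartree_eV}{1 hartree in eV}
#'     \item{au_time_fs}{1 atomic time unit in femtoseconds}
#'     \item{as_au}{1 attosecond in atomic time units (about 0.041341)}
#'     \item{amu_me}{1 unified atomic mass unit in electron masses}
#'   }
#' @export
#' @examples
#' raddyn_units()$as_au   # the default 1-as timestep in atomic units
raddyn_units <- function() {
  list(
    bohr_A     = 0.529177210903,
    hartree_eV = 27.211386245988,
    au_time_fs = 0.024188843265857,
    as_au      = 1e-3 / 0.024188843265857,
    amu_me     = 1822.888486209
  )
}

.u <- raddyn_units()

angstrom_to_bohr <- function(x) x / .u$bohr_A
bohr_to_angstrom <- function(x) x * .u$bohr_A
ev_to_hartree    <- function(x) x / .u$hartree_eV
hartree_to_ev    <- function(x) x * .u$hartree_eV
fs_to_au         <- function(x) x / .u$au_time_fs
au_to_fs         <- function(x) x * .u$au_time_fs
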