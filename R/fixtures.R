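#' Deterministic random-plasma test fixture
#'
#' Generates a partially ionized water-composition plasma with exact ion and
#' electron counts at a configurable composition ratio (defaults: 21% ions,
#' 29% free electrons of the atom count, the proportion shared by the
#' packaged presets).  Atom positions are uniform in a cube whose side
#' keeps the atom number density at the liquid-water value (about 0.0148
#' atoms/bohr^3) so that scaling ladders hold the density fixed; electron
#' speeds are Maxwellian.  A pure function of its arguments: the same seed
#' reproduces the state byte for byte.
#'
#' @param n_atoms Total atoms + ions Na.
#' @param ion_fraction,electron_fraction Fractions of `n_atoms` receiving a
#'   charge state and becoming free electrons; counts are rounded to exact
#'   integers and the charge-state distribution makes the net charge zero.
#' @param side_bohr Cube side; `NULL` derives it from the water density.
#' @param temp_eV Maxwellian temperature parameter for electrons (eV).
#' @param atom_temp_eV Temperature for atom velocities (eV); 0 leaves the
#'   atoms cold.
#' @param seed Integer seed.
#' @param tables Rate tables.
#' @return A `raddyn_state` with exactly the requested counts and net
#'   charge zero.
#' @export
#' @examples
#' st <- make_plasma(1000, seed = 42)
#' state_counts(st)   # Ni = 210, Ne = 290
make_plasma <- function(n_atoms, ion_fraction = 0.21,
                        electron_fraction = 0.29, side_bohr = NULL,
                        temp_eV = 10, atom_temp_eV = 0, seed = 1,
                        tables = load_rate_tables()) {
  stopifnot(n_atoms >= 1,
            ion_fraction >= 0, ion_fraction <= 1,
            electron_fraction >= 0, electron_fraction <= 1)
  u <- raddyn_units()
  set.seed(seed)
  ni <- as.integer(round(n_atoms * ion_fraction))
  ne <- as.integer(round(n_atoms * electron_fraction))
  if (ne < ni && ni > 0)
    stop("infeasible fractions: fewer electrons than ions")
  if (is.null(side_bohr)) {
    dens <- 3 * water_molecule_count(100, 0.997) / (100 / u$bohr_A)^3
    side_bohr <- (n_atoms / dens)^(1 / 3)
  }
  nO <- as.integer(round(n_atoms / 3))
  elem <- c(rep("O", nO), rep("H", n_atoms - nO))
  apos <- matrix(stats::runif(3 * n_atoms, 0, side_bohr), n_atoms, 3)
  avel <- if (atom_temp_eV > 0) {
    kT <- atom_temp_eV / u$hartree_eV
    matrix(stats::rnorm(3 * n_atoms), n_atoms, 3) *
      sqrt(kT / .element_masses(elem, tables))
  } else NULL
  st <- system_state(elem, apos = apos, avel = avel, tables = tables)
  attr(st, "side_bohr") <- side_bohr
  if (ni > 0) {
    spec <- sample_spec(side_bohr * u$bohr_A, n_atoms = n_atoms, n_ions = ni,
                        n_electrons = ne, temp_eV = temp_eV, seed = seed)
    st <- pre_ionize(st, spec, tables)
  }
  st
}
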