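#' Water-sample specification
#'
#' @param side_A Cube edge in angstrom.
#' @param density Mass density in g/cm^3, default 0.997 (liquid water).
#' @param n_atoms,n_ions,n_electrons Optional exact target counts.  When
#'   given, the generator hits exactly those counts (exact-count mode,
#'   trimming/padding the formula-derived molecule count) and assigns a
#'   charge-state distribution summing to `n_electrons` so the net charge
#'   is zero.
#' @param temp_eV Temperature parameter of the Maxwellian free-electron
#'   speeds (eV), default 10.
#' @param seed Integer seed; the generated state is a pure function of
#'   (spec, seed).
#' @return List of class `raddyn_sample_spec`.
#' @export
sample_spec <- function(side_A, density = 0.997, n_atoms = NULL,
                        n_ions = NULL, n_electrons = NULL,
                        temp_eV = 10, seed = 1) {
  stopifnot(side_A > 0)
  if (density <= 0) stop("density must be positive")
  if (!is.null(n_ions) && !is.null(n_atoms) && n_ions > n_atoms)
    stop("configuration error: n_ions exceeds n_atoms")
  structure(list(side_A = side_A, density = density, n_atoms = n_atoms,
                 n_ions = n_ions, n_electrons = n_electrons,
                 temp_eV = temp_eV, seed = as.integer(seed)),
            class = "raddyn_sample_spec")
}

#' Number of water molecules from the density formula
#'
#' \eqn{\lfloor \rho V N_A / M_{H_2O} \rfloor} with V the cube volume.
#'
#' @param side_A Cube edge (angstrom).
#' @param density Mass density (g/cm^3).
#' @return Integer molecule count.
#' @export
water_molecule_count <- function(side_A, density = 0.997) {
  NA_ <- 6.02214076e23
  M <- 18.01528
  V_cm3 <- (side_A * 1e-8)^3
  as.integer(floor(density * V_cm3 * NA_ / M))
}

#' Build a neutral water cube
#'
#' Places the molecules (O with two H at 0.96 angstrom and 104.5 degrees,
#' random orientation) on a jittered cubic lattice inside the cube, with
#' zero initial velocities.  Without target counts the molecule number comes
#' from [water_molecule_count()]; in exact-count mode the molecule count is
#' padded to ceiling(n_atoms / 3) and trailing hydrogens are trimmed so the
#' atom count is exact.  Deterministic given the spec's seed.
#'
#' @param spec A [sample_spec()].
#' @param tables Rate tables.
#' @return A neutral `raddyn_state` with attribute `"side_bohr"`.
#' @export
#' @examples
#' st <- build_water_cube(sample_spec(12, seed = 7))
#' state_counts(st)
build_water_cube <- function(spec, tables = load_rate_tables()) {
  u <- raddyn_units()
  set.seed(spec$seed)
  if (is.null(spec$n_atoms)) {
    n_mol <- water_molecule_count(spec$side_A, spec$density)
    n_atoms <- 3L * n_mol
  } else {
    n_atoms <- as.integer(spec$n_atoms)
    n_mol <- as.integer(ceiling(n_atoms / 3))
  }
  if (n_mol < 1) stop("cube too small: no molecules fit")
  side <- spec$side_A / u$bohr_A
  m <- ceiling(n_mol^(1 / 3))
  sp <- side / m
  grid <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m), z = seq_len(m)))
  grid <- grid[seq_len(n_mol), , drop = FALSE]
  # jitter amplitude keeps worst-case intermolecular contacts above ~0.5 A
  centers <- (grid - 0.5) * sp +
    matrix(stats::runif(3 * n_mol, -0.08 * sp, 0.08 * sp), n_mol, 3)
  roh <- 0.96 / u$bohr_A
  half <- (104.5 / 2) * pi / 180
  elem <- character(3 * n_mol)
  pos <- matrix(0, 3 * n_mol, 3)
  for (i in seq_len(n_mol)) {
    R <- .random_rotation()
    h1 <- roh * c(sin(half), 0, cos(half))
    h2 <- roh * c(-sin(half), 0, cos(half))
    base <- 3 * (i - 1)
    elem[base + 1:3] <- c("O", "H", "H")
    pos[base + 1, ] <- centers[i, ]
    pos[base + 2, ] <- centers[i, ] + as.vector(R %*% h1)
    pos[base + 3, ] <- centers[i, ] + as.vector(R %*% h2)
  }
  if (nrow(pos) > n_atoms) {                # exact-count trim (H atoms last)
    drop <- seq(n_atoms + 1, nrow(pos))
    pos <- pos[-drop, , drop = FALSE]
    elem <- elem[-drop]
  }
  st <- system_state(elem, apos = pos, tables = tables)
  attr(st, "side_bohr") <- side
  st
}

.random_rotation <- function() {
  # uniform random rotation from a random axis-angle pair
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Pre-ionize a sample to exact target counts
#'
#' Gives exactly `n_ions` atoms a charge state >= 1 with the minimal
#' charge-state distribution summing to `n_electrons` (as many +1 as
#' possible, the remainder one charge higher; multiply-charged states are
#' assigned to oxygen, since hydrogen can donate only one electron), strips
#' the corresponding electrons from the outermost orbitals, and places
#' `n_electrons` free electrons uniformly in the cube with Maxwellian
#' speeds.  The resulting net charge is exactly zero.
#'
#' @param state A neutral state from [build_water_cube()].
#' @param spec The [sample_spec()] carrying the target counts.
#' @param tables Rate tables.
#' @return The pre-ionized `raddyn_state`.
#' @export
pre_ionize <- function(state, spec, tables = load_rate_tables()) {
  if (is.null(spec$n_ions) || spec$n_ions == 0) {
    if (!is.null(spec$n_electrons) && spec$n_electrons > 0)
      stop("configuration error: free electrons require ions for net charge 0")
    return(state)
  }
  set.seed(spec$seed + 1L)
  u <- raddyn_units()
  na <- length(state$element)
  ni <- as.integer(spec$n_ions)
  ne <- as.integer(spec$n_electrons)
  if (ni > na) stop("configuration error: more ions than atoms")
  if (ne < ni) stop("configuration error: fewer electrons than ions (charge >= 1 each)")
  base <- ne %/% ni
  extra <- ne %% ni
  qs <- c(rep(base + 1L, extra), rep(base, ni - extra))
  strippable <- state$nel0
  need_multi <- sum(qs >= 2L)
  O_idx <- which(state$element == "O")
  if (need_multi > length(O_idx))
    stop("configuration error: charge-state distribution needs more oxygen atoms")
  pick_multi <- if (need_multi > 0) sample(O_idx, need_multi) else integer(0)
  rest_pool <- setdiff(seq_len(na), pick_multi)
  pick_single <- if (ni - need_multi > 0) sample(rest_pool, ni - need_multi) else integer(0)
  ions <- c(pick_multi, pick_single)
  if (any(qs > strippable[ions]))
    stop("configuration error: charge state exceeds strippable electrons")
  for (j in seq_along(ions)) {
    a <- ions[j]
    left <- qs[j]
    for (k in rev(seq_len(ncol(state$occ)))) {
      take <- min(left, state$occ[a, k])
      state$occ[a, k] <- state$occ[a, k] - take
      left <- left - take
      if (left == 0L) break
    }
  }
  state$charge <- as.integer(state$nel0 - rowSums(state$occ))
  side <- attr(state, "side_bohr")
  if (is.null(side)) side <- spec$side_A / u$bohr_A
  state$epos <- matrix(stats::runif(3 * ne, 0, side), ne, 3)
  kT_au <- spec$temp_eV / u$hartree_eV
  state$evel <- matrix(stats::rnorm(3 * ne, sd = sqrt(kT_au)), ne, 3)
  state$force_cache <- NULL
  state
}

#' Packaged water-sample presets
#'
#' Named presets for five cube sizes with exact (atoms & ions, ions, free
#' electrons) target triples sharing a common electron/atom proportion, the
#' configuration family used for the solver-scaling studies.
#'
#' @return data.frame with columns `name`, `side_A`, `atoms`, `ions`,
#'   `electrons`.
#' @export
water_presets <- function() {
  data.frame(
    name = c("47A", "60A", "75A", "100A", "150A"),
    side_A = c(47, 60, 75, 100, 150),
    atoms = c(9722L, 20534L, 40358L, 97655L, 328475L),
    ions = c(2102L, 4422L, 8717L, 21087L, 67828L),
    electrons = c(2806L, 5881L, 11603L, 28084L, 87369L)
  )
}

#' Build a preset sample
#'
#' @param name One of `"47A"`, `"60A"`, `"75A"`, `"100A"`, `"150A"`.
#' @param seed Integer seed.
#' @param temp_eV Electron temperature parameter (eV).
#' @param tables Rate tables.
#' @return A pre-ionized `raddyn_state` with the preset's exact counts.
#' @export
#' @examples
#' st <- build_preset("47A", seed = 1)
#' state_counts(st)     # Na = 9722, Ni = 2102, Ne = 2806
#' total_charge(st)     # 0
build_preset <- function(name, seed = 1, temp_eV = 10,
                         tables = load_rate_tables()) {
  pr <- water_presets()
  row <- pr[pr$name == name, ]
  if (nrow(row) != 1) stop("unknown preset '", name, "'")
  spec <- sample_spec(row$side_A, n_atoms = row$atoms, n_ions = row$ions,
                      n_electrons = row$electrons, temp_eV = temp_eV,
                      seed = seed)
  pre_ionize(build_water_cube(spec, tables), spec, tables)
}
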