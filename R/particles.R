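#' Construct a system state
#'
#' A `raddyn_state` holds every classical particle: atoms/ions with their
#' per-orbital electron occupations, and quasi-free electrons (mass 1,
#' charge -1 in atomic units).  An ion's charge state is always re-derivable
#' as (neutral electron count) - (current occupation sum); the constructor
#' enforces that identity and the per-orbital capacity bounds.
#'
#' All positions are in bohr, velocities in bohr per atomic time unit,
#' masses in electron masses, time in atomic time units.
#'
#' @param element Character vector of element symbols, one per atom/ion.
#' @param apos,avel Numeric Na x 3 matrices: atom positions and velocities.
#' @param epos,evel Numeric Ne x 3 matrices: free-electron positions and
#'   velocities (possibly zero rows).
#' @param occ Optional Na x K integer matrix of orbital occupations; defaults
#'   to the neutral occupations from `tables`.
#' @param tables Rate tables (see [load_rate_tables()]).
#' @param time Simulation clock in atomic time units.
#' @return Object of class `raddyn_state`.
#' @export
#' @examples
#' tb <- load_rate_tables()
#' st <- system_state(c("O", "H", "H"),
#'                    apos = rbind(c(0, 0, 0), c(1.8, 0, 0), c(-0.5, 1.7, 0)),
#'                    tables = tb)
#' state_counts(st)
system_state <- function(element, apos, avel = NULL,
                         epos = NULL, evel = NULL,
                         occ = NULL, tables = load_rate_tables(),
                         time = 0) {
  apos <- as_mat3(apos, length(element), "apos")
  na <- nrow(apos)
  if (is.null(avel)) avel <- matrix(0, na, 3) else avel <- as_mat3(avel, na, "avel")
  if (is.null(epos)) epos <- matrix(0, 0, 3) else epos <- as_mat3(epos, NULL, "epos")
  ne <- nrow(epos)
  if (is.null(evel)) evel <- matrix(0, ne, 3) else evel <- as_mat3(evel, ne, "evel")
  om <- .orbital_matrices(element, tables)
  if (is.null(occ)) occ <- om$occ
  storage.mode(occ) <- "integer"
  if (!identical(dim(occ), dim(om$occ)))
    stop("occ must be a ", na, " x ", om$K, " integer matrix")
  if (any(occ < 0) || any(occ > om$cap))
    stop("occupations must lie in [0, capacity] for every orbital")
  nel0 <- rowSums(om$occ)
  charge <- as.integer(nel0 - rowSums(occ))
  st <- list(
    element = element,
    apos = apos, avel = avel,
    amass = .element_masses(element, tables),
    charge = charge,
    occ = occ, cap = om$cap, bind = om$bind, sigma_ph = om$sigma_ph,
    nel0 = as.integer(nel0),
    epos = epos, evel = evel,
    time = time,
    force_cache = NULL
  )
  class(st) <- "raddyn_state"
  st
}

as_mat3 <- function(x, n, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(what, " must have 3 columns")
  if (!is.null(n) && nrow(x) != n) stop(what, " must have ", n, " rows")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Particle counts of a state
#'
#' Returns the bookkeeping counts: `Na` (atoms + ions), `Ni` (ions of
#' charge state 1 or higher), `Ne` (free electrons) and `Nq = Ni + Ne`
#' (charged classical particles; neutral atoms carry no Coulomb
#' interaction).
#'
#' @param state A `raddyn_state`.
#' @return Named list with `Na`, `Ni`, `Ne`, `Nq`.
#' @export
state_counts <- function(state) {
  ni <- sum(state$charge >= 1L)
  ne <- nrow(state$epos)
  list(Na = length(state$element), Ni = ni, Ne = ne, Nq = ni + ne)
}

#' Net charge of the system
#'
#' Sum of the atomic charge states minus the number of free electrons, in
#' units of the elementary charge.  Every block of the time loop conserves
#' this quantity: ionization creates an electron while incrementing a charge
#' state, recombination does the reverse.
#'
#' @param state A `raddyn_state`.
#' @return Integer total charge.
#' @export
total_charge <- function(state) {
  as.integer(sum(state$charge) - nrow(state$epos))
}

#' Kinetic and potential energy
#'
#' `kinetic_energy()` is \eqn{\sum \frac12 m v^2} over all classical
#' particles.  `potential_energy()` is the pairwise Coulomb energy of the
#' charged particles, \eqn{\sum_{i<j} q_i q_j / \sqrt{r_{ij}^2 +
#' \epsilon^2}}; with zero softening a coincident charged pair raises a
#' singular-configuration error.
#'
#' @param state A `raddyn_state`.
#' @param softening Plummer softening length in bohr (>= 0).
#' @return Energy in hartree.
#' @export
kinetic_energy <- function(state) {
  ka <- 0.5 * sum(state$amass * rowSums(state$avel^2))
  ke <- 0.5 * sum(rowSums(state$evel^2))   # electron mass = 1
  ka + ke
}

#' @rdname kinetic_energy
#' @export
potential_energy <- function(state, softening = 0) {
  cs <- charged_set(state)
  if (nrow(cs$pos) < 2) return(0)
  br <- cpp_brute_forces(cs$pos, cs$q, softening)
  0.5 * sum(cs$q * br$potential)
}

# Charged-particle subset: ions (charge >= 1) then electrons (q = -1), with
# index maps back into the state.  Neutral atoms are excluded.
charged_set <- function(state) {
  ion <- which(state$charge >= 1L)
  ne <- nrow(state$epos)
  pos <- rbind(state$apos[ion, , drop = FALSE], state$epos)
  q <- c(as.numeric(state$charge[ion]), rep(-1, ne))
  list(pos = pos, q = q, ion_idx = ion, n_ion = length(ion), n_e = ne)
}

#' @export
print.raddyn_state <- function(x, ...) {
  ct <- state_counts(x)
  cat(sprintf(
    "<raddyn_state> Na=%d (Ni=%d) Ne=%d | net charge %+d e | t = %.4f au (%.4f fs)\n",
    ct$Na, ct$Ni, ct$Ne, total_charge(x), x$time, au_to_fs(x$time)))
  invisible(x)
}

#' Read and write extended-XYZ snapshots
#'
#' Plain-text snapshot format: a count line, a comment line carrying the
#' simulation time, then one row per particle with columns
#' `species x y z vx vy vz charge`.  Atom rows use the element symbol; free
#' electrons use the species label `e`.  File units are angstrom and
#' angstrom/fs (converted from the internal atomic units on write).
#'
#' Occupations are not stored in the snapshot; on read they are reconstructed
#' from the charge state by stripping electrons from the outermost orbitals,
#' which matches how the sample generator assigns charge states.
#'
#' @param state A `raddyn_state`.
#' @param path File path.
#' @param tables Rate tables used to rebuild orbital bookkeeping on read.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` returns a
#'   `raddyn_state`.
#' @export
write_xyz <- function(state, path) {
  u <- raddyn_units()
  vconv <- u$bohr_A / u$au_time_fs          # bohr/au-time -> A/fs
  na <- length(state$element); ne <- nrow(state$epos)
  sp <- c(state$element, rep("e", ne))
  pos <- rbind(state$apos, state$epos) * u$bohr_A
  vel <- rbind(state$avel, state$evel) * vconv
  q <- c(state$charge, rep(-1L, ne))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(na + ne), con)
  writeLines(sprintf("time_fs=%.17g columns=species:x:y:z:vx:vy:vz:charge units=A,A/fs",
                     au_to_fs(state$time)), con)
  writeLines(sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g %d",
                     sp, pos[, 1], pos[, 2], pos[, 3],
                     vel[, 1], vel[, 2], vel[, 3], q), con)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path, tables = load_rate_tables()) {
  u <- raddyn_units()
  lines <- readLines(path)
  n <- as.integer(lines[1])
  tfs <- 0
  m <- regmatches(lines[2], regexec("time_fs=([-0-9.eE+]+)", lines[2]))[[1]]
  if (length(m) == 2) tfs <- as.numeric(m[2])
  f <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  sp <- vapply(f, `[`, character(1), 1)
  num <- t(vapply(f, function(r) as.numeric(r[2:8]), numeric(7)))
  is_e <- sp == "e"
  pos <- num[, 1:3, drop = FALSE] / u$bohr_A
  vel <- num[, 4:6, drop = FALSE] / (u$bohr_A / u$au_time_fs)
  q <- as.integer(num[, 7])
  elem <- sp[!is_e]
  om <- .orbital_matrices(elem, tables)
  occ <- om$occ
  for (i in which(q[!is_e] > 0L)) {
    left <- q[!is_e][i]
    for (k in rev(seq_len(ncol(occ)))) {
      take <- min(left, occ[i, k])
      occ[i, k] <- occ[i, k] - take
      left <- left - take
      if (left == 0L) break
    }
    if (left > 0L) stop("snapshot charge state exceeds strippable electrons")
  }
  system_state(elem,
               apos = pos[!is_e, , drop = FALSE],
               avel = vel[!is_e, , drop = FALSE],
               epos = pos[is_e, , drop = FALSE],
               evel = vel[is_e, , drop = FALSE],
               occ = occ, tables = tables, time = fs_to_au(tfs))
}
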