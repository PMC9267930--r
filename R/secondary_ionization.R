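#' Secondary-ionization configuration
#'
#' The SI block analyses every free electron against the atoms/ions for an
#' impact-ionization event.  Two interchangeable implementations ship:
#' `"brute"` scans all atoms per electron (exactly `Ne * Na` distance
#' evaluations per step) and `"tree"` queries a per-step oct-tree
#' (`O(Ne log Na)`).  Their event lists and post-states are bit-wise
#' identical by construction: the decision is a deterministic geometric
#' criterion, both implementations share the same distance kernel and
#' tie-break, and the emission direction comes from a keyed per-event
#' counter RNG rather than a shared stream.
#'
#' @param implementation `"tree"` or `"brute"`.
#' @param lotz_a Cross-section model constant a (bohr^2 eV^2); `NULL` takes
#'   the value from the rate tables.
#' @param max_depth Octree depth for the tree implementation.
#' @return List of class `raddyn_si_config`.
#' @export
si_config <- function(implementation = c("tree", "brute"), lotz_a = NULL,
                      max_depth = 10) {
  implementation <- match.arg(implementation)
  structure(list(implementation = implementation, lotz_a = lotz_a,
                 max_depth = as.integer(max_depth)),
            class = "raddyn_si_config")
}

#' Electron-impact ionization cross section (Lotz form)
#'
#' \deqn{\sigma(E) = a N \ln(E/B) / (E B)} for `E > B`, zero at and below
#' the threshold `B` (continuous at threshold); `N` is the orbital
#' occupation.  The maximum lies at `E = e * B` with value `a N / (e B^2)`.
#'
#' @param E_eV Relative kinetic energy of the impacting electron (eV), i.e.
#'   its kinetic energy in the target's rest frame.
#' @param binding_eV Orbital binding energy B > 0 (eV).
#' @param occupation Orbital electron count N >= 0.
#' @param a Model constant (bohr^2 eV^2), default the Lotz constant of the
#'   packaged tables.
#' @return Cross section in bohr^2.
#' @export
impact_cross_section <- function(E_eV, binding_eV, occupation,
                                 a = load_rate_tables()$lotz_a) {
  stopifnot(all(E_eV >= 0), binding_eV > 0, occupation >= 0)
  ifelse(E_eV > binding_eV,
         a * occupation * log(E_eV / binding_eV) / (E_eV * binding_eV),
         0)
}

#' Cutoff radius of the SI pre-assessment
#'
#' The nearest-target search is limited to the radius of the disc whose area
#' is the largest cross section over the orbital set at the given energy:
#' \eqn{r_{cut} = \sqrt{\max_k \sigma_k(E) / \pi}}; zero when every cross
#' section vanishes.
#'
#' @param E_eV Electron kinetic energy (eV).
#' @param orbitals data.frame with columns `binding_eV` and `occupation`
#'   (or `capacity`); defaults to all orbitals of the packaged tables at
#'   full capacity, the target-independent bound used for the search.
#' @param a Cross-section constant.
#' @param tables Rate tables (used for the default orbital set and `a`).
#' @return Radius in bohr.
#' @export
si_cutoff <- function(E_eV, orbitals = NULL, tables = load_rate_tables(),
                      a = tables$lotz_a) {
  if (is.null(orbitals)) {
    g <- .global_orbitals(tables)
    orbitals <- data.frame(binding_eV = g$B, occupation = g$N)
  }
  if (is.null(orbitals$occupation)) orbitals$occupation <- orbitals$capacity
  vapply(E_eV, function(E) {
    smax <- max(c(0, mapply(function(B, N) impact_cross_section(E, B, N, a),
                            orbitals$binding_eV, orbitals$occupation)))
    if (smax > 0) sqrt(smax / pi) else 0
  }, numeric(1))
}

#' Evaluate one electron-target pair for secondary ionization
#'
#' The deterministic SI criterion (no random draw): an event occurs iff the
#' pair distance is within the cutoff at the relative energy, the relative
#' energy reaches the smallest occupied binding, and (in the block) the
#' target is the electron's nearest atom/ion within the search radius.  The
#' ionized orbital is the occupied orbital with the largest cross section at
#' the relative energy.  The relative energy is the electron kinetic energy
#' in the target's rest frame, \eqn{\frac12 |v_e - v_a|^2} (atomic units).
#'
#' @param e_pos,e_vel Electron position/velocity (length 3, atomic units).
#' @param a_pos,a_vel Target position/velocity.
#' @param occ,bind Integer/numeric vectors over the target's orbitals:
#'   occupations and binding energies (eV); zero-capacity padding allowed.
#' @param a Cross-section constant (bohr^2 eV^2).
#' @return `NULL` if no event, else a list with `orbital`, `E_rel_eV`,
#'   `distance`.
#' @export
evaluate_pair <- function(e_pos, e_vel, a_pos, a_vel, occ, bind,
                          a = load_rate_tables()$lotz_a) {
  u <- raddyn_units()
  d <- sqrt(sum((e_pos - a_pos)^2))
  vrel2 <- sum((e_vel - a_vel)^2)
  E_rel <- 0.5 * vrel2 * u$hartree_eV
  sig <- numeric(length(occ))
  for (k in seq_along(occ))
    if (occ[k] > 0 && bind[k] > 0)
      sig[k] <- impact_cross_section(E_rel, bind[k], occ[k], a)
  if (max(sig) <= 0) return(NULL)
  if (d > sqrt(max(sig) / pi)) return(NULL)
  list(orbital = which.max(sig), E_rel_eV = E_rel, distance = d)
}

#' Run the secondary-ionization block
#'
#' Electrons are processed in ascending index order against the pre-block
#' atom snapshot.  Per event: the target's occupation drops by 1 and its
#' charge state rises by 1; the primary electron keeps
#' `E_rel - B - E_sec` (redirected along the relative velocity in the
#' target frame) and a new electron with `E_sec = min(0.1 (E_rel - B),
#' 10 eV)` is emitted isotropically from a keyed per-event RNG, placed
#' 0.5 bohr from the target.  Brute and tree implementations produce
#' bit-wise identical event lists and post-states.
#'
#' @param state A `raddyn_state`.
#' @param config A [si_config()].
#' @param step Step number (keys the per-event RNG together with `seed`).
#' @param seed Integer seed keying the per-event RNG.
#' @param tables Rate tables.
#' @return List with `state`, `events` (data.frame: step, electron, target,
#'   orbital) and `counters` (`dist_evals`, `box_tests`).
#' @export
si_block <- function(state, config = si_config(), step = 0L, seed = 0L,
                     tables = load_rate_tables()) {
  g <- .global_orbitals(tables)
  a_const <- if (is.null(config$lotz_a)) tables$lotz_a else config$lotz_a
  res <- cpp_si_block(state$apos, state$avel,
                      state$occ, state$bind, state$cap, state$charge,
                      state$epos, state$evel,
                      g$B, g$N, a_const,
                      config$implementation == "tree", config$max_depth,
                      as.integer(step), as.double(seed))
  state$occ <- res$occ
  state$charge <- res$charge
  state$evel <- res$evel
  if (nrow(res$new_epos)) {
    state$epos <- rbind(state$epos, res$new_epos)
    state$evel <- rbind(state$evel, res$new_evel)
    state$force_cache <- NULL
  }
  events <- as.data.frame(res$events)
  names(events) <- c("step", "electron", "target", "orbital")
  list(state = state, events = events,
       counters = c(dist_evals = res$dist_evals, box_tests = res$box_tests))
}
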