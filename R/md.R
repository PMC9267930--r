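#' Integrator configuration
#'
#' @param dt_as Timestep in attoseconds; the default 1 as converts to about
#'   0.041341 atomic time units.
#' @return List with `dt_as` and `dt_au`.
#' @export
integrator_config <- function(dt_as = 1) {
  stopifnot(dt_as > 0)
  list(dt_as = dt_as, dt_au = dt_as * raddyn_units()$as_au)
}

#' One velocity-Verlet step
#'
#' Symplectic second-order propagation of every classical particle:
#' \eqn{x \leftarrow x + v\,dt + \frac12 a\,dt^2}, forces recomputed at the
#' new positions, then \eqn{v \leftarrow v + \frac12 (a + a')\,dt}.  Neutral
#' atoms feel zero Coulomb force and drift ballistically.  The end-of-step
#' forces are cached on the state and reused as the next step's start-of-step
#' forces whenever the particle lists have not been mutated in between.
#'
#' @param state A `raddyn_state`.
#' @param dt Timestep in atomic time units.
#' @param force_provider Function `state -> list(Fa, Fe, pair_evals)`;
#'   defaults to the configured Coulomb solver via [coulomb_config()].
#' @return The propagated state (time advanced by `dt`).  Attribute
#'   `"pair_evals"` carries the force-evaluation work of the step.
#' @export
#' @examples
#' tb <- load_rate_tables()
#' st <- system_state("O", apos = matrix(0, 1, 3), avel = matrix(1, 1, 3),
#'                    tables = tb)
#' st2 <- velocity_verlet_step(st, dt = 0.1)
#' st2$apos  # pure drift: x = v * dt
velocity_verlet_step <- function(state, dt,
                                 force_provider = make_force_provider()) {
  stopifnot(dt > 0)
  f0 <- state$force_cache
  evals <- 0
  if (is.null(f0) || nrow(f0$Fa) != length(state$element) ||
      nrow(f0$Fe) != nrow(state$epos)) {
    f0 <- force_provider(state)
    evals <- evals + f0$pair_evals
  }
  check_finite_forces(f0)
  aa <- f0$Fa / state$amass
  ae <- f0$Fe                                  # electron mass = 1
  state$apos <- state$apos + state$avel * dt + 0.5 * aa * dt^2
  state$epos <- state$epos + state$evel * dt + 0.5 * ae * dt^2
  f1 <- force_provider(state)
  evals <- evals + f1$pair_evals
  check_finite_forces(f1)
  state$avel <- state$avel + 0.5 * (aa + f1$Fa / state$amass) * dt
  state$evel <- state$evel + 0.5 * (ae + f1$Fe) * dt
  state$time <- state$time + dt
  state$force_cache <- f1
  attr(state, "pair_evals") <- evals
  state
}

check_finite_forces <- function(f) {
  if (!all(is.finite(f$Fa))) {
    bad <- which(!is.finite(rowSums(f$Fa)))[1]
    stop("propagation error: non-finite force on atom ", bad)
  }
  if (!all(is.finite(f$Fe))) {
    bad <- which(!is.finite(rowSums(f$Fe)))[1]
    stop("propagation error: non-finite force on electron ", bad)
  }
}

#' Force provider from a Coulomb configuration
#'
#' @param config A [coulomb_config()].
#' @return Function mapping a state to `list(Fa, Fe, pair_evals)`.
#' @export
make_force_provider <- function(config = coulomb_config()) {
  function(state) state_forces(state, config)
}

#' Total momentum of a state
#'
#' @param state A `raddyn_state`.
#' @return Length-3 numeric vector (atomic units).
#' @export
total_momentum <- function(state) {
  colSums(state$avel * state$amass) + colSums(state$evel)
}
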