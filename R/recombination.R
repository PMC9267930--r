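#' Recombination configuration
#'
#' The RE block detects electron-ion pairs satisfying a classical capture
#' condition and merges them: the electron is removed, the ion's charge
#' drops by 1 and the outermost open orbital gains one electron (the exact
#' inverse of the ionization bookkeeping).
#'
#' @param capture_radius Capture radius r_rec in bohr (> 0), default 2.
#' @param implementation `"tree"` (oct-tree over the ions only) or
#'   `"brute"` (scan all ions per electron).
#' @param max_depth Octree depth for the tree implementation.
#' @return List of class `raddyn_re_config`.
#' @export
re_config <- function(capture_radius = 2, implementation = c("tree", "brute"),
                      max_depth = 10) {
  implementation <- match.arg(implementation)
  stopifnot(capture_radius > 0)
  structure(list(capture_radius = capture_radius,
                 implementation = implementation,
                 max_depth = as.integer(max_depth)),
            class = "raddyn_re_config")
}

#' Evaluate one electron-ion pair for recombination
#'
#' Capture iff (i) the pair distance is within the capture radius, (ii) the
#' pair is classically bound, \eqn{\frac12 m_{red} v_{rel}^2 - q_{ion}/r <
#' 0}, and (in the block) (iii) the ion is the electron's nearest ion within
#' the radius.
#'
#' @param e_pos,e_vel Electron position/velocity (atomic units).
#' @param i_pos,i_vel Ion position/velocity.
#' @param q_ion Ion charge state (>= 1).
#' @param mass_ion Ion mass in electron masses.
#' @param capture_radius Capture radius (bohr).
#' @return Logical: does the pair recombine?
#' @export
evaluate_recombination <- function(e_pos, e_vel, i_pos, i_vel, q_ion,
                                   mass_ion, capture_radius = 2) {
  stopifnot(q_ion >= 1)
  r <- sqrt(sum((e_pos - i_pos)^2))
  if (r > capture_radius) return(FALSE)
  if (r == 0) return(TRUE)
  mred <- mass_ion / (1 + mass_ion)
  vrel2 <- sum((e_vel - i_vel)^2)
  (0.5 * mred * vrel2 - q_ion / r) < 0
}

#' Run the recombination block
#'
#' Electrons in ascending index order against the pre-block ion snapshot; at
#' most one capture per ion per step (the first claiming electron wins; a
#' later electron whose nearest ion is taken gets no event).  The captured
#' electron's kinetic energy is dropped from the classical ledger and
#' reported as `energy_discarded` (no photon emission is modelled).  Brute
#' and tree implementations are bit-wise identical.
#'
#' @param state A `raddyn_state`.
#' @param config An [re_config()].
#' @param step Step number recorded in the event log.
#' @return List with `state`, `events` (data.frame: step, electron, ion),
#'   `energy_discarded` (hartree), `n_ions` and `counters`.
#' @export
re_block <- function(state, config = re_config(), step = 0L) {
  res <- cpp_re_block(state$apos, state$avel, state$amass,
                      state$occ, state$cap, state$charge,
                      state$epos, state$evel,
                      config$capture_radius,
                      config$implementation == "tree", config$max_depth,
                      as.integer(step))
  state$occ <- res$occ
  state$charge <- res$charge
  if (any(res$removed)) {
    keep <- !res$removed
    state$epos <- state$epos[keep, , drop = FALSE]
    state$evel <- state$evel[keep, , drop = FALSE]
    state$force_cache <- NULL
  }
  events <- as.data.frame(res$events)
  names(events) <- c("step", "electron", "ion")
  list(state = state, events = events,
       energy_discarded = res$energy_discarded,
       n_ions = res$n_ions,
       counters = c(dist_evals = res$dist_evals, box_tests = res$box_tests))
}
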