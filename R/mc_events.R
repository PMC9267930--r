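#' Pulse configuration
#'
#' Gaussian temporal envelope of the X-ray pulse.  The simulation clock
#' starts at the pulse center by default (`t0 = 0`), so step k samples the
#' envelope at `t = t0 + k * dt`.
#'
#' @param photon_energy_eV Photon energy, default 7120 eV (7.12 keV).
#' @param fluence Time-integrated flux, photons per square micrometer;
#'   default 3.5e12.
#' @param fwhm_fs Full width at half maximum of the envelope, default 15 fs.
#' @param t0_fs Pulse-center time, default 0.
#' @return List of class `raddyn_pulse`.
#' @export
pulse_config <- function(photon_energy_eV = 7120, fluence = 3.5e12,
                         fwhm_fs = 15, t0_fs = 0) {
  stopifnot(fluence >= 0, fwhm_fs > 0, photon_energy_eV > 0)
  structure(list(photon_energy_eV = photon_energy_eV, fluence = fluence,
                 fwhm_fs = fwhm_fs, t0_fs = t0_fs),
            class = "raddyn_pulse")
}

#' Instantaneous photon flux of the Gaussian pulse
#'
#' \deqn{\Phi(t) = F \cdot \frac{2\sqrt{\ln 2/\pi}}{\mathrm{fwhm}}
#'   \exp\!\left(-4 \ln 2 \, (t - t_0)^2 / \mathrm{fwhm}^2\right)}
#' normalized so the time integral equals the fluence `F`, with
#' half-maximum at `t0 +/- fwhm/2`.
#'
#' @param t_fs Time(s) in fs.
#' @param pulse A [pulse_config()].
#' @return Flux in photons/(um^2 fs).
#' @export
#' @examples
#' p <- pulse_config()
#' gaussian_flux(0, p) / gaussian_flux(7.5, p)   # = 2 at the half-maximum
gaussian_flux <- function(t_fs, pulse) {
  peak <- pulse$fluence * 2 * sqrt(log(2) / pi) / pulse$fwhm_fs
  peak * exp(-4 * log(2) * (t_fs - pulse$t0_fs)^2 / pulse$fwhm_fs^2)
}

# Per-atom channel probability matrix for one timestep.  Channels, in order:
# photoionization per orbital (K columns), Auger, fluorescence.  Per-orbital
# photo cross sections scale with the current occupation; channels of empty
# orbitals vanish.  Decay channels require a 1s hole and enough outer
# electrons (2 for Auger, 1 for fluorescence).
.mc_channel_probs <- function(state, tables, pulse, dt_fs, t_fs) {
  MB_UM2 <- 1e-10                     # 1 Mb = 1e-18 cm^2 = 1e-10 um^2
  flux <- gaussian_flux(t_fs, pulse)
  K <- ncol(state$occ)
  occ0 <- .orbital_matrices(state$element, tables)$occ
  frac <- ifelse(occ0 > 0, state$occ / occ0, 0)
  photo <- state$sigma_ph * frac * MB_UM2 * flux * dt_fs
  # no channel when the photon cannot reach the binding energy
  photo[state$bind >= pulse$photon_energy_eV] <- 0
  photo[state$occ == 0L] <- 0
  hole <- state$cap[, 1] > 0 & state$occ[, 1] < state$cap[, 1]
  outer <- rowSums(state$occ[, -1, drop = FALSE])
  arate <- frate <- numeric(length(state$element))
  for (el in unique(state$element)) {
    ch <- tables$elements[[el]]$core_hole
    if (is.null(ch)) next
    idx <- state$element == el
    arate[idx] <- ch$auger_rate_per_fs
    frate[idx] <- ch$fluor_rate_per_fs
  }
  auger <- ifelse(hole & outer >= 2, arate * dt_fs, 0)
  fluor <- ifelse(hole & outer >= 1, frate * dt_fs, 0)
  cbind(photo, auger = auger, fluor = fluor)
}

#' Sample stochastic atomic events for one timestep
#'
#' One uniform random draw per atom per step, consumed in ascending atom
#' order from R's global RNG stream, selects among the atom's channels
#' (per-orbital photoionization, Auger decay, fluorescence) by cumulative
#' probability; otherwise no event.  At most one event per atom per step.
#' The fixed one-draw-per-atom discipline makes event sequences reproducible
#' given the seed and independent of solver choices elsewhere.
#'
#' @param state A `raddyn_state`.
#' @param tables Rate tables.
#' @param pulse A [pulse_config()].
#' @param dt_fs Timestep in fs.
#' @param t_fs Current time in fs (pulse-envelope argument).
#' @return data.frame with one row per event: `atom`, `type` (one of
#'   `"photo"`, `"auger"`, `"fluor"`), `orbital` (ionized orbital for
#'   photoionization, `NA` otherwise).
#' @export
sample_events <- function(state, tables, pulse, dt_fs, t_fs) {
  na <- length(state$element)
  P <- .mc_channel_probs(state, tables, pulse, dt_fs, t_fs)
  ptot <- rowSums(P)
  if (any(ptot > 1))
    stop("timestep-too-large error: per-atom event probability exceeds 1")
  if (any(ptot > 0.1))
    warning("per-atom event probability above 0.1; consider a smaller timestep")
  u <- stats::runif(na)                     # exactly one draw per atom
  cum <- P
  for (j in seq_len(ncol(cum))[-1]) cum[, j] <- cum[, j] + cum[, j - 1]
  hit <- u < cum
  chan <- ifelse(rowSums(hit) > 0, max.col(hit, ties.method = "first"), 0L)
  sel <- which(chan > 0L)
  if (!length(sel))
    return(data.frame(atom = integer(0), type = character(0),
                      orbital = integer(0)))
  K <- ncol(state$occ)
  type <- ifelse(chan[sel] <= K, "photo",
                 ifelse(chan[sel] == K + 1, "auger", "fluor"))
  data.frame(atom = sel,
             type = type,
             orbital = ifelse(chan[sel] <= K, chan[sel], NA_integer_))
}

#' Apply one atomic event to the state
#'
#' Photoionization: the orbital occupation drops by 1, the charge state
#' rises by 1, and a new free electron is created at the atom's position
#' plus a 0.5-bohr offset along an isotropically drawn direction, with
#' kinetic energy `photon_energy - binding`.  Auger decay: the 1s hole is
#' filled from the outermost occupied orbital and a second outer electron is
#' emitted with the tabulated Auger energy (charge +1).  Fluorescence: the
#' hole moves outward (occupations shifted); charge and electron count are
#' unchanged, no classical photon particle is created.
#'
#' Directions consume two draws from R's global RNG per emitted particle.
#'
#' @param state A `raddyn_state`.
#' @param event One-row slice of the [sample_events()] output (or a list
#'   with `atom`, `type`, `orbital`).
#' @param tables Rate tables.
#' @param pulse A [pulse_config()] (photon energy for photoionization).
#' @return The updated state.
#' @export
apply_event <- function(state, event, tables, pulse) {
  u <- raddyn_units()
  a <- event$atom
  add_electron <- function(state, a, ke_eV) {
    dir <- .iso_direction()
    sp <- sqrt(2 * max(ke_eV, 0) / u$hartree_eV)
    state$epos <- rbind(state$epos, state$apos[a, ] + 0.5 * dir)
    state$evel <- rbind(state$evel, state$avel[a, ] + dir * sp)
    state
  }
  outermost_occ <- function(occ_row, cap_row) {
    k <- which(cap_row > 0 & occ_row > 0)
    if (!length(k)) stop("bookkeeping error: no occupied orbital to draw from")
    max(k)
  }
  if (event$type == "photo") {
    k <- event$orbital
    if (state$occ[a, k] < 1L)
      stop("bookkeeping error: photoionization of an empty orbital")
    state$occ[a, k] <- state$occ[a, k] - 1L
    state$charge[a] <- state$charge[a] + 1L
    state <- add_electron(state, a, pulse$photon_energy_eV - state$bind[a, k])
  } else if (event$type == "auger") {
    ch <- tables$elements[[state$element[a]]]$core_hole
    if (state$occ[a, 1] >= state$cap[a, 1])
      stop("bookkeeping error: Auger decay without a core hole")
    k1 <- outermost_occ(state$occ[a, ], state$cap[a, ])
    state$occ[a, k1] <- state$occ[a, k1] - 1L       # fills the core hole
    state$occ[a, 1] <- state$occ[a, 1] + 1L
    k2 <- outermost_occ(state$occ[a, ], state$cap[a, ])
    state$occ[a, k2] <- state$occ[a, k2] - 1L       # emitted electron
    state$charge[a] <- state$charge[a] + 1L
    state <- add_electron(state, a, ch$auger_energy_eV)
  } else if (event$type == "fluor") {
    if (state$occ[a, 1] >= state$cap[a, 1])
      stop("bookkeeping error: fluorescence without a core hole")
    k1 <- outermost_occ(state$occ[a, ], state$cap[a, ])
    state$occ[a, k1] <- state$occ[a, k1] - 1L
    state$occ[a, 1] <- state$occ[a, 1] + 1L         # charge unchanged
  } else {
    stop("unknown event type: ", event$type)
  }
  state$force_cache <- NULL
  state
}

.iso_direction <- function() {
  ct <- 2 * stats::runif(1) - 1
  ph <- 2 * pi * stats::runif(1)
  st <- sqrt(max(0, 1 - ct^2))
  c(st * cos(ph), st * sin(ph), ct)
}

#' Monte-Carlo block: sample and apply one step of atomic events
#'
#' @inheritParams sample_events
#' @return List with the updated `state` and the `events` data.frame.
#' @export
mc_block <- function(state, tables, pulse, dt_fs, t_fs) {
  events <- sample_events(state, tables, pulse, dt_fs, t_fs)
  if (nrow(events)) {
    for (i in seq_len(nrow(events)))
      state <- apply_event(state, events[i, ], tables, pulse)
  }
  list(state = state, events = events)
}
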