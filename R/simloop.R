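#' Simulation configuration
#'
#' Bundles the sub-configurations of the four-block time loop.  The blocks
#' execute in the fixed order recombination (RE), secondary ionization (SI),
#' Monte-Carlo atomic events (MC), molecular dynamics (MD); all particle
#' mutations by the event blocks happen between MD steps, never mid-step.
#'
#' @param n_steps Number of timesteps.
#' @param dt_as Timestep in attoseconds (default 1).
#' @param pulse A [pulse_config()].
#' @param coulomb A [coulomb_config()].
#' @param si An [si_config()].
#' @param re An [re_config()], or `NULL` to disable recombination.
#' @param seed Integer seed; mandatory for any run that will be compared
#'   across solver choices.  Seeds R's RNG for the MC block; the SI block
#'   derives keyed per-event streams from it.
#' @param tables Rate tables.
#' @param out_dir Optional output directory for snapshots and logs.
#' @param snapshot_every Snapshot cadence in steps (0 disables).
#' @param diag_every Energy-ledger cadence in steps.
#' @return List of class `raddyn_sim_config`.
#' @export
simulation_config <- function(n_steps, dt_as = 1,
                              pulse = pulse_config(),
                              coulomb = coulomb_config(),
                              si = si_config(),
                              re = re_config(),
                              seed = 1,
                              tables = load_rate_tables(),
                              out_dir = NULL,
                              snapshot_every = 0,
                              diag_every = 1) {
  stopifnot(n_steps >= 0, dt_as > 0)
  structure(list(n_steps = as.integer(n_steps), dt_as = dt_as,
                 dt_au = dt_as * raddyn_units()$as_au,
                 pulse = pulse, coulomb = coulomb, si = si, re = re,
                 seed = as.integer(seed), tables = tables,
                 out_dir = out_dir, snapshot_every = snapshot_every,
                 diag_every = diag_every),
            class = "raddyn_sim_config")
}

#' Execute one step of the four-block loop
#'
#' RE, then SI, then MC, then MD, in exactly that order; the clock advances
#' by one timestep (inside the MD block).  The step index keys the SI
#' per-event RNG and the pulse-envelope time `t = t0 + step * dt`.
#'
#' @param state A `raddyn_state`.
#' @param config A [simulation_config()].
#' @param step Zero-based step index.
#' @param force_provider Optional cached force provider (built from
#'   `config$coulomb` when `NULL`).
#' @return List with `state`, `events` (list: `re`, `si`, `mc`) and
#'   `counters` (named numeric: per-block pair-evaluation work).
#' @export
sim_step <- function(state, config, step = 0L, force_provider = NULL) {
  if (is.null(force_provider))
    force_provider <- make_force_provider(config$coulomb)
  t_fs <- au_to_fs(state$time)
  re <- if (is.null(config$re)) {
    list(state = state,
         events = data.frame(step = integer(0), electron = integer(0),
                             ion = integer(0)),
         counters = c(dist_evals = 0, box_tests = 0))
  } else {
    re_block(state, config$re, step = step)
  }
  si <- si_block(re$state, config$si, step = step, seed = config$seed,
                 tables = config$tables)
  mc <- mc_block(si$state, config$tables, config$pulse,
                 dt_fs = config$dt_as * 1e-3, t_fs = t_fs)
  st <- velocity_verlet_step(mc$state, config$dt_au, force_provider)
  list(state = st,
       events = list(re = re$events, si = si$events, mc = mc$events),
       counters = c(re = unname(re$counters["dist_evals"] + re$counters["box_tests"]),
                    si = unname(si$counters["dist_evals"] + si$counters["box_tests"]),
                    coulomb = attr(st, "pair_evals")))
}

#' Run a simulation
#'
#' Repeats [sim_step()] `n_steps` times from the given (or preset-derived)
#' initial state, collecting per-step diagnostics (particle counts, event
#' counts, pair-evaluation counters, energies at the configured cadence)
#' and the full event logs.  With `out_dir` set, writes extended-XYZ
#' snapshots at the snapshot cadence, TSV event/diagnostic logs and a YAML
#' run manifest with the resolved configuration and seed.
#'
#' Identical config + seed reproduce the trajectory byte for byte.
#'
#' @param config A [simulation_config()].
#' @param state Initial `raddyn_state`.
#' @return List of class `raddyn_run`: `state` (final), `diagnostics`
#'   (data.frame), `events` (list of data.frames `re`, `si`, `mc`).
#' @export
sim_run <- function(config, state) {
  set.seed(config$seed)
  fp <- make_force_provider(config$coulomb)
  outd <- config$out_dir
  if (!is.null(outd) && !dir.exists(outd))
    dir.create(outd, recursive = TRUE)
  diag_rows <- vector("list", config$n_steps)
  ev_re <- list(); ev_si <- list(); ev_mc <- list()
  for (k in seq_len(config$n_steps)) {
    step <- k - 1L
    res <- sim_step(state, config, step = step, force_provider = fp)
    state <- res$state
    ct <- state_counts(state)
    row <- data.frame(step = step, t_fs = au_to_fs(state$time),
                      Na = ct$Na, Ni = ct$Ni, Ne = ct$Ne, Nq = ct$Nq,
                      n_re = nrow(res$events$re), n_si = nrow(res$events$si),
                      n_mc = nrow(res$events$mc),
                      evals_re = res$counters[["re"]],
                      evals_si = res$counters[["si"]],
                      evals_coulomb = res$counters[["coulomb"]],
                      E_kin = NA_real_, E_pot = NA_real_)
    if (config$diag_every > 0 && (step %% config$diag_every == 0)) {
      row$E_kin <- kinetic_energy(state)
      row$E_pot <- potential_energy(state, config$coulomb$softening)
    }
    diag_rows[[k]] <- row
    if (nrow(res$events$re)) ev_re[[length(ev_re) + 1]] <- res$events$re
    if (nrow(res$events$si)) ev_si[[length(ev_si) + 1]] <- res$events$si
    if (nrow(res$events$mc)) {
      m <- res$events$mc; m$step <- step
      ev_mc[[length(ev_mc) + 1]] <- m
    }
    if (!is.null(outd) && config$snapshot_every > 0 &&
        (step %% config$snapshot_every == 0))
      write_xyz(state, file.path(outd, sprintf("snapshot_%06d.xyz", step)))
  }
  diagnostics <- do.call(rbind, diag_rows)
  events <- list(
    re = if (length(ev_re)) do.call(rbind, ev_re) else
      data.frame(step = integer(0), electron = integer(0), ion = integer(0)),
    si = if (length(ev_si)) do.call(rbind, ev_si) else
      data.frame(step = integer(0), electron = integer(0),
                 target = integer(0), orbital = integer(0)),
    mc = if (length(ev_mc)) do.call(rbind, ev_mc) else
      data.frame(atom = integer(0), type = character(0),
                 orbital = integer(0), step = integer(0)))
  if (!is.null(outd)) {
    utils::write.table(diagnostics, file.path(outd, "diagnostics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(events$si, file.path(outd, "events_si.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(events$re, file.path(outd, "events_re.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(events$mc, file.path(outd, "events_mc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest <- list(
      n_steps = config$n_steps, dt_as = config$dt_as, seed = config$seed,
      pulse = unclass(config$pulse), coulomb = unclass(config$coulomb),
      si = unclass(config$si)[c("implementation", "max_depth")],
      re = unclass(config$re))
    yaml::write_yaml(manifest, file.path(outd, "run_manifest.yaml"))
    write_xyz(state, file.path(outd, "final.xyz"))
  }
  structure(list(state = state, diagnostics = diagnostics, events = events),
            class = "raddyn_run")
}

#' @export
print.raddyn_run <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<raddyn_run> %d steps | final Na=%d Ni=%d Ne=%d | events: %d RE, %d SI, %d MC\n",
              nrow(d), d$Na[nrow(d)], d$Ni[nrow(d)], d$Ne[nrow(d)],
              sum(d$n_re), sum(d$n_si), sum(d$n_mc)))
  invisible(x)
}

#' Per-step solver work over a size ladder
#'
#' For each `n_atoms` value, builds a fixed-composition plasma and measures
#' the pair-evaluation work of a single execution of each solver: Coulomb
#' brute and tree (at the configured theta), SI brute and tree.  These
#' hardware-independent operation counts are the package's proxy for
#' wall-clock scaling studies.
#'
#' @param n_atoms Integer vector, the ladder of sample sizes.
#' @param theta Opening angle for the tree Coulomb solver.
#' @param seed Seed for the plasma generator.
#' @param max_depth Octree depth.
#' @param tables Rate tables.
#' @return data.frame with one row per size: the four counters plus `Nq`,
#'   `Ni`, `Ne`.
#' @export
count_ladder <- function(n_atoms, theta = 0.4, seed = 1, max_depth = 10,
                         tables = load_rate_tables()) {
  rows <- lapply(n_atoms, function(n) {
    st <- make_plasma(n, seed = seed, tables = tables)
    ct <- state_counts(st)
    cs <- charged_set(st)
    cb <- cpp_brute_forces(cs$pos, cs$q, 0.05)
    tr <- cpp_tree_forces(cs$pos, cs$q, 0.05, theta, 1L, as.integer(max_depth))
    sb <- si_block(st, si_config("brute"), step = 0L, tables = tables)
    stt <- si_block(st, si_config("tree", max_depth = max_depth),
                    step = 0L, tables = tables)
    data.frame(n_atoms = n, Nq = ct$Nq, Ni = ct$Ni, Ne = ct$Ne,
               coulomb_brute = cb$pair_evals,
               coulomb_tree = tr$pair_evals,
               si_brute = sum(sb$counters),
               si_tree = sum(stt$counters))
  })
  do.call(rbind, rows)
}

#' Log-log slope of work versus size
#'
#' Least-squares slope of `log(count)` against `log(n)`: the empirical
#' scaling exponent of a solver over a size ladder.
#'
#' @param n Sizes.
#' @param count Work measures (same length).
#' @return Numeric slope.
#' @export
loglog_slope <- function(n, count) {
  stopifnot(length(n) == length(count), length(n) >= 2)
  unname(stats::coef(stats::lm(log(count) ~ log(n)))[2])
}
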