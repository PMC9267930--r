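tb <- load_rate_tables()

test_that("a step on a cold neutral sample with no fluence is a no-op drift", {
  st <- build_water_cube(sample_spec(8, seed = 14), tables = tb)
  cfg <- simulation_config(1, seed = 2, pulse = pulse_config(fluence = 0),
                           tables = tb, diag_every = 0)
  res <- sim_step(st, cfg, step = 0L)
  expect_equal(res$state$apos, st$apos)            # zero velocity, zero force
  expect_true(all(res$state$avel == 0))
  expect_identical(nrow(res$events$si), 0L)
  expect_identical(nrow(res$events$re), 0L)
})

test_that("total charge is invariant across full steps and runs are reproducible", {
  st <- make_plasma(500, seed = 33, temp_eV = 20, tables = tb)
  cfg <- simulation_config(8, seed = 12, tables = tb, diag_every = 0)
  q0 <- total_charge(st)
  r1 <- sim_run(cfg, st)
  r2 <- sim_run(cfg, st)
  expect_identical(total_charge(r1$state), q0)
  expect_identical(r1, r2)                          # byte-identical trajectories
})

test_that("swapping brute for tree SI leaves the whole trajectory bit-wise unchanged", {
  st <- make_plasma(600, seed = 44, temp_eV = 25, tables = tb)
  mk <- function(impl) simulation_config(12, seed = 3, si = si_config(impl),
                                         coulomb = coulomb_config("tree", theta = 0.4),
                                         tables = tb, diag_every = 0)
  rb <- sim_run(mk("brute"), st)
  rt <- sim_run(mk("tree"), st)
  expect_identical(rb$state, rt$state)
  expect_identical(rb$events, rt$events)
})

test_that("brute and theta = 0 tree Coulomb give matching trajectories", {
  st <- make_plasma(300, seed = 55, temp_eV = 15, tables = tb)
  mk <- function(cc) simulation_config(10, seed = 6, coulomb = cc,
                                       tables = tb, diag_every = 0)
  rb <- sim_run(mk(coulomb_config("brute")), st)
  rt <- sim_run(mk(coulomb_config("tree", theta = 0)), st)
  expect_identical(rb$events$si, rt$events$si)      # identical event logs
  expect_identical(rb$events$mc, rt$events$mc)
  scale <- max(abs(rb$state$apos))
  expect_lt(max(abs(rb$state$apos - rt$state$apos)) / scale, 1e-10)
  expect_lt(max(abs(rb$state$epos - rt$state$epos)) / scale, 1e-10)
})

test_that("with recombination disabled, the electron count never decreases", {
  st <- make_plasma(400, seed = 66, temp_eV = 25, tables = tb)
  cfg <- simulation_config(10, seed = 8, re = NULL, tables = tb, diag_every = 0)
  run <- sim_run(cfg, st)
  expect_true(all(diff(run$diagnostics$Ne) >= 0))
})

test_that("run outputs: diagnostics, event logs, snapshots and manifest", {
  outd <- file.path(tempdir(), "raddyn-run-test")
  st <- make_plasma(200, seed = 77, temp_eV = 20, tables = tb)
  cfg <- simulation_config(4, seed = 9, tables = tb, out_dir = outd,
                           snapshot_every = 2, diag_every = 2)
  run <- sim_run(cfg, st)
  expect_identical(nrow(run$diagnostics), 4L)
  expect_true(all(c("Na", "Ni", "Ne", "Nq", "evals_si", "evals_coulomb") %in%
                    names(run$diagnostics)))
  expect_false(anyNA(run$diagnostics$E_kin[c(1, 3)]))
  expect_true(file.exists(file.path(outd, "diagnostics.tsv")))
  expect_true(file.exists(file.path(outd, "events_si.tsv")))
  expect_true(file.exists(file.path(outd, "run_manifest.yaml")))
  expect_true(file.exists(file.path(outd, "snapshot_000000.xyz")))
  expect_true(file.exists(file.path(outd, "final.xyz")))
  # the manifest records the resolved seed
  man <- yaml::read_yaml(file.path(outd, "run_manifest.yaml"))
  expect_identical(man$seed, 9L)
  unlink(outd, recursive = TRUE)
})
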