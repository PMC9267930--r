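tb <- load_rate_tables()

test_that("Gaussian pulse: normalization, FWHM and peak closed form", {
  p <- pulse_config()
  I <- integrate(gaussian_flux, -6 * 15, 6 * 15, pulse = p, rel.tol = 1e-12)$value
  expect_equal(I, p$fluence, tolerance = 1e-6)
  expect_equal(gaussian_flux(7.5, p), 0.5 * gaussian_flux(0, p))
  expect_equal(gaussian_flux(-7.5, p), 0.5 * gaussian_flux(0, p))
  expect_equal(gaussian_flux(0, p), 3.5e12 * 2 * sqrt(log(2) / pi) / 15)
})

test_that("no events without fluence or open channels", {
  st <- build_water_cube(sample_spec(8, seed = 4), tables = tb)
  ev <- sample_events(st, tb, pulse_config(fluence = 0), dt_fs = 1e-3, t_fs = 0)
  expect_identical(nrow(ev), 0L)
  # fully stripped atoms expose no channels even at enormous fluence
  st$occ[] <- 0L
  st$charge <- as.integer(st$nel0)
  ev <- sample_events(st, tb, pulse_config(fluence = 3.5e16), dt_fs = 1e-3, t_fs = 0)
  expect_identical(nrow(ev), 0L)
})

test_that("event frequency matches the per-step probability (binomial oracle)", {
  st <- system_state("O", apos = matrix(0, 1, 3), tables = tb)
  boost <- 2e4
  pulse <- pulse_config(fluence = 3.5e12 * boost)
  # closed-form per-step probability from the table constants
  sig_tot <- sum(tb$elements$O$orbitals$sigma_ph_Mb)
  p <- sig_tot * 1e-10 * gaussian_flux(0, pulse) * 1e-3
  n_trials <- 20000
  set.seed(99)
  hits <- 0
  for (k in seq_len(n_trials))
    hits <- hits + nrow(sample_events(st, tb, pulse, dt_fs = 1e-3, t_fs = 0))
  se <- sqrt(n_trials * p * (1 - p))
  expect_lt(abs(hits - n_trials * p), 3 * se)
})

test_that("an oversized timestep is rejected", {
  st <- system_state("O", apos = matrix(0, 1, 3), tables = tb)
  expect_error(
    suppressWarnings(sample_events(st, tb, pulse_config(fluence = 3.5e19),
                                   dt_fs = 1, t_fs = 0)),
    "timestep-too-large")
})

test_that("photoionization bookkeeping: occupation, charge and electron energy", {
  u <- raddyn_units()
  st <- system_state("O", apos = matrix(0, 1, 3), tables = tb)
  pulse <- pulse_config()
  set.seed(1)
  st2 <- apply_event(st, list(atom = 1L, type = "photo", orbital = 1L), tb, pulse)
  expect_identical(st2$occ[1, 1], 1L)
  expect_identical(st2$charge[1], 1L)
  expect_identical(nrow(st2$epos), 1L)
  expect_identical(total_charge(st2), 0L)
  ke <- 0.5 * sum((st2$evel[1, ] - st2$avel[1, ])^2) * u$hartree_eV
  expect_equal(ke, 7120 - 543.1, tolerance = 1e-9)
})

test_that("Auger and fluorescence bookkeeping around a 1s hole", {
  st <- system_state("O", apos = matrix(0, 1, 3), tables = tb)
  occ_hole <- st$occ; occ_hole[1, 1] <- 1L        # single core hole
  sth <- system_state("O", apos = matrix(0, 1, 3), occ = occ_hole, tables = tb)
  set.seed(2)
  au <- apply_event(sth, list(atom = 1L, type = "auger"), tb, pulse_config())
  expect_identical(au$occ[1, 1], 2L)              # hole filled
  expect_identical(sum(au$occ), sum(sth$occ) - 1L)
  expect_identical(au$charge[1], sth$charge[1] + 1L)
  expect_identical(nrow(au$epos), 1L)
  expect_identical(total_charge(au), total_charge(sth))

  fl <- apply_event(sth, list(atom = 1L, type = "fluor"), tb, pulse_config())
  expect_identical(fl$occ[1, 1], 2L)              # hole moved outward
  expect_identical(sum(fl$occ), sum(sth$occ))
  expect_identical(fl$charge[1], sth$charge[1])
  expect_identical(nrow(fl$epos), 0L)             # no classical photon
  expect_identical(total_charge(fl), total_charge(sth))

  # decay without a hole is a bookkeeping error
  expect_error(apply_event(st, list(atom = 1L, type = "auger"), tb, pulse_config()),
               "bookkeeping")
})
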