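tb <- load_rate_tables()

test_that("density formula: molecule counts and volume scaling", {
  # rho V N_A / M arithmetic for the 47 A cube at 0.997 g/cm^3
  expect_identical(water_molecule_count(47), 3460L)
  # doubling the side multiplies the count by 8 (up to rounding)
  expect_lte(abs(water_molecule_count(94) - 8 * water_molecule_count(47)), 8)
})

test_that("water-cube geometry: bonds, containment and spacing", {
  u <- raddyn_units()
  spec <- sample_spec(15, seed = 12)
  st <- build_water_cube(spec, tables = tb)
  na <- length(st$element)
  expect_identical(na %% 3L, 0L)
  expect_identical(st$element[1:3], c("O", "H", "H"))
  # every O-H bond is 0.96 A
  o <- seq(1, na, 3)
  for (h in 1:2) {
    d <- sqrt(rowSums((st$apos[o + h, ] - st$apos[o, ])^2)) * u$bohr_A
    expect_equal(d, rep(0.96, length(o)), tolerance = 1e-9)
  }
  # all atoms inside the cube, pair distances above 0.5 A
  side <- 15 / u$bohr_A
  expect_true(all(st$apos > 0 & st$apos < side))
  dmin <- min(dist(st$apos * u$bohr_A))
  expect_gt(dmin, 0.5)
  # zero initial velocities, neutral
  expect_true(all(st$avel == 0))
  expect_identical(total_charge(st), 0L)
})

test_that("generation is a pure function of spec and seed", {
  s1 <- build_preset("47A", seed = 4, tables = tb)
  s2 <- build_preset("47A", seed = 4, tables = tb)
  s3 <- build_preset("47A", seed = 5, tables = tb)
  expect_identical(s1, s2)
  expect_false(identical(s1$apos, s3$apos))
})

test_that("pre-ionization hits exact target counts with zero net charge", {
  spec <- sample_spec(20, n_atoms = 700, n_ions = 151, n_electrons = 202,
                      seed = 3)
  st <- pre_ionize(build_water_cube(spec, tables = tb), spec, tables = tb)
  ct <- state_counts(st)
  expect_identical(ct$Na, 700L)
  expect_identical(ct$Ni, 151L)
  expect_identical(ct$Ne, 202L)
  expect_identical(sum(st$charge), 202L)
  expect_identical(total_charge(st), 0L)
  # minimal charge-state distribution: only +1 and +2 here
  expect_true(all(st$charge %in% 0:2))
  expect_identical(sum(st$charge == 2L), 202L - 151L)

  # no targets: unchanged neutral state
  spec0 <- sample_spec(10, seed = 3)
  st0 <- build_water_cube(spec0, tables = tb)
  expect_identical(pre_ionize(st0, spec0, tables = tb), st0)

  # infeasible targets are rejected
  bad <- sample_spec(20, n_atoms = 30, n_ions = 10, n_electrons = 5, seed = 1)
  expect_error(pre_ionize(build_water_cube(bad, tables = tb), bad, tables = tb),
               "configuration error")
})

test_that("the 47 A preset regenerates its exact composition triple", {
  st <- build_preset("47A", seed = 1, tables = tb)
  ct <- state_counts(st)
  expect_identical(c(ct$Na, ct$Ni, ct$Ne), c(9722L, 2102L, 2806L))
  expect_identical(total_charge(st), 0L)
  # composition ratios shared across the preset family
  pr <- water_presets()
  expect_equal(pr$electrons / pr$atoms, rep(0.288, 5), tolerance = 0.08)
  expect_equal(pr$electrons[5] / pr$atoms[5], 0.266, tolerance = 1e-3)
})

test_that("plasma fixture: exact counts, ratios and byte-level determinism", {
  st <- make_plasma(1000, seed = 42, tables = tb)
  ct <- state_counts(st)
  expect_identical(ct$Ni, 210L)
  expect_identical(ct$Ne, 290L)
  expect_identical(total_charge(st), 0L)
  expect_identical(st, make_plasma(1000, seed = 42, tables = tb))
  # Table-style 47 A electron/atom proportion when so configured
  st2 <- make_plasma(9722, ion_fraction = 2102 / 9722,
                     electron_fraction = 2806 / 9722, seed = 7, tables = tb)
  ct2 <- state_counts(st2)
  expect_identical(ct2$Ne, 2806L)
  expect_identical(ct2$Ni, 2102L)
})
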