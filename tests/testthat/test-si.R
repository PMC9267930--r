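tb <- load_rate_tables()

test_that("Lotz cross section: threshold, maximum location and positivity", {
  a <- tb$lotz_a
  B <- 13.6
  expect_identical(impact_cross_section(B, B, 4, a), 0)
  expect_identical(impact_cross_section(0.5 * B, B, 4, a), 0)
  # maximum at E = e*B with value a*N/(e*B^2)
  expect_equal(impact_cross_section(exp(1) * B, B, 4, a),
               a * 4 / (exp(1) * B^2))
  E <- seq(0, 50 * B, length.out = 500)
  s <- impact_cross_section(E, B, 4, a)
  expect_true(all(s >= 0))
  expect_lt(max(s), a * 4 / (exp(1) * B^2) + 1e-12)
})

test_that("cutoff radius is the equivalent-disc radius of the largest cross section", {
  a <- tb$lotz_a
  orb <- data.frame(binding_eV = c(13.6, 41.6), occupation = c(4, 2))
  E <- 100
  smax <- max(impact_cross_section(E, 13.6, 4, a),
              impact_cross_section(E, 41.6, 2, a))
  expect_equal(si_cutoff(E, orb, tb), sqrt(smax / pi))
  # sigma = pi corresponds to exactly 1 bohr
  E1 <- exp(1) * 13.6
  a1 <- pi * exp(1) * 13.6^2            # makes sigma(E1) = pi for N = 1
  expect_equal(si_cutoff(E1, data.frame(binding_eV = 13.6, occupation = 1),
                         tb, a = a1), 1)
  # below every threshold: no cutoff
  expect_identical(si_cutoff(5, orb, tb), 0)
  # nondecreasing in energy up to the cross-section maximum
  r <- si_cutoff(seq(14, exp(1) * 13.6, length.out = 20), orb, tb)
  expect_true(all(diff(r) >= 0))
})

test_that("pair evaluation follows the deterministic geometric criterion", {
  a <- tb$lotz_a
  occ <- tb$elements$O$orbitals$occupation
  bind <- tb$elements$O$orbitals$binding_eV
  v100 <- sqrt(2 * 100 / raddyn_units()$hartree_eV)   # 100 eV electron
  rc <- sqrt(impact_cross_section(100, 13.6, 4, a) / pi)
  # inside half the cutoff: event on the orbital maximizing sigma (2p)
  hit <- evaluate_pair(c(0.5 * rc, 0, 0), c(v100, 0, 0), c(0, 0, 0), c(0, 0, 0),
                       occ, bind, a)
  expect_identical(hit$orbital, 3L)
  expect_equal(hit$E_rel_eV, 100)
  # outside the cutoff: nothing
  expect_null(evaluate_pair(c(2 * rc, 0, 0), c(v100, 0, 0), c(0, 0, 0),
                            c(0, 0, 0), occ, bind, a))
  # slow electron below every binding, even at zero distance: nothing
  vslow <- sqrt(2 * 5 / raddyn_units()$hartree_eV)
  expect_null(evaluate_pair(c(0, 0, 0), c(vslow, 0, 0), c(0, 0, 0), c(0, 0, 0),
                            occ, bind, a))
})

test_that("SI block: brute and tree are bit-wise identical on random plasmas", {
  for (s in 1:12) {
    na <- sample(c(300, 800, 2000, 5000), 1)
    st <- make_plasma(na, seed = 300 + s, temp_eV = 30, tables = tb)
    sb <- si_block(st, si_config("brute"), step = s, seed = 77, tables = tb)
    tt <- si_block(st, si_config("tree"), step = s, seed = 77, tables = tb)
    expect_identical(sb$events, tt$events)
    expect_identical(sb$state, tt$state)
    expect_identical(total_charge(sb$state), total_charge(st))
  }
})

test_that("SI block edge cases and counters", {
  # no electrons: nothing happens
  st <- build_water_cube(sample_spec(10, seed = 6), tables = tb)
  res <- si_block(st, si_config("brute"), tables = tb)
  expect_identical(nrow(res$events), 0L)
  expect_identical(res$state$occ, st$occ)

  # brute distance evaluations: exactly Ne * Na
  st2 <- make_plasma(1000, seed = 61, tables = tb)
  ct <- state_counts(st2)
  rb <- si_block(st2, si_config("brute"), tables = tb)
  expect_equal(unname(rb$counters["dist_evals"]), ct$Ne * ct$Na)
  expect_equal(unname(rb$counters["box_tests"]), 0)

  # tree does strictly less work at scale
  st3 <- make_plasma(10000, seed = 62, tables = tb)
  rt <- si_block(st3, si_config("tree"), tables = tb)
  ct3 <- state_counts(st3)
  expect_lt(sum(rt$counters), ct3$Ne * ct3$Na)
})

test_that("SI events conserve charge and feed energy-split bookkeeping", {
  u <- raddyn_units()
  # one fast electron aimed at a neutral O: exactly one event
  st <- system_state("O", apos = matrix(0, 1, 3), tables = tb,
                     epos = matrix(c(0.5, 0, 0), 1, 3),
                     evel = matrix(c(-sqrt(2 * 100 / u$hartree_eV), 0, 0), 1, 3))
  res <- si_block(st, si_config("brute"), step = 3L, seed = 5, tables = tb)
  expect_identical(nrow(res$events), 1L)
  expect_identical(res$events$orbital, 3L)
  s2 <- res$state
  expect_identical(s2$occ[1, 3], 3L)
  expect_identical(s2$charge[1], 1L)
  expect_identical(nrow(s2$epos), 2L)
  expect_identical(total_charge(s2), total_charge(st))   # conserved (-1 here)
  # energy split: E_rel - B shared as (avail - E_sec) + E_sec,
  # with E_sec = min(0.1 * avail, 10 eV)
  avail <- 100 - 13.6
  Esec <- min(0.1 * avail, 10)
  ke1 <- 0.5 * sum(s2$evel[1, ]^2) * u$hartree_eV
  ke2 <- 0.5 * sum(s2$evel[2, ]^2) * u$hartree_eV
  expect_equal(ke1, avail - Esec, tolerance = 1e-9)
  expect_equal(ke2, Esec, tolerance = 1e-9)
  # new electron sits 0.5 bohr from the target
  expect_equal(sqrt(sum(s2$epos[2, ]^2)), 0.5, tolerance = 1e-12)
})
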