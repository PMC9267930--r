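test_that("brute-force solver reproduces closed-form pair physics", {
  # single charge: nothing to interact with
  br <- brute_forces(matrix(0, 1, 3), 5, 0)
  expect_equal(br$force, matrix(0, 1, 3))
  expect_equal(br$potential, 0)

  # +1/-1 at 1 bohr: attractive force of 1 hartree/bohr on each
  br <- brute_forces(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, -1), 0)
  expect_equal(br$force[1, ], c(1, 0, 0))     # pulled toward +x
  expect_equal(br$force[2, ], c(-1, 0, 0))
  expect_equal(br$potential, c(-1, 1))

  # equilateral triangle of +1 charges: symmetric outward forces, zero sum
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  br <- brute_forces(tri, c(1, 1, 1), 0)
  mags <- sqrt(rowSums(br$force^2))
  expect_equal(mags, rep(mags[1], 3), tolerance = 1e-14)
  expect_equal(colSums(br$force), c(0, 0, 0), tolerance = 1e-14)
})

test_that("momentum conservation: forces sum to zero for any configuration", {
  set.seed(7)
  pos <- rand_positions(200, side = 6, seed = 7)
  q <- sample(c(-1, 1, 2, 3), 200, replace = TRUE)
  br <- brute_forces(pos, q, 0.05)
  scale <- max(abs(br$force))
  expect_lt(max(abs(colSums(br$force))) / scale, 1e-12)
})

test_that("cell moments equal direct sums over their particles", {
  set.seed(13)
  pos <- rand_positions(400, side = 5, seed = 13)
  q <- sample(c(-1, 1, 2), 400, replace = TRUE)
  mom <- compute_moments(pos, q, max_depth = 4)
  perm <- attr(mom, "perm")
  for (row in sample(nrow(mom), 40)) {
    idx <- perm[mom$slot_from[row]:mom$slot_to[row]]
    expect_equal(mom$Q[row], sum(q[idx]), tolerance = 1e-12)
    aw <- abs(q[idx])
    ctr <- colSums(pos[idx, , drop = FALSE] * aw) / sum(aw)
    expect_equal(c(mom$cx[row], mom$cy[row], mom$cz[row]), unname(ctr),
                 tolerance = 1e-10)
    dip <- colSums((pos[idx, , drop = FALSE] -
                      matrix(ctr, length(idx), 3, byrow = TRUE)) * q[idx])
    expect_equal(c(mom$px[row], mom$py[row], mom$pz[row]), unname(dip),
                 tolerance = 1e-10)
  }
  # single charge in a box: dipole about its own position vanishes
  one <- mom[mom$slot_from == mom$slot_to & mom$depth == 4, ][1, ]
  expect_equal(c(one$px, one$py, one$pz), c(0, 0, 0))
})

test_that("theta = 0 opens every cell and reproduces the brute-force result", {
  for (s in 1:5) {
    n <- c(50, 120, 251, 400, 37)[s]
    pos <- rand_positions(n, side = 4, seed = 50 + s)
    q <- sample(c(-1, 1), n, replace = TRUE)
    br <- brute_forces(pos, q, 0)
    tr <- tree_forces(pos, q, coulomb_config("tree", theta = 0, softening = 0))
    scale <- max(abs(br$force))
    expect_lt(max(abs(tr$force - br$force)) / scale, 1e-10)
    expect_lt(max(abs(tr$potential - br$potential)) / max(abs(br$potential)), 1e-10)
    expect_equal(tr$pair_evals, br$pair_evals)   # same symmetric pair count
  }
})

test_that("far-field monopole error is bounded by the multipole truncation", {
  # 100 unit charges in a side-1 box, test charge at 50 box sides:
  # force ~ Q/d^2 with relative error O((s/d)^2) <= 1e-3
  set.seed(3)
  cloud <- matrix(runif(300), 100, 3)
  target <- c(50.5, 0.5, 0.5)
  pos <- rbind(cloud, target)
  q <- c(rep(1, 100), 1)
  tr <- tree_forces(pos, q, coulomb_config("tree", theta = 0.4, softening = 0,
                                           multipole_order = 0))
  d <- 50
  fmag <- sqrt(sum(tr$force[101, ]^2))
  expect_equal(fmag, 100 / d^2, tolerance = 1e-3)
})

test_that("theta = 0.4 accuracy and monotone improvement as theta decreases", {
  set.seed(29)
  n <- 1500
  pos <- rand_positions(n, side = 12, seed = 29)
  q <- rep(c(1, -1), length.out = n)                # neutral plasma
  br <- brute_forces(pos, q, 0)
  fn <- sqrt(rowSums(br$force^2))
  errs <- vapply(c(0.6, 0.4, 0.2, 0.1, 0), function(th) {
    tr <- tree_forces(pos, q, coulomb_config("tree", theta = th, softening = 0))
    max(sqrt(rowSums((tr$force - br$force)^2)) / fn)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  tr4 <- tree_forces(pos, q, coulomb_config("tree", theta = 0.4, softening = 0))
  rel <- sqrt(rowSums((tr4$force - br$force)^2)) / fn
  expect_lt(median(rel), 1e-2)
  expect_lt(unname(quantile(rel, 0.99)), 1e-1)
})

test_that("pair-evaluation counts: exact closed form for brute, sublinear growth for tree", {
  ns <- c(2000, 4000, 8000, 16000)
  counts <- vapply(ns, function(n) {
    pos <- rand_positions(n, side = (n / 0.0148)^(1 / 3), seed = n)
    q <- rep(c(1, -1), length.out = n)
    br <- brute_forces(pos, q, 0)
    expect_equal(br$pair_evals, n * (n - 1) / 2)
    tree_forces(pos, q, coulomb_config("tree", theta = 0.4))$pair_evals
  }, numeric(1))
  expect_lt(loglog_slope(ns, counts), 1.4)
})
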