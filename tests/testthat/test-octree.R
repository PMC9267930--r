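test_that("box identifiers follow the geometric subdivision convention", {
  box <- list(origin = c(0, 0, 0), side = 8)
  # minimum corner: all level bits zero at any depth
  expect_equal(compute_box_id(c(0, 0, 0), 5, box), 0)
  expect_equal(compute_box_id(c(0, 0, 0), 1, box), 0)
  # depth-5 identifiers occupy 3 * 5 = 15 bits
  expect_identical(octree_id_bits(5), 15L)
  expect_lt(compute_box_id(c(7.999, 7.999, 7.999), 5, box), 2^15)
  expect_equal(compute_box_id(c(8, 8, 8), 5, box), 2^15 - 1)  # upper face inclusive
  # exact center, depth 1: >=-midpoint convention selects octant 7
  expect_equal(compute_box_id(c(4, 4, 4), 1, box), 7)
  # outside the root box
  expect_error(compute_box_id(c(9, 0, 0), 3, box), "out-of-box")
})

test_that("box identifiers match an independent recursive-descent oracle", {
  box <- list(origin = c(-2, 1, 0), side = 6)
  set.seed(17)
  pts <- cbind(runif(60, -2, 4), runif(60, 1, 7), runif(60, 0, 6))
  for (d in c(1, 3, 5)) {
    got <- compute_box_id(pts, d, box)
    want <- apply(pts, 1, oracle_box_id, origin = box$origin, side = box$side,
                  depth = d)
    expect_equal(got, want)
  }
})

test_that("tree build sorts identifiers with a stable tie-break", {
  # single particle: one occupied leaf, identity permutation
  tr <- octree_build(matrix(c(1, 2, 3), 1, 3), max_depth = 4)
  info <- octree_ids(tr)
  expect_identical(info$perm, 1L)

  # 8 particles at the depth-1 octant centers: sorted ids are exactly 0..7
  box <- list(origin = c(0, 0, 0), side = 4)
  ctr <- as.matrix(expand.grid(c(1, 3), c(1, 3), c(1, 3)))[, 3:1]
  tr8 <- octree_build(ctr, max_depth = 1, root_box = box)
  expect_equal(octree_ids(tr8)$ids, 0:7)

  # random cloud: ids nondecreasing, perm a bijection, rebuild identical
  pos <- rand_positions(5000, seed = 23)
  tr1 <- octree_build(pos, max_depth = 6)
  tr2 <- octree_build(pos, max_depth = 6)
  i1 <- octree_ids(tr1); i2 <- octree_ids(tr2)
  expect_true(!is.unsorted(i1$ids))
  expect_identical(sort(i1$perm), 1:5000)
  expect_identical(i1, i2)

  # equal ids (coincident particles) keep original order
  dup <- rbind(c(1, 1, 1), c(2, 2, 2), c(1, 1, 1))
  trd <- octree_build(dup, max_depth = 3, root_box = list(origin = c(0, 0, 0), side = 4))
  infod <- octree_ids(trd)
  expect_identical(infod$perm[infod$ids == infod$ids[1]][1:2], c(1L, 3L))

  expect_error(octree_build(matrix(0, 0, 3)), "empty-tree")
})

test_that("fixed-radius and nearest queries agree with exhaustive search", {
  for (d in 3:7) {
    pos <- rand_positions(800, side = 12, seed = 100 + d)
    tr <- octree_build(pos, max_depth = d)
    set.seed(200 + d)
    queries <- rbind(matrix(runif(3 * 40, -1, 13), 40, 3),
                     pos[sample(800, 10), ])     # particle-coincident points
    for (i in seq_len(nrow(queries))) {
      p <- queries[i, ]
      r <- runif(1, 0, 4)
      expect_identical(octree_neighbors(tr, p, r), oracle_neighbors(pos, p, r))
      got <- octree_nearest(tr, p, r)
      want <- oracle_nearest(pos, p, r)
      expect_identical(got$index, want$index)
      expect_equal(got$distance, want$distance)
    }
  }
})

test_that("query edge cases: full ball, empty ball, coincident point, ties", {
  pos <- rand_positions(300, side = 5, seed = 31)
  tr <- octree_build(pos, max_depth = 5)
  # radius beyond the root diagonal returns everything
  expect_identical(octree_neighbors(tr, c(2.5, 2.5, 2.5), 100), 1:300)
  # r = 0 away from any particle returns nothing
  expect_identical(octree_neighbors(tr, c(-50, 0, 0), 0), integer(0))
  expect_identical(octree_nearest(tr, c(-50, 0, 0), 0)$index, NA_integer_)
  # point coincident with particle k
  got <- octree_nearest(tr, pos[137, ], 1)
  expect_identical(got$index, 137L)
  expect_identical(got$distance, 0)
  # equidistant pair: smallest original index wins
  sym <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  trs <- octree_build(sym, max_depth = 3,
                      root_box = list(origin = c(-2, -2, -2), side = 4))
  expect_identical(octree_nearest(trs, c(0, 0, 0), 2)$index, 1L)
})

test_that("query work grows much slower than brute-force scanning", {
  ns <- c(1000, 8000)
  work <- vapply(ns, function(n) {
    pos <- rand_positions(n, side = n^(1 / 3), seed = 41)   # fixed density
    tr <- octree_build(pos, max_depth = 10)
    set.seed(42)
    q <- matrix(runif(3 * 200, 0, n^(1 / 3)), 200, 3)
    for (i in 1:200) octree_nearest(tr, q[i, ], 1.5)
    octree_counters(tr)[["dist_evals"]] + octree_counters(tr)[["box_tests"]]
  }, numeric(1))
  brute_work <- 200 * ns
  # tree work grows sublinearly in N while brute grows linearly per query set
  expect_lt(work[2] / work[1], 3)
  expect_lt(work[2], brute_work[2] / 5)
})
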