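# Independent brute-force oracles, kept deliberately separate from the
# package's compiled implementations.

# all indices within r of point (plain vectorized distance filter)
oracle_neighbors <- function(pos, point, r) {
  d2 <- (pos[, 1] - point[1])^2 + (pos[, 2] - point[2])^2 +
    (pos[, 3] - point[3])^2
  which(d2 <= r^2)
}

# nearest index within r, ties broken by smallest index; NA if none
oracle_nearest <- function(pos, point, r) {
  d2 <- (pos[, 1] - point[1])^2 + (pos[, 2] - point[2])^2 +
    (pos[, 3] - point[3])^2
  ok <- which(d2 <= r^2)
  if (!length(ok)) return(list(index = NA_integer_, distance = NA_real_))
  i <- ok[which.min(d2[ok])]           # which.min returns the first minimum
  list(index = i, distance = sqrt(d2[i]))
}

# pairwise Coulomb potential energy by explicit double loop
oracle_potential_energy <- function(pos, q, eps = 0) {
  n <- nrow(pos)
  pe <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2) + eps^2)
    pe <- pe + q[i] * q[j] / r
  }
  pe
}

# geometric box-identifier oracle: explicit recursive octant descent
oracle_box_id <- function(p, origin, side, depth) {
  lo <- origin
  hi <- origin + side
  id <- 0
  for (k in seq_len(depth)) {
    oct <- 0
    for (a in 1:3) {
      mid <- (lo[a] + hi[a]) / 2
      if (p[a] >= mid) {
        oct <- oct + 2^(3 - a)
        lo[a] <- mid
      } else {
        hi[a] <- mid
      }
    }
    id <- id * 8 + oct
  }
  id
}

# deterministic uniform positions in a cube
rand_positions <- function(n, side = 10, seed = 1) {
  set.seed(seed)
  matrix(runif(3 * n, 0, side), n, 3)
}
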