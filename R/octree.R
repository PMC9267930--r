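#' Build a linear oct-tree over positions
#'
#' The root cube is subdivided recursively into eight octants up to
#' `max_depth`; each position gets a `3 * max_depth`-bit identifier assembled
#' from the per-level octant choices (3 bits per level: x-high, y-high,
#' z-high; most significant level first, >=-midpoint convention).  Particles
#' are kept as a permutation sorted by (identifier, original index), so every
#' box at every depth owns one contiguous slot range; per-level offset tables
#' over the occupied boxes support the recursive searches.
#'
#' By default the root box is the tight bounding cube of the positions,
#' expanded by 1e-6 relative so boundary particles are interior.
#'
#' @param positions Numeric n x 3 matrix (bohr).
#' @param max_depth Tree depth d >= 1; identifiers have `3 * d` bits.
#' @param root_box Optional list with `origin` (length 3) and `side`;
#'   computed from the positions when `NULL`.
#' @return Object of class `raddyn_octree`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- octree_build(matrix(runif(300), 100, 3), max_depth = 5)
#' octree_nearest(tr, c(0.5, 0.5, 0.5), r_max = 0.2)
octree_build <- function(positions, max_depth = 10, root_box = NULL) {
  positions <- as_mat3(positions, NULL, "positions")
  if (nrow(positions) < 1) stop("empty-tree error: need at least one position")
  if (is.null(root_box)) {
    bc <- cpp_bounding_cube(positions, 1e-6)
    root_box <- list(origin = bc[1:3], side = bc[4])
  }
  ptr <- cpp_oct_build(positions, as.integer(max_depth),
                       root_box$origin, root_box$side)
  structure(list(ptr = ptr, max_depth = as.integer(max_depth),
                 root_box = root_box, n = nrow(positions)),
            class = "raddyn_octree")
}

#' Box identifier of a position
#'
#' Returns the identifier of the smallest (depth-`max_depth`) box containing
#' each position: per level, each coordinate contributes a 1-bit iff it is
#' >= the box midpoint on that axis (lower-inclusive, upper-exclusive, with
#' the root box's upper face inclusive).  Positions outside the root box
#' raise an out-of-box error.
#'
#' @param positions Numeric vector of length 3 or n x 3 matrix.
#' @param max_depth Tree depth.
#' @param root_box List with `origin` and `side`.
#' @return Numeric vector of identifiers (integers of `3 * max_depth` bits,
#'   returned as doubles).
#' @export
compute_box_id <- function(positions, max_depth, root_box) {
  if (is.null(dim(positions))) positions <- matrix(positions, 1, 3)
  cpp_box_id(as_mat3(positions, NULL, "positions"), as.integer(max_depth),
             root_box$origin, root_box$side)
}

#' Identifier bit length of a tree depth
#'
#' Three bits per level, so a depth-5 tree indexes its smallest boxes with
#' 15-bit identifiers.
#'
#' @param max_depth Tree depth.
#' @return Integer bit length `3 * max_depth`.
#' @export
octree_id_bits <- function(max_depth) 3L * as.integer(max_depth)

#' Sorted identifiers and permutation of a tree
#'
#' @param tree A `raddyn_octree`.
#' @return List with `ids` (sorted ascending), `perm` (sorted slot ->
#'   original index, 1-based), `depth`, `n`, `origin`, `side`.
#' @export
octree_ids <- function(tree) cpp_oct_info(tree$ptr)

#' Fixed-radius neighbor query
#'
#' Exactly the indices of indexed particles with Euclidean distance
#' `<= r_max` from `point`; sub-boxes are descended only if the ball of
#' radius `r_max` around the point intersects them (squared-distance
#' pruning, no approximation).
#'
#' @param tree A `raddyn_octree`.
#' @param point Numeric length-3 position.
#' @param r_max Search radius >= 0.
#' @return Integer vector of particle indices (ascending).
#' @export
octree_neighbors <- function(tree, point, r_max) {
  stopifnot(r_max >= 0)
  cpp_oct_neighbors(tree$ptr, as.numeric(point), r_max)
}

#' Nearest-neighbor query within a radius
#'
#' The closest indexed particle within `r_max` of `point`; ties are broken
#' by the smallest original index.  Sub-boxes farther (point-to-box) than
#' the current best are pruned.
#'
#' @inheritParams octree_neighbors
#' @return List with `index` and `distance`, both `NA` if no particle
#'   qualifies.
#' @export
octree_nearest <- function(tree, point, r_max) {
  stopifnot(r_max >= 0)
  cpp_oct_nearest(tree$ptr, as.numeric(point), r_max)
}

#' Query-work counters
#'
#' Cumulative point-particle distance evaluations and box-ball intersection
#' tests performed by queries on this tree since the last reset.  These are
#' the hardware-independent work measures used to verify the O(log N) query
#' cost.
#'
#' @param tree A `raddyn_octree`.
#' @return Named numeric vector `dist_evals`, `box_tests`.
#' @export
octree_counters <- function(tree) cpp_oct_counters(tree$ptr)

#' @rdname octree_counters
#' @export
octree_reset_counters <- function(tree) {
  cpp_oct_reset_counters(tree$ptr)
  invisible(tree)
}

#' Debug dump of the tree index
#'
#' One row per occupied box at every depth: identifier prefix, depth and the
#' contiguous slot range it owns.  `path` writes the table as TSV.
#'
#' @param tree A `raddyn_octree`.
#' @param path Optional TSV output path.
#' @return A data.frame (invisibly if written to `path`).
#' @export
octree_index_dump <- function(tree, path = NULL) {
  df <- as.data.frame(cpp_oct_index_dump(tree$ptr))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' @export
print.raddyn_octree <- function(x, ...) {
  cat(sprintf("<raddyn_octree> n=%d depth=%d (%d-bit ids) side=%.4g bohr\n",
              x$n, x$max_depth, octree_id_bits(x$max_depth), x$root_box$side))
  invisible(x)
}
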