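#' Coulomb solver configuration
#'
#' @param method `"brute"` (exact all-pairs reference) or `"tree"`
#'   (Barnes-Hut multipole approximation).
#' @param theta Opening angle: a cell of geometric side s at distance d from
#'   the target (measured to the cell's center of charge) is evaluated
#'   unopened when `s/d < theta`.  `theta = 0` forces full opening and
#'   degenerates to the exact sum.  Values in [0.1, 0.6] are the recommended
#'   accuracy/speed trade-off; a warning is issued outside that range for the
#'   tree method.  Default 0.4, the production setting.
#' @param multipole_order 0 (monopole) or 1 (monopole + dipole, default).
#' @param softening Plummer softening length in bohr, default 0.05 for
#'   production dynamics (prevents classical collapse of electron-ion pairs
#'   between recombination checks); use 0 for solver-accuracy checks.
#' @param max_depth Octree depth for the tree method.
#' @return List of class `raddyn_coulomb_config`.
#' @export
coulomb_config <- function(method = c("tree", "brute"), theta = 0.4,
                           multipole_order = 1, softening = 0.05,
                           max_depth = 10) {
  method <- match.arg(method)
  stopifnot(theta >= 0, multipole_order %in% c(0, 1), softening >= 0)
  if (method == "tree" && theta > 0 && (theta < 0.1 || theta > 0.6))
    warning("theta = ", theta, " outside the recommended [0.1, 0.6] range")
  structure(list(method = method, theta = theta,
                 multipole_order = as.integer(multipole_order),
                 softening = softening, max_depth = as.integer(max_depth)),
            class = "raddyn_coulomb_config")
}

#' Exact all-pairs Coulomb forces and potentials
#'
#' Reference brute-force evaluation in atomic units:
#' \eqn{F_i = \sum_{j \ne i} q_i q_j (r_i - r_j)/(|r_i - r_j|^2 +
#' \epsilon^2)^{3/2}} and the analogous potential
#' \eqn{\phi_i = \sum_{j \ne i} q_j/\sqrt{r^2 + \epsilon^2}}, accumulated
#' symmetrically (Newton's third law) in ascending-j order.  Performs exactly
#' `n*(n-1)/2` pair evaluations.
#'
#' @param positions Numeric n x 3 matrix (bohr).
#' @param charges Numeric vector of charges (e).
#' @param softening Softening length epsilon >= 0 (bohr); coincident charges
#'   with `softening = 0` raise a singular-configuration error.
#' @return List with `force` (n x 3, hartree/bohr), `potential` (hartree/e)
#'   and `pair_evals`.
#' @export
brute_forces <- function(positions, charges, softening = 0) {
  positions <- as_mat3(positions, NULL, "positions")
  stopifnot(length(charges) == nrow(positions), softening >= 0)
  cpp_brute_forces(positions, as.numeric(charges), softening)
}

#' Barnes-Hut Coulomb forces and potentials
#'
#' Builds an octree over the charged particles, aggregates per-cell
#' multipole moments (total charge, |q|-weighted center of charge, dipole
#' about that center; parents assembled from children by the shift theorem),
#' then walks the tree per target particle.  Cells passing the opening-angle
#' criterion are evaluated via their multipole expansion; opened leaves are
#' evaluated directly (excluding self) with the configured softening.
#'
#' The reported `pair_evals` is a symmetric-pair-equivalent count: direct
#' interactions (walked from both ends) count one half each, plus one per
#' multipole evaluation, so `theta = 0` reproduces the brute-force count.
#'
#' @inheritParams brute_forces
#' @param config A [coulomb_config()].
#' @return List with `force`, `potential`, `pair_evals`, `direct_evals`,
#'   `multipole_evals`.
#' @export
tree_forces <- function(positions, charges, config = coulomb_config()) {
  positions <- as_mat3(positions, NULL, "positions")
  stopifnot(length(charges) == nrow(positions))
  cpp_tree_forces(positions, as.numeric(charges), config$softening,
                  config$theta, config$multipole_order, config$max_depth)
}

#' Multipole moments of the octree cells
#'
#' One row per occupied box at every depth: total charge `Q`, center of
#' charge (`cx`, `cy`, `cz`), dipole moment about it (`px`, `py`, `pz`),
#' geometric side and slot range.  Exposed for inspection and for the
#' direct-sum moment checks.
#'
#' @inheritParams brute_forces
#' @param max_depth Octree depth.
#' @return A data.frame; attribute `"perm"` maps sorted slots to original
#'   particle indices.
#' @export
compute_moments <- function(positions, charges, max_depth = 10) {
  positions <- as_mat3(positions, NULL, "positions")
  res <- cpp_moments(positions, as.numeric(charges), as.integer(max_depth))
  perm <- res$perm
  res$perm <- NULL
  df <- as.data.frame(res)
  attr(df, "perm") <- perm
  df
}

# Forces on a full state: assemble the charged subset (ions + electrons;
# neutral atoms feel no Coulomb force), run the configured solver, scatter
# per-particle forces back.  Returns atom forces, electron forces and the
# pair-evaluation count.
state_forces <- function(state, config) {
  na <- length(state$element)
  cs <- charged_set(state)
  Fa <- matrix(0, na, 3)
  Fe <- matrix(0, cs$n_e, 3)
  if (nrow(cs$pos) >= 2) {
    res <- if (config$method == "brute")
      cpp_brute_forces(cs$pos, cs$q, config$softening)
    else
      cpp_tree_forces(cs$pos, cs$q, config$softening, config$theta,
                      config$multipole_order, config$max_depth)
    ni <- cs$n_ion
    if (ni > 0) Fa[cs$ion_idx, ] <- res$force[seq_len(ni), , drop = FALSE]
    if (cs$n_e > 0) Fe[, ] <- res$force[ni + seq_len(cs$n_e), , drop = FALSE]
    count <- res$pair_evals
  } else {
    count <- 0
  }
  list(Fa = Fa, Fe = Fe, pair_evals = count)
}
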