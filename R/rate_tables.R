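#' Load per-element rate tables
#'
#' Rate tables supply, per element: the flat orbital list (name, capacity,
#' neutral occupation, binding energy), photoionization cross sections at the
#' pulse photon energy, inner-shell (core-hole) Auger and fluorescence rates,
#' and the impact-ionization model constant.  They are plain YAML inputs; the
#' packaged toy tables cover H and O, which is all a water sample needs.
#'
#' @param path Path to a YAML rate-table file.  Defaults to the packaged toy
#'   tables for hydrogen and oxygen.
#' @return An object of class `raddyn_tables`: a list with `elements` (per
#'   element: `mass_u`, `orbitals` data.frame, `core_hole`) and `lotz_a`
#'   (impact-ionization constant, bohr^2 eV^2).
#' @export
#' @examples
#' tb <- load_rate_tables()
#' tb$elements$O$orbitals
load_rate_tables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rates_toy.yaml", package = "raddyn")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$elements) || !length(raw$elements))
    stop("rate-table file has no 'elements' section")
  elements <- lapply(raw$elements, function(el) {
    orb <- do.call(rbind, lapply(el$orbitals, function(o)
      data.frame(name = o$name, capacity = as.integer(o$capacity),
                 occupation = as.integer(o$occupation),
                 binding_eV = as.numeric(o$binding_eV),
                 sigma_ph_Mb = as.numeric(o$sigma_ph_Mb),
                 stringsAsFactors = FALSE)))
    stopifnot(all(orb$capacity >= orb$occupation), all(orb$occupation >= 0),
              all(orb$binding_eV > 0), all(orb$sigma_ph_Mb >= 0))
    ch <- el$core_hole
    if (!is.null(ch))
      stopifnot(ch$auger_rate_per_fs >= 0, ch$fluor_rate_per_fs >= 0)
    list(mass_u = as.numeric(el$mass_u), orbitals = orb, core_hole = ch)
  })
  out <- list(elements = elements,
              lotz_a = as.numeric(raw$impact$lotz_a_bohr2_eV2))
  class(out) <- "raddyn_tables"
  out
}

#' @export
print.raddyn_tables <- function(x, ...) {
  cat("<raddyn_tables> elements:", paste(names(x$elements), collapse = ", "),
      "| lotz_a =", x$lotz_a, "bohr^2 eV^2\n")
  invisible(x)
}

# Maximum number of orbitals over the elements in `elem` (character vector).
.orbital_K <- function(elem, tables) {
  max(vapply(tables$elements[unique(elem)],
             function(e) nrow(e$orbitals), integer(1)))
}

# Per-atom orbital matrices (Na x K): capacity, neutral occupation, binding.
# Columns beyond an element's orbital count are zero-capacity padding.
.orbital_matrices <- function(elem, tables) {
  K <- .orbital_K(elem, tables)
  na <- length(elem)
  cap <- matrix(0L, na, K)
  occ <- matrix(0L, na, K)
  bind <- matrix(0, na, K)
  sig <- matrix(0, na, K)
  for (el in unique(elem)) {
    tab <- tables$elements[[el]]
    if (is.null(tab)) stop("no rate table for element '", el, "'")
    idx <- which(elem == el)
    ko <- nrow(tab$orbitals)
    cap[idx, seq_len(ko)] <- matrix(tab$orbitals$capacity, length(idx), ko, byrow = TRUE)
    occ[idx, seq_len(ko)] <- matrix(tab$orbitals$occupation, length(idx), ko, byrow = TRUE)
    bind[idx, seq_len(ko)] <- matrix(tab$orbitals$binding_eV, length(idx), ko, byrow = TRUE)
    sig[idx, seq_len(ko)] <- matrix(tab$orbitals$sigma_ph_Mb, length(idx), ko, byrow = TRUE)
  }
  list(cap = cap, occ = occ, bind = bind, sigma_ph = sig, K = K)
}

# Global orbital table at full capacity (for the SI search-radius bound):
# unique (binding, capacity) pairs across all elements in the tables.
.global_orbitals <- function(tables) {
  B <- numeric(0); N <- numeric(0)
  for (el in tables$elements) {
    B <- c(B, el$orbitals$binding_eV)
    N <- c(N, el$orbitals$capacity)
  }
  keep <- !duplicated(paste(B, N))
  list(B = B[keep], N = N[keep])
}

.element_masses <- function(elem, tables) {
  u <- raddyn_units()
  vapply(elem, function(el) tables$elements[[el]]$mass_u * u$amu_me, numeric(1),
         USE.NAMES = FALSE)
}
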