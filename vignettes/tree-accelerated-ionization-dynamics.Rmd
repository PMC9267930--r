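---
title: "Tree-accelerated simulation of X-ray-driven ionization dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-accelerated simulation of X-ray-driven ionization dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raddyn)
```

# The model

`raddyn` follows the femtosecond-scale evolution of an atomic assembly —
the packaged study system is a water cube — under an intense X-ray pulse.
Every atom, ion and quasi-free electron is a classical point particle;
electronic structure is reduced to per-orbital occupation numbers of the
corresponding isolated atom (H: 1s; O: 1s, 2s, 2p in the packaged
tables).  Ionization events create classical electrons and increment the
parent's charge state while decrementing the orbital occupation;
recombination is the exact inverse.  Charged particles interact through
Coulomb forces; neutral atoms feel no force but drift ballistically and
remain valid secondary-ionization targets.

Each timestep executes four blocks in a fixed order — recombination
(RE), secondary ionization (SI), stochastic atomic events (MC), then
molecular dynamics (MD) — and all particle-list mutations happen between
MD steps, never mid-step.  Whether electrons created during a step feel
forces within that same step's propagation is a genuine design choice;
here every block mutation precedes the step's force evaluation, so they
do.

## Units

Internally everything is in Hartree atomic units (length bohr, energy
hartree, mass electron masses, time ħ/Eₕ ≈ 24.19 as), which removes all
constants from Coulomb's law: F = q₁q₂/r².  Configuration and reports
use Å, eV, fs and attoseconds with the fixed conversions returned by
`raddyn_units()`.  The default timestep of 1 as is 0.041341 atomic time
units.

## The pulse and the stochastic block

The pulse envelope is Gaussian,
Φ(t) = F · (2√(ln2/π)/fwhm) · exp(−4 ln2 (t−t₀)²/fwhm²),
normalized so that ∫Φ dt equals the fluence F.  Defaults: 7120 eV
photons, F = 3.5×10¹² photons/μm², 15 fs FWHM, and the simulation clock
starting at the pulse center (t₀ = 0).

The MC block draws exactly **one uniform number per atom per step**, in
ascending atom order, and selects among the atom's channels by
cumulative probability: per-orbital photoionization (σ_ph Φ dt, with the
tabulated cross section scaled by the current occupation), Auger decay
and fluorescence (Γ dt, active only with a 1s hole and enough outer
electrons).  The fixed draw discipline makes event sequences a function
of the seed alone, independent of solver choices elsewhere — a
precondition for the cross-solver bit-wise comparisons below.  A
per-atom probability above 0.1 warns; above 1 it aborts with a
timestep-too-large error.

The rate tables are **inputs**.  The packaged YAML tables carry
synthetic, order-of-magnitude constants (O 1s binding 543.1 eV; hard
X-ray photo cross sections of order 10⁻⁵ Mb; Auger rate 0.42 fs⁻¹)
chosen to be plausible for 7 keV photons on water, and nothing in the
package's verification depends on their absolute accuracy.  An ab initio
electronic-structure engine is explicitly out of scope.

## The secondary-ionization criterion

The physical rate of impact ionization depends on the relative distance
and velocity of an electron–target pair.  The packaged criterion is a
**deterministic geometric** one, built so that per-electron decisions
are pure functions of the (electron, nearest-target) pair:

* cross-section model: Lotz form σ(E) = a·N·ln(E/B)/(E·B) above the
  orbital binding B, zero at and below it, with N the orbital occupation
  and a = 1607 bohr²eV² (the classic 4.5×10⁻¹⁴ cm²eV² constant
  converted);
* search radius: r = √(σ_max/π) evaluated at the electron's lab-frame
  kinetic energy over the orbital table at full capacity — a
  target-independent upper bound, which is what lets a spatial search
  structure pre-assess pairs at all;
* the candidate is the **nearest** atom/ion within that radius
  (ties: smallest index); the pair is then re-evaluated with the true
  relative-frame energy E_rel = ½|v_e − v_a|², and the event fires iff
  the distance is within r_cut(E_rel), ionizing the occupied orbital of
  largest σ.

On an event the available energy E_rel − B is split: the new electron
receives E_sec = min(0.1(E_rel − B), 10 eV) and is emitted isotropically
0.5 bohr from the target (avoiding a zero-distance singularity); the
primary keeps the rest, redirected along the pair's relative velocity.
The emission direction comes from a counter-based RNG keyed by
(seed, step, electron index), so both SI implementations draw identical
numbers without sharing a stream.

Nearest-target semantics (rather than all-targets-within-cutoff) is a
deliberate choice: it makes electron decisions order-independent, which
is what makes bit-wise agreement between implementations achievable.
If two electrons pick the same target in one step, decisions are taken
against the pre-block snapshot and a later event whose chosen orbital
has already been emptied is dropped — the same rule on both sides.

## Recombination

An electron is captured by its nearest ion within r_rec = 2 bohr when
the pair is classically bound, ½ m_red v_rel² − q_ion/r < 0.  At most
one capture per ion per step; the first claiming electron (ascending
index) wins and a later electron gets no event rather than falling back
to its second-nearest ion.  Capture fills the outermost open orbital —
classical capture lands in high shells, and the exact level is beyond
this model.  The captured electron's kinetic energy leaves the classical
ledger and is logged; no photon is emitted.  Both defaults (radius and
the energy bookkeeping) are model choices, not literature constants.

# The two tree structures

## Linear oct-tree for neighbor search

The SI and RE searches use an array-backed oct-tree rebuilt from scratch
each step (construction is O(Na log Na) and a negligible share of the
work).  The root box is the tight bounding cube of the indexed
particles, expanded by 10⁻⁶ relative so boundary particles are interior.
Each particle receives a 3·d-bit identifier for tree depth d — 3 bits
per level (x-high, y-high, z-high), most significant level first, with
the ≥-midpoint convention (lower-inclusive, upper face of the root box
inclusive).  A depth-5 tree therefore uses 15-bit identifiers; the
production default is depth 10.  Particles are sorted by (identifier,
original index) — the stable tie-break matters: bit-wise reproducibility
must not depend on an unstable sort — so every box at every depth owns a
contiguous slot range, recovered from per-level offset tables over the
occupied boxes.  That per-level table layout is one admissible
realization of the needed search index; nothing downstream depends on
its specifics.

Queries prune with squared point-to-box distances (no square roots).
`neighbors_within` returns exactly the particles within r;
`nearest_within` tracks the best (distance², index) pair and — a detail
that protects the tie-break — descends boxes at exactly the current best
distance, since they may hold an equally distant particle with a smaller
index.  Ranges of at most 8 slots are scanned directly rather than
descended; slots ascend left-to-right across children, so the visit
order and hence the result are unchanged.  Both queries are exact: the
tree changes the work, never the answer.

## Barnes–Hut Coulomb solver

The tree solver aggregates per-cell moments bottom-up: total charge Q, a
center of charge weighted by |q| (so it stays defined for near-neutral
cells), and the dipole moment about that center, with parents assembled
from children by the shift theorem.  A walk per target accepts a cell of
geometric side s at distance d (to its center of charge) when s/d < θ,
evaluating Q and the dipole there; otherwise it opens the cell, and
opened leaves (or ranges of ≤ 8 slots) are summed directly with the
softening ε, excluding self.  A cell whose slot range contains the
target is always opened.  θ = 0 therefore degenerates to the exact
all-pairs sum.  The expansion is capped at dipole order: quadrupole is a
documented extension point, and the dipole order already meets the
accuracy targets at θ = 0.4 (recommended range 0.1–0.6; a warning is
issued outside it).

Softening defaults to ε = 0.05 bohr in production dynamics — it prevents
the classical collapse of electron–ion pairs between recombination
checks — and to 0 in all solver-accuracy checks.  The regularization is a
model choice; point-charge classical dynamics has no natural
small-distance scale of its own.

## Operation counters instead of wall clocks

Every solver counts its work: symmetric pair evaluations for the brute
Coulomb solver (exactly Nq(Nq−1)/2); direct evaluations (halved, since
the walk visits each pair from both ends) plus multipole evaluations for
the tree solver, so that θ = 0 reproduces the brute count; distance
evaluations and box-ball tests for the searches (the brute SI scan
performs exactly Ne·Na distance evaluations per step).  Wall-clock
timing is hardware- and load-dependent; counts are not, and the
test suite fits log–log slopes of count versus N over a
fixed-composition ladder to verify the O(N²) → O(N log N) change — and
the synergy effect: the combined per-step work only scales favourably
when *both* solvers use their tree implementation, because the worse
scaling always dominates asymptotically.

# The bit-wise equivalence contract

The headline correctness property is that brute and tree SI (and RE)
produce byte-identical event lists and post-states.  Three mechanisms
carry it:

1. exact searches with one shared, deliberately non-inlined
   squared-distance kernel, so both code paths round identically;
2. a single tie-break rule (smallest original index at equal distance)
   applied by the same comparison code on both sides;
3. keyed per-event randomness, so neither implementation's draws depend
   on how many candidates it inspected.

The MD block is excluded from the byte-level contract only when the
*Coulomb* solver differs: brute and θ = 0 tree accumulate the same terms
in different orders, so trajectories agree to ~10⁻¹² relative rather
than exactly.  With the same Coulomb solver on both sides, whole
trajectories compare `identical()`.

# The synthetic samples

`build_water_cube()` places ⌊ρVN_A/M⌋ water molecules (O–H 0.96 Å,
104.5°, random orientation) on a jittered cubic lattice — with the
packaged density the lattice constant is about 3.1 Å, and the jitter
amplitude (8% of it) keeps worst-case intermolecular contacts above
0.5 Å.  The five packaged presets (47–150 Å) instead use exact-count
mode: the molecule count is padded to the atom target and trailing
hydrogens trimmed, `pre_ionize()` assigns the minimal charge-state
distribution summing to the electron target (as many +1 as possible,
the remainder one higher, multiply-charged states on oxygen), and free
electrons are placed uniformly with Maxwellian speeds at a 10 eV
temperature parameter — a plausible scale for secondary electrons in an
X-ray-heated sample.

These generators emulate the *composition* of partially ionized
samples — exact counts, net charge zero, a fixed electron/atom
proportion across sizes (needed for meaningful scaling ladders) — but
not the spatial or velocity correlations a real damage trajectory would
carry: no electron–ion spatial correlation, no temperature gradients, no
directed photoelectrons.  Tests passing on these fixtures therefore
certify the solvers and the bookkeeping, not the fidelity of any
particular damage prediction, which would additionally require real rate
tables.

The test suite runs the cross-implementation comparison on 100 seeded
plasmas up to 2×10⁴ atoms plus a 100-step run of the 47 Å preset, fits
scaling slopes over N = 10³…6.4×10⁴, and checks Barnes–Hut accuracy on
5×10³-charge neutral plasmas — sizes chosen so the full suite completes
in a few minutes on one CPU while the asymptotic trends are already
clean.

# Numerical choices and degenerate inputs

* Coincident charges with ε = 0 raise a singular-configuration error
  rather than silently producing infinities; non-finite forces abort
  propagation naming the offending particle.
* Velocity-Verlet caches the end-of-step forces and reuses them as the
  next step's start-of-step forces only if no event block mutated the
  particle lists in between (pure-MD runs thus evaluate forces once per
  step; event-active steps need a second evaluation because the arrays
  change shape).
* Deeper-than-resolution particles (identical identifiers) are allowed
  and stored contiguously; the stable sort keeps them in input order.
* θ = 0 forces full opening by construction (the acceptance test uses a
  strict inequality), so the degenerate case needs no special path.
* Empty electron sets, ion-free states and zero-fluence pulses are all
  no-ops for their respective blocks, exercised in the test suite.

# Known limitations

No chemical bonds, no relativistic dynamics, no magnetic interactions,
no periodic boundaries or Ewald summation, no fast-multipole translation
operators, no photon transport, no shake-off, no three-body
recombination physics.  The SI/RE criteria are documented stand-ins
honoring the stated distance-and-velocity dependence, not calibrated
rate models; the packaged rate tables are synthetic.  Trajectory output
is extended-XYZ plus TSV logs and a YAML manifest.
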