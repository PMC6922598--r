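---
title: "Models and methods behind c3bind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind c3bind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c3bind)
```

# The problem

A C3-symmetric small molecule such as amantadine (an adamantane cage
bearing an amine) can in principle be bound by a C3-symmetric protein
homo-trimer so that all three subunits make identical contacts with the
ligand, with the two three-fold axes coincident. `c3bind` implements a
desk-scale version of that design protocol — parametric bundle generation,
axial ligand placement, symmetric rotamer design, hydrogen-bond network
detection — together with the analyses used to characterize the resulting
binding equilibrium in solution: two-state NMR lineshape fitting,
fraction-bound dissociation-constant bounds, and thermofluor melt
processing.

The package is organized so that each stage is usable on its own; the
pipeline (`run_design_pipeline()`) merely chains them.

# Geometry

## Structures and the amantadine template

Structures are heavy-atom tables (class `c3_structure`) read and written
in the fixed-column PDB dialect, with waters (HOH) and ligands partitioned
from the protein chains. Hydrogens are not modeled anywhere in the design
data model: hydrogen-bond geometry uses heavy-atom proxies throughout
(below), which is standard practice when coordinates come from design
models or moderately resolved crystal structures.

`build_amantadine()` constructs the ligand from the diamond lattice, which
makes the three-fold axis through the amine nitrogen and the quaternary
cage carbon *exact* rather than fitted: all C–C bonds are 1.54 Å, the C–N
bond 1.47 Å, and all angles tetrahedral. The amine's protonation state is
not modeled geometrically — the nitrogen is treated as a C3-symmetric
polar group, and any charge effect belongs to the (scalar) energy terms.

For symmetric design the ligand is reduced to one third
(`symmetrize_ligand()`): the nine off-axis carbons partition into three
equivalence classes under the 120° rotation, one class is kept as real
atoms, and the two on-axis atoms (N and cage C) are kept but flagged
*virtual* — they are shared by all three asymmetric units and must not
contribute physical interactions, or they would be triple-counted.

## Crick bundles

Backbones are generated from the Crick coiled-coil equations: a minor
helix of radius $R_1$ and frequency $\omega_1$ wound on a superhelix of
radius $R_0$ and frequency $\omega_0$, with pitch angle $\alpha$ solved by
bisection so the mean consecutive C$\alpha$ spacing is 3.8 Å. With
$\omega_1 = 102.85^\circ$/residue the minor helix makes ~3.5
residues/turn and the radial coordinate repeats every 7 residues — the
heptad signature of coiled coils.

The closed-form trace is not perfectly uniform: the residual spacing error
grows with the superhelical curvature, roughly with $R_0\,|\omega_0|$, and
stays below 0.01 Å when $R_0\,|\omega_0| \lesssim 26\ {}^\circ\!\cdot$Å.
The default bundle respects this domain: the inner ring uses $R_0 = 7$ Å,
$\omega_0 = -2.85^\circ$/res and the outer ring $R_0 = 14$ Å,
$\omega_0 = -1.43^\circ$/res — i.e. the outer frequency is scaled by
$R_0^{\rm in}/R_0^{\rm out}$ so both rings share the same helix tilt.
These defaults are the package's own stand-ins for a two-ring C3 scaffold
family; they are **not** the published parameters of any deposited
scaffold, which come from prior work and are not reproduced here. Helix
ends are left unconnected: loop building is out of scope, and monomers are
emitted as a single chain with a residue-numbering break between rings.

Backbone atoms (N, C, O) are placed from the C$\alpha$ trace with ideal
bond lengths; both atoms flanking a peptide bond are built in the same
per-segment frame, so the C–N peptide bond comes out at 1.33 Å for any
trace curvature. This is an idealized stub builder sufficient for packing
and hydrogen-bond geometry, not a full backbone reconstruction.

# Placement

With both axes on global z, two rigid-body degrees of freedom remain: the
axial offset $z$ and the rotation $\theta$ about the axis. Both are
enumerated on a grid (default $z \in [-8, 8]$ Å in 0.5 Å steps,
$\theta \in [0^\circ, 120^\circ)$ in 5° steps — the ligand's own C3
symmetry makes larger ranges redundant — and both amine directions).
Placement scoring is purely geometric: heavy-atom pairs closer than 2.8 Å
count as clashes, pairs in [2.8, 4.5] Å as contacts, and the score is
contacts − 100 × clashes. Energetics enter only at the design stage; the
two stages are deliberately sequential, with the top-k placements (default
5) forwarded to design.

# Symmetric design

`symmetric_pack()` optimizes one asymmetric unit; every accepted move is
applied to all three chains simultaneously, so the output is exactly C3
and all chains share one sequence. Identities are free within a
ligand-distance shell (default 12.5 Å, the radius of the realized design;
a 15 Å shell is available through the same argument since both radii are
plausible readings of the protocol), and fixed outside it where only
rotamers move. Residues designated as ligand hydrogen-bonding positions
can be pinned to Ser/Thr, and designated network residues can be frozen
entirely.

Burial layers come from Shrake–Rupley SASA (core < 20 Å², surface >
60 Å²) and restrict the alphabet: core AVILMF, surface DEKRNQSTH,
boundary the union. The rotamer library is a small built-in ideal-geometry
set — canonical staggered chi values, 1–9 rotamers per amino acid, grown
from the backbone stub by internal coordinates. It is deliberately tiny
and backbone-independent, and is **not** equivalent to a statistical
rotamer library.

The energy is a simplified physical stand-in: a 12-6 Lennard-Jones term
over heavy-atom pairs within 10 Å (r$_{\min}$ = sum of van der Waals
radii, capped at +10 per pair so clashes stay finite), a −2.0 bonus per
geometric hydrogen bond, per-amino-acid reference energies (default 0),
and a buried-unsatisfied-polar penalty used in evaluation. There is no
solvation or electrostatics term; with reference energies at zero the
hydrogen-bond bonus makes designed surfaces polar-rich. The point of this
function is to exercise the protocol's shape — symmetric packing,
one-third ligand accounting, restriction machinery — not to reproduce a
production force field's sequence preferences.

Optimization is Metropolis simulated annealing with a geometric
temperature schedule (kT 3.0 → 0.3 over 10 stages, 100 × n moves per
stage, seeded RNG, best-seen state returned). The one-third ligand is
expanded back to the full molecule for energies, and each
symmetry-distinct interaction is counted once per asymmetric unit; the
reported energy is three times the per-unit energy. On small instances
(≤ 6 positions × ≤ 5 rotamers) the annealer provably reaches the
exhaustive-enumeration optimum, which the test suite checks against an
independent energy route.

# Hydrogen-bond networks

Hydrogen bonds are detected from heavy atoms alone: donor–acceptor
distance in [2.5, 3.5] Å and an antecedent–donor–acceptor angle of at
least 90°, where the antecedent is the donor's bonded heavy atom; atoms
with no antecedent in the model (waters, ligand polar atoms) pass the
angle test by construction. Both directions are tried for N/O atoms that
can both donate and accept. Networks are connected components of the
polar-group graph, reported when they have at least 3 members (the
smallest chemically interesting network; the threshold is an argument). A
network *spans the interface* when its protein members come from two or
more chains — ligand and water nodes do not count toward chains.

Waters are excluded from design-stage detection (the design model contains
none) and included when evaluating crystal structures, where
`water_mediated_hbonds()` additionally reports ligand→water→protein and
ligand→water→water→protein bridges. This mirrors a known failure mode of
water-free design: a binding-site amine may recruit ordered waters that
reorient the designed direct hydrogen bonds into water-mediated ones.

# Structural evaluation

Superposition is Kabsch (SVD with reflection excluded), cross-checked in
the tests against a quaternion oracle to 1e-9 Å. A printed design-vs-
crystal RMSD from the literature will generally derive from a specific
alignment convention (e.g. TM-align's); matching such a number requires
that convention, which this package does not re-implement. SASA is
Shrake–Rupley with 960 deterministic golden-spiral points (≈ 2% accuracy
on an isolated sphere) and radii C 1.7 / N 1.55 / O 1.52 / S 1.8 Å, probe
1.4 Å.

Sequence observables follow NMR bookkeeping: `count_amide_groups()`
returns peptide-bond amides (length − 1; for the 80-residue cleaved chain
of the amantadine-binding trimer, 79). The alternative NH-observable count
(excluding X-Pro linkages) is exposed as `mode = "NH"` since the two
conventions differ for proline-containing chains — only the peptide-bond
reading reproduces the published count. `count_methyl_probes()` applies a
labeling scheme (default AILV: A 1, I 1, L 2, V 2; 51 for the same chain).

# Binding analysis

## Two-state exchange model

A protein observable exchanging between free (F) and bound (B) states is
simulated with the two-site Bloch–McConnell steady-state solution

$$ S(\omega) = \Re\!\left[\mathbf{1}^\top (i\omega I - A)^{-1} p_0\right],
\qquad A = i\,\Omega - R_2 + K_{\rm ex}, $$

with populations from the single-site binding quadratic
(`free_ligand()`), forward pseudo-first-order rate
$k_{FB} = k_{\rm on} L_{\rm free}$, reverse rate $k_{BF} = k_{\rm off}$,
and $k_{\rm on} = k_{\rm off}/K_D$, which satisfies detailed balance with
the equilibrium populations by construction. Two-dimensional peaks are
modeled as separable outer products of per-dimension 1D lineshapes — a
simplification of full 2D HMQC evolution that keeps the same parameter
semantics at desk scale.

`fit_titration()` jointly fits ($K_D$, $k_{\rm off}$, bound-state shifts
per peak and dimension, bound-state $R_2$ per peak, one global scale)
against all spectra by Levenberg–Marquardt least squares, with free-state
shifts and widths pinned to the apo point. Errors come from
residual-resampling bootstrap (100 replicas, seeded). A `fix_kd` argument
supports the constrained-fit check that fixing $K_D$ at half or twice the
fitted value must raise the chi-square. Because a fitted
$k_{\rm off}$ from lineshapes of this kind is best read as an upper
limit, the bootstrap percentile interval is reported alongside the point
estimate.

`fraction_bound_kd()` implements the classical chemical-shift-perturbation
analysis: $f_i = \Delta\delta_i/\Delta\delta_{\max}$ fit to the binding
quadratic. Two bracketing assumptions about $\Delta\delta_{\max}$ give the
bounds — taking the last titration point as saturated overestimates every
$f_i$ and yields the lower $K_D$ bound; jointly fitting the asymptote
yields the upper. On a short, non-saturating titration the lower bound is
accordingly loose.

## Thermofluor

`process_thermofluor()` averages replicate fluorescence curves on a shared
temperature grid (the standard ramp, 25→95 °C in 0.5 °C steps, gives 141
points), subtracts the no-protein control average, and reports the initial
fluorescence (high values flag molten-globule-like exposed cores), the
temperature of maximum dF/dT by central differences, and a
monotonic-decrease flag (the signature of a protein that begins the ramp
already dye-bound and only aggregates).

# Synthetic data and what the tests show

`make_fixtures()` regenerates every test input from a seed: (i) a C3
trimer with a *planted* binding site — three symmetry-related Ser
hydroxyls 2.85 Å from an axial amine plus an Ile/Leu/Ala collar around the
cage; (ii) a titration at the study conditions (118 µM protein; ratios
1:0, 1:0.58, 1:1.35, 1:2.47; generating $K_D$ 24.1 µM, $k_{\rm off}$
60.7 s⁻¹; 2% Gaussian amplitude noise); (iii) melt replicates as a
sigmoid centered at 80 °C over a flat background.

These fixtures emulate the geometry and the data *regime* of a real study,
not real data: spectra are separable and noise is white, the planted
pocket is sparse rather than densely packed, and the bundle fixtures carry
poly-glycine backbones. Passing tests therefore demonstrate correctness of
the algorithms and self-consistency of the models — parameter recovery,
symmetry exactness, oracle equivalence — and not that the simplified
energy function would reproduce a published sequence.

Problem sizes used by the suite and the acceptance script were chosen at
desk scale: bundles of 18–28 residues per helix, placement grids of a few
hundred nodes, 20 seeded titration repeats with 100 bootstrap replicas
each. All are arguments, not limits.

# Numerical choices

- Pitch angle $\alpha$: bisection on (0.1°, 89.9°) to machine tolerance;
  the degenerate straight-helix case ($R_1 = 0$, $\omega_0 = 0$) bypasses
  the solve.
- Placement ties: equal scores break toward smaller $|z|$, then smaller
  $\theta$, making rankings deterministic.
- Annealing: seeded `sample.int`/`runif`; identical seed ⇒ identical
  design, which the suite asserts.
- Lineshape evaluation inverts the 2×2 complex system analytically per
  grid point; no matrix factorization is involved, so there is no
  singular-point fallback to log in practice.
- Kabsch excludes reflections via the sign of det(VUᵀ); degenerate
  (collinear) inputs are rejected rather than silently fit.

# Known limitations

- The energy function is a teaching-grade stand-in; no solvation,
  electrostatics, or backbone flexibility. Designed sequences are
  polar-biased relative to production design suites.
- Explicit waters are not designed against — only detected at evaluation
  time. The water-mediated-bond reporter exists precisely because this
  omission is the main observed discrepancy mode for axial amine sites.
- The one-third ligand bookkeeping assumes the protein is exactly C3; the
  packer refuses inputs deviating by more than 0.5 Å.
- `mutation_count()` is plain Hamming distance on pre-aligned sequences;
  no alignment is performed.
- TM-align-convention RMSDs are not reproduced (see above).
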