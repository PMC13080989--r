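---
title: "Fragment-based MOP design: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based MOP design: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mopforge)
```

This vignette documents the scientific model behind `mopforge`, the
parameters that matter, the numerical choices, and what the packaged
tests do and do not establish. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Fragmentation model

An organic chemical building unit (CBU) is held as a molecular graph with
explicit hydrogens. Fragmentation cleaves every single bond that is
(a) not a member of any ring — a bond is "in a ring" exactly when it is
not a bridge of the graph, so biaryl bonds between two ring systems are
cleaved — and (b) not a bond to hydrogen. Each cleaved bond leaves a
dummy atom (`*`) on both sides, placed at the position of the removed
neighbor, so a later rejoin reproduces the original bond length exactly.

Binding groups are privileged. Patterns (dummy-marked fragment SMILES;
defaults carboxylate `*C(=O)[O-]` and pyrazolate `*c1c[n-]nc1`, both kept
anionic throughout) are matched as colored subgraphs *before* cleavage,
and bonds interior to a match are protected — otherwise the carboxylate
C–O⁻ bond would itself be exocyclic and the group would be shredded.
After cleavage, any fragment containing a pattern match is typed
`binding_group` regardless of its site count; a multi-site fragment that
happens to contain a match is therefore also typed as a binding group,
which we prefer over silent reclassification (the choice only matters for
exotic inputs). Remaining one-site fragments are side chains; their
attachment dummies on *parent* fragments are replaced by hydrogen at a
standard X–H bond length, so parents stay valid molecules and
functionalization is reintroduced only through controlled substitution.
When both sides of a cleaved bond are one-site fragments (ethane-like
inputs) neither is reverted; such inputs are outside the intended domain
and the behaviour is simply deterministic. Remaining fragments are typed
by final site count (2 = linker, ≥ 3 = node, 0 = untyped).

Flags per fragment: `cyclic` (any ring bond), `linear` (two-site
fragments only: the two anchor→dummy vectors within 15° of antiparallel;
the threshold is a config constant of `fragment_is_linear()`), and
`symmetric` (two-site fragments: exchanging the two dummies — tested via
isotope labels 1/2 — leaves the canonical SMILES unchanged). Canonical
keys are OpenBabel canonical SMILES with isotopes cleared; keys preserve
bond stereo, so an (E)-alkene linker and its unspecified counterpart are
distinct library entries.

## Side-chain substitution

`substitute_linker()` treats every C–H of a two-site linker as a
bonding site: the hydrogen plays the role of the host dummy and the side
chain's dummy maps onto the carbon, using exactly the same geometric join
(and torsion scan) as CBU assembly. Products are deduplicated by
canonical key, so symmetry-equivalent ring positions collapse — benzene's
four free positions give one unique product per side chain, which is why
24 distinct side chains yield exactly 24 unique asymmetric linkers.
A hydrogen-equivalent side chain is rejected (it would reproduce the
input), and a linker without C–H (e.g. an ether bridge) returns an empty
set.

## CBU templates and assembly

A template is an ordered slot sequence: binding group at position 0,
linkers at 1..k, and a terminal binding group (two_linear/two_bent) or
node (three_planar, in which case the partially assembled arm is
replicated onto every node site). Slot constraints (`max_atoms` on heavy
atoms, `cyclic`, `linear`) restrict but never mutate fragments; a
constraint on a flag that is unknown (no geometry) fails validation
explicitly rather than guessing. Validation also enforces a single
binding-group species per CBU — mixed binding groups are rejected. The
eight shipped templates (four two_linear with 1–3 linker slots, two
two_bent, two three_planar) are representative stand-ins whose slot
constraints are our own choices, not a reproduction of any published
template table.

Orientation: each linker slot carries one bit choosing which of the
linker's two sites joins the preceding fragment; site order follows the
stored geometry's atom order. Symmetric linkers contribute a fixed 0.
Under the symmetric constraint the bits alternate along the linker
sequence, phase 0 at the first linker slot (the phase is irrelevant when
the two termini are equivalent), yielding exactly one vector; otherwise
asymmetric linkers expand to 2^k vectors.

Geometric joining: the local frame of a site has its origin at the
anchor atom, x toward the dummy, y orthogonalized toward the anchor's
nearest other neighbor, z by the right-hand rule. The incoming fragment
is rotated so its site frame is anti-aligned with the host's and
translated so the new bond lies along the host's anchor→dummy direction.
The bond length is the longer of the two stored anchor–dummy distances:
for fragments cut from a common parent both equal the original bond, so
the rejoin is exact; for library fragments the dummies are normalized at
embedding time to the anchor's covalent radius plus a carbon radius
(1.38–1.50 Å), since OpenBabel otherwise places dummies nearly on top of
their anchors.

Clash criterion: nonbonded pairs closer than 0.7 × the sum of Bondi vdW
radii, excluding pairs within graph distance 3 of each other across the
new bond. Excluding 1–4 pairs (not only 1–2/1–3) is deliberate: 1–4
separations are fixed by bond geometry, not by the junction torsion, and
ordinary chemistry (an aryl ether's O···ortho-H sits at 1.88 Å against a
1.90 Å threshold) would otherwise be rejected at every torsion angle.
The torsion about each new bond is scanned in 10° increments from the
constructed pose; the first clash-free angle is accepted and failure is
declared past 360°, raising a structured condition that carries the slot
index. After assembly, binding groups are aligned by rotating each about
its terminal junction bond only: mutually parallel planes for two-arm
CBUs, otherwise onto the least-squares plane through the binding-group
contact points; an alignment rotation that would introduce a new clash is
discarded. MMFF94 relaxation (via the `obabel` tool) is available behind
`minimize = TRUE` and off by default, matching a workflow that screens
unrelaxed geometries.

SMILES-level assembly shares the same graph-joining code without
coordinates, and enumeration deduplicates by *constitutional* canonical
SMILES: the graph joiner does not track cis/trans stereo (a V2000 block
without coordinates cannot carry it), so product identity is declared
stereo-agnostic, and the independent RDKit oracle used in the tests
strips stereo before its own canonicalization for the same reason.
Geometry-level assembly carries real 3D structure instead.

## MOP assembly

Reference polyhedra: `(3-pyramidal)4(2-linear)6` is a regular tetrahedron
with metals at vertices and linkers on edges; `(3-pyramidal)4(3-planar)4`
adds face centers; the two `(3-pyramidal)2(...)3` models are trigonal
lanterns with metals on ±z and three organics at 120° about the equator
(equatorial radius 0.5 before scaling). One global scale factor
minimizes the squared mismatch between paired site separations and the
sum of the two units' binding reaches (reach = mean distance from unit
centroid to binding contact; the contact of an organic binding group is
the centroid of its O/N donor atoms). Units are docked by Kabsch
superposition of [centroid, contacts, contact + outward pseudo-atoms]
onto the site's targets, trying all site-to-partner pairings and keeping
the best fit (first on ties, so assembly is deterministic and, because
the source points rotate with the input, invariant to rigid motions of
the inputs).

Inter-unit clash handling mirrors the CBU criterion with two exemptions:
an organic's binding-group atoms against the metal unit they coordinate
(these contacts are bonds, not sterics), and binding-group/binding-group
contacts between two organics chelating the same metal cluster — with
idealized site frames the donor atoms of adjacent organics necessarily
crowd a shared vertex, and how chelates interleave around a real cluster
is cluster chemistry this purely geometric protocol does not model.
Backbone contacts always count, which is what makes narrow topologies
(the linear lantern, small panels on small metals) fail with an
informative unit pair — wide linkers such as 9,10-anthracenediyl fail on
the lantern exactly as expected. Clashing organic units are first spun
about their site axis in 15° steps before failure is declared.

## Descriptors

Inner sphere: centroid = unweighted mean of all atom positions;
`d = 2·max(0, min_i(|r_i − c| − vdw_i))`, volume `πd³/6`. Window
diameter: rays from the centroid on a Fibonacci lattice (default 500
directions); a ray escapes when its clearance (minimum over atoms of
distance to the half-line minus the vdW radius) is positive; escaping
rays are clustered by angular adjacency (2.5 × the mean lattice spacing)
and each cluster's best ray is refined by letting the escape path shift
laterally (Nelder-Mead over the origin offset in the plane perpendicular
to the direction), which recovers off-center windows. The window of an
open (non-cage) structure is not well defined and the reported value
should then be read as a ray-clearance statistic only.

SAscore is computed through the RDKit reference implementation
(fragment-contribution + complexity penalty, range 1–10) invoked via the
system `python`: the score's fragment table is derived from a large
compound corpus and re-deriving it would change the metric, so the
reference implementation *is* the metric here. Side-chain counts come
from fragment provenance (substitutions recorded per fragment, times the
number of arms a slot instantiates), not from re-fragmenting the product.

## Widom insertion

⟨U_int⟩ is the unweighted arithmetic mean of
U_int = U(host+probe) − U(host) − U(probe) over accessible random rigid
insertions, matching a plain ensemble-average reading; a
Boltzmann-weighted variant (`boltzmann = TRUE`, temperature in K) is
available but not the default. Sampling is uniform over the host
bounding box plus a 5 Å margin with uniform random orientations;
accessibility uses the same 0.7 × vdW hard-core rule as the assemblers.
The packaged backend is classical: TraPPE CO₂ (3-site rigid, LJ + point
charges) against per-element UFF LJ host parameters with
Lorentz–Berthelot mixing and a 14 Å cutoff; host partial charges default
to zero because the package assigns none, so the electrostatic term
contributes only if the user supplies charges. Machine-learned
potentials fit the same backend contract (`evaluate(config) → eV`,
declared cutoff) but are not packaged. The default insertion count is
10⁴; the statistical error is reported as sd/√n over accessible poses.
Because the mean is taken over a box that extends well beyond the
attractive well, its absolute value depends on the margin; comparisons
should use a fixed margin, as the optimizer does.

## Genetic algorithm

One run fixes a CBU template; models, metals and per-slot fragment lists
are filtered beforehand, and the chromosome is
[model index, metal index, fragment index per slot, orientation bit per
linker slot]. Defaults: population 30, 30 generations, mutation 0.15 per
gene (resampling excluding the current value), uniform per-gene crossover
at probability 0.9 (the crossover operator is configurable; uniform was
chosen over one-point because chromosome positions have heterogeneous
meaning), elitism 0.05 with at least one elite, tournament size 3
(unstated in the source material; 3 is the common default), optional
replacement of duplicate chromosomes by random ones. Failed assemblies
keep their slot in the population with a sentinel fitness one unit below
the worst finite fitness seen, so selection pressure against them is
strong but the population size never shrinks. Evaluations are cached by
phenotype key (orientation bits of symmetric linkers erased), so
revisited configurations are free. The cavity fitness combines
`|V − 625 Å³|`, SAscore and side-chain count with weights 1:10:10 as
printed — the terms deliberately keep their mixed units (Å³ vs
dimensionless) with no normalization.

## What the synthetic data does and does not show

The fixture library reproduces the *category structure* of a curated
71-fragment set (2 binding groups, 2 nodes, 5 nonlinear acyclic linkers,
24 side chains, 20 linear cyclic, 18 linear acyclic) from a hand-written
pool of simple motifs — para-azine and fused-ring diyls, alkyne/alkene/
azo chains, small bent connectors, common substituents. Category
membership is verified at generation time against the computed flags, and
the within-pool draw is seeded. The synthetic metal units are parametric
trioxo clusters, labelled synthetic: geometric stand-ins with a realistic
reach (2.2–3.6 Å), not experimentally derived structures. Passing tests
therefore demonstrate the correctness of the algorithms (cleavage rules,
enumeration counts against an independent toolkit, geometric contracts,
GA dynamics, estimator limits) on chemically valid inputs; they do not
certify absolute cavity sizes or interaction energies for any
experimentally reported MOP, which would require the original building
blocks, templates and an ab-initio-quality potential.

Problem sizes used by the suite: enumeration oracles on 20 randomized
libraries of at most a few hundred configurations; GA validation on a
960-configuration space exhaustively enumerated for the reference
optimum, 10 seeds; Widom checks at 10⁵ insertions against a midpoint-rule
grid quadrature of the same integrand. These sizes were chosen to make
every statistical comparison decisive (3 standard errors) while keeping
a full run in minutes on one core.

## Known limitations

* CBU conformation is rigid within a MOP: fragment geometries are
  embedded once, junction torsions are the only intramolecular degrees of
  freedom explored, and no post-assembly relaxation of the whole cage is
  attempted (metal centers are not parameterized for force fields here).
* The clash exemption for co-chelating binding groups means donor-atom
  crowding at a vertex is never a failure mode; only backbone sterics
  are.
* SMILES-level enumeration is stereo-agnostic (constitutional isomers);
  libraries whose members differ only by bond stereo will enumerate to
  the same products.
* Window diameters for structures without a closed shell are heuristic.
* ⟨U_int⟩ from the classical backend is suitable for ranking within a
  fixed protocol, not for absolute adsorption energetics; host partial
  charges default to zero.
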