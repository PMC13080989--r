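# mopforge

Fragment-based design and optimization of metal–organic polyhedra (MOPs)
in R.

Metal–organic polyhedra are discrete cage molecules built from metal
clusters and organic linkers — the molecular analogues of MOFs. The
number of experimentally reported organic building units is small, which
limits how much of the realistic design space enumeration-based screening
can reach. `mopforge` implements a fragment-level route around that
limit:

1. **Fragmentation.** Organic chemical building units (CBUs) are cleaved
   at every exocyclic, non-hydrogen single bond; each fragmentation point
   receives a dummy atom (`*`) on both sides marking a bonding site.
   Fragments are deduplicated by canonical SMILES and typed by site
   count — 1 site = side chain, 2 = linker, ≥ 3 = node — except fragments
   matching a binding-group pattern (carboxylate `*C(=O)[O-]`, pyrazolate
   `*c1c[n-]nc1`), which always type as binding groups. Side-chain
   attachment points on parent fragments are reverted to hydrogen so
   parents stay valid molecules, and substitution can later be applied
   under control.
2. **CBU assembly.** Typed templates (ordered fragment slots with
   atom-count / cyclicity / linearity constraints) are filled with
   fragments and joined — at the SMILES level for fast enumeration of the
   combinatorial product, or at the geometry level, where each junction
   aligns local site frames, maps each dummy onto the partner's neighbor
   atom, bonds the neighbors, and resolves steric overlap by scanning the
   torsion about the new bond (10° steps; failure past 360°). Asymmetric
   linkers carry an orientation bit per slot; a symmetric constraint
   forces alternating orientations so coordination environments stay
   equivalent.
3. **MOP assembly.** A purely geometric protocol: a reference polyhedron
   (e.g. `(3-pyramidal)4(2-linear)6` = tetrahedron with metal vertices and
   linker edges) is uniformly scaled so paired binding-site separations
   equal the sum of the units' binding reaches, every unit is rigidly
   docked by least-squares superposition of its binding contacts and
   outward vectors, and inter-unit clashes (0.7 × vdW-radius sum) fail the
   assembly after an axial spin scan.
4. **Scoring and optimization.** Cavity descriptors (inner-sphere
   diameter/volume, ray-cast window diameter), SAscore synthetic
   accessibility, side-chain counts, and an ensemble-average CO₂
   interaction energy ⟨U_int⟩ from Widom insertion
   (U_int = U_host+CO₂ − U_host − U_CO₂, rigid TraPPE CO₂ against UFF
   Lennard-Jones host parameters). A genetic algorithm over the
   fragment encoding — genes = [assembly model, metal CBU, fragment per
   slot, orientation bit per linker] — optimizes either
   `−(|V − 625 Å³| + 10·SA + 10·n_side)` (cavity fit for a C₆₀ guest) or
   `−⟨U_int⟩`, with population 30, 30 generations, mutation 0.15,
   crossover 0.9, elitism 0.05.

A seeded synthetic fragment library (71 fragments in the standard
category structure: 2 binding groups, 2 nodes, 5 nonlinear acyclic
linkers, 24 side chains, 20 linear cyclic linkers, 18 linear acyclic
linkers) and parametric synthetic metal units let every workflow run
self-contained.

## Worked example

```r
library(mopforge)

# fragment a methylated terephthalate
fragment_library(fragment_cbu("Cc1cc(ccc1C(=O)[O-])C(=O)[O-]"))
#> # A tibble: 3 x 9
#>   key          frag_type     n_sites cyclic linear symmetric ...
#> 1 *C           side_chain          1 FALSE  NA     TRUE
#> 2 *c1ccc(cc1)* linker              2 TRUE   TRUE   TRUE
#> 3 [O-]C(=O)*   binding_group       1 FALSE  NA     TRUE
```

The methyl group is split off as a side chain and its attachment point on
the ring is reverted to hydrogen, so the linker is plain 1,4-phenylene;
the carboxylates survive cleavage intact as binding groups.

```r
# enumerate one template over the synthetic library
lib  <- generate_fixture_library(seed = 1)       # 71 fragments
cbus <- enumerate_cbus(shipped_templates()$linear_1, lib)
nrow(cbus)
#> [1] 40

# assemble a tetrahedral cage from terephthalate + a synthetic metal unit
carbox <- fragment_from_smiles("*C(=O)[O-]", frag_type = "binding_group")
phen   <- fragment_from_smiles("*c1ccc(*)cc1")
cbu <- assemble_geometry(shipped_templates()$linear_1,
                         list("0" = carbox, "1" = phen, "2" = carbox))
mop <- assemble_mop(assembly_model("(3-pyramidal)4(2-linear)6"),
                    synthetic_metal_cbu("large"), cbu)
glance(mop)
#> # A tibble: 1 x 7
#>   model                     scale n_atoms n_units inner_sphere_diameter ...
#> 1 (3-pyramidal)4(2-linear)6  8.71     124      10                  4.68
```

`scale` is the fitted polyhedron scale in Å; the 10 units are 4 metal
vertices + 6 linkers, and the inner-sphere diameter (4.68 Å) is the
largest sphere at the cage centroid clearing every vdW surface.

```r
widom_average(mop, backend_lj(), n_insertions = 5000, seed = 42)$mean_U_int
#> [1] 0.0188   # eV; mean over accessible CO2 insertions in the box + 5 A margin
```

GA runs return a trajectory object with `tidy()`, `glance()` and
`autoplot()` methods; see `?evolve` and the methods vignette
(`vignettes/mopforge-methods.Rmd`) for the model details, parameter
choices and limitations.

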