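---
title: "Modelling the freeze-drying pipeline: stage operators and observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the freeze-drying pipeline: stage operators and observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyotraj)
```

## The problem

Lyophilization (freeze-drying) turns a liquid protein formulation into a solid
by freezing, sublimating the bulk ice (primary drying), desorbing residual
water (secondary drying), and finally re-dissolving the cake (reconstitution).
Each step stresses the protein: ice fronts concentrate solutes, water removal
breaks the hydrogen-bond network and weakens the hydrophobic effect, and
multi-domain proteins can collapse onto themselves. Excipients — free arginine
(ARG, net charge +1 at formulation pH), tranexamic acid (TXA, zwitterionic,
net 0) and sucrose (SUC, neutral) — are added to protect against these
stresses, either by direct binding or by preferential exclusion.

`lyotraj` implements this five-stage protocol as a chain of *geometric system
operators* plus the *structural observables* used to judge what each stage did
to the protein. The stages are labelled `RT` (room temperature), `F`
(freezing), `1D` (primary drying), `2D` (secondary drying) and `REC`
(reconstitution), and each stage consumes the previous stage's output. The
package deliberately stops short of molecular dynamics itself: thermostats,
force fields and integrators are out of scope. What remains is everything
around the dynamics — system construction rules, cutoff semantics, counting
rules and scores — made deterministic and testable at desk scale.

## Stage operators

The numeric rules live in one place, `stage_config()`:

* box margins: protein-to-box-face distance of **15 Å** at `RT` and `REC`,
  **7.5 Å** for the coarse-grained multi-monomer systems, **50 Å** for the
  drying-stage vacuum boxes;
* **3 Å** bulk-water strip cutoff at the start of primary drying (a water is
  retained iff its oxygen lies within the cutoff of any protein atom;
  the boundary is inclusive);
* **1.5 Å** crystal-water match cutoff for the residual waters kept through
  secondary drying;
* **2.4 Å** steric clash cutoff wherever new atoms are placed;
* a **2 × 2 × 2** monomer grid at **85 Å** centre-of-mass spacing for the
  aggregation systems;
* a **4 Å** (strict `<`) inter-monomer contact cutoff and a **25 %** heatmap
  retention threshold.

`run_fd_pipeline()` chains the operators:

```{r pipeline}
protein <- make_ideal_fragment("hairpin", 12)
stages <- run_fd_pipeline(protein,
                          excipients = excipient_spec("ARG", conc_mM = 100),
                          protein_net_charge = -1, seed = 1)
vapply(stages, function(s) nrow(s$atoms), 1L)
c(RT = box_margin(stages$RT), drying = box_margin(stages$`1D`),
  REC = box_margin(stages$REC))
```

Choices worth spelling out, because the protocol leaves them open:

* **% w/w basis.** A mass fraction *f* is interpreted as excipient mass over
  (excipient + water) mass, so the molecule count is
  `round(f/(1−f) · n_waters · M_water / M_excipient)`. The basis is
  configurable through the arguments of `count_excipients_ww()`.
* **Counterions.** The solute net charge (protein plus excipients) is an
  input, not computed from pKa. A positive total is balanced with that many
  Cl⁻, a negative one with Na⁺ (`neutralize()`); the inventory never mixes
  species. The protein's default charge of −1 is implied by the
  excipient-free formulation needing exactly one Na⁺.
* **Ice.** `build_ice_block()` places oxygens on an ice-Ih (lonsdaleite)
  lattice with hexagonal cell constants a = 4.497 Å, c = 7.322 Å (4 molecules
  per cell, nearest O–O ≈ 2.75 Å). Hydrogens get ideal intramolecular
  geometry with seeded random orientations — proton disorder without
  Bernal–Fowler ring bookkeeping, which is defensible here because nothing
  downstream evaluates energetics, only geometry. "Covering the box
  surfaces" is interpreted as one slab per axis placed outside the +x, +y
  and +z faces; molecules clashing with the solute are deleted, the
  geometric counterpart of relaxing bad contacts by minimization.
* **Ice at primary drying.** The MD protocol lets the ice front become bulk
  water before stripping; the pipeline mirrors this by relabelling ice as
  water (`melt_ice()`) before applying the 3 Å rule.
* **Residual waters.** "Placed similarly to the crystal waters" is
  operationalized as nearest-neighbour matching within 1.5 Å after
  superposition onto the protein frame; the crystal-water list is an
  explicit input because the chimeric model's provenance leaves no canonical
  list.
* **Solvent and excipient placement** is grid-based (3.1 Å water grid,
  roughly liquid density; 6 Å excipient grid) with clash exclusion and a
  fixed seed — reproducible by construction, where an MD engine would
  delegate packing to its own tools.

## Observables

* `rmsd_timecourse()` — least-squares superposed RMSD (Kabsch, SVD with
  determinant correction) of every frame against the *fixed starting
  structure* of the first stage. The atom selection defaults to Cα and is
  configurable to heavy atoms; the underlying protocol does not state its
  selection.
* `radius_of_gyration()` / `rg_timecourse()` — mass-weighted RMS distance
  from the centre of mass; tracks the domain collapse under drying.
* `sasa()` — Shrake–Rupley with a 1.4 Å probe, Bondi-type van der Waals
  radii and a deterministic golden-spiral point set (default 240
  points/atom). `nonpolar_sasa_ratio()` counts carbon and sulfur as
  non-polar, with hydrogens inheriting their bonded heavy atom's class;
  the ratio rises as hydrophobic residues become exposed.
* `beta_sheet_content()` — Kabsch–Sander electrostatic hydrogen-bond
  criterion (bond if E < −0.5 kcal/mol, with the amide H reconstructed 1 Å
  from N opposite the preceding carbonyl when absent) followed by
  parallel/antiparallel bridge assignment; the content is the fraction of
  residues in any bridge. Sheet topology classes are not distinguished
  because a single content number is the readout.
* `hbond_count()` — geometric criterion: donor–acceptor heavy-atom distance
  ≤ 3.5 Å and deviation from linear D–H···A ≤ 30°. The criterion is a
  package choice (none is stated by the protocol); the published per-stage
  averages come from microsecond trajectories and are not desk-reproducible,
  so they are not test targets.
* `domain_separation()` — centre-of-mass distance between two residue
  ranges (e.g. kringle-2 vs catalytic domain), with the minimum
  inter-domain atom distance reported alongside; domain ranges are user
  configuration since the chimera's numbering is not canonical.

## Aggregation statistics

`inter_monomer_contacts()` records a residue pair on two different chains
when the *minimum atom–atom distance* is strictly below 4 Å (minimum-image
convention when a box is present), once per unordered pair per frame.
`ppi_count()` sums records over frames — the counting unit is "one per
residue pair per frame", which supports both a trajectory total and per-pair
heatmaps from one definition; a unique-pair variant is exposed as an option.
`normalize_ppi()` divides by the smallest positive count so the
weakest-interacting condition maps to exactly 1. `contact_heatmap()` zeroes
cells below 25 % of the strongest pair of the reference (non-aggregating)
condition; cells exactly at the threshold are retained, because the rule
removes what occurs "less than" the threshold. `oligomer_size_distribution()`
is connected components on the monomer contact graph.
`excipient_contact_occupancy()` reports the fraction of frames in which any
excipient atom sits within the cutoff of a chosen residue — the readout
behind binding-site occupancies such as Lys40 against ARG or TXA.

## The APR stand-in score

Published aggregation-prone-residue (APR) maps for this protocol come from an
external predictor. `apr_score()` implements a transparent structure-based
stand-in rather than a re-implementation: for residue *i*,

score_i = Σ_j w(d_ij) · h_j · rsa_j over residues *j* whose Cα lies within
R = 10 Å of Cα_i, with w(d) = 1 − d/R a linear decay, h_j the
Kyte–Doolittle hydropathy of residue *j*'s type and rsa_j its relative SASA
(residue SASA over its fully-exposed reference area). Buried neighbourhoods
score 0; exposing a hydrophobic residue can only raise its score. The
convention is fixed: **higher = more aggregation-prone**, and
`apr_difference(a, b)` is element-wise a − b with the operand order recorded
in the result. The order is explicit because published difference maps can be
read with either sign convention ("subtracted from" versus "negative means
more prone") and the two readings conflict; recording the operands avoids
guessing. `region_summary()` averages differences over labelled windows such
as the Met35–Val41 hotspot. No numeric equivalence with any external
predictor is claimed.

## Synthetic fixtures: what they do and do not show

`synthetic_data` generators replace microsecond MD output:

* `make_ideal_fragment()` builds backbones from ideal torsions (helix
  φ = −57°, ψ = −47°; strand φ = −139°, ψ = 135°). The hairpin pairs two
  ideal strands antiparallel — flip 180° about z, then an offset of
  (−1.9, 3.6, 0) Å calibrated once on the ideal strand geometry so
  Kabsch–Sander bonds form between opposing residues; the two connector
  residues are plain interpolants and carry no β structure. Registered
  hairpins need ≥ 10 residues.
* `make_solvated_fixture()` places water oxygens at scripted distances from
  the protein (± 0.05 Å), giving exact ground truth for the strip rule.
* `make_aggregation_trajectory()` starts monomers on the 85 Å lattice and
  rigidly translates scheduled pairs along their centre-of-mass line until
  the pair's minimum distance equals the scripted value (solved by root
  finding). Scheduled distances must clear the contact cutoff by ≥ 0.5 Å so
  ground truth is never a floating-point coin flip; the per-frame contact
  count is recomputed by an independent brute-force loop and shipped with
  the fixture.
* `make_excipient_population()` builds n single-residue excipient molecules
  with the formulation charge logic (ARG +1, TXA/SUC 0) on a non-clashing
  grid.

Fixture monomers are small (4–50 residues); the 355-residue two-domain
chimera of the motivating system is emulated in shape only. Passing tests
therefore demonstrate that the *operators and counting rules* are correct —
they say nothing about force-field physics, sampling, or the specific
microsecond-scale outcomes (the 2× PPI ratio, the 66→70 H-bond shift, the
90 %/62.5 % occupancies), which are structurally mirrored by scripted
fixtures but not numerically reproduced.

## Numerical choices

* Distances are computed from per-axis coordinate differences, which keeps
  cutoff boundaries exact (an expanded-square formulation can misclassify a
  pair sitting exactly at the cutoff by one ulp).
* SASA accuracy: with 240 points/atom the total area of small fixtures is
  stable to < 1 % under point doubling; isolated spheres match the closed
  form to the sampling resolution, and overlapping diatomics match the
  analytic two-sphere area within 2 %. Orientation dependence of the fixed
  point set means rigid-motion invariance also holds only to sampling
  accuracy.
* Superposition needs ≥ 3 non-collinear atoms; the SVD sign correction
  guarantees a proper rotation (det = +1) even for reflective optima.
* Ties: equal minima in `normalize_ppi()` all map to 1; heatmap cells exactly
  at the threshold are retained; the water-strip boundary is inclusive.
* Degenerate inputs fail loudly: empty trajectories, all-zero PPI maps,
  empty crystal-water lists (warning + all waters removed), overlapping
  domain ranges, chains beyond the 62-symbol PDB alphabet.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on a
12-residue hairpin in a ~50 Å box (≈ 4000 waters, ≈ 6000 ice atoms during
freezing), eight-monomer aggregation fixtures with 20-frame schedules, and
SASA fixtures of up to ~50 atoms at 240–960 sphere points. These sizes were
chosen so every check recomputes from scratch in seconds while still
exercising each rule at its boundary; all operators accept larger systems
unchanged.

## Known limitations

* Orthorhombic boxes only; the hexagonal ice block is embedded in an
  orthorhombic bounding region.
* The PDB subset covers ATOM/HETATM/MODEL/ENDMDL/CRYST1/TER — no altloc
  handling beyond the first, no anisotropic records; binary trajectory
  formats are out of scope.
* Excipient molecule geometry is schematic (small rigid fragments); only
  counts, charges and contact geometry matter to the pipeline.
* The APR score is a stand-in with its own scale; compare differences and
  regions, not absolute values, across conditions.
* XYZ input carries no residue or chain structure, so each atom becomes its
  own residue on one chain.
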