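# lyotraj

Freeze-drying (lyophilization) stresses protein therapeutics in ways a liquid
formulation never does: ice growth concentrates solutes, water removal strips
the hydrogen-bond network and the hydrophobic effect, and multi-domain
proteins collapse onto themselves. Formulation scientists probe these
stresses *in silico* by simulating the process as five consecutive stages —
room temperature (RT), freezing (F), primary drying (1D), secondary drying
(2D) and reconstitution (REC) — and by watching how excipients such as free
arginine (ARG, +1), tranexamic acid (TXA, net 0) and sucrose (SUC, 0) change
the outcome.

`lyotraj` implements everything around the molecular dynamics itself, as
deterministic, testable computation:

* **Stage operators** — cubic box construction at fixed protein-to-face
  margins (15 Å at RT/REC, 7.5 Å for coarse-grained multi-monomer systems,
  50 Å for the drying vacuum boxes), excipient loading by molarity
  (`N = round(C·V·N_A)`) or mass fraction
  (`N = round(f/(1−f)·n_w·M_w/M_x)`), counterion neutralization (positive
  total charge → Cl⁻, negative → Na⁺), hexagonal ice-Ih slab placement with
  clash pruning, 3 Å bulk-water stripping, crystal-water-matched residual
  water selection (1.5 Å) and grid re-solvation.
* **Trajectory observables** — Kabsch-superposed RMSD against the starting
  structure, radius of gyration, Shrake–Rupley SASA and the non-polar SASA
  ratio, Kabsch–Sander β-sheet content, geometric hydrogen-bond counts and
  inter-domain separation, all emitted as stage-labelled time series.
* **Aggregation statistics** — inter-monomer residue contacts (strict
  < 4 Å minimum atom distance, minimum-image aware), per-frame PPI counts,
  normalization to the weakest condition, 25 %-thresholded contact
  heatmaps, oligomer size distributions and excipient-contact occupancy.
* **APR difference maps** — a transparent exposure-weighted hydrophobicity
  score (higher = more aggregation-prone) with element-wise difference maps
  whose operand order is recorded, plus per-region summaries.
* **Synthetic fixtures** — ideal helices/hairpins built from backbone
  torsions, solvated systems with scripted water shells, multi-monomer
  trajectories with scripted contact events and brute-force-verified ground
  truth, and excipient populations with the formulation charge logic.

See the vignette (`vignettes/freeze-drying-pipeline.Rmd`) for the model
conventions and the reasoning behind each numeric rule.

## Worked example

```r
library(lyotraj)

# a 12-residue idealized beta-hairpin stands in for the protein
protein <- make_ideal_fragment("hairpin", 12)
stages <- run_fd_pipeline(protein,
                          excipients = excipient_spec("ARG", conc_mM = 100),
                          protein_net_charge = -1, seed = 1)
stages$RT
#> structure_model: 4114 atoms, 4 chain(s)
#>   roles: excipient=35, ion=6, protein=48, water=4025
#>   box: 49.89 x 49.89 x 49.89 A
stages$`1D`
#> structure_model: 106 atoms, 4 chain(s)
#>   roles: excipient=35, ion=6, protein=48, water=17
#>   box: 119.89 x 119.89 x 119.89 A
```

The RT system is a 15 Å-margin cubic box holding the protein, 35 excipient
atoms, grid solvent and the counterions that cancel the total charge; after
primary drying only the 17 waters within 3 Å of the protein survive, inside
a 50 Å vacuum box. Aggregation is scored on scripted eight-monomer fixtures
(85 Å lattice); a condition whose contact schedule is twice as long shows
exactly twice the PPI count:

```r
mono <- make_ideal_fragment("extended", 4)
scr_none <- aggregation_script(n_monomers = 8, n_frames = 20,
  schedule = list(list(frames = 1:20, pair = c(1, 2), distance = 3.4)))
scr_arg <- aggregation_script(n_monomers = 8, n_frames = 20,
  schedule = list(list(frames = 1:10, pair = c(1, 2), distance = 3.4)))
counts <- c(no_excipient = ppi_count(make_aggregation_trajectory(mono, scr_none)),
            with_arg = ppi_count(make_aggregation_trajectory(mono, scr_arg)))
counts
#> no_excipient     with_arg
#>           40           20
normalize_ppi(counts)       # weakest condition maps to exactly 1
#> no_excipient     with_arg
#>            2            1

beta_sheet_content(make_ideal_fragment("helix", 12))    # 0
beta_sheet_content(make_ideal_fragment("hairpin", 12))  # 0.5
```

The PPI counts are per-residue-pair per-frame sums; 40 and 20 are each one
scripted contact pair held for 20 and 10 frames. The β content of the ideal
hairpin is 0.5 because the ten strand residues pair through Kabsch–Sander
hydrogen bonds while the two connector residues do not.

A thin command-line wrapper over these functions ships at
`inst/scripts/lyotraj` (subcommands `prepare`, `analyze`, `ppi`, `apr`,
`fixtures`).

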