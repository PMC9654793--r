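# hingedock

Structure-based virtual screening for ATP-competitive kinase inhibitors,
at desk scale, in R. `hingedock` implements the full screening loop:

* a **ligand model** — SDF/SMILES input, Gasteiger–Marsili (PEOE) partial
  charges, docking-dialect rotatable-bond counting, Rule-of-Five
  druggability filtering;
* **receptor preparation** — rule-based protonation of titratable
  residues from their hydrogen-bonding neighborhood (3.5 Å limit),
  ideal-geometry hydrogen placement, designation of the kinase *hinge*
  anchor residue;
* an **empirical binding free energy function** with five weighted terms:

  ΔG = W_vdW Σ (A/r¹² − B/r⁶) + W_hbond Σ E(t)(C/r¹² − D/r¹⁰)
     + W_elec Σ 332.06 q_i q_j / (ε(r) r) + W_tor N_tor
     + W_sol Σ_i S_i (Occᵢᵐᵃˣ − Σ_j V_j exp(−r²/2σ²))

  where ε(r) is a sigmoidal distance-dependent dielectric and the last
  term is a solvent-contact **ligand dehydration** energy: a Gaussian
  occupancy sum measures each ligand atom's burial, and the clamped
  deficit from its maximum occupancy prices the residual hydration;
* **grid-based stochastic docking** — precomputed per-type affinity,
  electrostatic and occupancy maps, trilinear interpolation, and a
  seed-deterministic genetic-algorithm pose search with local refinement;
* a **two-step screen** — energy ranking with a top-N slice, then a hinge
  hydrogen-bond filter (ligand acceptor within 3.5 Å of the hinge
  backbone N, or ligand donor within 3.5 Å of the hinge backbone O);
* **core-fixed de novo growth** — substituent enumeration at marked
  attachment points of a docked scaffold, scored with the core frozen;
* a **fixtures module** — synthetic pockets, planted poses and labeled
  libraries, plus an independent brute-force energy oracle, so everything
  is testable offline.

The shipped energy parameters are a documented generic placeholder set
(the fitted solvation parameters and weights behind published kinase
screens are not public); every constant lives in an editable
`ParameterSet` with recorded provenance.

## Worked example

Score a planted toy complex and run the two-step screen on a labeled
synthetic library:

```r
library(hingedock)
params <- default_parameters()

tc <- make_toy_complex(1, "binder")      # synthetic pocket + planted ligand
binding_free_energy(tc$receptor, tc$ligand, tc$planted_pose, params)
#> dG = -1.6546 kcal/mol (vdw -1.2895 | hbond -0.3931 | elec -0.0029 | tor 0.0000 | desolv 0.0309)

grids <- build_grids(tc$receptor, grid_box(c(-1, 0.2, 0), 9, 0.375),
                     params, types = c("C", "OA"))
lib <- make_library(1, 200, 0.1)         # 20 planted hinge binders
rep <- run_screen(lib$molecules, tc$receptor, grids, params,
                  screen_config(n_runs = 3, seed = 11,
                                search_cfg = dock_config(pop_size = 28,
                                                         n_gens = 30,
                                                         local_steps = 80)))
rep
#> ScreeningReport: 200 in library -> 192 drug-like -> 192 in energy slice -> 20 hinge-bonded hits
```

The planted complex scores −1.65 kcal/mol: the hydrogen bond to the hinge
amide (−0.39), favorable shell dispersion (−1.29) and a small dehydration
cost for the partially buried carbonyl oxygen (+0.03).

The screen keeps the 192 Rule-of-Five-compliant molecules, docks each
one, and the hinge filter retains exactly the 20 planted binders — the
nonpolar decoys cannot satisfy the 3.5 Å donor/acceptor criterion.

The scaffold worked example (the low-molecular-weight screening hit
4-(2-amino-5-phenylpyrimidin-4-yl)benzene-1,3-diol, shipped as an SDF
fixture):

```r
mol <- load_library(system.file("extdata", "inhibitor2_scaffold.sdf",
                                package = "hingedock"))[[1]]
molecular_weight(mol)
#> [1] 279.299
rule_of_five(mol)
#> Rule-of-Five: PASS (0 violation(s))
#>    MW   HBD   HBA  logP
#> 279.3   4.0   5.0   0.4
```

A thin CLI wraps the same functions (`exec/hingedock`): subcommands
`descriptors`, `prep` (with `--hinge CHAIN:RESNUM`), `fixtures`,
`rescore`, `dock`, `grow`, and `screen --config cfg.yaml`.

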