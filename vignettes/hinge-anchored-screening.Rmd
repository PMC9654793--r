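---
title: "Hinge-anchored virtual screening with a solvent-contact desolvation score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hinge-anchored virtual screening with a solvent-contact desolvation score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hingedock` is a desk-scale toolkit for structure-based discovery of
ATP-competitive kinase inhibitors. It covers the full loop a screening
study walks through: ligand preparation and druggability filtering,
rule-based receptor protonation, an empirical binding free energy function
whose distinguishing feature is a solvent-contact ligand dehydration term,
grid-accelerated stochastic docking, a two-step hit filtration anchored on
the kinase hinge hydrogen bond, and core-fixed de novo derivative growth.
This vignette explains the model, its assumptions, the tunable parameters,
and what the synthetic test fixtures do and do not demonstrate.

## The binding free energy model

The score of a ligand pose is a sum of five weighted terms over
receptor-ligand atom pairs:

$$
\Delta G^{aq}_b =
W_{vdW}\sum_{i,j}\Big(\frac{A_{ij}}{r_{ij}^{12}}-\frac{B_{ij}}{r_{ij}^{6}}\Big)
+ W_{hbond}\sum_{i,j}E(t)\Big(\frac{C_{ij}}{r_{ij}^{12}}-\frac{D_{ij}}{r_{ij}^{10}}\Big)
+ W_{elec}\sum_{i,j}\frac{332.06\,q_iq_j}{\varepsilon(r_{ij})\,r_{ij}}
+ W_{tor}N_{tor}
+ W_{sol}\sum_{i}S_i\Big(Occ_i^{max}-\sum_{j\neq i}V_j e^{-r_{ij}^2/2\sigma^2}\Big)
$$

* **van der Waals** — a 12-6 potential with Lorentz–Berthelot-combined
  per-type parameters (`rii`, `eps` in the parameter table). Pairs that are
  hydrogen-bond eligible are excluded from this sum, and polar hydrogens
  have no 12-6 interaction with acceptors; both exclusions prevent double
  counting of the same contact.
* **hydrogen bond** — a 12-10 well (default depth 5 kcal/mol at 2.9 Å)
  evaluated between the donor *heavy* atom and the acceptor, modulated by a
  directional weight `E(t) = cos^2` of the deviation from ideal alignment.
  Directionality is computed from the receptor atom's local geometry only
  (the N–H bond axis of a donor; the lone-pair axis, anti to the bonded
  neighbors, of an acceptor). This choice is what makes the hydrogen-bond
  affinity maps exactly precomputable on a grid; the ligand-side
  H orientation is deliberately not part of the inter-molecular term.
  Intra-ligand hydrogen bonds, which are never gridded, use the full
  donor-H geometry.
* **electrostatics** — screened Coulomb with the sigmoidal
  distance-dependent dielectric
  $\varepsilon(r)=A+\frac{\varepsilon_0-A}{1+k\,e^{-\lambda(\varepsilon_0-A)r}}$
  (defaults $\varepsilon_0=78.4$, $A=-8.5525$, $k=7.7839$,
  $\lambda=0.003627$), rising monotonically from protein-interior-like
  values to bulk water.
* **torsional entropy** — `W_tor` per rotatable bond, pose-independent.
* **dehydration** — the solvent-contact term. For each ligand atom the
  Gaussian-weighted volumes of all neighbors (receptor atoms *and* the
  ligand's other atoms) accumulate into an occupancy; the deficit from the
  atom's maximum occupancy `Occ_max`, clamped at zero so full burial cannot
  flip the sign, measures residual hydration and is scaled by the atomic
  solvation energy density `S_i`. Polar atoms carry negative `S` (they lose
  favorable hydration when buried), nonpolar atoms positive `S` (burial is
  rewarded). `sigma` defaults to 3.5 Å. Setting `use_solvation = FALSE`
  (or `W_sol = 0`) recovers a pure four-term score, so the contribution of
  the dehydration term is always separable.

### Parameter provenance

The five weights default to the classic free-energy-calibrated docking
coefficients (0.1485, 0.0656, 0.1146, 0.3113, 0.1711). The solvation table
ships with documented placeholder values (Bondi fragmental volumes, sign
conventions as above): the fitted solvent-contact parameters and refitted
weights used in the published kinase study are not public, so this package
deliberately records `provenance` inside every `ParameterSet` and exposes
the whole table as self-describing text
(`write_parameter_table()` / `read_parameter_table()`). Consequently
published per-complex binding energies (for example −26 kcal/mol scale
values) and assay potencies are *not* reproducible here and are not
targets; the test suite instead verifies structural and algorithmic
properties that do not depend on the fit.

### Numerical choices

* Nonbonded cutoff 12 Å on every pair sum (matching the MD convention the
  study family uses); intra-ligand pairs enter only when separated by ≥ 4
  bonds or 1-4 across a rotatable bond.
* The 12-6 and 12-10 radial profiles are evaluated at the distance clamped
  to within 0.25 Å of the pair minimum ("well smoothing", full width
  `smooth_width = 0.5` Å). This is the classic engine treatment of
  coordinate error; it also bounds the curvature of the affinity maps so
  trilinear interpolation at 0.25 Å spacing stays within 0.1 kcal/mol of
  the direct sum (verified in the tests at 1.0/0.5/0.25 Å).
* Distances are accumulated dimension-wise so the vectorized scorer and
  the scalar brute-force oracle agree to better than 1e-9 kcal/mol on
  valid poses. Hard-clash geometries (r^-12 walls of magnitude 1e5 and
  more) agree to relative, not absolute, precision — the comparison is
  precision-limited there, so the equivalence suite uses physically posed
  complexes and checks clashes separately.
* A contact below 1.2 Å flags the pose (`clash`) but still returns an
  energy, so downstream ranking never loses candidates silently.

## Ligand model

SDF V2000 records are parsed with ChemmineR; SMILES input is embedded in
3D with explicit hydrogens through OpenBabel (`obabel` on the PATH).
Partial charges use the Gasteiger–Marsili PEOE scheme: 8 rounds with the
damping factor halved per round and an additional 1e-6 convergence check;
formal charges seed the iteration and total charge is conserved exactly.
Atom types (and with them hydrogen-bond roles and solvation parameters)
derive from element, aromaticity and bonded hydrogens; a hydroxyl oxygen
is both donor and acceptor.

Rotatable bonds follow the docking dialect: single acyclic bonds between
heavy atoms that each carry a further heavy neighbor, amides excluded,
terminal methyls excluded. Polar-hydrogen rotors (O–H, N–H2) are always
sampled as torsions and are counted in `N_tor` by default
(`count_polar_h = FALSE` switches to the heavy-rotor count), since the
entropy penalty models every rotor frozen on binding.

The Rule-of-Five filter passes a molecule with at most one violation of
MW ≤ 500, donors ≤ 5 (O–H/N–H), acceptors ≤ 10 (N+O), logP ≤ 5. The logP
estimator is a deliberately coarse additive atomic-contribution scheme
(named in the `ParameterSet` as `logp_method`); it only has to separate
grossly greasy molecules from drug-like ones, and any estimator can be
substituted by overwriting the verdict inputs.

## Receptor preparation

Titratable sidechains are assigned by the hydrogen-bonding neighborhood of
the heavy-atom structure, with 3.5 Å as the distance limit: Asp/Glu are
neutral iff a carboxylate oxygen has an acceptor within the limit; Lys is
charged unless a donor sits near its amine; His follows the same
donor-neighborhood criterion (the neutral tautomer puts the H on the
nitrogen away from the donor; N-epsilon-H when ambiguous). Arg is always
charged. "Points toward" is operationalized as pure distance; an optional
angular gate (≥ 90° off the C–O bond) can be enabled. Decisions are logged
per residue and written as REMARK lines by `write_receptor_pdb()`.
Hydrogens are placed at ideal internal coordinates with no minimization —
the receptor model is for scoring, not refinement. Receptor charges come
from the same PEOE scheme, seeded with the formal charges the protonation
states imply.

The *hinge residue* — in a kinase, the central residue of the linker whose
backbone amide hydrogen-bonds nearly every ATP-competitive inhibitor — is
designated explicitly (`designate_hinge_residue()`), caching handles to
its backbone N–H and C=O.

## Docking

`build_grids()` precomputes, over a user box (or the whole receptor
domain), per-ligand-type 12-6 and directional 12-10 probe maps, an
electrostatic potential map per unit charge, and a Gaussian receptor
occupancy map for the dehydration term; `grid_energy()` then scores a pose
by trilinear interpolation plus exact torsion and intra-ligand terms. The
default spacing is the conventional 0.375 Å. Poses with atoms outside the
box are rejected with an infinite score rather than extrapolated.

`dock()` runs `n_runs` independent searches; each is a small genetic
algorithm over translation, orientation (unit quaternion) and torsions
with tournament selection, uniform block crossover, Gaussian mutation and
elitism, followed by a greedy shrinking-step local refinement of the run's
best pose. Every run is seeded deterministically from `(seed, run index)`,
so results are bit-reproducible and independent of execution order, and
the best-over-runs energy can only improve as runs are added. Final poses
are clustered by symmetry-aware heavy-atom RMSD (graph automorphisms via
igraph; cutoff 2.0 Å). Desk-scale defaults (population 50, 100
generations) suit pockets of tens of atoms; the test fixtures use smaller
populations because their 4-atom rigid probes converge within a few
hundred evaluations.

## The two-step screen

`run_screen()` mirrors the published filtration design: (1) Rule-of-Five,
(2) dock every survivor and keep the best-energy slice — a top-N rank
cutoff by default, matching how a fixed number of initial virtual hits is
selected in practice, with an absolute-threshold mode also provided — then
(3) keep only molecules whose best pose forms at least one hinge hydrogen
bond: a ligand acceptor within 3.5 Å of the hinge backbone N, or a ligand
donor heavy atom within 3.5 Å of the hinge backbone O. The criterion is
heavy-atom distance only, as the published protocol states a distance
limit and no angle. Ties in the energy ranking break by molecule id, so
permuting the library changes nothing. The report carries every molecule
with its stage flags, and survivor sets are nested by construction.

## Core-fixed growth

`core_template()` marks up to four substitution points (terminal
hydrogens) on a docked scaffold; `enumerate_derivatives()` forms the full
Cartesian product over a small fragment library (H, methyl, ethyl,
methoxy, chloro, bromo, phenyl — the chemistry of the published SAR
series), deduplicated by element-colored canonical graph form.
Enumeration is exhaustive up to `max_enum` (default 1e5, the scale of the
published design); larger spaces are refused rather than silently
subsampled — grow one site subset at a time instead.
`grow_and_score()` places each fragment on the old C–H vector at ideal
bond length and optimizes only the substituent dihedrals (coarse scan,
two passes) while every core atom stays bit-identical to the docked
coordinates; the all-H derivative therefore scores exactly as the core,
and the core RMSD of every scored derivative is exactly zero.
`select_candidates()` applies the druggability filter and truncates to the
top K.

## What the synthetic fixtures show — and what they do not

`make_toy_complex()` builds an abstract pocket: a carbon shell of ~5.3 Å
radius with a cone opening toward a single backbone-like amide (residue
"ALA 1950"), and a rigid 4-atom ketone probe planted either on the hinge
N–H axis at 2.9 Å (binder), deep in the cavity with its oxygen ≥ 4 Å from
the hinge (nonbinder), or overlapping a shell atom (clash). The planted
binder pose is constructed to sit in the score's basin: hydrogen bond,
electrostatics and shell dispersion all favor it. `make_library()` plants
rigid polar binders among nonpolar hydrocarbons (plus a few oversized
molecules that fail two Rule-of-Five rules), so the expected outcome of
every pipeline stage is known by construction.

These fixtures exercise the *logic* end to end — term arithmetic against
an independent oracle, grid fidelity, search convergence, filtration
exactness, growth contracts — on problems whose answers are provable.
They do not emulate a real kinase ATP site: real pockets are larger and
anisotropic, real ligands are flexible and tautomerize, real charge
distributions are subtler, and the placeholder solvation table is not the
fitted one. Passing tests therefore certify the machinery, not predictive
accuracy on real proteins; predictive use requires a fitted parameter
table dropped in via `read_parameter_table()`.

Problem sizes used by the automated checks: 100 toy complexes for oracle
equivalence; grid fidelity at 1.0/0.5/0.25 Å on four complexes; 10 seeds
of 20 docking runs for pose recovery; one 200-molecule library with 20
planted binders for the pipeline; 625 derivatives (4 sites of 5 fragments)
for the enumeration contract.

## Known limitations

* No tautomer or stereoisomer enumeration and no pKa model on the ligand
  side; ligand protonation is whatever the input records carry.
* Receptor sidechains are rigid; no covalent docking.
* The inter-molecular hydrogen-bond term ignores ligand H orientation (by
  design, for grid consistency); ligand donors are treated isotropically.
* The additive logP is crude; substitute a fitted estimator for
  production-grade filtering.
* Aromaticity perception is ring-pattern based and adequate for the
  drug-like chemistry handled here, not a full aromaticity model.
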