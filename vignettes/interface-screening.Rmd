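---
title: "Targeting helix-mediated dimer interfaces: methods and design notes"
author: "helixscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeting helix-mediated dimer interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixscreen)
```

## The problem

Some enzymes are only active as dimers: when the catalytic site spans the
subunit interface — transketolase-like enzymes are the classic case — a
small molecule that binds one monomer's half of the interface can act as a
dimerization inhibitor. The interfaces in question are often a pair of
antiparallel alpha helices, where a handful of residues (a glutamine and a
lysine donating hydrogen bonds into a partner glutamate, flanked by a
hydrophobic contact) carry most of the binding energy. `helixscreen`
implements the complete screening protocol against such an interface:

1. **Interface energetics** — per-residue interaction energies between the
   two chains, averaged over a coordinate ensemble;
2. **Hot-spot ranking** — energy, interaction type (hydrogen-bond
   occupancy) and optional sequence conservation;
3. **Pharmacophore derivation** — the protein-side hot spots are converted
   into the complementary ligand-side feature set;
4. **Constrained screening** — multi-conformer libraries are matched
   rigidly against the model, gated on RMSD, and filtered sterically with
   reduced radii;
5. **Rescoring** — an empirical contact score, then MM-GBSA-style binding
   energies with per-group electrostatic decomposition.

## Energetics

For two residues on opposite chains the interaction energy is the full
double sum over their atoms, with no distance cutoff:

$$E_{vdw} = \sum_{ij} \varepsilon_{ij}\left[\left(\tfrac{r^{min}_{ij}}{r_{ij}}\right)^{12} - 2\left(\tfrac{r^{min}_{ij}}{r_{ij}}\right)^{6}\right],
\qquad
E_{elec} = \sum_{ij} \frac{332.0637\, q_i q_j}{\epsilon(r_{ij})\, r_{ij}}$$

with Amber-convention combining rules
($\varepsilon_{ij} = \sqrt{\varepsilon_i\varepsilon_j}$,
$r^{min}_{ij} = r^{min}_i/2 + r^{min}_j/2$) and the Coulomb constant
332.0637 kcal·Å/(mol·e²) throughout. Because the decomposition is run
without explicit solvent, the default dielectric is distance-dependent,
$\epsilon(r) = 4r$, which bounds short-range electrostatics; a constant
dielectric is available through `dielectric_model()`. No 1–4 or exclusion
bookkeeping is needed: the two chains share no bonds. The ensemble mean and
the per-pair standard deviation over frames are reported; frame 1 is always
the unjittered reference and frame order is the file/model order.

Hydrogen bonds are detected geometrically: donors are N/O atoms with an
attached hydrogen (attachment inferred within each residue at a 1.25 Å
cutoff), acceptors are oxygens plus hydrogen-free nitrogens, and an event
requires donor–acceptor distance ≤ 3.5 Å and a donor–H–acceptor angle
≥ 120°. These thresholds are deliberately permissive defaults and are
arguments, not constants. Occupancy is the fraction of frames with an
event.

Hot spots are ranked by the per-residue total against the entire opposite
chain (ties break by occupancy, then residue number). A residue is flagged
when its energy is ≤ −2 kcal/mol **and** its best occupancy is ≥ 0.5
**and**, when a conservation map is supplied, conservation is ≥ 0.5; with
no map the conservation criterion is reported as not evaluated rather than
silently passed. Hydrophobic contributors rarely pass an electrostatic
flag, so the pipeline adds chain-A hydrophobic residues whose summed vdW
term is ≤ −0.25 kcal/mol — the leucine-like patch enters the model through
this route.

## Pharmacophore derivation and matching

Features are typed points: HD (ligand donor), HA (ligand acceptor), HY
(hydrophobic). Derivation runs on the reference frame and emits, per
hot-spot residue:

* one **HA** per protein donor group, 2.9 Å from the donor heavy atom
  along its most exposed N–H direction (one feature per donor nitrogen,
  not per hydrogen — a lysine ammonium contributes one point);
* one **HD** per hydrogen-free acceptor oxygen, 2.9 Å along the extended
  antecedent→oxygen direction;
* one **HY** per hydrophobic side chain, 4.0 Å from the side-chain carbon
  centroid along the outward normal from the chain's helix axis.

The 2.9 Å projection is a typical heavy-atom hydrogen-bond distance and
4.0 Å a typical hydrophobic contact; both are arguments. The default
synthetic interface yields exactly five points (HA×2, HD×2, HY), matching
the donor/acceptor/hydrophobe pattern planted in the dimer.

Matching enumerates every kind-compatible injective assignment of model
features to ligand features (capped at 10⁶; beyond that the caller is told
to prune), superposes each candidate by least squares with **proper
rotations only** (chirality is never mirrored), and keeps the minimal-RMSD
assignment, breaking ties lexicographically. A conformer is accepted when
that RMSD is at most the gate, 1.0 Å by default.

A finding worth recording: a single feature displaced 2.5 Å among five
would give RMSD $2.5/\sqrt{5} = 1.118$ Å if the transform were held fixed,
but the *optimal* refit absorbs much of a single-point displacement —
measured minima run 0.5–0.95 Å depending on direction, often inside the
1.0 Å gate. Decoy construction therefore never assumes a displacement is
sufficient: the generator verifies each decoy against the matcher and
escalates its displacement (×1.4, at most six times) until rejection is
confirmed. Actives are audited the same way (they must pass).

## Screening, placement and refinement

Accepted matches place the whole conformer rigidly; placement preserves
all intra-ligand distances to numerical precision. Steric filtering scales
every collision radius by 0.6 — a 40% reduction that tolerates minor
clashes as a crude stand-in for flexibility — and counts heavy-atom pairs
with $d < 0.6\,(r_i + r_j)$; hydrogens are ignored (their radii are poorly
defined and their clashes are meaningless at this resolution). The default
tolerance is zero residual clashes at the reduced radii; both the scale
and the allowance are configuration. The ranking is RMSD-first, ties by
empirical score, then name, which makes the output independent of library
input order.

Poses are refined by greedy rigid-body descent (six degrees of freedom:
±0.05 Å translations, ±0.5° rotations about the ligand centroid, 200
accepted moves maximum) on the intermolecular MM energy at dielectric 1.
The ligand is internally frozen — conformational search belongs to the
conformer library, not the minimizer. Descent is monotone by construction
and deterministic.

## Scoring

The **empirical score** is an additive contact score with configurable
weights (defaults 0.004, 0.5, 0.1, 0.5): a soft 8–4 vdW contact sum, a
hydrogen-bond term built from piecewise-linear distance (1 below 3.0 Å, 0
at 3.5 Å) and angle (1 above 150°, 0 at 120°) ramps, a count of C–C
contacts within 4.5 Å, and a rotor penalty of −0.5 per rotatable bond.
Higher is better. Its absolute values are not comparable to any published
empirical scoring function's outputs, and no such comparison should be
made.

The **binding energy** is an end-point MM-GBSA-style estimate on the
(ideally minimized) pose:

$$\Delta G = E_{vdw} + E_{elec} + \Delta G_{polar} + \Delta G_{nonpolar}$$

* MM terms: intermolecular, dielectric 1.
* $\Delta G_{polar}$: pairwise generalized-Born with
  $f_{ij} = \sqrt{r^2 + \alpha_i\alpha_j e^{-r^2/4\alpha_i\alpha_j}}$,
  solvent dielectric 80, and HCT-style pairwise-descreened effective radii
  (intrinsic radius = collision radius − 0.09 Å, uniform scale 0.8),
  computed complex-minus-parts with radii re-derived per species. The
  single-ion limit reproduces the Born closed form
  $-\tfrac{k}{2}(1 - 1/80)\,q^2/\alpha$ to within 0.1%, which anchors the
  implementation. A finite-difference Poisson–Boltzmann solver is outside
  this package's scope; the GB term is labelled `g_polar` and documented
  as such.
* $\Delta G_{nonpolar} = 0.00542\,\Delta SASA + 0.92$ kcal/mol, with SASA
  from Shrake–Rupley sampling (960 deterministic golden-spiral points per
  atom, probe 1.4 Å, identical grids for complex and parts so quadrature
  error largely cancels). At infinite separation the offset survives, so
  the reported total tends to +0.92 rather than exactly zero; within a
  congeneric series the constant is irrelevant. Because the quadrature
  grid has a fixed orientation, SASA-dependent terms are rotation
  invariant only to ~0.01 kcal/mol; the distance-only terms are exact.
* Entropy is never computed; `entropy_included` is always `FALSE` and
  totals are comparable only within a series.

**Group electrostatics** report the Coulomb sum (dielectric 1, as in the
MM term) of named ligand atom groups against the whole receptor; a
partition of the ligand reproduces the MM electrostatic term exactly,
which the tests assert at 1e−6. Group energies are read off *minimized*
poses: on the toy receptor a raw placement puts the net-negative nitro
group simultaneously near the target lysine and near the adjacent
glutamate carboxylate, and relaxation is what resolves that frustration —
the same reason end-point protocols score minimized structures.

## The synthetic benchmark

The generators are pure functions of spec + seed and define the study
conditions; they are not tuning knobs.

* **Dimer**: two ideal helices (rise 1.5 Å, twist 100°, CA radius 2.3 Å,
  axis separation 10 Å), 11 residues per chain numbered 200–210,
  antiparallel. Reduced pseudo side chains (3–6 atoms) realize the planted
  pattern: Gln-203 and Lys-204 of each chain donate into Glu-207 of the
  partner (donor–acceptor distances analytically exact at 2.9 Å), and
  leucines at the helix ends (A:201/B:209) meet at 4.0 Å. Charges come
  from the built-in table (+1 lysine, −1 glutamate, all residues sum to
  their formal charge within 1e−6 e). Side chains are geometric, not
  rotameric; the point is energetics and geometry, not chemistry.
* **Ensemble**: i.i.d. Gaussian jitter (σ = 0.1 Å default, 20 frames) on
  the reference coordinates. This emulates the *magnitude* of thermal
  coordinate noise, not dynamics: no correlated motions, no side-chain
  flips, no drift. Passing tests show the pipeline's statistics are
  stable under coordinate noise — they do not show robustness to
  conformational change.
* **Library**: actives place one chemical group per model point (amine at
  HD, carbonyl at HA, a nitro group at the lysine-facing HA, benzene on
  HY) with uniform placement noise < 0.3 Å on a linker-chain scaffold
  pushed away from the receptor; every ligand is a valence-correct graph
  with explicit hydrogens and two conformers. Analogs replace the nitro
  with a neutral carbonyl — still pharmacophore-compatible, but stripped
  of the charged-group electrostatics. Decoys cycle through displaced-HY,
  displaced-HD and donor→methyl kind swaps, matcher-audited as described
  above.

Problem sizes throughout (52-atom dimer, 20 frames, 52-ligand library, 960
SASA points) were chosen so a full run is a desk-scale computation — the
default end-to-end pipeline completes in well under a minute — while every
stage still exercises the same code paths a larger system would.

## Repository shape

The package exposes every stage as ordinary functions (`interface_matrix()`,
`derive_interface_pharmacophore()`, `screen_library()`, `mmpbsa_energy()`,
…) plus one orchestrator, `run_pipeline()`, driven by a validated config.
The numbered scripts under `analysis/` are thin narrative drivers of those
functions — the package presents the protocol as a reproducible analysis
rather than a shell tool, so no separate command-line binary is shipped.

## Known limitations

* Force-field parameters ship as a minimal documented table (element-level
  LJ/radii plus the synthetic residues' charges); reproducing a published
  charge model requires a user-supplied table. SDF input does not carry
  partial charges.
* The GB/SASA solvation pair is a fast analytic stand-in for grid-based
  Poisson–Boltzmann; absolute binding energies are not comparable to
  published end-point results and only within-series contrasts are
  meaningful.
* Rigid-ligand refinement cannot resolve strain that a torsional
  minimizer would; conformer quality is the library's responsibility.
* The hot-spot criteria act on a toy interface with planted signals;
  thresholds will need re-examination on real ensembles, where energies
  are noisier and occupancies rarely saturate at 1.0.
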