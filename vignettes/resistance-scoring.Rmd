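---
title: "Scoring target-site mutations for herbicide resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring target-site mutations for herbicide resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistrank)
library(dplyr)
```

## The problem

Target-site resistance to acetohydroxyacid synthase (AHAS/ALS)
inhibitors — the largest herbicide site-of-action group — arises from
amino-acid substitutions that weaken inhibitor binding without
destroying catalysis. Given a wild-type enzyme–herbicide complex and a
panel of candidate substitutions, the question is which substitutions
are resistance mutations. `resistrank` answers it with a desk-scale,
biophysics-based pipeline:

1. build each variant structure in silico (side-chain grafting plus
   clash relief on the wild-type complex);
2. score every structure with a single-structure implicit-solvent
   binding free energy,
   $\Delta G_{bind} = G_{complex} - (G_{receptor} + G_{ligand})$, where
   $G = E_{ele} + E_{vdW} + G_{pol} + G_{np}$ (internal terms cancel,
   the entropy term is dropped);
3. rank variants from weak to strong binding and call the top of the
   ranking resistant;
4. quantify discrimination with accuracy, enrichment factor (EF) and
   ROC-AUC, compare method families with paired t-tests, and probe
   robustness to class imbalance by subset resampling.

Scores from the bundled simplified parameter sets are meaningful
*comparatively* — wild type versus variants under one consistent model —
not as absolute binding affinities.

## The energy model

**Single-trajectory convention.** Receptor and ligand coordinates are
taken from the complex. Consequently the gas-phase difference reduces
exactly to receptor×ligand cross terms (`interaction_energy()`), the
internal bond/angle/dihedral terms cancel identically, and the reported
`e_internal` and `entropy_term` are exactly zero rather than silently
omitted.

**Electrostatics and dispersion.** Full pairwise screened Coulomb
(`k_C = 332.0637` kcal·Å/(mol·e²), no cutoff) and 12-6 Lennard-Jones
with Lorentz–Berthelot combination. The bundled LJ table is keyed by
element with literature-typical well depths; production force-field
atom typing is deliberately out of scope, and users can supply their
own table (`read_lj_table()`, or an `atom_class` column).

**Polar solvation** (`epsilon_in` 4 by default, 2 selectable;
`epsilon_out` 80, zero ionic strength):

* *GB-OBC*: Hawkins–Cramer–Truhlar pairwise descreening with the OBC
  model-II tanh rescaling (α = 1.0, β = 0.8, γ = 4.85, offset 0.09 Å).
  An isolated atom recovers $R = \rho - 0.09$ Å and a single ion the
  Born energy exactly.
* *GBn*: the same machinery with that model's published coefficients
  plus the interatomic neck correction. The published neck lookup
  tables are not shipped here; instead the neck position `d0` and
  height `m0` are computed at first use by direct numerical quadrature
  of the defining integral (the $1/r^4$ integral over the
  solvent-excluded neck between two spheres with a 1.4 Å probe) and
  memoised per radius pair. This is the package's own numerical
  realisation of the published functional form; all constants are
  `gb_config()` fields a user can override.
* *ALPB*: the analytical linearized PB correction
  $\frac{1}{1+\alpha\beta}\sum_{ij} q_i q_j (1/f_{GB} + \alpha\beta/A)$
  with α = 0.571412 and electrostatic size `A` from a bounding-sphere
  rule (default) or a second-moment rule. ALPB is exact for a Born ion
  with `A = R` — it then *equals* plain GB — and tends to
  GB/(1+αβ) as `A` grows.
* *PB*: a finite-difference Poisson solver with a two-dielectric map.
  The dielectric boundary is the van der Waals surface (edge
  dielectrics fractionally harmonic-averaged where a sphere cuts a
  lattice edge; no reentrant molecular-surface construction — a
  documented simplification), charges are spread trilinearly, boundary
  potentials are Coulombic, and red-black SOR iterates to a maximum
  per-sweep update below `sor_tolerance`. The reaction energy is the
  difference of a solvated and a uniform-dielectric solve on the same
  grid, which cancels the grid self-energy. On a Born ion at 0.4 Å
  spacing the solver lands well within 5% of the closed form and the
  error shrinks as the grid refines.

**Nonpolar solvation.** Shrake–Rupley SASA on a deterministic
golden-spiral point set (960 points/atom, 1.4 Å probe) times
γ = 0.0072 kcal/(mol·Å²), plus β = 0.

## Structure handling

Structures are tibbles of atom records read from whitespace-separated
PQR (charge and radius as the final two fields; `MODEL`/`ENDMDL`
ensembles become a `model` column). Chains are tagged
receptor/ligand — HETATM-only chains default to ligand. The package is
heavy-atom oriented: bundled templates and toys carry no hydrogens,
but hydrogens present in input are treated as ordinary atoms with
their given charge and radius.

**Mutation grafting.** Panel positions are translated between
numbering conventions through an explicit `numbering_map()`; because
the offset between conventions is not constant (e.g. reference 197 ↦
target 189 but 376 ↦ 372), unlisted positions are an error, never an
extrapolation. The target side chain is replaced by an idealized
template placed through the backbone N–CA–C frame, spun through 12
trial rotations about the CA–CB axis, and the lowest-nonbonded-energy
rotamer is kept before rigid-fragment clash relief. Published rotamer
libraries and full force-field minimisation in explicit solvent are
intentionally not reproduced; the grafting protocol is a deterministic
stand-in adequate for comparative scoring, and grafting a residue onto
itself is defined as a no-op.

**Clash relief.** `relax_mutant()` moves the mobile selection as one
rigid fragment (translation + rotation; translation only for a single
atom) downhill on the nonbonded potential, steepest descent followed
by Polak–Ribière conjugate gradient with a backtracking line search,
so energy is monotone non-increasing and results are bit-reproducible.
Two numerical choices matter: the site's own backbone is excluded from
the potential during post-graft relief (a nonbonded-only energy would
otherwise be dominated by the covalent CA–CB contact), and the
fragment is rigid, so internal template geometry is preserved by
construction rather than by bonded force terms.

## The evaluation layer

Variants are sorted by `dg` descending (weak binders first), ties
broken by `variant_id` so results are independent of input order. With
`A` resistant labels among `N` variants, the resistance call cut
defaults to `A`; accuracy is `(TR + TS)/N`, the enrichment factor at
depth 10 is `(a/10)/(A/N)` (ceiling `N/A`, e.g. 29/25 = 1.16 for the
curated panel), and the ROC sweeps the cut from 0 to `N`. AUC is
integrated by trapezoid over tie blocks, which provably equals
Mann–Whitney pair counting with half credit for tied cross-class
pairs; the tests verify that identity exhaustively on small panels.
The paired t-test is delegated to `stats::t.test(paired = TRUE)` with
one decided degenerate case: all-zero differences return `t = 0, p =
1` instead of an error.

**Imbalance resampling.** `imbalance_resample()` re-evaluates accuracy
on reduced panels of `k` resistant variants (all susceptible variants
and the wild type always retained), `k` from 4 to 24 by default, with
the call cut re-set to `k`. Per `k` it draws up to 1000 *unique*
subsets, switching to exhaustive enumeration whenever
`choose(A, k) <= draws` — so a 25-strong resistant pool yields exactly
25 subsets at `k = 24` and 300 at `k = 23`. One integer seed drives a
single generator per call.

## Synthetic data: what it emulates and what it does not

`gen_toy_complex()` builds a ring of rigid 4-atom pseudo-residues
around a small charged ligand with complementary contact charges at
favourable contact distances, then derives variants: contact-charge
flips and steric inflation weaken binding (resistant-like), while
deleting distal bulk or flipping a far-away small charge leaves
binding essentially untouched (susceptible-like). Defaults (8 pocket
residues, 12 ligand atoms, ±0.3–0.5 e charges, ~3.6 Å contacts) were
chosen once to give a favourable wild type (ΔG < 0 under GB-OBC,
ε = 4) with clear but not caricatured perturbations.
`gen_toy_peptide()` plays the same role with real template residues so
grafting is exercised on genuine N–CA–C backbones.

`gen_affinity_table()` emulates score tables directly:
`dG = base + delta·[R] + √ρ·Z_v + √(1−ρ)·E_vm` with per-variant shared
effects giving inter-method correlation ρ. Defaults mirror the curated
panel composition (25 R, 3 S + WT) with a 2 kcal/mol resistant shift
and 0.5 kcal/mol noise.

Neither generator emulates conformational sampling, temporal
correlation of trajectory frames, protonation equilibria, or
full-size dimeric enzymes. Passing tests therefore demonstrate the
correctness of the scoring and evaluation machinery and the stated
statistical behaviour of the generators — not that the simplified
energy function reproduces experimental resistance profiles of real
enzymes.

One statistical property deserves honesty: with 25 resistant versus 4
susceptible variants and per-variant noise σ, a 4σ class shift leaves
roughly a 12% chance that the extremes of the two classes overlap
(order statistics of 25 vs 4 Gaussians), so *perfect* separation in
≥99% of seeds is only reached at larger shifts; the test suite pins
near-certain separation at 8σ and the chance-level behaviour of the
null (δ = 0) table.

## Curated panel fixture

`load_kochia_panel()` ships the curated *Kochia scoparia* AHAS panel —
wild type plus 28 substitutions at seven sites (reference numbering
197, 225, 268, 284, 376, 434, 574; ten single-point substitutions at
197; 25 resistant, 3 susceptible) — checksum-verified on load, with
`ahas_numbering_map()` carrying the reference↔Kochia position pairs.
The panel supplies labels and mutation strings; scoring it requires a
user-supplied structure of the enzyme–herbicide complex.

## Problem sizes and numerical choices

Everything here is desk-scale by design: pocket models of tens of
atoms, panels of tens of variants, full O(n²) pairwise sums with no
cutoffs (exact and reproducible at this size), PB grids of ~50³ nodes.
The test suite runs the PB Born benchmark at 0.8 and 0.4 Å spacing,
oracle comparisons up to 200 atoms and 12-variant exhaustive AUC
checks, and resampling caps on the real panel composition; these sizes
were chosen as the smallest that exercise every code path
meaningfully. Degenerate inputs are errors, not warnings: coincident
atoms in a Coulomb sum, single-class ROC panels, unmapped residue
positions, non-convergent PB solves, and corrupted fixtures all abort
with informative messages.

## Known limitations

* The energy model is comparative, not calibrated: no force-field atom
  typing, no protonation assignment, no conformational ensembles
  beyond user-supplied frames (frame-averaging is provided, molecular
  dynamics is not).
* The PB dielectric boundary is the van der Waals surface; absolute
  polar energies differ from molecular-surface solvers, though
  rankings at fixed settings are stable.
* GBn neck parameters come from the package's own quadrature of the
  defining integral, not the published lookup table; small deviations
  from other implementations are expected.
* The idealized template geometry closes five-membered and fused rings
  only approximately (sub-0.1 Å); adequate for comparative nonbonded
  scoring, not for stereochemical analysis.
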