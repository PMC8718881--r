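---
title: "Methods: criteria-driven PEGylation site engineering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: criteria-driven PEGylation site engineering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegsite)
```

This vignette is the package's account of its models and the design choices
behind them: what each stage computes, which thresholds matter and why their
defaults are what they are, what the synthetic fixtures do and do not
emulate, and where the numerical corners are.

## The selection model

Amine-targeted PEG reagents (NHS esters) react with solvent-exposed lysine
epsilon-amines and the N-terminal alpha-amine. The package treats PEGylation
design as a residue classification problem over two disjoint candidate
sets.

**Engineer-in (R→K).** An arginine is a good site to convert into a PEG
acceptor when all applicable criteria hold, as a hard conjunction — no
scoring or weighting is invented on top:

| criterion | measured value | pass condition | default |
|---|---|---|---|
| not conserved | identity fraction to the query in its alignment column | `< conservation_max` | 0.7 |
| accessible | residue SASA (Å²) | `> sasa_min`, strict | 75 |
| not on a loop | Cα secondary-structure class | class ≠ C | — |
| no salt bridge | min N–O distance to Asp/Glu carboxylates | no pair ≤ cutoff | 4.0 Å |
| far from active site | min atom distance to the active-site set | `≥ active_site_min_distance` | 10 Å |

The SASA comparison is deliberately strict (`>`, not `≥`) and the audit
table reports the measured value, so a site that barely clears the
threshold shows its margin rather than hiding it. The conservation bound of
0.7 and the 10 Å active-site floor are documented, overridable defaults:
reasonable values for "not highly conserved" and "does not gate the
substrate channel", not constants of nature. Arginine-specific rationale:
arginine is the conservative surface swap for lysine (charge preserved,
reactivity removed/created), which is why the two directions are R→K and
K→R rather than arbitrary mutations.

**Engineer-out (K→R).** A lysine should be removed from the reactive
inventory when its modification is expected to cost activity. The verdict
is `accessible AND (flexible-loop OR active-site-proximal)` — disjunctive
in the liability, conjunctive with accessibility, since a buried lysine
needs no protection. "Flexible loop" is operationalised as coil class
*and* B-factor z ≥ `loop_bz_min` (default 1.0): crystallographic B-factors
are the only flexibility readout a single structure offers, and the z-score
form makes the threshold transferable across structures with different
overall B scales (it is invariant to positive affine rescaling of B).

Missing inputs are never imputed. Without an alignment the conservation
criterion is *inapplicable*: the verdict is computed from the remaining
criteria and the result carries a prominent `partial` flag, so a partial
evaluation can never be mistaken for a full one. The same applies to a
missing active-site definition.

## Feature computation

**SASA (Shrake–Rupley).** Each atom's expanded sphere (van der Waals radius
plus a 1.4 Å water probe) is sampled with a deterministic golden-spiral
lattice of 960 points; the accessible fraction times the sphere area is the
atom's SASA. Determinism was chosen over library defaults so identical
inputs give bit-identical reports; a point exactly on a neighbour's sphere
counts as buried, which fixes the tie deterministically. Radii: C 1.70,
N 1.55, O 1.52, S 1.80, P 1.80 Å, overridable; unknown elements are an
error listing the offending atoms rather than a silent fallback. Residue
SASA is reported both as the total and as the side-chain-only sum (atoms
beyond the backbone set N/CA/C/O), with a config switch for which one the
accessibility criteria read; the default is the total, and the assembly
(all deposited chains) is the default context because the biologically
relevant surface of an obligate homodimer is the dimer surface. The
monomer context is available for comparison; per-residue assembly SASA is
provably ≤ the isolated-chain value, and the test suite checks this.

**Secondary structure.** A Cα-only, P-SEA-style distance-window
assignment: residue *i* is helix when the two four-residue spans covering
it have start-to-end distances in the helix windows (3-step span 4.2–5.8 Å,
4-step span 5.0–6.9 Å; an ideal helix gives 5.05 and 6.20 Å) and the local
Cα pseudo-torsion is in 20–80° (ideal ≈ +50°, right-handed); strand uses
9.0–12.5 Å and 12.0–16.5 Å. Everything else, including the two residues at
each terminus and chains shorter than five residues, is coil. This is
coarser than a hydrogen-bond method (DSSP-exact assignment is a declared
non-goal: no hydrogens, no electrostatics), but the loop criterion only
needs the helix/strand/coil trichotomy.

**Salt bridges.** A bridge is a basic side-chain nitrogen (Lys NZ; Arg
NE/NH1/NH2; His ND1/NE2) within 4.0 Å of an acidic carboxylate oxygen (Asp
OD1/OD2; Glu OE1/OE2), deduplicated per residue pair at the minimum
distance. Residues whose charged atoms are unresolved are skipped with a
warning — absence of evidence is not evidence of a bridge. The pKa concern
behind this criterion is encoded *only* as this exclusion; no electrostatic
calculation is attempted.

**Disorder and numbering.** Author (PDB) numbering is authoritative
throughout, with `seqres_offset` reconciling deposits whose SEQRES does not
start at full-length residue 1. Unresolved segments are maximal runs of
SEQRES positions without coordinates; without SEQRES only internal
author-numbering gaps are detectable, a documented limitation (N/C-terminal
disorder is invisible in that case).

## Truncation design

N-terminal truncation candidates come from three signals, each carried as a
rationale flag: the first residue after a disorder boundary, the first
unflagged residue after a proline-rich window (≥ 3 prolines in any 5-residue
window — the ribosome-stalling motif), and the query residue aligned to an
ortholog's first residue. Candidates merge flags when they coincide and are
ranked by flag count, ties toward the larger truncation (the more
EcTP-like construct). Enumeration is bounded to the first 60 residues —
this is N-terminal design, not domain dissection. Pairwise alignment is
Needleman–Wunsch with affine gaps (BLOSUM62, open 11, extend 1, end gaps
penalised) via Biostrings; because published percent identities rarely
state their denominator, both matches/columns and matches/shorter-sequence
are reported, and no bit-exact identity target is asserted anywhere.
Translation-initiation-rate rescoring of candidates is deliberately not
performed: it belongs to a third-party thermodynamic model outside this
package's scope, and the report leaves that judgement to the user.

## Kinetics

The steady-state model is v/[E] = kcat·[S]/(KM+[S]). Initial rates come
from the least-squares slope of the absorbance progress curve restricted to
< 10% substrate conversion (inferred from the absorbance change itself),
divided by Δε·l; the defaults Δε = 1000 M⁻¹cm⁻¹ (290 nm, dThd) and
1370 M⁻¹cm⁻¹ (282 nm, dUrd) match the standard depyrimidination assay.
Fitting is Levenberg–Marquardt (minpack.lm) initialised at
kcat₀ = max(v/[E]), KM₀ = median([S]), capped at 500 iterations with
relative tolerance 1e-10; standard errors come from the Jacobian-based
covariance at the optimum. KM stays in µM and efficiency is kcat/KM in
M⁻¹s⁻¹, with the single 10⁶ conversion applied in exactly one function.
Efficiency SE uses first-order (delta-method) propagation, by default
ignoring the kcat–KM covariance — the covariance-aware option exists, but
published "best fit ± SE" tables do not state their propagation, so the
simpler default is also the more comparable one. Replicates are fitted
pooled by default with a mean-per-concentration mode available, since
published methods rarely say which was used; on balanced data the point
estimates coincide. A KM whose relative SE exceeds 50% (the classic
all-[S]≪KM design flaw) triggers an explicit warning. Fold changes are
reported raw and at two significant figures, the convention of published
fold-change claims.

One calibration caveat, verified in the test suite: under multiplicative
noise an unweighted fit's reported SEs are only approximately calibrated
(empirical 3-SE coverage ≈ 95% rather than 99.7%). The acceptance study
therefore judges *mean* recovery across 200 datasets against the published
SEs and checks that reported SEs sit within a factor of two of the
empirical spread, rather than asserting exact per-fit coverage.

## The synthetic fixtures

`make_toy_structure()` builds a single chain from canonical geometry
templates — three right-handed helices (rise 1.5 Å, 100° twist, radius
2.3 Å) on parallel axes joined by sharp zigzag coils — with an unresolved
N-terminal prefix declared in SEQRES, and plants ground truth for every
feature: three arginines constructed to pass all engineer-in criteria; five
decoys that each fail exactly one (conserved column, occluder-shell burial,
loop location, a 3.4 Å Asp carboxylate, ligand proximity); two flexible-loop
lysines (B ≈ 55 against a backbone of B ≈ 20) that must be engineered out;
and a rigid-helix plus a buried lysine that must not be. Side chains are
minimal — a Cβ-outward atom chain only where SASA or bridge ground truth
requires it — and burial is enforced by an explicit shell of occluder
pseudo-atoms rather than by packing, because the fixture's job is to
exercise the feature computations at unambiguous margins, not to be a
plausible protein. A small seeded coordinate jitter (σ = 0.08 Å) and the
seeded B-factor/alignment draws make the 20-seed replicate suite vary
without ever moving a planted label across a threshold.

What passing the fixture suite shows: the geometry, conservation and
selection machinery implement their definitions correctly, with precision
and recall 1.0 against planted labels. What it does not show: that the
default thresholds reproduce any particular real protein's published site
list. Real structures have continuous exposure gradients, ambiguous
secondary structure, and conservation signals that depend on alignment
depth and taxon sampling; the real-structure check is therefore a separate,
data-requiring test that reports margins instead of pretending the
thresholds are sharp. The alignment generator realises per-column identity
targets by exact count construction (within 0.5/depth of the target), and
the kinetics generator applies multiplicative Gaussian noise with
zero-clipping counted and reported.

Problem sizes used by the shipped studies — 68 resolved residues per toy
structure, 60-sequence alignments, 200 simulated datasets of 21 points per
recovery study — were chosen as the smallest sizes at which the planted
margins and the stochastic checks are stable across seeds.

## Numerical and degenerate-input choices

* Altloc conformers: highest occupancy wins, ties alphabetically —
  determinism over sophistication.
* Zero B-factor variance: all z-scores 0 with a warning, not NaN.
* Empty active-site target set: distance +Inf, criterion inapplicable.
* All-gap alignment columns and query-gap columns: NA, never 0.
* Ladder arithmetic treats the PEG adduct at its nominal 5 kDa (linker mass
  ignored), matching how approximate conjugate masses are read off gels;
  the base mass is the explicit construct sequence's average mass — His-tags
  and cloning scars count when and only when they are in the sequence given.
* Substitutions validate the stated source residue at the stated position
  and fail loudly on mismatch, the cheapest guard against numbering-offset
  mistakes between construct and full-length coordinates.

## Known limitations

No hydrogen placement, electrostatics or pKa computation; no ΔΔG stability
prediction for proposed substitutions; no conjugation kinetics or PEG
polydispersity; no mmCIF, NMR ensembles, or symmetry expansion; chains of a
homodimer are treated equivalently rather than recommended asymmetrically.
The Cα secondary-structure assignment trims helix termini conservatively,
which slightly over-calls coil at segment boundaries — conservative in
exactly the direction that matters for the loop-exclusion criterion.
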