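# pegsite

Rational, criteria-driven design of amine-targeted PEGylation for
therapeutic enzymes, with the surrounding structural bioinformatics and
steady-state kinetics needed to execute and evaluate such a campaign.

## The problem

Covalent attachment of polyethylene glycol (PEG) to a therapeutic enzyme
extends its serum half-life, but NHS-ester PEG reagents react with primary
amines — lysine side chains and the N-terminal alpha-amine — wherever they
are solvent-exposed. Two failure modes follow: a protein with few and
marginally exposed lysines PEGylates inefficiently, giving a heterogeneous
mixture of PEG-mer species, and PEGylation of the *wrong* lysines (on
catalytically important flexible loops, or near the active site) destroys
activity. A remedy is surface engineering in both directions:

* **engineer-in (R→K)**: substitute surface arginines with lysines to create
  good PEG acceptor sites. A candidate arginine must (1) not be highly
  conserved among orthologs, (2) have a large solvent-accessible surface
  area (SASA > 75 Å² by default), (3) not sit on a loop whose dynamics PEG
  would rigidify, (4) form no salt bridge with Asp/Glu (which would perturb
  the introduced lysine's pKa), and (5) lie far from the active site.
* **engineer-out (K→R)**: substitute lysines whose PEGylation is expected to
  harm activity — accessible lysines on flexible loops (coil with elevated
  B-factor z-score) or close to the active site — with arginine, which
  keeps the charge but cannot react.

`pegsite` implements this criteria engine with a per-criterion audit trail,
plus every computation feeding it: PDB parsing with SEQRES-based disorder
detection, Shrake–Rupley SASA (deterministic golden-spiral quadrature),
Cα-geometry secondary structure, salt-bridge detection, alignment-based
conservation, N-terminal truncation design (structural disorder, proline
stalling motifs, ortholog anchors), PEG-mer mass ladders, and
Michaelis–Menten kinetics

v/[E] = kcat·[S] / (KM + [S])

fitted by nonlinear least squares with standard errors and catalytic
efficiency kcat/KM in M⁻¹s⁻¹. A synthetic-fixture generator plants known
ground truth (exposed/buried residues, salt bridges, flexible loops,
conserved columns, kinetic parameters) so the whole pipeline is testable
without downloading anything.

## Worked example

```r
library(pegsite)

fx  <- make_toy_structure(seed = 1)          # toy enzyme, planted ground truth
msa <- make_msa(declared_sequence(fx$structure), depth = 60,
                conservation = fx$conservation_targets, seed = 1)
res <- run_selection_pipeline(fx$structure, msa = msa, query_id = "query",
                              active_site = list(ligand = "LIG", cutoff = 4.5))

res$engineer_in[res$engineer_in$verdict, c("id", "sasa", "n_pass")]
#>     id     sasa n_pass
#> 2 A:97 183.2274      5
#> 3 A:40 170.3583      5
#> 5 A:87 148.3330      5

res$engineer_out[res$engineer_out$verdict, c("id", "sasa")]
#>     id     sasa
#> 2 A:57 112.4113
#> 3 A:55 108.6542

res$variant$mutations
#> [1] "K55R" "K57R" "R40K" "R87K" "R97K"
```

The three arginines reported verdict-true are exactly the three the
generator planted to pass all five engineer-in criteria (large SASA, helix,
non-conserved, bridge-free, remote from the ligand); the two lysines are the
planted flexible-loop sites. The five decoy arginines each fail exactly one
criterion, visible in `attr(res$engineer_in, "audit")`.

Kinetics, at the scale of a typical thymidine phosphorylase assay:

```r
d   <- simulate_mm_dataset(kcat = 5, KM = 25, S_uM = c(5,10,25,50,100,250,500),
                           noise_cv = 0.02, replicates = 3, seed = 1)
fit_mm(d)
#> <mm_fit> kcat 5.039 +/- 0.03 1/s; KM 25.21 +/- 0.59 uM; kcat/KM 2e+05 +/- 4.8e+03 1/M/s (n=21)

fold_change(5, 1.8, "kcat")$two_sig        # activity loss upon heavy PEGylation
#> [1] 2.8
```

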