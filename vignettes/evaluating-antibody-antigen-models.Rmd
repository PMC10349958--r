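---
title: "Evaluating predicted antibody-antigen complexes with abagqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating predicted antibody-antigen complexes with abagqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abagqc)
```

## The evaluation problem

A predicted antibody-antigen complex can be locally excellent (well-folded
variable domains, accurate CDR loops) and still useless, because the
antibody is docked on the wrong epitope or in the wrong orientation.
`abagqc` treats complex evaluation as three separable questions:

1. **How good is a model, given the experimental structure?** Answered by
   reference-based scores: fnat, I-RMSD, L-RMSD, the DockQ composite, and
   the discrete CAPRI class.
2. **Can we tell without the experimental structure?** Answered by
   confidence signals: interface pLDDT (I-pLDDT) and the pTM/ipTM
   combination, assessed by how well they discriminate accurate from
   incorrect models (ROC/AUC).
3. **Over which targets should either be measured?** Answered by the
   benchmark curation rules, which remove redundant and poorly determined
   complexes so aggregate rates are not inflated by near-duplicates.

## Scoring model and conventions

All scores operate on a *partition* of the complex: heavy (+ optional
light) chains form the antibody body, one or more chains form the antigen.
We adopt the receptor/ligand convention that the **antigen is the
receptor** and the **antibody is the ligand** — L-RMSD measures how far
the antibody sits from its true pose after the antigens are superposed,
which is exactly the failure mode of interest in antibody docking.

- **Contacts** are residue pairs spanning the partition with any
  non-hydrogen atom pair at or under the cutoff (inclusive `<=`). fnat
  uses 5 Å; the I-RMSD interface definition uses 10 Å; I-pLDDT uses
  4.0 Å; glycan proximity uses 4.5 Å. Hydrogens are excluded by element
  everywhere, so deposited structures with and without hydrogens score
  identically.
- **Backbone** is N, CA, C, O; residues missing some of the four
  contribute the atoms they have.
- **DockQ** uses the standard scaling constants d1 = 1.5 Å (interface
  term) and d2 = 8.5 Å (ligand term). The score is 1 exactly when
  fnat = 1 and both RMSDs are 0.
- **CAPRI classes** follow the usual cascade: High when fnat >= 0.5 and
  (I-RMSD <= 1.0 or L-RMSD <= 1.0); Medium when fnat >= 0.3 and
  (I-RMSD <= 2.0 or L-RMSD <= 5.0); Acceptable when fnat >= 0.1 and
  (I-RMSD <= 4.0 or L-RMSD <= 10.0); otherwise Incorrect.
- **Residue correspondence** between model and reference is built once,
  per role, by global sequence alignment (match +1, mismatch 0, gap -1)
  with an identity floor of 0.6; below the floor we refuse to score
  rather than silently pair the wrong chains. Multi-copy antigens are
  assigned by best identity, greedily. Residues absent from either side
  (for example not experimentally resolved) simply never enter a score
  term.

Model-vs-reference chain pairing for multi-copy antigens is a genuinely
open design point: we use best-identity sequence assignment because it is
deterministic and auditable, not because it is known to be what any
particular study did.

## Confidence metrics

I-pLDDT is the mean per-residue pLDDT over the *union* of both sides'
interface residues at 4.0 Å, each residue counted once. Per-residue pLDDT
is read from the CA temperature factor (predictors write one value per
residue), with a mean-over-heavy-atoms fallback for CA-less residues.
When a prediction has **no** interface residues at all, I-pLDDT is defined
as exactly **30** — the floor of the pLDDT "very low" band — so fully
dissociated predictions get a minimal, not missing, score. We average per
residue rather than per atom because the metric is defined on residues at
the interface; with per-residue-uniform pLDDT the two readings coincide
anyway.

Model confidence is `0.8 * ipTM + 0.2 * pTM`, the weighting popularised by
multimer predictors. Ranking ties are broken by model label so that ranks
are reproducible under permutation of the input.

## CDR accuracy

CDR loops are defined on AHo scheme positions (1-149 per domain): CDR1 =
24-42, CDR2 = 57-76, CDR3 = 107-138, everything else framework. Numbering
is consumed as a table (chain, author residue, scheme position, role) —
recomputing the HMM-based assignment is out of scope, and the synthetic
generator emits consistent numbering so tests need no external tool.
Superposition uses the backbone of all framework residues present on both
sides, heavy and light **jointly as one rigid body**; the per-chain
alternative was considered and rejected because a joint fit also penalises
packing errors between the two domains, which per-chain fits hide. Loop
RMSDs are then reported without further superposition.

## Annotations

- **Glycans:** HETATM residues whose component code is in a configurable
  saccharide set (default: NAG, NDG, BMA, MAN, FUC, GAL, GLC, SIA, XYS,
  BGC) and whose nearest atom is within 4.5 Å of any antibody
  non-hydrogen atom. The full chemical-component-dictionary saccharide
  class is not bundled; the default covers the common N- and O-glycan
  residues.
- **TM-score:** normalised by the reference length, with
  d0 = 1.24 (L-15)^(1/3) - 1.8 floored at 0.5 Å (short chains would
  otherwise get a non-positive scale). The maximisation is a deterministic
  heuristic: seeds from the full-length Kabsch fit plus sliding windows of
  lengths 4, L/2 and L, each refined by re-superposing on residues with
  d_i < d0 until the selected set stabilises (at most 20 rounds). The
  search provably never returns less than the full-length Kabsch seed
  score; tests additionally compare it against window-enumeration
  brute force on small chains.
- **Neff:** greedy incremental clustering at 80% identity, rows ordered
  longest-ungapped-first, each row joining the first cluster whose
  *founder* it matches at or above the cutoff. Gaps become `U` before
  identity computation, and identity is matches over the full alignment
  width. This mirrors a CD-HIT-style depth measure but is not a
  re-implementation of CD-HIT: word-size heuristics and length-difference
  cutoffs are absent, so cluster counts on real MSAs should be treated as
  approximate relative depth, not exact CD-HIT output.

## Curation rules

Candidates are processed in release-date, then id order (the rules
reference earlier-accepted entries, so a deterministic order is required
for a reproducible benchmark). A candidate is removed when:

1. resolution > 3.0 Å, or release date on/before the cutoff;
2. antigen completeness fails: (SEQRES - resolved)/SEQRES > 0.70, or
   > 0.35 with resolved antigen length > 500;
3. sequence redundancy: heavy or full variable-domain identity >= 90%
   against a prior *and* an antigen match (a local alignment of >= 30
   columns at >= 30% identity — an internal, deterministic stand-in for a
   default-parameter BLAST hit);
4. structural redundancy: heavy-chain CA RMSD < 5 Å after antigen
   superposition *and* any of heavy, light, or concatenated-CDR identity
   > 70%.

Identity denominators are alignment columns, so a domain embedded in a
longer construct still reads as highly identical — the behaviour a local
aligner would give. When the antigen correspondence cannot be built the
candidate is kept with a warning: redundancy must be proven, not assumed.
Manual-inspection removals are supported as an explicit exclusion list;
they are not expressible as rules.

## What the synthetic generator emulates — and what it does not

`build_toy_complex` produces an idealized backbone-only (N, CA, C, O)
antibody-like chain: serpentine strands standing in for the framework
sheet, AHo-numbered segments populating all three CDR ranges, and an
antigen slab 4.4 Å beneath it, giving a genuine contact interface
(hundreds of 5 Å contacts; at least five is guaranteed and tested). A
small coordinate jitter (uniform, ±0.15 Å) breaks exact planarity so
superpositions are never degenerate. Defaults: 102 heavy residues, 40
antigen residues, reference pLDDT 90; `config = list(light = TRUE)` adds
a light chain for Ab (vs Nano) cases.

Decoys move the antibody rigidly — translations along a fixed axis and/or
rotations about the antibody centroid — so ground truth is analytic:
a pure translation of magnitude m has L-RMSD exactly m. Planted pLDDT
follows `base - slope * error + noise` (defaults 95, 1.5 /Å, SD 2),
clipped to [0, 100]; planted ipTM follows the same linear-with-noise form.
These defaults were chosen once as a plausible strength of the
confidence-accuracy association — strong enough that discrimination is
recoverable, noisy enough that it is not a tautology — and are not tuned
per test.

What the toys do **not** emulate: real antibody folds, side chains, clash
constraints, flexible-loop error modes, partial antigen assemblies, or
predictor internals (recycling, templates, MSA pairing). Consequently,
passing tests demonstrate that the *measurement machinery* is correct —
scores recover planted transformations, oracles agree, aggregation is
faithful — not that any predictor achieves any particular accuracy on
real complexes, which requires real model sets.

## Numerical choices

- Kabsch superposition corrects reflections by negating the axis of the
  smallest singular value; exactly collinear point sets are an error
  (no unique rotation), planar sets are fine.
- All coordinates double precision, distances in Å; contacts use
  inclusive cutoffs with a 1e-12 slack so boundary-distance pairs are
  kept regardless of floating-point representation.
- Altloc conformers: highest occupancy wins, ties keep the first
  encountered.
- RNG: every generator takes an explicit seed and is bit-reproducible;
  cohort complexes derive per-complex seeds as `seed * 1000 + i` (kept
  under 2^31).
- Problem sizes in the test suite were chosen at desk scale: decoy-oracle
  agreement on ~50 decoys, cohorts of 10 complexes x 25 models, MSAs of
  100 columns. These exercise every code path with margins; larger
  cohorts change runtimes, not code paths.

## Limitations

- Scheme numbering is an input; garbage numbering gives garbage regions.
- The TM-score search is a deterministic heuristic, not the exhaustive
  rotation search of the original program; on pathological multi-domain
  antigens it may undershoot (never below the Kabsch-seed bound).
- Neff approximates, not reproduces, CD-HIT cluster counts.
- Curation cannot reproduce manually curated benchmark lists exactly,
  by design: manual removals arrive via the exclusion list.
- mmCIF reading relies on `bio3d::read.cif` and inherits its dialect
  handling; structures with exotic atom_site categories should be
  converted to PDB first.
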