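---
title: "Methods: structure-based annotation of LDLR missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based annotation of LDLR missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlrstruct)
```

## Scope and model

LDLR binds LDL particles through its seven cysteine-rich class-A repeats
at extracellular pH and releases them in the acidified, calcium-depleted
endosome. Each repeat is a ~40-residue module whose fold depends on three
disulfide bonds and one Ca²⁺ ion; a missense variant can therefore have
very different consequences in the two physiologic states. This package
annotates variants against coordinate models of both states and
classifies their predicted stability effects. It deliberately does *not*
build the models (no homology modeling), does not recompute empirical
folding energies (per-condition ΔΔG_fold values are ingested from tables
produced by an external energy function), and does not call external
conservation servers (an internal entropy scorer replaces that step).

All residue positions are stored in precursor coordinates (the canonical
UniProt frame for the receptor, signal peptide = 21 residues). Variant
tables in mature numbering are recognized automatically: the stated
reference residues are checked against the canonical sequence in both
frames and the better-matching frame is used; records whose reference
matches neither frame are excluded and logged, since a silent off-by-21
error would corrupt every downstream count.

## Structural role detection

**Disulfides.** Cysteine Sγ–Sγ pairs at ≤ 2.5 Å (covalent range) are
candidate bonds, accepted greedily nearest-first so each cysteine joins
at most one bond. The greedy rule is what a curator would do by eye and
is deterministic; in a pathological cluster of three mutually close
cysteines it keeps the closest pair and leaves one unpaired, with a
warning.

**Calcium coordination.** For each Ca²⁺ ion, every protein oxygen within
3.2 Å is a coordinator (mean Ca–O distance in proteins is ~2.4 Å; the
margin absorbs modeling error). Side-chain and backbone-carbonyl
coordination are tracked separately because they behave differently under
substitution: a side-chain coordinator loses its ligand when the new
residue lacks a side-chain oxygen, whereas backbone-carbonyl coordination
survives any substitution except those that change backbone geometry
itself — so backbone-only coordinators flag a variant only when the
substitution is to or from proline or glycine. Second-shell residues are
not counted; this is the strict, defensible reading of "alters a calcium
site", and the cutoff is exposed if a broader shell is wanted.

**Burial.** Shrake–Rupley numerical accessibility (probe 1.4 Å, 960
deterministic Fibonacci sphere points per atom), normalized by the
residue's theoretical maximum area and clipped to [0, 1].
Core membership is RSA ≤ 0.15, the conventional buried cutoff. The sphere
sampling is fixed in the laboratory frame, so RSA is rigid-body invariant
only to the sampling resolution (~10⁻³ relative); every exact metric in
the quality panel is invariant to 10⁻⁶ or better.

**Conservation.** Per reference-residue column of an MSA the raw score is
`1 − H/H_max` with `H` the Shannon entropy over amino acids (gaps
excluded) and `H_max = log 20`; raw scores are z-normalized across the
protein. A position is "structurally conserved" when it is an invariant
column or its z-score reaches the threshold (default 1.5). An absolute
quantile rule ("top quartile") was considered and rejected: whenever
genuinely conserved positions make up a quarter or less of the protein,
the 75th percentile falls inside the background score distribution and
necessarily flags background columns, so planted-column recovery cannot
reach precision 1. The z-threshold form has no such failure mode and is exposed
in the configuration, since the published count of conserved-site
variants depends on the (unstated) cutoff used with the original
conservation grades.

**Glycosylation.** O-glycosylation positions are supplied as a plain
position list; a variant is "near" a site within 5 residues of sequence
distance. The shipped list under `extdata/` is synthetic (named so) — it
demonstrates the mechanism and is not a curated claim about LDLR.

## Stability classification

ΔΔG_fold is in kcal/mol with positive values destabilizing (the
convention of the FoldX-style tools that produce such tables; echoed in
every output header). Thresholds: changes are significant past
0.6 kcal/mol and strong past 1.8 kcal/mol, so per condition:
neutral |ΔΔG| ≤ 0.6; destabilizing 0.6 < ΔΔG ≤ 1.8; strongly
destabilizing ΔΔG > 1.8; stabilizing ΔΔG < −0.6. The between-condition
difference uses the absolute value, d = |ΔΔG_extra − ΔΔG_endo| — the
signed value is also emitted for plotting — and the orange band is closed
on both sides ([1.8, 3.0]) with red strictly above 3.0, following the
band wording ("between", "greater than"); both choices are configurable.
Records missing one condition are excluded from category counts rather
than imputed.

The package also ships a deliberately simple, interpretable ΔΔG
*estimator* for synthetic end-to-end runs: a weighted sum of a steric
term (effective side-chain sphere overlap at Cβ), lost side-chain
hydrogen-bonding capability, burial-weighted Kyte–Doolittle hydropathy
change, a fixed disulfide-removal penalty, and a fixed side-chain
calcium-loss penalty (weights in `extdata/ddg_estimator_params.tsv`). It
is not an empirical energy function, reports its term breakdown on every
call, and is never used where an ingested table exists.

## Clinical harmonization

A variant is **pathogenic** if any source record meets a pathogenic
criterion: a ClinVar label containing "pathogenic" (case-insensitive,
excluding "conflicting…"), the exact HGMD class `DM` (not `DM?`), or
ACGS class 4/5 from LOVD. It is **benign** if some record meets a benign
criterion (ClinVar "benign", ACGS 1/2) *and* no pathogenic criterion
holds. Everything else — including presence only in a population
database — is a **VUS**. Matching is tolerant on ClinVar free text and
strict on the HGMD code because the former varies across exports and the
latter is a controlled vocabulary. Uniqueness is at the protein-change
level; positions where sources disagree on the reference amino acid are
excluded entirely and logged. Because raw database exports contain
non-missense and duplicated records, reports carry both the raw record
count and the unique-missense count rather than reconciling the two.

## Model quality panel

* **Ramachandran**: φ/ψ from backbone geometry; residues binned
  core/allowed/outlier by analytic basin definitions (α, β and left-α
  boxes; glycine adds the mirror basins; proline restricts φ). The
  outlier z uses shipped reference constants (μ = 0.02, σ = 0.02) — a
  coarse calibration meant for comparing models against each other, not
  against crystallographic databases.
* **Hydrogen bonds**: heavy-atom criterion (donor–acceptor ≤ 3.5 Å,
  antecedent–donor–acceptor angle ≥ 120°), backbone and side-chain bonds
  counted alike; the reported fraction is residues participating in ≥ 1
  bond.
* **Clashes**: non-bonded heavy-atom pairs closer than the vdW-radius sum
  minus 0.4 Å, excluding covalent/constrained geometry (adjacent backbone,
  disulfide bridges); rate per 1000 atoms standardized by shipped
  constants (μ = 8, σ = 6).
* **Contact potential**: a coarse log-odds potential over four residue
  classes and three Cβ–Cβ distance bins (`extdata/contact_potential.tsv`),
  scored against sequence-shuffled decoys on fixed coordinates;
  z = (native − mean)/sd, more negative = more favorable. It is labelled
  "dope-like" because it reproduces the *z-versus-decoys* concept, not the
  published atomic potential. With all decoys identical to the native the
  z is 0 by convention. Because the z magnitude of a well-ordered fixture
  is large (≈ −5), its sampling spread across decoy samples is assessed
  relative to the mean (< 10 % at 200 decoys) rather than as an absolute
  bound.

## Synthetic data: what it does and does not emulate

`build_minidomain()` produces a 40-residue hairpin of two ideal
antiparallel helices joined by a schematic loop: planted Sγ–Sγ pairs at
exactly 2.05 Å, one Ca²⁺ ion with four Asp side-chain oxygens and two
backbone carbonyls at exactly 2.4 Å, and hydrophobic residues on the
helix–helix interface so that burial, contact-potential and perturbation
properties hold. Side chains are schematic (Cβ plus the functionally
required terminal atom). The generator therefore emulates the *geometric
signatures* the detectors test for — not the class-A fold itself, which
is loop-rich with a C-terminal calcium cage. Passing tests show the
detectors recover planted geometry exactly; they do not show that real
receptor models are accurate.

`synth_msa()` plants invariant columns on a uniform six-letter background;
real alignments have phylogenetic correlation and intermediate
conservation, so planted-recovery results bound the easy case only.
`synth_variant_table()` plants clinical classes (realized through source
records that harmonize to the intended class), role flags, and ΔΔG values
drawn per class — pathogenic shifted by +2.5 kcal/mol (sd 1.5), benign
from N(0, 0.3) truncated to |ΔΔG| ≤ 0.6 so that no benign variant is
destabilizing, VUS an equal mixture — with condition differences placed
firmly inside the gray/orange/red bands (56 % / 14 % / 30 % by default,
the observed category proportions in the receptor's class-A repeats) so
recovery is exact rather than approximate. These are study conditions,
fixed once; they qualitatively mimic the reported class separation, with
no claim of matching empirical distributions.

## Numerical and reporting choices

Statistics delegate to the standard implementations: Spearman via
rank-then-Pearson with average ties, rank-sum tests exact for small
groups and normal-approximated with continuity correction otherwise, raw
p-values reported (a Benjamini–Hochberg column is appended, clearly
labelled, because the original analyses report unadjusted values).
The association between conservation and stability quantities is
Spearman's ρ, stated as such in the output since the original statistic
is not specified. Percentages are rounded half-up to integers alongside
raw counts. Reports are deterministic: fixed row ordering, no timestamps,
full-precision numbers — two runs on identical input are byte-identical.

Test and acceptance problem sizes — 400-variant tables, 20 generator
seeds, 40-residue fixtures, 100–200 decoys — were chosen as the smallest
sizes at which planted-truth recovery is exact and stochastic properties
are stable; the whole suite runs in well under a minute on one core.

## Limitations

* Detectors assume reasonably complete heavy-atom models; missing Sγ or
  backbone atoms degrade to warnings and exclusions, not imputation.
* The quality panel's reference constants are package-level conventions;
  its z-scores are comparable between structures scored by this package,
  not with external validation servers.
* The internal ΔΔG estimator is a transparent toy; all quantitative
  stability analyses should ingest energies from a dedicated method.
* mmCIF, biological assemblies and multi-model ensembles are out of
  scope (the first model of a multi-model file is used, with a warning
  from the underlying reader).
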