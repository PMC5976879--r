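---
title: "bshscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bshscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical and algorithmic choices behind
`bshscreen`: what each stage computes, why the defaults are what they are,
and where the package deliberately departs from the most obvious
convention. The code chunks are illustrative and not evaluated when the
vignette is built; the test suite is the executable specification.

## The problem and the pipeline shape

Bile salt hydrolase (BSH) and penicillin-V acylase (PVA) are homologous
Ntn-hydrolases. A similarity search against a bacterial genome finds both
and cannot separate them, so the pipeline is two-stage by design: a
permissive similarity **screen** that finds everything resembling either
family, then a discriminative **dual profile-HMM classification** that
assigns each candidate to the family whose model explains it better, or
removes it.

The package follows a hybrid of the classic R modelling idiom and a plain
function pipeline. The parts that genuinely are fitted models are S3 model
objects:

- `profile_hmm(msa)` returns a fitted model with `print()`, `summary()`,
  `predict()` (forward scores) and `simulate()` methods;
- `bsh_classifier(msa_bsh, msa_pva)` bundles two fitted HMMs plus their
  decoy calibrations, with a `predict()` method that yields labels and
  E-values.

Everything else — screening, clustering, motif profiling, trees, repertoire
summaries — is a pipeline of plain, composable functions orchestrated by
`run_all()`. Forcing those stages into a formula-and-data estimator would
misrepresent what they are.

## Stage 1: the screen

`extract_orfs()` translates all six reading frames (Biostrings under the
hood, cross-checked in the tests against a hand-written per-codon oracle),
and enumerates Met-initiated ORFs with an inclusive length floor
(`min_orf_len = 100` residues by default — short enough to keep real BSH/PVA
genes, long enough to suppress spurious ORFs).

`screen_candidates()` aligns every ORF against the combined reference panel
with Smith–Waterman local alignment (BLOSUM62, gap open 10 / extend 0.5).

**Identity convention.** The screen retains an ORF when its best identity
to any reference reaches `min_ref_identity = 0.30`. Identity here is
*identical positions divided by the length of the shorter sequence*, not
divided by the alignment length. The alignment-length convention
(BLAST-style) looks natural but fails in this setting: without BLAST's
E-value and HSP-length machinery, an unrelated ORF can produce a 3–4 column
local alignment at 75–100% "identity" and sail past any floor — decoys then
pass the screen and can even displace true genes when overlapping loci are
collapsed. Normalising by the shorter sequence length makes a tiny
high-identity fragment score low, which is the behaviour a screen needs.
Both conventions are computed and exposed (`identity`, `identity_short`);
the screen decision uses the short-sequence one.

Overlapping candidate ORFs on the same genome are collapsed to the single
best hit per locus, mirroring one-gene-one-call behaviour.

## Stage 2: profile HMMs and classification

`profile_hmm()` estimates a match/insert/delete profile HMM from a
reference alignment:

- columns with gap fraction strictly below 0.5 become match states;
- emissions and transitions are Laplace-smoothed (+1) relative frequencies;
- scoring is the full forward algorithm in log space (an Rcpp kernel — the
  delete-state recursion makes the \(O(L \times M)\) loop infeasible in
  pure R at realistic lengths), reported in bits as log-odds against the
  background composition.

The tests pin this down hard: emissions and transitions are checked against
hand-tallied counts on a four-row toy alignment, and forward scores are
checked to `1e-9` bits against exhaustive enumeration of *all* state paths
in probability space on small models.

**E-value calibration.** `calibrate_evalues()` scores `n_decoys` random
background sequences and locates the high-score tail. Two methods are
implemented:

- `"fixed-lambda"` (default): Gumbel tail with the slope fixed at
  \(\lambda = \ln 2\) per bit — the standard convention for forward bit
  scores — with only the location \(\mu\) estimated from the decoys.
- `"gumbel-ml"`: a two-parameter maximum-likelihood Gumbel fit
  (\(\mu, \lambda\) both estimated).

The default matters. Measured on synthetic families, the free-\(\lambda\)
fit yields slopes of roughly 0.05–0.1 per bit; extrapolated to true-hit
scores hundreds of bits above the decoy bulk, that produces E-values around
\(10^{-20}\)–\(10^{-60}\), and a retention rule at \(10^{-99}\) would
discard every true hit. The fixed-\(\lambda\) convention reproduces the
regime in which such deep thresholds are meaningful. The ML variant is
retained, tested (including the check that the fitted \(\mu\) sits at the
\(1 - e^{-1} \approx 0.632\) quantile of the decoy scores) and selectable.

**Retention rule and labels.** `predict.bsh_classifier()` computes both
families' E-values per candidate (Bonferroni-style `db_size` scaling
available), removes candidates whose *better* E-value does not clear
`retention_evalue`, labels survivors by the smaller E-value, and removes
exact ties as `ambiguous`. The default bound of \(10^{-99}\) is calibrated
to full-length (~320-residue) proteins. Forward bit scores — and therefore
E-value exponents — grow roughly linearly with sequence length, so analyses
at reduced scale must scale the bound accordingly: the package's fast tests
use \(10^{-30}\) for 80–160-residue toys, with the arithmetic documented in
the test files. This is a property of the score scale, not a tunable knob.

## Stage 3: clustering and naming

`greedy_cluster()` is deterministic single-pass clustering: sequences are
sorted by decreasing length (ties by id), each sequence joins the first
existing cluster whose representative it matches at
`cluster_identity = 0.95` or founds a new cluster. Tests verify the
invariants (every member matches its representative at threshold;
representatives are mutually below threshold at founding time) by brute
force on random datasets. `name_clusters()` produces species-aware ordinal
names (`gasseri_1`, `gasseri_and_hominis_1`, …).

## Stage 4: alignment, conservation, motifs

Representatives are aligned with a deterministic center-star progressive
alignment: the center is the sequence with the highest total pairwise
similarity; all pairwise global alignments are projected onto a common
gapped frame. No external aligner is invoked — determinism and zero
system dependencies outweigh alignment optimality here, and the synthetic
families are indel-free by default, where star alignment is exact.

`column_conservation()` scores each column by the modal-residue fraction
among non-gap rows; `find_motifs()` calls maximal runs of columns at or
above `conservation_threshold = 0.75` of at least `min_motif_len = 3`
columns. `audit_active_sites()` maps canonical catalytic residues (Cys2,
Asp21, Asn82, Asn175, Arg228) from consensus coordinates to alignment
columns and reports conservation and motif membership per site.

## Stage 5: trees

`neighbor_joining()` implements canonical NJ with a deterministic
first-minimum tie-break and non-negativity clamping: a negative branch
estimate is set to zero and the deficit moved to the sister edge, the
standard remedy. The implementation is exact on additive matrices
(tested: path-length matrices of random trees are recovered to `1e-9`) and
agrees with `ape::nj` topologies on noisy matrices. `bootstrap_support()`
resamples alignment columns with replacement, recomputes trees, and reports
per-bipartition support as a percentage, keyed by a canonical bipartition
encoding (the side not containing the alphabetically first leaf). Newick
I/O single-quotes labels containing metacharacters so arbitrary species
names round-trip.

## Stage 6: repertoire summaries

`strain_call_records()` joins classification output to strain metadata
(absent strains get explicit zero counts). Summaries report, per species,
the percent of strains with BSH and copy-number class counts; the
`category_breakdown()` is the four-way BSH / PVA / both / neither split,
and `lifestyle_crosstab()` gives, per enzyme, the percentage distribution
over lifestyles (vertebrate-adapted, free-living, insect-adapted, nomadic,
unknown).

**Rounding.** All printed percentages use half-up rounding at two decimals
(`round_half_up()`), not banker's rounding — this is what reproduces
published-style values such as 80.77% (147/182) and 64% / 28% / 8%
copy-number shares.

## The synthetic-data generator

`generate_dataset()` builds a complete survey bundle from a seeded
configuration: two family consensi with controlled shared ancestry
(`shared_ancestry = 0.4` by default — close enough to confuse a similarity
screen, distinct enough to classify), members evolved at a per-site
substitution `divergence` that spares the motif-anchor blocks, genes
reverse-translated and embedded on random strands with in-frame stops
founding each ORF, plus decoy ORFs, reference alignments, metadata and a
truth table. Generation is byte-deterministic under the seed. The default
motif anchors assume full-length (320-column) consensi; `sim_config()`
takes a `motif_blocks` argument for smaller scales.

## Reproducibility

`run_all()` writes a `manifest.yaml` with the config snapshot, md5 digests
of inputs and of every output file, stage timings and the RNG seed; reruns
under the same seed are byte-identical (tested). `scripts/acceptance.R`
recomputes the headline survey quantities and numerical cross-checks into a
flat JSON file.

## Limitations

- The star alignment is not an optimizing MSA; with substantial indels a
  dedicated aligner would do better.
- E-value calibration rests on a background-composition decoy model;
  strongly biased genome composition would shift \(\mu\).
- The classifier is a two-class model by construction; a third homologous
  family would be forced into BSH/PVA/removed.
- NJ with clamping is a distance method; likelihood methods would be
  preferred for deep phylogenies.
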