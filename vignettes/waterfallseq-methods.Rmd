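---
title: "Methods: reference-free transcriptome profiling with waterfallseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free transcriptome profiling with waterfallseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waterfallseq)
```

## The problem

Comparing the transcriptomes of two somatosensory ganglia — the trigeminal
ganglion (TG), which innervates the head, and the dorsal root ganglion
(DRG), which innervates the body — is a classical route to candidate touch
and pain transduction molecules: a gene enriched in the ganglion serving a
specialized sensory surface is a candidate for that surface's physiology.
The catch for unusual sensory specialists is that no annotated genome or
transcriptome may exist for the species of interest. `waterfallseq`
implements, as a tested and reusable pipeline, the computational strategy
for exactly this situation:

1. **Waterfall mapping** — align short RNA-seq reads to an *ordered cascade*
   of related-species transcriptomes (e.g. human, then dog, then mouse);
   reads unmapped at one stage are passed to the next.
2. **Homolog-collapsed quantification** — sum, per gene, the reads landing
   on that gene's homologs across all reference species, using a homology
   cluster table, so one focal-species gene gets one count.
3. **Negative-binomial differential expression** between the two ganglia,
   written from scratch: median-of-ratios normalization, method-of-moments
   dispersion with a parametric trend, a per-gene two-sided exact test on
   condition totals, Benjamini–Hochberg correction.
4. **Cross-species exclusion** — discard genes that are *also*
   differentially expressed between the same ganglia in a well-studied
   species (mouse): those differences reflect generic TG-vs-DRG biology,
   not the specialist's adaptations.
5. **Membrane consensus** — candidate transducers must look like membrane
   proteins: signal-peptide trimming followed by three independent
   transmembrane-helix predictors and a 2-of-3 vote.
6. **Candidate tables** — per-direction candidate lists, Gene Ontology-style
   category tallies, and a channel ranking by fold enrichment.

Because no raw data are published for the motivating study, the package is
validated end-to-end on synthetic data with planted ground truth; the
generator is first-class, tested code.

## The synthetic study and what it emulates

`sim_config()` fixes the study conditions. The defaults encode: three
reference transcriptomes each diverged 3% per site from the focal
transcriptome (the stated cross-species substitution rate), 50 bp
single-end reads (the middle of the 36–76 bp range such libraries used) at
1% sequencing error, three focal replicates per ganglion and two for the
cross-check species, NB dispersion 0.1, and 4-fold planted enrichment in
20% of genes.

Design choices worth making explicit:

* **The focal transcriptome is the ancestor.** Each reference species is
  derived from the focal sequence by i.i.d. per-site substitution at its
  divergence rate. The alternative — an unobserved ancestor with the focal
  copy *and* every reference independently substituted from it — doubles
  the focal-to-reference divergence (two independent 3% branches give
  ~5.9% pairwise), which is not the regime the mapping strategy is
  specified for. Making the focal sequence the ancestor keeps
  focal-vs-reference divergence exactly at the configured 3% while leaving
  reference-vs-reference divergence realistic (~5.9%).
* **Reads per gene equal the count-matrix entry exactly** (no Poisson
  resampling), so quantification is exactly checkable: with zero divergence
  and zero error the collapsed count table must *equal* the simulated
  matrix, and the test suite asserts that it does.
* **Orphan genes** (default 10%) exist in exactly one reference species and
  in no homology cluster. They exercise both the later waterfall stages
  (a gene private to the third species can only be found there) and the
  orphan-row policy of the collapse step.
* **Substitutions only, no indels.** The mapper is deliberately ungapped
  (below), and the modelled cross-species distance is a substitution rate.
* **`depth` is the expected library size of an all-null sample.** Planted
  enrichment adds reads on top (the default run emits ~60k reads across six
  samples). This keeps every per-gene mean exactly what the NB model says,
  at the cost of library sizes that grow slightly with the planted signal —
  which is also what a real enriched library does.
* **Planted proteins.** Background residues follow a hydrophilic-biased
  composition under which a random 19-residue window essentially never
  reaches the transmembrane hydropathy bar; planted TM segments are one to
  three hydrophobic 19–23-mers; planted signal peptides follow the
  n-region / h-region / A-X-A cleavage architecture with the cleavage site
  within the first 35 residues.
* **Planted cascade candidates.** Twelve genes per direction are forced to
  satisfy the whole cascade (enriched in the focal species, null in the
  cross species, transmembrane, channel-annotated). The ground-truth
  candidate set recorded for evaluation is the *emergent* set of genes
  whose labels satisfy the cascade — the forced ones plus any that satisfy
  it by chance — so end-to-end recovery is measured against the truth, not
  against bookkeeping.

What the generator does **not** emulate: indels and rearrangements between
species, paired-end protocols, empirical quality profiles (qualities are
constant and never used), isoform switching between conditions, GC or
length biases, and gene-family cross-mapping beyond what random sequence
sharing produces. Passing tests therefore demonstrate the pipeline's
internal correctness and its statistical calibration under the stated
model, not robustness to those artefacts.

The sizes used in the tests — 250-gene default study (~60k reads),
2000-gene count-level simulations, 500 proteins — were chosen as the
smallest sizes at which the binomial/normal error bars of the measured
quantities are comfortably inside the asserted bands (e.g. a ±4 s.d. check
on a 3% divergence needs ~1 kb transcripts; an 80% recovery bar needs a
double-digit planted set).

## The waterfall mapper

Each reference is indexed by every forward k-mer (default `k = 16`;
k-mers containing non-ACGT are skipped). A read is seeded from **every**
offset of the read and of its reverse complement; each seed hit proposes a
candidate (transcript, start, strand) diagonal, candidates are scored by
full-length Hamming distance, and the minimum-distance locus is accepted
iff its distance is at most `ceiling(budget_rate * L)` (default rate 0.06:
3% divergence plus sequencing-error headroom, so 3 mismatches for a
50-mer).

Stride-1 seeding makes sensitivity analyzable: a locus with `d` mismatches
always retains a clean stretch of `ceiling((L - d)/(d + 1))` bases, so seed
discovery is *guaranteed* whenever `k` is at most that bound — for 50-mers
within a 3-mismatch budget, any `k <= 12`. The oracle-equivalence tests run
at `k = 12`, where agreement with an exhaustive all-position, all-strand
scan is exact by construction; the default `k = 16` trades a small,
quantifiable sensitivity loss for a sparser index.

Tie and ambiguity policy: minimum-distance ties across *distinct genes*
are discarded by default (the read is flagged ambiguous and cascades to
the next stage) — the conservative choice that prevents double counting in
quantification; `first_best` instead picks deterministically by
lexicographic transcript id, then position. Ties within one gene always
resolve the same way. Coordinates are 0-based half-open internally; the
minimal SAM exporter (`write_sam()`) emits 1-based POS with M-only CIGARs,
which is all an ungapped transcriptome hit needs.

A read is attempted at stage `t` only if unmapped (including
ambiguous-discarded) at all earlier stages. Note the cascade *rescues*
reads: a read over budget against the first species may still be within
budget against another, so the total mapped fraction exceeds the
single-stage expectation.

## Quantification and homolog collapse

Counting is deliberately literal: one read, at most one alignment, one
count. Transcript counts are alignment-record counts; gene counts sum a
gene's transcripts; collapsed counts sum a homology cluster's (species,
gene) members. Genes in no cluster are kept as species-qualified orphan
rows rather than dropped — homology tables patched by manual annotation
have gaps, and silently losing those genes would bias every downstream
step. Count conservation (reads = transcript counts = gene counts =
collapsed counts, per sample) is asserted at run time by the pipeline and
in the tests. A transcript assigned to two genes is a hard error, not a
heuristic split; a duplicated read id is a hard error, not a dedup.

## Differential expression

All four stages are implemented from scratch and checked against
independently coded brute-force oracles.

**Size factors.** `s_j = median_i k_ij / (prod_v k_iv)^(1/m)` over genes
positive in every sample — the arithmetic median of ratios to the
geometric-mean pseudo-reference. Size factors are meaningful up to a
common scale; the tests assert the exact *ratio* behaviour (doubling one
sample's counts doubles its size factor relative to every other) plus
1e-10 agreement with the brute-force transcription of the formula.

**Dispersions.** Per-gene method of moments on normalized counts,
`alpha_i = max(0, (v_i - mu_i)/mu_i^2)` with `v_i` the mean
within-condition variance; a parametric trend `alpha(mu) = a0 + a1/mu`
fitted by least squares over genes with positive raw dispersion; final
`alpha_i = max(raw, trend(mu_i), alpha_min)` with floor `alpha_min = 1e-8`.
The max rule is deliberately conservative (it can only inflate p-values);
the closed-form trend replaces local regression to keep the estimator
deterministic and auditable. Degenerate cases: a gene with identical
normalized counts has raw dispersion 0; a constant-`mu` gene set (which
makes the trend unidentifiable) falls back to an intercept-only trend.

**Exact test.** Condition totals `k_A, k_B` are each modelled as one NB
with mean `q0 * S_c` (pooled normalized mean times the condition's summed
size factors) and variance `mean + alpha * q0^2 * sum_j s_j^2`
(moment-matching the sum of per-sample NBs). The two-sided p-value sums,
over all splits `(a, b)` of the observed total, the joint probabilities no
larger than the observed split's, normalized by the total over all splits.
Splits within a 1e-7 *relative* tolerance of the observed probability are
counted as ties: mathematically symmetric splits otherwise flip in or out
on the last floating-point ulp, and the enumeration-oracle agreement at
1e-8 would be luck rather than arithmetic. As `alpha -> 0` the model
degenerates to Poisson and the test provably converges to the
binomial-conditional exact test — asserted numerically. `K = 0` returns
p = 1 by convention.

**Multiplicity and calls.** BH over all genes with nonzero total (zero
genes are excluded before testing and from `m`); enrichment calls use
`padj <= threshold` (inclusive, default 0.05) and the fold direction. The
fold change `(normalized mean cond2)/(normalized mean cond1)` gets a +0.5
pseudocount on both means when either is zero, and is reported but never
thresholded. On an all-null 2000-gene simulation the raw type-I rate sits
near 0.04 (slightly conservative, as the max rule intends) and BH yields
zero discoveries; at 4-fold planted enrichment with means >= 100 the test
recovers >= 90% at empirical FDR < 0.03.

## Membrane consensus

The published strategy this reproduces is a *vote*: trim the signal
peptide, run three independent transmembrane predictors, and call a
protein "membrane" iff at least two report a segment. The three legacy
programs are replaced by three defined, independent predictors that share
only that interface — the vote and the trimming, which are the method's
substance, are preserved exactly, and every threshold is an exposed
argument rather than a binary blob's default:

1. **Hydropathy windows**: 19-residue windows with mean Kyte–Doolittle
   hydropathy > 1.6; overlapping qualifying windows merged, merged segments
   capped at 35 residues.
2. **GES + amphiphilicity**: 18-residue windows on the GES transfer scale
   (threshold 1.0 kcal/mol); a candidate segment is *rejected* if its
   normalized 100°-periodicity hydrophobic moment exceeds 0.35 — an
   amphipathic surface helix is hydrophobic on one face only, and the
   moment detects exactly that.
3. **Two-state decoder**: membrane/loop states with emissions
   `exp(KD/2)` (membrane) and `exp(-KD/4)` (loop, mildly hydrophilic),
   self-transition 0.95, initial loop probability 0.95; Viterbi decoding,
   membrane runs >= 15 reported. The decoder is verified against exhaustive
   path enumeration on short sequences.

Signal peptides are called from the classical architecture: a positive
charge (K/R) in the first six residues, a hydrophobic window (>= 8
residues, mean KD > 1.6) starting in residues 5–25, cleavage at the
best-scoring small-residue (A/G/S) position in residues 15–35 (ties to the
earliest; default 25 if no eligible position; never called under 40
residues). Unknown residues (`X`) score 0 on all scales. The trimming
matters: a secreted protein's h-region looks like half a TM helix, and
removing it before voting is what keeps secreted proteins out of the
membrane set — the tests include exactly that construction.

## The candidate cascade

`candidate_transducers()` applies, in order: focal-species enrichment in
the requested ganglion at `padj <= 0.05` (inclusive boundary); *not*
cross-species DE at the same threshold — a gene untested in the cross
species (absent, or zero counts) counts as not-DE but is flagged via
`cross_tested`, because absence of evidence should be visible, not fatal;
and the 2-of-3 membrane call, where a missing membrane prediction warns
and keeps the row with `NA` votes (strict mode errors instead). Rows are
ordered by fold enrichment toward the requested direction with
gene-id-stable ties. Category tallies fall back to "unannotated" so the
tally always sums to the candidate count; the channel ranking is the
candidate ∩ channel-annotation intersection sorted by fold enrichment.
Every criterion is relaxable independently, and the tests assert that
relaxing any single one yields a superset.

## Assay quantification rules

Three small rules used around such studies are implemented with *strict*
inequalities, so every boundary case is negative: a calcium-imaging cell
is responsive iff max(stimulus ratio) > 1.10 × mean(baseline ratio); a
cell is marker-positive iff intensity > 1.30 × background; qPCR fold
expression assumes 100% efficiency (one cycle = one doubling), averaging
Ct over wells, then ΔCt over runs, then over biological replicates, then
`fold = 2^(ΔCt_baseline − ΔCt_tissue)`. The well → run → replicate
averaging order is fixed and documented; for balanced designs the
alternatives differ only in floating-point noise, but a fixed order makes
results reproducible to the bit. Reciprocity `fold(a|b) × fold(b|a) = 1`
holds on any fixture and is tested.

## Reproducibility mechanics

One global seed fans out to per-stage child seeds via a fixed
name-keyed derivation (`derive_seed()`), so any stage can be re-run in
isolation and the whole bundle is byte-identical across reruns — the tests
compare md5 sums of every output file. Every written table is stamped with
the seed and a hash of the configuration; `resume = TRUE` will reuse an
on-disk alignment table only if its stamp matches. Wall-clock timings live
in the in-memory report only — serializing them would break byte-identical
reruns by definition.

## Known limitations

* The mapper is ungapped and unspliced by design; reads spanning
  insertions/deletions relative to the reference are lost, and the
  simulated world contains none.
* The dispersion trend `a0 + a1/mu` is a two-parameter stand-in for
  local-regression sharing; it is conservative under the max rule but can
  overshoot for genes far above the fitted trend's range.
* The three TM predictors share the Kyte–Doolittle scale between methods 1
  and 3 (method 2 uses GES); they are independent implementations, not
  independent information sources in the strict statistical sense.
* Homology is consumed, never inferred: a wrong cluster table propagates
  silently into collapsed counts. Orphan retention makes the gaps
  auditable but cannot fix mis-clustering.
* The cross-species exclusion treats "untested in the cross species" as
  "not differentially expressed", flagged; under sparse cross-species
  coverage this is permissive by construction.
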