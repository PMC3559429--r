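# waterfallseq

Reference-free transcriptome profiling for species with no annotated
genome: iterative ("waterfall") cross-species read mapping,
homolog-collapsed quantification, from-scratch negative-binomial
differential expression, consensus membrane-protein prediction, and a
cross-species candidate-gene filter cascade — validated end to end on
synthetic data with planted ground truth.

## The problem

Candidate touch/pain transduction molecules can be found by contrasting
the transcriptomes of the two somatosensory ganglia — the trigeminal
ganglion (TG, innervating the head) and the dorsal root ganglion (DRG,
innervating the body). For a sensory specialist with no reference genome,
reads cannot be aligned to their own species. `waterfallseq` implements
the workaround as a tested R package:

1. **Waterfall mapping.** Short single-end reads are aligned to an
   *ordered cascade* of related-species transcriptomes; reads unmapped at
   one stage cascade to the next. The inner aligner is a seed-and-extend
   ungapped Hamming mapper (Rcpp): exact k-mer seeds from every read
   offset on both strands, candidates scored by full-length Hamming
   distance, accepted iff distance ≤ ⌈0.06·L⌉ (3% cross-species
   divergence + sequencing-error headroom).
2. **Homolog collapse.** A gene's count is the sum of reads aligning to
   its homologs across all reference species (HomoloGene-style cluster
   table); genes in no cluster are kept as species-qualified orphan rows.
3. **Differential expression**, written from scratch:
   size factors `s_j = median_i k_ij / (∏_v k_iv)^{1/m}`;
   method-of-moments dispersions `α_i = max(0, (v_i − μ_i)/μ_i²)` with a
   least-squares trend `α(μ) = a0 + a1/μ` and the conservative rule
   `α_i ← max(raw, trend, 10⁻⁸)`; a two-sided NB exact test on condition
   totals (variance `μ + α μ²`, exhaustive split enumeration); and
   Benjamini–Hochberg adjustment. Enrichment calls use `p_adj ≤ 0.05`.
4. **Membrane consensus.** Signal-peptide trimming, then three
   independent transmembrane predictors — Kyte–Doolittle windows (19
   residues, mean > 1.6), GES windows (18 residues, > 1.0 kcal/mol) with
   a hydrophobic-moment amphipathicity filter (cap 0.35), and a
   two-state Viterbi decoder (membrane runs ≥ 15) — with a protein
   called "membrane" iff ≥ 2 of 3 predict a segment.
5. **Candidate cascade.** Genes enriched in one ganglion of the focal
   species, *not* differentially expressed between the same ganglia of a
   cross-check species, and predicted membrane proteins; tallied by
   annotation category and ranked by fold enrichment among annotated ion
   channels.

The package also implements the small assay quantification rules used
around such studies (calcium-imaging responsiveness: > 10% above
baseline; immunomarker positivity: > 30% above background; qPCR ΔΔCt
fold under 100% efficiency), all with strict inequalities.

## Worked example

The synthetic generator produces every input the pipeline consumes, with
ground truth: three reference transcriptomes diverged 3% per site from
the focal one, NB counts for 3v3 focal and 2v2 cross-species ganglia,
~60k 50 bp reads at 1% error, and proteins with planted TM helices and
signal peptides.

```r
library(waterfallseq)
res <- run_pipeline(sim_config(seed = 1))
print(res)
#> pipeline run (seed 1 ): 63143 reads, 97.3% mapped; 250 genes tested;
#> TG 22, DRG 25 enriched; TG 15, DRG 13 candidates
print(res$mapping$summary)
#> waterfall mapping: 63143 reads, 61449 mapped (97.3%)
#>        sp1  sp2 sp3 unmapped total
#> TG_1  8406 1194 457      276 10333
#> TG_2  8641 1249 367      274 10531
#> ...
head(res$channels_ranked, 3)
#>    gene fold_enrichment direction         conductance
#> 1 C0130        7.490799       DRG                 Cl-
#> 2 C0217        7.416058       DRG nonselective cation
#> 3 C0183        6.730031       DRG                 Cl-
```

Reading the output: most reads map at stage 1 (the closest reference);
stages 2–3 pick up reads over budget at earlier stages plus reads from
genes private to later species. Of 250 gene entities tested, 22/25 are
called TG-/DRG-enriched at `p_adj ≤ 0.05` (50 were planted at 4-fold, so
the per-test power at these depths is ~0.9); the final channel ranking
recovers 11 of the 12 planted TG candidate channels with no unplanted
rows. `run_pipeline(..., outdir = "out")` writes the full bundle
(alignments, counts, DE tables, membrane votes, candidate tables, run
report) as seed-stamped TSVs, byte-identical across reruns of the same
seed.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --seed 1 --outdir out
```

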