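# isotarget

Many transcription factors are expressed as N-terminal isoforms with
identical DNA-binding domains but opposite biology — the p63 isoforms
ΔNp63 and TAp63 are the canonical case. Because a pan-isoform antibody
cannot tell them apart, the cleanest way to attribute a binding site to
one isoform is genetic: ChIP in cells knocked out for one isoform can
only report binding by the other. `isotarget` implements the
computational side of that design for R users working on regulatory
genomics: it classifies peaks by *isoform ownership* from three-genotype
ChIP-seq, integrates knockout RNA-seq to call *direct target genes*, and
screens peak-centered windows for *differentially abundant cofactor
motifs* that explain how two factors with the same binding site can run
different programs.

## What it computes

Given peak calls from wild-type, ΔNp63⁻ᐟ⁻ and TAp63⁻ᐟ⁻ cells, a gene
model, a genome, a count matrix and a motif library:

1. **Ownership** — on the merged-region universe
   U = ⋃(peaks), a region is *TA-specific* iff it is supported by the
   ΔN-knockout set and not the TA-knockout set, *ΔN-specific* in the
   mirrored case, and *common* when both knockouts support it. Wild-type
   evidence is optional corroboration; WT-only regions default to
   *common* (they are p63-bound but unassignable to one isoform).
2. **Differential expression** — per knockout contrast, a transparent
   negative-binomial Wald test: median-of-ratios size factors,
   method-of-moments dispersion moderated by a mean–dispersion trend
   α(m) = a₀ + a₁/m, fold change log₂((m_KO+c₀)/(m_WT+c₀)), and a
   delta-method standard error Var(log₂ m̂) = (1/ln2)²·(1+αm)/(nm)
   summed over groups. Significance: BH-adjusted P < 0.05 and linear
   fold change > 1.25.
3. **Direct targets** — a gene is a direct target of isoform I iff I
   regulates it (direction = the sign-flipped knockout change) *and* an
   ownership-consistent peak lies within 10 kb of the gene body;
   genes partition into ΔN-only / common / TA-only classes.
4. **Motif screen** — 2-kb windows around peak summits are scanned with
   log-odds PWMs (pseudocount 0.01) at per-motif thresholds set by an
   exact dynamic-programming null (background tail p = 1e-4, 0.01-bit
   bins); each motif × ownership group is tested one-vs-rest with the
   hypergeometric upper tail, BH across tests, top-10 report per group.
5. **Enrichment** — hypergeometric over-representation and a
   weighted-KS (GSEA-style) enrichment score with a gene-label
   permutation null; PWM similarity as the maximal Pearson correlation
   over alignments and reverse complements.

A first-class synthetic-data module generates a genome, gene model,
genotype peak files, sequences with motif instances planted at
group-specific rates, negative-binomial counts with knockout effects
tied to target classes, and gene sets with planted enrichment — all with
recoverable ground truth (`truth.json`), so every stage is testable
without external downloads.

## Worked example

```r
library(isotarget)

run <- runPipeline(syntheticConfig(seed = 7),
                   pipelineConfig(seed = 7),
                   outdir = "demo_run")
ownershipSummary(run$ownership)
#> dN_specific      common TA_specific
#>         200         300         100
run$report$ownership$accuracy
#> [1] 1
run$report$targets$per_class_recovery
#> dN_only  common TA_only    none
#>   1.000   1.000   1.000   0.975
run$report$de$TAp63KO$sensitivity
#> [1] 1
```

The generator planted 200/300/100 ΔN-specific/common/TA-specific peaks;
classification recovers every planted owner (accuracy 1). Of the planted
direct-target genes, all ΔN-only, common and TA-only genes are recovered
into their classes; 2.5% of non-target genes are pulled in by
false-positive DE calls, consistent with the 5% FDR the caller controls.
Stage outputs (`ownership.tsv`, `de_*.tsv`, `targets.tsv`,
`ora_*.tsv`) land in `demo_run/` with JSON provenance sidecars.

A motif screen on planted signal:

```r
lib <- c(p63MotifPair(), list(cofactorMotif()))
cfg <- syntheticConfig(seed = 11, motifs = lib,
         motifPlantRates = list(NRF2_like = c(dN_specific = .05,
                                              common = .05,
                                              TA_specific = .6)))
run <- runPipeline(cfg, pipelineConfig(seed = 11))
subset(run$motifs$top, group == "TA_specific" & rank == 1)
#>    motif_id       group  k   n   K   N odds_ratio            p            q
#>   NRF2_like TA_specific 63 100 241 600   3.059384 3.809948e-07 3.428953e-06
```

The cofactor motif planted at 60% in TA-specific windows versus 5%
elsewhere ranks first in its group at q ≈ 3e-6.

## Scope

Read alignment, peak calling, read counting and de novo motif discovery
are consumed as inputs, not reimplemented. Coordinate lift-over is
replaced by explicit ortholog ID-mapping tables. See the methods
vignette (`vignettes/isotarget-methods.Rmd`) for the model, parameter
and calibration details.
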