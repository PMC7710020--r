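# bindscape

Transcription factors that share near-identical DNA motifs — paralogous
homeodomain factors being the canonical case — nonetheless bind different
genomic sites. A major reason is that factors differ in their ability to
engage chromatin that was **inaccessible** before they were expressed.
`bindscape` is an R package for quantifying exactly this: it classifies
multi-condition differential ChIP-seq binding, measures the prior
(pre-induction) ATAC-seq accessibility of each binding class, scans motifs
with empirically calibrated thresholds, and tests whether binding classes
associate with differential-expression gene sets. A synthetic-data
generator with complete ground truth makes the whole pipeline verifiable.

It is intended for computational biologists analysing inducible-TF
ChIP/ATAC/RNA experiments, and for method work that needs a tested,
ground-truthed reference implementation of this analysis pattern.

## The statistics at the core

**Differential binding.** At a site with replicate window counts for
factors A and B, counts are normalized to the mean library size and pooled.
Under a common negative-binomial dispersion φ (variance `m + φ m²`),
conditioning on the pooled total `n` gives A's count a Dirichlet-multinomial
law with shapes `n_A/φ`, `n_B/φ` (Binomial when φ = 0). The reported
p-value is the doubled smaller tail, capped at 1 — an exact test with no
asymptotics, checked against full enumeration in the test suite. A
method-of-moments common dispersion is estimated from replicates.

**Category labels.** With binding significance q < 0.001 and differential
significance q < 0.01, each site in the cross-factor union is labeled
`A=B=C`, `A>B,C`, `A,B>C`, … or `unclassified`; categories under 500
events are folded away. Pioneer preference is then read out as, e.g., the
fraction of `B>A,C` summits inside ATAC-derived accessible domains versus
the shared category.

**Motif thresholds.** PWM windows are scored by
`Σ log2(p_motif/p_bg)`; the hit threshold is the smallest score where the
null/query hit-rate ratio falls to 0.1, with null sequences drawn from a
second-order Markov model of the genome.

**Gene-set association.** Peaks map to nearest-TSS genes;
`logit P(bound) = β0 + β1·membership + β2·log10(length)` is fit per
(category, gene set) pair, with Wald tests BH-adjusted as one family.

## Worked example

Simulate the default study — three factors A/B/C with pioneer indices
0.05/0.9/0.1 on a 20 Mb genome — then call, classify and measure:

```r
library(bindscape)

scen <- simulate_scenario(default_landscape_config(seed = 42))
ev   <- lapply(scen$chip, function(l) call_events(l, scen$input, scen$genome))
cls  <- classify_sites(ev, scen$chip, scen$input, scen$genome)
cls$categories
#>                 label n_sites
#> 1:              A>B,C    1564
#> 2:              C>A,B    1402
#> 3:              B>A,C     805
#> 4:              B,C>A     797
#> 5:              A,B>C     789
#> 6:              A=B=C     782
#> 7: unclassified/minor      17

dom    <- call_domains(scen$atac_prior, scen$genome)
shared <- scen$truth$sites[category == "A=B=C", .(chrom, summit = pos)]
bspec  <- scen$truth$sites[category == "B>A,C", .(chrom, summit = pos)]
fraction_in_domains(shared, dom)   # 1.0  -- shared sites sit in open chromatin
fraction_in_domains(bspec, dom)    # 0.0  -- B-preferential sites do not
site_density(bspec, scen$atac_prior)$summary$median   # 27.8 tags/million
site_density(shared, scen$atac_prior)$summary$median  # 155  tags/million
```

The classifier recovers the planted six-category landscape almost exactly
(the category table above matches the planted 800/1556/800/800/800/1400
design), and the B-preferential class shows the planted accessibility
deficit: ~0.18× the shared-category median ATAC density and no overlap with
called accessible domains — the pioneer-binding signature the package is
built to measure.

`run_pipeline(default_pipeline_config(), outdir, seed)` runs the whole
chain (events → classification → accessibility → motifs → gene sets →
profiles) and writes deterministic TSV/BED artifacts plus a run log; a thin
CLI lives at `inst/cli/bindscape.R`.

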