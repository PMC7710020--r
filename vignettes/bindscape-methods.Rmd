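---
title: "Models and methods behind bindscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bindscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bindscape studies a question that comes up whenever a family of
transcription factors shares similar DNA motifs: if two factors can read the
same sequence, what makes their genomic binding diverge?  One mechanism with
strong experimental support is differential engagement of inaccessible
chromatin — some factors ("pioneer-like") occupy motif instances that were
closed before the factor was expressed, others bind almost exclusively
within already-open chromatin.  The package implements the complete
computational path for this analysis: calling point-source binding events
from ChIP-seq tags, classifying sites into multi-way differential-binding
categories with a negative-binomial exact test, quantifying the prior
(pre-induction) accessibility of each category from ATAC-seq, scanning
motifs with empirically calibrated score thresholds, and associating binding
categories with differential-expression gene sets.  A synthetic-data
generator with complete ground truth makes every step testable.

This vignette documents the models, the defaults and why they were chosen,
the numerical decisions, and what the synthetic validation does and does not
establish.

## Tag model and coordinates

All coordinates are 0-based, half-open, matching BED, the only interval
format the package emits.  Aligned reads are reduced at load time to their
stranded 5' positions ("tags"); every downstream quantity ("tags per
million", binned coverage, 100 bp read extension for visualization) is
defined on tags, so fragment-level information is not retained.  Paired-end
ATAC input is treated as independent tags per mate.

## Point-source event calling

Genuine generative peak-callers model each binding event as a distribution
over read positions.  bindscape deliberately uses a simpler caller with the
same downstream contract (point-source events with q-values):

* 200 bp windows at 50 bp steps, pooled replicate 5' counts;
* expected count = max(local control estimate, global rate), where the
  local estimate is the control count in a 5 kb window scaled by the
  signal/control total-tag ratio — scaling by totals makes the test
  invariant to control sequencing depth;
* Poisson upper-tail p-value per window, Benjamini–Hochberg over all tested
  windows, retention at q < 0.001;
* overlapping significant windows merged; the summit is the position
  maximizing 5' tag density smoothed over ±25 bp (leftmost on ties).

This is a fidelity limit worth stating: the caller assumes unimodal,
well-separated events (which the generator produces by construction) and
will not deconvolve closely spaced binding the way a mixture model can.

## Differential binding and category labels

Differential testing between two factors at a site uses the exact
negative-binomial conditional test.  Counts are normalized to the mean
library size and pooled within factors; conditional on the pooled total, the
first factor's count follows a Dirichlet-multinomial with shapes
$n_A/\phi$ and $n_B/\phi$ (Binomial in the $\phi \to 0$ limit), where
$n_A$, $n_B$ are replicate numbers and $\phi$ the common dispersion in the
$\mathrm{Var} = m + \phi m^2$ parameterization.  The two-sided p-value
doubles the smaller tail (both tails include the observed value), capped at
one; swapping the groups leaves it unchanged.  The common dispersion is a
method-of-moments estimate pooled over sites, with a small-sample correction
for the squared sample mean and a floor at zero; without replication a
configurable default (0.1) is used with a warning.  No tagwise shrinkage and
no trimmed-mean normalization are attempted: the exact conditional test with
a common dispersion is reference-implementable and can be checked against
full enumeration, which the test suite does to 1e-10 for all pooled totals
up to 200.

Category labels follow the closed vocabulary used in multi-TF comparisons.
With binding significance $q_b < 0.001$ and differential significance
$q_d < 0.01$:

* `A=B=C` — events called for all factors, no pair differential;
* `A>B,C` — event called for A, A significantly exceeds both others (with
  the larger input-normalized log fold change, pseudocount 1);
* `A,B>C` — events for A and B, A and B not differential with respect to
  each other, both exceed C.

Sites from different factors are considered the same location when their
summits lie within 100 bp (single-linkage, midpoint summit); the merge
radius is configurable because published analyses rarely state it.  Every
site receives exactly one label or `unclassified`; categories with fewer
than 500 events (configurable) are folded into `unclassified/minor`.
Benjamini–Hochberg for differential tests is applied per factor pair, over
the sites significant in at least one member of the pair.

## Accessibility

Accessible domains are called by binning pooled ATAC 5' counts (50 bp),
flagging bins above the Poisson upper tail of the genome-average rate at
p < 1e-3, merging across gaps up to 200 bp, and dropping domains shorter
than 200 bp.  The published domain-segmentation tool this stands in for has
unpublished parameters, so these four values are explicit arguments; what
downstream analyses need is only the binary genome partition used for
percent-overlap statistics.  Site membership in a domain is judged by the
summit point, not interval overlap, because events are point-source; a
switch to any-overlap semantics would only increase overlap fractions.

Per-site density is the 5' count in a 2 kb centered window scaled to tags
per million; composite profiles extend each read 100 bp 3'-ward, sum
base-level overlap per offset over sites, scale to tags per million per
1000 sites, and average replicates after normalization (replicate-first
normalization applied uniformly).  The pre-normalization overlap is kept as
an integer so conservation can be asserted exactly.  Quartile summaries use
linear interpolation between order statistics (type 7).

## Motif scanning and empirical FDR

Window scores are $\sum_i \log_2 p_{\mathrm{motif}}(b_i) /
p_{\mathrm{bg}}(b_i)$ with mononucleotide background frequencies taken from
the trained Markov model's base composition; a 0.01 pseudocount is added to
every PWM cell before the log transform, and any window containing N scores
$-\infty$.  Reverse-strand windows are scored with the reverse-complement
matrix at the same window start.

The second-order Markov background (pseudocount 1, N-containing windows
skipped) is used where a sequence null is needed: large samples of 100 bp
null sequences for threshold calibration.  The score threshold is the
smallest value at which the null/query per-sequence hit-rate ratio drops to
the FDR target (0.1), evaluated on per-sequence maximum scores.  Two
numerical guards matter here.  First, candidate thresholds must be supported
by at least 10 query sequences: with finitely many query maxima, the extreme
upper tail otherwise produces spurious ratio dips when query and null are
identically distributed, and the procedure would "find" a threshold in
roughly a tenth of seeds.  Second, when no supported threshold reaches the
target the result is an explicit no-discriminative-threshold status rather
than a fallback value.  A one-sample variant (null $(1-\mathrm{fdr})$
quantile, ignoring the query set) is available behind `method =
"null_quantile"` since the empirical-FDR construction admits more than one
reading.  Peak-level hits require a window whose start lies within ±50 bp of
the summit; over-representation compares against 10,000 windows sampled
uniformly from the genome with Fisher's exact test.

## Gene sets and association

Gene sets are built from differential-expression summary tables by
deterministic threshold rules (|LFC| > 2, adjusted p < 0.01): shared sets
require the change in every factor-versus-baseline contrast and no
differential expression between factors; factor-specific and two-of-three
sets are defined from the pairwise contrasts.  One wording subtlety is
resolved here: "not differentially expressed between factors" is implemented
as $|\mathrm{LFC}| \le 2$ — the only reading consistent with the phrase.  A
consequence of defining specific sets purely from pairwise contrasts is that
a two-of-three up set is extensionally identical to the opposite
one-of-three down set; both labels are reported.

Association between a binding category and a gene set assigns each peak to
the gene with the nearest TSS (ties to the lexicographically smaller id) and
fits logistic regression of the per-gene bound indicator on set membership
with a $\log_{10}$ mappable-length covariate, by iteratively reweighted
least squares to tolerance 1e-8.  The length control is a linear term rather
than a smoother: it is the minimal faithful implementation of
"controlled by gene length", and the validation suite checks that it
absorbs a constructed length confound.  Significance is the Wald test on the
membership coefficient; complete separation is flagged and no p-value
reported.  All category-by-set pairs form one BH family.

## Profiles and reporting

Cross-experiment PCA treats experiments as observations over the
$\log_2(c+1)$-transformed window counts at the union of top-ranked sites
(top 10,000 per factor, summits merged within 50 bp).  The regularized-log
transform used by DE packages is intentionally replaced by $\log_2(c+1)$,
which is dependency-free and monotone; the choice is configurable.  Each
component's sign is fixed by making its largest-magnitude loading positive.
Heatmap matrices count 100 bp-extended reads in 100 bp bins over 1 kb
windows, order rows by binding significance, and set the color maximum to
the 85th-percentile bin count (floor 5, applied to the color scale only,
never to stored counts).

## The synthetic landscape

The generator is the package's ground-truth instrument, and its defaults are
the package's study conditions:

* genome: 4 chromosomes by 5 Mb, i.i.d. composition (A/T 0.29, C/G 0.21).
  20 Mb keeps planted sites at ~2% of bases, as in real ChIP, so
  total-count normalization behaves; sequences long enough to train a
  stable second-order background;
* three factors A, B, C with pioneer indices 0.05, 0.9, 0.1 and shared
  homeodomain-style motifs (TAAT-core 6-mers for the anterior side,
  TTTAT/TTTAC-core 7-mers for the posterior side), planted at high fidelity
  (0.995 per-position consensus probability);
* six site categories: five of 800 sites (`A=B=C`, `A>B,C`, `B>A,C`,
  `A,B>C`, `B,C>A`) plus a C-exclusive class, with the `A>B,C` and
  C-exclusive classes enlarged (1556 and 1400 sites) so that every factor's
  summed occupancy is equal.  This balance is load-bearing: sequencing
  depth is fixed per experiment, so a factor concentrating the same tag
  total on fewer sites would show genuinely higher normalized counts at
  sites it "shares", and the planted equal-binding labels would be
  operationally false.  Biologically this corresponds to each factor having
  private binding sites, which is what is observed for real paralogous
  factors;
* the B-preferential category is planted entirely in inaccessible
  chromatin with the same posterior motif as the accessible `B,C>A`
  category: B's advantage there is purely its pioneer index, which is the
  mechanism under study;
* per-site, per-replicate ChIP counts are NB with mean
  $\lambda \cdot \mathrm{scale}$ and dispersion $\phi = 0.1$
  ($\lambda = \mathrm{affinity} \times \pi$ at inaccessible sites); tags are
  placed Normal(0, 35 bp) around the site point, 50% of depth (2e6 per
  replicate, 2 replicates) is uniform background.  $\phi = 0$ switches to
  deterministic rounded means so bookkeeping tests can be exact;
* accessibility: ground-truth domains (0.6–1.4 kb) around every accessible
  site plus 400 decoy domains away from all sites; ATAC rate 10x inside
  domains; post-induction libraries add opener mass proportional to
  occupancy, spread Normal(0, 300 bp) — prior and post modes consume
  randomness identically so a zero opener strength reproduces the prior
  libraries exactly;
* expression: 3000 genes with log-normal lengths; genes within 10 kb of a
  planted site inherit the category's LFC pattern (effect 4, noise 0.2)
  with probability 0.8 — the 20% holdout keeps the bound/member
  contingency tables away from separation.

What passing the synthetic validation shows: the category rules, the exact
test, the accessibility quantification and the association machinery
recover a landscape whose generative assumptions they match.  What it does
not show: robustness to multimodal or closely spaced events, sequence
composition bias, Tn5 insertion bias, PCR duplicates, mappability holes, or
dispersion that varies with mean — none of which the generator emulates.

## Problem sizes and seeds

Unit tests run on scaled-down scenarios (2 x 1.5 Mb, 60 sites per
category); the acceptance suite simulates the full default scenario once
and reuses it across checks.  FDR calibration is validated with 1e5 null
sequences per seed across 10 seeds — one order below the scale a production
scan would use, chosen as the point where the threshold estimate is stable
to the third significant figure.  All stochastic steps take explicit seeds;
the pipeline derives stage seeds from one master seed, and rerunning
`run_pipeline()` with the same configuration and seed is byte-identical
across all TSV/BED outputs (tag libraries themselves are not written by
default; a config flag enables it).

## Known limitations

The caller's Poisson window test ignores replicate-level overdispersion at
the calling stage (it reappears in the differential test); the domain
caller has no local background correction, so very large accessible blocks
inflate the global rate slightly; Markov backgrounds above order ~8 are
memory-hungry (4^k contexts); and genome generation uses i.i.d. composition
rather than a full Markov chain — the Markov model is reserved for null
sequence generation, where it is actually exercised by the analysis.
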