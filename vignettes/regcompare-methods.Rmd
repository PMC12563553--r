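---
title: "Methods: cross-species regulatory-element comparison in regcompare"
author: "regcompare authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species regulatory-element comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the operational
definitions it implements, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one reasonable option
existed.  It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The comparison model

The package treats "regulatory element" as a purely operational class
defined by histone-mark co-occupancy, not by functional assay.  Active
promoters are marked by H3K4me3 (alone or together with H3K27ac);
active enhancers carry H3K27ac without appreciable H3K4me3.  The
pipeline therefore consists of set operations on intervals plus a small
number of statistical tests, and every step is deterministic given its
inputs:

1. *Reproducibility.*  A replicate peak is supported when a peak of the
   other replicate overlaps it by at least `min_frac` (default 0.5) of
   its own length.  Pairs satisfying the rule for **both** lengths are
   union-merged, transitively, into consensus peaks carrying the mean
   fold enrichment of their members and the summit of the
   strongest member.  This two-replicate, peak-file-only rule stands in
   for read-level consensus machinery; it keeps the 50 %-of-length
   criterion while operating purely on narrowPeak input.
2. *Classification.*  The reciprocal-overlap test for double-marked
   promoters is **inclusive** (`>= recip_frac` of both lengths,
   default 0.5).  Published descriptions of such rules oscillate
   between "more than 50 %" and "a minimum of 50 %"; the boundary case
   is measure-zero on real data but must be deterministic, and the
   inclusive reading matches the operational wording.  Overlapping
   H3K4me3/H3K27ac pairs that *fail* the reciprocal test satisfy
   neither the promoter definition (insufficient reciprocal overlap)
   nor the enhancer definition ("marked only by H3K27ac"), so both
   peaks are labelled `ambiguous` and excluded from downstream sets
   rather than forced into a class.
3. *TSS annotation.*  Distances are measured from the closer element
   edge (0 when the TSS lies inside the element, using half-open edge
   coordinates), signed negative when the TSS is 5' of the element
   along the gene's strand; ties are broken by the lexicographically
   smallest gene id.  Promoters within `max_tss_distance` (default
   3000 bp) are "high-confidence"; the more distal promoter-like
   elements are returned separately, not discarded, because distal
   H3K4me3 clusters are biologically real (low-level enhancer H3K4me3)
   and a user may want them.  The 3 kb default is a configurable
   stand-in: the grouping that a specific study applied may differ, and
   the threshold is exposed for exactly that reason.
4. *Liftover.*  `mapInterval` projects an interval through the single
   best-scoring chain covering it (ties by smaller chain id, mirroring
   liftOver's deterministic chain ranking), requires an aligned
   fraction of at least `min_match` (default 0.95, the UCSC liftOver
   default), and reports the `[min, max)` envelope of the projected
   bases in forward query coordinates.  Because one chain has exactly
   one query sequence and strand, the `split` status of the API cannot
   occur under single-best-chain semantics; it is retained for
   interface stability.  The units lifted by the pipeline are 100-bp
   summit windows; full-length elements can be passed instead.
5. *Reciprocal filter.*  An element is alignable when both liftover
   legs map and the round-trip interval has the same nearest-gene call
   as the interval that was lifted.  Both calls are computed on the
   lifted unit itself: a 100-bp summit window's nearest gene can
   legitimately differ from its parent element's, and comparing across
   units would reject elements even under identity chains.  Gene ids
   are compared within the source species (no ortholog conversion in
   the comparison).
6. *Conservation calls.*  A mapped element is conserved at a stage when
   it overlaps (>= 1 bp) any same-class element of that stage;
   cross-class overlaps are recorded (`cross_class_only`) but do not
   count, since enhancer and promoter inventories are intersected per
   class.  An alignable element conserved at no stage is
   species-specific.  Together with the unalignable set, the three
   outcomes partition the source elements.

## Expression and temporal machinery

TPM and CPM are computed from their closed forms; both satisfy the
per-sample identity Σ = 1e6 exactly, which the tests assert.
Thresholds follow the conventional boundaries: reproducible expression
is **strictly** > 1 TPM in every replicate; the low-expression filter
keeps genes > 2 CPM in at least two of three replicates; "highly
expressed in A only" means mean TPM > 10 in A and mean TPM < 1 at every
B stage through a one-to-one ortholog map.  The < 1 TPM reading of "low
to no activity" reuses the pipeline's own expressed/not-expressed
boundary rather than inventing a second cutoff; it is configurable
(`tpm_low`).  Stage-level aggregation uses replicate means.

Dynamic-gene selection replaces negative-binomial GLM testing with a
documented fold-change rule: a gene is dynamic when
max~t~ |log2((CPM~t~ + 0.5)/(CPM~0~ + 0.5))| > 2 on stage-mean CPM.
The pseudocount 0.5 stabilizes ratios at low counts and is the same
prior used for the log-CPM profiles that are z-scaled for clustering.
No dispersion estimation is performed — the package's contract is to
reproduce the clustering *input* (genes changing > 4-fold from
baseline), not the GLM machinery, which would pull in a full
differential-expression stack.

Fuzzy c-means is the standard Bezdek iteration (fuzzifier m = 2, the
common soft-clustering default; Euclidean distance on z-scaled
profiles; membership rows summing to 1; a profile coincident with a
center receives membership 1 there).  Convergence is declared when the
largest center shift drops below 1e-6; the objective Σ u^m d² is
recorded per iteration and is non-increasing, which the tests assert
per run.  Initial centers are k distinct profiles drawn under the
user's seed, making runs reproducible.  Cluster-count selection uses
the Calinski–Harabasz index on **hard** k-means partitions (10
restarts per k), with k = 1 reported as undefined; the final soft
clustering is then run at the chosen k.  This hard-selection /
soft-assignment split mirrors the widespread two-tool practice
(cascadeKM followed by a fuzzy clusterer) and keeps the index's
between/within decomposition well defined.

z-scaling uses the population standard deviation (divide by
sqrt(mean((x−mean)²))), the convention of temporal soft-clustering
tools; zero-variance profiles are an error because dynamic-gene
selection is expected to remove them upstream.

## Enrichment statistics

`fisherExact2x2` computes the exact two-sided p by enumerating the
hypergeometric distribution over tables with the observed margins, and
reports the *sample* odds ratio with the Haldane–Anscombe +0.5
correction when any cell is zero, and a Woolf (log-normal) 95 % CI.
The conditional-MLE odds ratio that `fisher.test` reports was
deliberately not used: the sample OR has a closed form that an
independent oracle can verify, and the two agree to about two decimals
in the large, balanced tables this pipeline produces.  Holm adjustment
is used across cluster tests (family-wise control over a handful of
clusters); BH FDR is used for the larger gene-set and motif families.
Both adjustments delegate to `stats::p.adjust`.

Motif enrichment scans both strands with log2 odds against the
background base composition, calls a sequence a hit when any window
reaches 80 % of the motif's maximum achievable score (standard PWM
practice; configurable because no universal threshold exists), counts
zero-or-one occurrence per sequence, and compares foreground to a GC-
and length-matched random background with a one-sided hypergeometric
test.  The background sampler matches each sequence's length exactly
and its GC count to within rounding, comfortably inside a ±2
percentage-point matching tolerance.  Note that exact tests on small
discrete tables are *conservative*: under the null the p-values
stochastically dominate the uniform distribution, so calibration is
checked one-sidedly (the rejection rate must not exceed the nominal
level by more than sampling error), not by a two-sided
uniformity test.

## The synthetic-data generator

`simulateGenomePair` builds two genomes from co-linear conserved
segments (default 4 per chromosome covering 70 % of its length)
separated by diverged gaps whose lengths are drawn independently for
the two genomes — these length differences are the indels that make
the chains non-trivial — plus, by default, one whole-chromosome
inversion to exercise minus-strand chain handling.  Chains are emitted
directly from the segment map and the reverse direction is the exact
algebraic inverse, so round-trip liftover is the identity on covered
intervals; this is an *assumption the generator makes true by
construction*, and real chain pairs built independently per direction
need not satisfy it.  Genes sit on a 6-kb grid inside segments (far
enough apart that promoter and enhancer intervals can never collide),
conserved genes get orthologs at the projected position, and planted
elements are promoters containing a conserved gene's TSS or enhancers
at distal sites, with exact partner intervals in genome B for the
conserved fraction.

`simulatePeakReplicates` emits the mark pattern the classifier assumes
(promoters: both marks co-located; enhancers: H3K27ac only), with
endpoint jitter ~ round(N(0, jitterSd)) and independent per-replicate
dropout.  Fold enrichments are log-normal (meanlog 1.5, sdlog 0.4 —
median ≈ 4.5-fold, a typical peak-intensity scale).
`simulateExpression` plants expected TPM values and draws
negative-binomial counts (dispersion 0.05, the low-variability regime
of inbred-line bulk RNA-seq; library size 1e6; 3 replicates; Poisson at
dispersion 0); 300 flat "rest-of-transcriptome" filler genes absorb
the remaining per-million mass so that planted TPM values land on the
true TPM scale.  Planted temporal patterns are five canonical shapes
(late spike, interior peak, monotone fall, monotone rise, early peak)
with log2 amplitude 4, i.e. safely beyond the |log2 FC| > 2 selection
boundary.  All draws run through named per-output pseudo-random
streams derived from one seed, so equal seeds give byte-identical
files.

What the generator does **not** emulate: nucleotide sequence (motif
analyses use separately supplied sequences), read-level noise and
mappability artifacts, peak-width/intensity correlations, overlapping
or nested real elements, many-to-many orthology, chain construction
error, or between-replicate library-size variation.  Passing tests
therefore demonstrate that the interval algebra, liftover, thresholds
and statistics are implemented correctly — not that the operational
definitions themselves would recover biology from noisy real data.

### Recovery metrics under dropout

With per-replicate dropout p, a promoter whose H3K4me3 peaks are lost
in either replicate has, by construction, exactly the evidence pattern
of an enhancer — no method operating on the surviving peaks can label
it correctly.  The package therefore reports two views
(`evaluateRecovery`): the *unconditional* accuracy over all planted
elements (bounded above by the data-survival rate, ≈ (1−p)² per
required mark) and the *observable-conditional* accuracy over elements
whose class-defining mark survived both replicates in the species where
the label is evaluated.  The conditional view isolates what is actually
under test — jitter handling, overlap rules and liftover — and is the
quantity asserted (>= 95 %) in the acceptance suite; the detection rate
is reported alongside so the two are never conflated.

### A note on a non-monotonicity

Raising `min_frac` always removes replicate peaks from the consensus
(the contributing-peak count is monotone), but the number of merged
consensus *intervals* is not monotone: a stricter fraction can cut the
middle link of a transitive overlap chain A1–B1–A2 and split one
consensus peak into two.  Randomized testing surfaced this, and the
property suite asserts monotonicity of the contributing-peak count, the
quantity that is actually guaranteed.

## Problem sizes and tolerances

The test and acceptance runs use: 500 planted elements (30 % conserved,
5 bp jitter, 10 % dropout) for end-to-end recovery; 2500 genes
(500 per cluster) for fuzzy c-means recovery at k = 5 and 20 seeds of
120-gene, 3-cluster data for Calinski selection; 50 randomized fixtures
of up to ~160 intervals for the brute-force interval oracles; 100
random tables (N <= 60) for exact-test enumeration; 1000 null draws for
Fisher calibration against a binomial 99 % CI.  These sizes give each
stochastic check a comfortable margin relative to its threshold while
keeping a full run in the low tens of seconds.  Numerical tolerances:
membership row sums to 1e-9, normalization identities to 1e-6
(relative), closed-form oracle comparisons to 1e-9 or tighter.

## Known limitations

* Ambiguous peaks are excluded rather than rescued; a study wanting to
  re-assign them (e.g. by signal ratio) must do so upstream.
* `nearestTSS` is an O(elements × genes-per-chromosome) scan —
  appropriate for gene-scale tables, not for transcript-level
  annotations with hundreds of thousands of rows.
* The liftover maps through one chain per interval; genuinely split
  mappings (breakpoints inside an element) are reported as unmapped
  coverage loss rather than as multi-part mappings.
* The OR/CI estimator is the sample odds ratio; studies whose published
  intervals came from the conditional MLE will match only
  approximately, and no contingency table is recomputable from
  published marginals alone.
* The temporal module's fold-change selector is not a differential
  time-course test; it deliberately trades dispersion modelling for
  transparency.
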