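---
title: "Methods: cohort-contrast chromatin analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-contrast chromatin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(chromcontrast)
```

This vignette is the package's account of its models, the parameters that
matter, the numerical choices, and what the synthetic validation does and
does not demonstrate.

## Study design

The pipeline contrasts a small disease cohort against a reference cohort
(defaults: 5 "APL" vs 9 "AML" samples, 4 normal-marrow controls), each
profiled for eight histone marks at 1 kb bin resolution, with matched
RNA-seq. All interval arithmetic is 0-based half-open (the BED convention);
GTF input is converted at the boundary, and the TSS is the strand-aware 5'
gene end (gene-level, one TSS per gene — transcript-level TSSs would only
tighten distances and are not modeled).

## Chromatin states

**Binarization.** Counts are pooled within each cohort and a bin is called
present for a mark iff the Poisson upper tail at the mark's global mean
rate is at most `1e-4`. This is a control-free rule: the design contains no
input/IgG channel, so the background rate is the genome-wide mean; with
strongly enriched tracks the global mean overestimates background, which
makes the call conservative — acceptable at the default signal-to-noise.

**Model.** A hidden Markov chain over bins with independent Bernoulli
emissions per mark. Baum-Welch EM with scaled forward-backward recursions
(compiled, C++) over per-chromosome, per-cohort sequences under one joint
model; per-cohort segmentations are obtained by posterior (maximum
marginal) decoding, matching standard segmentation practice. Joint learning
with per-cohort decoding keeps state identities comparable across cohorts,
which the downstream per-state Jaccard and the screen require.

**EM settings.** 3 restarts, convergence when the per-bin log-likelihood
improvement falls below `1e-4`, at most 200 iterations; the log-likelihood
is asserted non-decreasing every iteration. Restarts are initialized from
jittered *prototypes* (`0.15 + 0.7 * pattern`): the first restart uses the
K most frequent distinct mark combinations, later restarts sample
combinations with frequency-damped (square-root) weights. Rationale: with
small state classes (a few hundred Polycomb bins among 10^5) uniformly
random initialization often reaches a local optimum that splits an abundant
class instead of modeling a rare coherent one; anchoring at observed
combinations and keeping the best restart by likelihood makes the rare
classes reproducibly recoverable. The number of states is a configuration
choice (`chromstate$K`, default 8 on the surrogate genome, which has five
to six planted mark classes plus room for mixtures); model correlation
across K (`model_correlation()`, greedy matching of emission vectors) is
provided for selecting K on real data, but no automatic selection rule is
applied.

**Labels.** States are named by an ordered first-match rule table on
emission probabilities (bivalent TSS before active TSS before enhancer,
etc.), with an optional strict mode that errors on contradictory matches
and an optional annotation-enrichment condition (e.g. LAD fold > 2 for the
heterochromatin-LAD label). Unmatched states get "Other".

## Separation screen

For each (mark, state) combination the per-segment mark signal
(`counts / segment kb / library millions`) is computed for the contrasted
samples, rows are ranked by variance of `log2(x + 1)` (deterministic tie
break by genomic position), and the top window (default ranks 1..2000; an
offset selects e.g. 2001..4000) is consensus-clustered: 100 feature
resamples at 80%, average linkage on 1 − Pearson, cut at each k in 2..5,
consensus matrix per k, final partition by average-linkage on
1 − consensus. The screen flags a combination when, for some k, every
cluster is pure in the contrasted cohorts — i.e. merging clusters to two
groups by majority label leaves no minority sample anywhere, an exact
bipartition. The combination list defaults to each mark crossed with the
states whose emission for that mark exceeds 0.3. The contrasted samples are
clustered jointly (not per cohort), which is what makes "no overlapping
samples" well defined.

## Differential testing

TMM normalization follows the weighted-trimmed-mean-of-M-values recipe
(30% M trim, 5% A trim, precision weights, reference by the upper-quartile
rule, factors rescaled to geometric mean 1); the test suite cross-checks it
against an independent implementation. Dispersions are per-feature method
of moments on normalized counts (pooled within-group variance corrected
for the Poisson component), shrunk 70/30 in log space toward a lowess
mean-dispersion trend and floored at `1e-8`; the strong shrinkage reflects
that per-feature moments at n = 14 are noisy while the study-level trend is
stable. The Wald test fits per-group means by Newton iterations on the NB
score equation with library-size offsets and uses a t reference with n − 2
degrees of freedom — the small-sample correction keeps the null rejection
rate near nominal (measured ~0.04 at alpha 0.05 in the acceptance
simulation). Conventions: all-zero features get p = 1 and log2FC = 0;
classification is gain/loss/ns with a strict adjusted-p cut and an
inclusive fold cut for the enhancer rule (p.adj < 0.05, log2FC >= 1) but a
strict fold cut for the treatment-response rule (|log2FC| > 2), matching
the published operators of those thresholds.

**Normalization per family.** The enhancer analysis normalizes by TMM on
the segment count matrix (a minority of segments carries the cohort
effect, so the trimmed mean is anchored by null segments). The
heterochromatin and Polycomb families are normalized by raw library size
instead: most segments of those families carry the planted effect by
construction, which violates TMM's majority-null assumption and would
absorb the effect into the normalization factors.

## Super-enhancers

Peaks fully inside a +/-500 bp TSS exclusion zone are removed (the
`-t 500` convention), the rest stitched with an inclusive 12.5 kb gap.
Regions are scored by cohort-mean, depth-normalized signal **summed** over
the region: the rank-ordering geometry requires a cluster of k enhancers
to outrank a single enhancer of the same height, which a per-bp mean
cannot do. Ranked ascending with both axes scaled to the unit square, the
cutoff is the point where a unit-slope line is tangent to the curve from
below — computed as the minimizer of `scaled_score − scaled_rank`, i.e.
sliding the diagonal up until it touches the curve; ties break toward the
larger rank (fewer super-enhancers). A discrete first-slope-exceeds-one
scan is equivalent on curves with monotone slopes but is unstable on noisy
curves at a few hundred regions, so the global tangent is used. A
perfectly linear curve touches everywhere and yields no super-enhancers;
so does a constant curve. Flags are invariant to rescaling all scores.
Cohort-unique super-enhancers have no 1-bp overlap with the other cohort's
super-enhancers and contain at least one cohort-specific enhancer call.

## Linkage

Candidate pairs put a gene TSS within 1 Mb (inclusive) of the enhancer
edges. Both channels are transformed `log2(x + 1)` before the Pearson
correlation — the planted association acts multiplicatively, and logging
both sides makes the test statistic linear in the latent activity; the
two-sided p comes from `t = r * sqrt((n − 2) / (1 − r^2))` on n − 2 df
(r = +/-1 gives p = 0; zero-variance input gives NA). A link passes at
r >= 0.7 and p <= 0.01, both inclusive. The correlations are computed
across the two contrasted cohorts jointly (n = 14 by default). The hijack
grid restricts enhancers to a 2 Mb flank of the breakpoint on one
chromosome and genes to the flank on the partner chromosome, reports both
directions separately, stars raw p < 0.05 (no multiplicity correction on
the stars, a BH column is emitted alongside). Over-representation uses the
upper-tail hypergeometric against a user-supplied universe; the dependency
join filters to negative effect scores (threshold 0 by default, −0.5
available).

## Heterochromatin and transposable elements

Sites are merged state segments (bin mode would treat each 1 kb bin as a
site; segment mode is the default because the planted biology is
segment-shaped). TE overlap is count-based with touch (>= 1 bp) semantics:
a site counts once per TE class and subfamily it touches, so fractions are
invariant to interval order and to splitting a TE into adjacent pieces.
Gene-to-site assignment for the expression cross-tab uses gene-body
overlap by default (promoter-window mode, TSS +/- 2 kb, is available); the
cross-tab reports `(n_marked, n_DE, n_down, n_up)` per direction.

## The synthetic cohort

The generator emulates the study conditions, not a particular dataset: a
2 x 20 Mb surrogate genome at 1 kb bins, ~800 genes including a 10-gene
HOX-like cluster, LAD cores (1–2 Mb), a TE annotation (LINE/SINE/LTR/DNA
with L1/Alu/ERV1/ERVK/other subfamilies, denser in LADs), CpG islands, and
negative-binomial counts `NB(mean = lib * rate * fold, dispersion 0.1)`
with log-normal library factors. Baseline rates are mark-specific spatial
profiles (promoter-elevated active marks, LAD-elevated H3K9me2/3,
Polycomb-domain H3K27me3); the exact levels were fixed once, at values
giving ChIP-like binarization rates and differential power at desk scale.

Planted truth (all recorded in a machine-readable table):

* 60 APL-specific enhancers (log2 effect 2.0 on H3K27ac, multiplying the
  APL mean), of which 8 clusters of 5 enhancers within a 12.5 kb stitching
  span; specific enhancers are primed-to-active (H3K4me1 in all cohorts,
  H3K27ac gained), so the H3K4me1 screen combo must stay quiet while the
  H3K27ac combo separates. Cluster baselines sit below the contrast
  cohort's binarization threshold, so clusters are enhancer peaks only in
  the disease cohort — the property that makes them *unique*
  super-enhancers.
* 200 shared single enhancers and 6 shared clusters with log-normal
  strengths: the non-specific landscape that populates the rank curve and
  becomes super-enhancers in both cohorts.
* fusion-protein binding sites: 30% of planted enhancers carry a site; a
  TSS-proximal pool fixes the fraction of sites within 3 kb of a TSS at
  0.49; the remainder are distal.
* 40 H3K9me3 gain regions (log2 effect 2.0) inside LAD-annotated extension
  regions, pre-marked with H3K9me2 in all cohorts; exactly 70% overlap a
  TE by construction (the extensions are otherwise kept TE-free so the
  fraction is realized, not approximated).
* 10 H3K27me3 gain domains covering the HOX-like genes, with the genes'
  expression repressed (log2 −2) in APL; 30 silent-gene Polycomb domains
  with no cohort effect form the null family of that analysis.
* 20 enhancer-gene links plus one cross-breakpoint (hijack) link sharing a
  per-sample latent activity factor between enhancer signal and gene
  expression. The latent loading is solved per link from the target
  correlation (0.85) given the NB noise at that enhancer's level and the
  cohort shifts both channels share; the multiplier is normalized to
  cohort mean 1 so the planted fold stays exact while the covariation is
  preserved. Link genes are distinct by construction (a gene carrying two
  latent factors would dilute both correlations).
* 30 background differentially expressed genes (log2 +/-1.5), so the
  linkage stage sees a realistic DE background — passing links beyond the
  planted ones are predominantly such genes near planted enhancers, which
  is the intended guilt-by-association behavior, not a false-positive
  pathology.

The translocation is represented by a breakpoint coordinate pair plus the
planted cross-chromosome correlation; no fusion contig or contact map is
generated. Enhancer sequences (500 bp, with a consensus motif planted in a
configurable fraction) support the motif stage.

**What the generator does not model:** mappability and GC bias, fragment
size, input controls, copy-number structure, per-bin dispersion
heterogeneity (a common dispersion matches the differential model class,
so parameter recovery is well-posed; real data are less kind),
transcript-level annotation, and real TE sequence content. Passing tests
therefore demonstrate correctness of the algorithms and recoverability of
effects under the stated noise model — not robustness to the full
messiness of patient ChIP-seq.

## Reproducibility and problem sizes

Every stage draws its randomness from substreams derived from one global
seed; regenerating with the same seed is byte-identical. The test-suite
simulations use the full default cohort (40,000 bins, 18 samples) for the
end-to-end run and the screen power/false-positive loops (20 effect and 40
null seeds), a 10^5-bin sequence for HMM parameter recovery, 5,000
features for the differential calibration, and 20 cohort seeds for the
linkage/hijack pass rates — sizes chosen to make the Monte-Carlo bounds
sharp at desk scale.

## Known limitations

* The control-free Poisson binarization is sensitive to the background
  rate when a mark's enriched fraction is large; a user-supplied rate is
  accepted.
* The NB Wald test has no covariate/blocking support and no fold-change
  shrinkage; at very low counts its t-calibration is approximate.
* The consensus screen's "exact bipartition" flag is strict: a single
  outlying sample suppresses the flag even when the clustering is
  otherwise clean.
* TMM is inappropriate for region families where most regions are
  differential (see the normalization note above); the pipeline switches
  to library-size normalization for the repressive-mark families, and the
  choice is exposed rather than hidden.
* The hijack analysis takes the breakpoint from configuration; it does not
  infer breakpoints from contact maps.
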