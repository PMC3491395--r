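---
title: "Decorating pseudogene annotations with activity evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decorating pseudogene annotations with activity evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(pseudoDecoR))
```

# The problem

Pseudogenes are gene copies that have lost coding potential, yet many of
them are anything but inert: some are transcribed, some sit in open or
actively marked chromatin, some keep transcription-factor and RNA
polymerase II (Pol2) occupancy in their upstream regions, and some evolve
far more slowly than neutral decay predicts. `pseudoDecoR` implements a
complete survey pipeline that integrates these evidence layers into one
per-pseudogene, per-cell-context "decoration" table (a psiDR-style
annotation file), plus the statistics used to compare transcribed and
non-transcribed loci. Because the genome-scale inputs of such a survey
(GENCODE-class annotation, ENCODE-class functional genomics, population
variants) cannot ship with a package, a first-class synthetic-corpus
generator with planted, known activity labels accompanies the pipeline so
that every calling rule is testable end to end.

# The models and rules

## Annotation consensus and levels

Manual pseudogene annotation is intersected with two automated caller
sets under a minimum-overlap criterion of 50 bp (inclusive: an overlap of
exactly 50 bp counts; the published criterion states no strictness and
the inclusive reading is conventional). A manual locus recovered by both
pipelines is *level 1*; otherwise *level 2*. Two-way pipeline consensus
absent from the manual set is tracked separately ("delta-2way"), as are
single-pipeline calls. Support is boolean per caller — several
overlapping calls from one pipeline count once — and strand is ignored,
since degraded automated calls can be strand-ambiguous. Polymorphic
pseudogenes (coding in part of the population) are excluded from the
surveyed set.

Two extrapolators estimate the genome-wide manually-annotatable count
from a fully annotated region: scaling the manual count by an automated
pipeline's genome/region call ratio, or by the genome/annotated
nucleotide ratio. Results are rounded to the nearest integer.

## Parent assignment and sequence identity

Each pseudogene's parent is the highest-priority candidate among manual
annotation, sequence-alignment match, and automated curation, in that
order. Pseudogene and parent are aligned region-wise — CDS against CDS,
3' UTR against the parent's 3' region extended 2 kb downstream — with a
global affine-gap aligner (match +1, mismatch −1, gap open 5, gap extend
1, deterministic tie-breaking). Because the parent 3' region carries the
extension, the UTR alignment is pattern-global/subject-local: the
pseudogene UTR aligns globally, but may land anywhere within the extended
parent region. A fully global UTR alignment would force the short
pseudogene UTR across the entire extension and destroy the identity
signal; the region-wise scheme keeps the statistic well defined.

Identity is matches over aligned columns, *including* gap columns in the
denominator, so indel-riddled pseudogenes are penalized consistently.
Over the UTR a 100-column window slides with step 1 and the best window
represents the region — short parental regulatory elements (e.g.
small-RNA target sites) are better captured by the best local window
than by the regional mean. Each pseudogene is then binned on both axes:
low (< 60%), mid (closed [60, 80]), high (> 80%), giving nine identity
classes. The mid bin is closed on both edges; the published thresholds
are stated as strict "> 80%" and "< 60%", which leaves the edge points
to the mid bin. This edge convention is arbitrary off a measure-zero set
and is fixed here once.

## Transcription calling

Three computational pipelines are OR-combined; any one suffices and the
evidence tags record which fired (plus an optional externally supplied
RT-PCR validation tag):

* **EST/mRNA**: locus-specific database evidence — a best-in-genome
  alignment at the pseudogene locus *and* clear differences from the
  parent locus, both required on the same evidence record.
* **Total RNA**: reads on the pseudogene with none on the parent, or
  both covered with pairwise similarity strictly below 90% (reads then
  attributable to the pseudogene).
* **Multi-tissue coverage (BodyMap-style)**: at least half of the locus
  covered at depth ≥ 2 in at least one tissue. For loci with similar
  regions elsewhere in the genome, a mapping artifact is additionally
  ruled out by requiring the pseudogene's cross-tissue expression
  profile to be *discordant* with the parent's. The survey describes
  discordance qualitatively; here it is quantified as Spearman rank
  correlation ≤ 0.5 between the per-tissue expression vectors
  (expression = mean depth over the locus). The 0.5 default is a
  config knob (`decorThresholds(discordance_max_cor = ...)`), flagged
  as an interpretation rather than a published constant.

"Reads mapped" is realized on coverage: a base is covered by ≥ 2 reads
iff its depth is ≥ 2, and "no reads on the parent" means summed parent
depth exactly 0 — any tolerance would need a threshold the rules do not
provide.

## Conservation

Substitutions accumulate under the null as Poisson with mean *rL*, with
background rate *r* = 1.5% per site against chimp and 5% against mouse,
and *L* the pseudogene length. The conservation p-value is the lower
tail P(X ≤ k), computed by log-space accumulation of the pmf. Selection
is Benjamini–Hochberg at FDR 0.05, implemented as the standard step-up
rule (largest k with p(k) ≤ fdr·k/n). The survey's prose describes the
per-rank comparison with "less than"; it cites Benjamini & Hochberg, and
the standard step-up is implemented, with this reading documented.

Dividing by pseudogene length rather than aligned length means unaligned
bases count as unmutated — a conservative bias that slightly favors
calling conservation, inherited from the published definition. The
per-species flags combine by union into the decoration flag by default
(`conserved_combine` also allows chimp-only or intersection; the survey
reports a single conserved count without stating the combination rule).

Derived-allele-frequency spectra are binned per variant class and
pseudogene group and compared by a two-sample Kolmogorov–Smirnov test —
assumption-light, and configurable, since no test is named for the
published comparison.

## Chromatin

Signal profiles average a per-base track over ±4 kb windows anchored at
strand-aware 5' ends (minus-strand loci reversed so upstream is left).

The active-chromatin classifier works on segmentation label frequencies:
per region, the bp fraction covered by each of 25 labels, normalized by
the label's genome-wide bp fraction. A locus is active when (1) the TSS
label frequency is at least 3× the repressive level, or (2) the
gene-body start/middle/end labels (GS, GM, GE) are all at least 2× the
repressive level; criterion 1 takes precedence in reporting. Three
details are fixed here because the published description leaves them
open: the repressive level aggregates as the *maximum* over repressive
labels (criterion 1 says "any repressive markers"; the same aggregation
is applied to criterion 2 for consistency; `repressive_aggregate =
"mean"` is available); the evaluation region is the locus span plus 2 kb
upstream, so the TSS label is observable for criterion 1; and the
inequalities are inclusive. An all-zero frequency row is inactive — the
criteria additionally require a positive numerator, otherwise empty
regions would be vacuously active. The classifier is scale-invariant by
construction.

The 25-label vocabulary itself lives in the original survey's
supplementary material; the package ships a synthetic stand-in vocabulary
with the same structure (12 active labels including TSS/GS/GM/GE, 13
repressive) and accepts any vocabulary with that partition.

The DNase accessibility flag is realized as mean signal within ±4 kb of
the 5' end ≥ 2× the genome-wide track mean (`dnase_fold`); the published
field integrates DNase hypersensitivity over the same ±4 kb region
through an unspecified model, so this transparent fold-over-background
rule is documented as an interpretation.

## Upstream regulation

The upstream window is the 2 kb strand-aware region 5' of the locus,
clipped at chromosome edges. Loci whose 5' end lies strictly within 4 kb
of a protein-coding TSS are excluded from upstream calls (their signals
are not attributable), and carry NA calls with an exclusion marker.

A ChIP-seq peak belongs to a window iff strictly more than half of its
width falls inside (the exactly-half case is excluded — "majority" read
literally). Pol2 activity requires either one peak that is
simultaneously wider than 519 bp and stronger than 2.38 signal units
(the published top-5% operating points; both criteria on the *same*
peak, as the rule speaks of "a Pol2 binding peak" — `same_peak = FALSE`
relaxes this), or any peak of the seven Pol2 cofactors (Taf1, Taf7,
Tbp, Nelfe, Gtf2f1, Gtf2b, Ccnt2) in the window.
`derivePol2Thresholds()` recomputes the top-5% cut points from a pooled
peak set as 95th percentiles with linear interpolation. Promoter
activity needs only ≥ 1 bp of overlap between a supplied
promoter-region call and the window.

Enrichment of binary activity in transcribed loci uses one-sided
Fisher's exact tests; TFBS-count comparisons use the two-sided Wilcoxon
rank-sum test.

## Integration

The decoration table holds one row per surveyed pseudogene per cell
context with the identity class, transcription flag + evidence tags +
tissues, and per-context DNase/chromatin/Pol2/promoter/conservation
flags. Cross-context similarity of active sets is summarized by pairwise
Jaccard indices (defined 0 when both sets are empty). Partial-activity
classes formalize the survey's narrative in an explicit, ordered rule
set — the original names "dying" and "resurrected" but never states a
closed rule table, so this order is a documented design choice:

1. *dying*: not transcribed, active chromatin, upstream activity (Pol2
   or promoter) and conserved;
2. *resurrected*: transcribed with active chromatin but without
   retention of the parent's upstream elements;
3. *fully_active*: transcribed, active chromatin, upstream activity;
4. *dead*: every activity flag 0;
5. *partially_active*: everything else.

"Retention of the parent's upstream elements" is likewise never defined
operationally; the proxy here is: duplicated biotype *and* at least one
TF with peaks assigned to both the pseudogene's and the parent's
upstream windows. Processed pseudogenes, which retrotranspose without
flanking sequence, never retain under this proxy.

# The synthetic corpus

`simulateCorpus()` generates a miniature genome — by default 2
chromosomes × 2 Mb, 60 coding genes, 200 pseudogenes (70% processed,
25% duplicated, 6 polymorphic), 4 tissues and 2 cell contexts — chosen
so the full pipeline runs in seconds while leaving every rule a
non-trivial population to act on. All generation is a pure function of
the config; each stage draws from its own stream seeded from the master
seed, so one stage's output is reproducible even when another stage's
parameters change.

Planted signals are constructed to clear or miss each calling rule by
construction: transcribed loci get depth 3 over 60–80% of their length
in a designated tissue (vs the ≥ 2 over ≥ 50% rule), or EST/total-RNA
evidence satisfying the respective criteria; concordant decoys pass the
coverage rule but share the parent's expression ranking and carry
similar regions, so the discordance rule must reject them;
active-chromatin loci have their evaluation region covered by TSS labels
(criterion 1) or GS/GM/GE thirds (criterion 2) while all other loci sit
in repressive segments; Pol2-active loci receive one wide strong peak or
a cofactor peak with its majority in the window, inactive loci at most
narrow weak peaks; conserved loci draw substitutions at 0.1× the
background rate (mean 1.5 vs 15 per kb against chimp). A few
pseudogenes are placed within 4 kb of a coding TSS to exercise the
exclusion filter, and small "dying", "resurrected" and fully-active
subsets are forced so each partial-activity class is populated. Pol2
peak signal is drawn as a monotone (slightly noisy) function of width,
mirroring the empirical coupling of ChIP peak width and strength; this
makes the top-5% width and signal cuts select essentially the same
peaks, so the percentile-derived thresholds flag ≈ 5% of null windows.
Per-context Pol2/promoter sets share a 35% core, putting planted
cross-context Jaccard similarity in the low-0.3 range reported for real
cell lines.

What the generator does **not** emulate: realistic sequence composition
or repeat structure, read-level noise and mapping ambiguity, fragmented
or partially overlapping caller models, correlated evidence layers
(beyond the planted subsets), or segmentation label noise. Passing
recovery tests therefore demonstrates that the callers implement their
rules exactly and that the pipeline is internally consistent — not that
the rules are robust to the noise structure of real data. The published
genome-scale counts (11,216 surveyed, 876 transcribed, 1,019 conserved,
and so on) depend on GENCODE/ENCODE/1000-Genomes inputs and are out of
desk-scale reach; they are covered instead by the oracle equivalences,
the calibration checks, and qualitative-ordering tests (coding >
transcribed pseudogene > non-transcribed pseudogene TSS-profile signal).

# Numerical choices and degenerate inputs

* Poisson tails are accumulated in log space and clamped to [0, 1];
  rate 0 gives p = 1 (the degenerate null rejects nothing).
* BH ties are broken by stable input order; an empty p-value vector
  selects nothing.
* Identity with zero aligned columns is NA with a warning, never 0.
* Alignment tie-breaking is delegated to a deterministic
  dynamic-programming implementation; scores are validated against an
  exhaustive affine-gap oracle in the tests.
* Unstranded loci are treated as + strand for upstream computations,
  with a warning.
* Windows clipped at chromosome edges contribute only their covered
  bins to profiles; bins with no data are NA, not 0.
* A segmentation label absent genome-wide has an undefined normalized
  frequency; it is reported as 0 with a note attribute.
* The decoration table validates that flags are 0/1/NA, that evidence
  tag "None" co-occurs exactly with transcribed = 0, and that
  (pseudogene, context) keys are unique.

# Problem sizes

The default corpus (200 pseudogenes, 2 × 2 Mb, 2 contexts, 4 tissues)
decorates in well under a minute. The calibration experiments use 200
replicates of 1,000-locus panels for FDR and power, 1,000 random lists
for the BH oracle, a (k ≤ 100) × (λ ≤ 50) grid for the Poisson oracle,
and 200 random 500-column alignments for the window-identity oracle —
sizes at which the brute-force oracles are exact and fast.

# Limitations

The package consumes caller outputs, promoter calls, divergence counts
and DAFs as inputs; it does not re-implement homology search, peak
calling, the upstream promoter model, read mapping, or multiple-genome
alignment. Where the published description left a constant or an
aggregation unstated (discordance threshold, repressive aggregation,
chromatin evaluation region, DNase rule, identity bin edges,
conservation combination, retention proxy, partial-activity rule order),
the choice made here is explicit, configurable where sensible, and
flagged in the relevant help page.
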