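---
title: "Detecting and interpreting time-course isoform switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and interpreting time-course isoform switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoswitch)
```

## The problem

Bulk RNA-seq quantified at transcript resolution (e.g. Salmon `quant.sf`
tables, in TPM) over a sampled time course can reveal *isoform switches*:
two transcripts of the same gene reversing their relative abundance over
time. Because TPM is within-sample normalised and isoform effects often
cancel at the gene level, a gene's cumulative expression can be nearly
flat while its isoform composition — and hence the encoded protein —
changes drastically. `chronoswitch` detects such switches in single-sample
time courses (one library per time point), locates when in the time course
switching concentrates (*switch time peaks*, STPs), classifies what the
exchange of isoforms does to the gene product, and tests switching-gene
sets for pathway over-representation.

## Switch detection

For each unordered isoform pair of a gene (single-isoform genes are
excluded), crossings of the two expression series are located; a crossing
between consecutive samples where the difference changes sign is dated by
linear interpolation. Consecutive crossings partition the samples into a
flanking interval $I_1$ (before) and $I_2$ (after). Each crossing is then
scored on the *observed* per-timepoint values:

* **Magnitude** $S_2 = d(I_1) + d(I_2)$ with
  $d(I_k) = \frac{1}{|I_k|}\sum_{m \in I_k} |x_i(m) - x_j(m)|$, the mean
  absolute separation of the pair in TPM. $S_2$ is the headline
  "difference" score: larger values mean larger expression changes on
  both sides of the switch.
* **Probability**: the fraction of flanking samples ordered consistently
  with the switch (isoform $i$ above $j$ before, below after). Exact ties
  count as inconsistent — a deliberate conservative choice so that flat
  zero-TPM profiles can never look like confident switches.
* **P-value**: within each interval, a two-sided one-sample t-test of the
  paired differences $x_i(m) - x_j(m)$ against zero; the event's p-value
  is the larger of the two (both flanks must show separation). With no
  replicates the time points inside an interval serve as the test's
  samples. Zero-variance differences yield $p = 0$ (non-zero mean) or
  $p = 1$ (zero mean).
* **Minimum points**: $\min(|I_1|, |I_2|)$; intervals with fewer than two
  samples leave the t-test undefined and the event is removed by this
  filter.
* **Correlation**: the Pearson correlation of the two full series
  (defined as 0 for constant series).

The default filter keeps events with probability ≥ 0.5, $S_2$ ≥ 1 TPM,
p ≤ 0.001, ≥ 2 points per flank, |correlation| ≥ 0 and a switch time
inside 0–30 h of experimental time. The correlation bound is applied to
the *magnitude* of the correlation: genuinely switching pairs are
anti-correlated (an antiphase pair has correlation near −1), so a signed
bound at 0 would discard exactly the events the method exists to find; a
cutoff of 0 therefore disables the correlation filter, and positive
cutoffs select strongly coupled pairs of either sign.

### Smoothing

Crossing localisation (only) can run on a degree-4 B-spline least-squares
fit of each series, which suppresses noise-induced zig-zag crossings. The
default basis dimension is `degree + 1`, i.e. one interior knot: a
knot-free degree-4 basis is a bare quartic polynomial whose edge bias can
displace crossings near the first and last samples by about an hour,
enough to push them across a flanking sample and through the
minimum-points filter. With one interior knot the fit still reproduces
any polynomial up to degree 4 exactly (the package tests assert this to
1e-8) while recovering ~99% of identifiable planted crossings instead of
~90%. Metrics are always computed on observed values, never on fitted
ones, because $S_2$ is defined on sample expressions.

### What the p-value filter can and cannot certify

The per-interval t-test measures whether the pair's separation is
consistently non-zero across an interval. For *step-like* switches the
within-interval differences are roughly constant, the t-statistic grows
like the separation-to-noise ratio, and the p ≤ 0.001 cutoff is routinely
passed (≈97% of planted step switches at noise half-range 2 TPM). For
*smoothly oscillating* pairs the situation is structurally different: in
an interval between two crossings the differences trace a sinusoid
half-arch, whose shape fixes the ratio of mean to standard deviation at
about 2.1 regardless of amplitude, so $t \approx 2.1\sqrt{n}$ no matter
how clean the data. With 11 samples 3 h apart and a 24-h period, flanking
intervals hold at most 5 samples, capping the per-interval p-value near
0.02; reaching 0.001 would need ~26 samples per flank. Consequently the
full default filter cannot pass sinusoidal switches in this design — a
property of the test construction at these sample sizes, not of the
implementation — and the package's sinusoid recovery figures are reported
with the p-value filter disabled (`switch_thresholds(pval_max = 1)`),
where ~98–99% of identifiable crossings are recovered to within ±1.5 h.
With replicated libraries per time point the intervals would carry enough
samples for the cutoff to become usable; replicate-aware scoring is out
of scope here.

### Identifiability of crossings

A crossing can only satisfy the minimum-points filter if at least two
samples fall strictly inside each flanking partition. The synthetic
generator records this flag per planted crossing, and recovery rates are
reported over identifiable crossings: a crossing 2 h after the first
sample is unrecoverable *by definition* of the filter, not by failure of
the detector.

## Switch time peaks

Filtered events are binned into half-open `[a, b)` bins of one sampling
interval (3 h), aligned to the experimental time origin. An STP is a bin
(or plateau of equal bins, resolved to the earliest) whose count is
strictly greater than both neighbours and at least
`mean(counts) + alpha * sd(counts)` (`alpha = 1` by default). The rule is
deliberately parameter-light — it reproduces the "one tall bin among ten"
pattern a reader would call a peak — and is scale-invariant, so it
depends on the shape of the histogram, not the number of events. A flat
histogram has no peak. `alpha` is exposed because real histograms vary in
how prominent their peaks are.

## Consequence classification

For every filtered pair the *gained* isoform is the one dominant after
the switch time; all gain/loss polarity flows from that single
definition. Axes:

* **Coding potential (CP)** — scored per transcript and thresholded at
  0.725. Externally computed coding probabilities (CPAT-format tables)
  are used verbatim when supplied; otherwise a built-in logistic
  heuristic applies:
  `plogis(2*log(L+1) + 2*coverage + fickett - 10)` with `L` the length of
  the longest complete ORF, `coverage` its fraction of the transcript and
  `fickett` a TESTCODE-style position/composition statistic. The
  constants are fixed; the scorer exists so the pipeline is
  self-contained and separates long-ORF transcripts from ORF-free ones
  decisively, but it is not a trained model and real analyses should
  supply external scores.
* **ORF** — the longest ATG-initiated, stop-terminated forward-frame ORF
  (ties 5'-most; codons containing N never match). Classes: relative
  length difference ≤ 0.1 is "similar"; otherwise longer/shorter; ORFs
  absent on one side are complete gain/loss.
* **ORF similarity** — the Jaccard index of the two ORFs' genomic
  footprints (each ORF projected through its isoform's exon structure);
  ≥ 0.9 counts as "similar sequence".
* **NMD** — the canonical 50-nt rule: sensitive when the stop codon ends
  more than 50 nt upstream of the last exon–exon junction. This fixed
  rule is the field's standard first-order predictor; it ignores
  long-3'UTR and EJC-independent effects.
* **Intron retention and splice events** — a strand-aware structural
  comparison of the two exon chains on genomic coordinates: differing
  outermost 5'/3' boundaries (alternative TSS/TTS), exons of one isoform
  inside introns of the other (exon skipping), exons spanning an entire
  intron of the partner plus both flanking exon ends (intron retention),
  and internal donor/acceptor shifts (alt 5'/3' site; exon pairs already
  explained by a retention are not re-classified).
* **Domains** — literal regular-expression motifs from a user-supplied
  table scanned against the ORF proteins, with overlapping hits all
  reported. This is a motif scanner for planted or curated signatures,
  explicitly not a profile-HMM search.

Per STP, gains and losses on each axis are tested with a two-sided exact
binomial test against 0.5 (unchanged pairs excluded; p computed by
integer summation of binomial coefficients, so small-n values like
9-vs-1 → 0.021484375 are exact) with a 95% Clopper–Pearson interval for
the gain fraction.

## Over-representation analysis

Switching genes (events deduplicated to genes) are tested against GMT
collections with the hypergeometric upper tail
$P(X \ge k)$, computed by exact summation. The universe defaults to the
union of collection members. Sets overlapping the query in at least one
gene enter the Benjamini–Hochberg correction; results are kept at
p ≤ 0.05 and adjusted p ≤ 0.2 (0.5 is the conventional relaxation for
disease-ontology collections), sorted and truncated to the top 10.
"Bonferroni" is available as an alternative adjustment.

Because the hypergeometric null is discrete, $P(p \le 0.05)$ under random
queries equals the largest achievable level below 0.05, which for
arbitrary set geometries can sit far under the nominal level. The
package's calibration check therefore uses a geometry chosen analytically
so the achievable level is essentially nominal — a universe of 40 genes
partitioned into four sets of 10 with queries of 10, where the atom is
0.0498 — and verifies the empirical rate across 2,000 seeded replicates.

## The synthetic generator

`simulate_profiles()` emulates the study design this package models: 11
time points 3 h apart (30 h of experimental time), one sample per time
point, ~24-h periodic isoform profiles with baseline 10 TPM and amplitude
5 TPM, and uniform measurement noise of half-range 2 TPM added then
clamped at zero (mirroring jitter-style noise injection for single-sample
designs). Planted switching pairs are antiphase sinusoids by default —
the archetype of a period-locked switch, with analytic crossings at the
sine zeros recorded in the truth table — with step and ramp archetypes
for sharp, single-crossing switches. Non-switching genes get
proportional copies of a common rhythmic profile (never crossing in the
clean signal); remaining isoforms of switching genes are low constant
profiles. What this does *not* emulate: quantification uncertainty
correlated across isoforms, count-based (negative-binomial) noise,
library-size artefacts, or genes with more than one switching pair — so
passing recovery tests demonstrates correctness of the detection logic
under the stated noise model, not robustness to every property of real
RNA-seq.

`simulate_gene_models()` plants one consequence contrast per gene
(coding→noncoding via an alternative start inside the 3'UTR, NMD gain via
a 3'UTR intron 60 nt past the stop, intron retention, alternative
TSS/TTS, and a frame-preserving domain-removing exon skip), on both
strands, with every transcript sequence spliced consistently from a
common notional locus. The generator re-samples a gene until its
structural truth is self-consistent — the planted ORF is the longest ORF
and planted motifs occur exactly where intended — so the truth table is
guaranteed by construction; it never consults the coding-potential
scorer, keeping truth recovery a genuine test of the classifier.

## Numerical and design choices

* Time axis: hours since the first sample; reports can be shifted to ZT
  by an origin offset. The 0–30 h filter window refers to this axis.
* Internal coordinates are 0-based half-open everywhere; conversion to
  GTF's 1-based inclusive convention happens only at I/O.
* Missing transcripts across samples abort assembly unless zero-filling
  is explicitly enabled — silent zero-fill fabricates switches.
* All binning is half-open; an event at an edge belongs to the later bin.
* TSV outputs print doubles with 17 significant digits, making every
  write/read round trip bit-exact.
* One global seed fans out to per-stage seeds, so a pipeline re-run with
  the same configuration is hash-identical (the MANIFEST records MD5s).
* No multiple-testing correction is applied to switch p-values (the raw
  0.001 cutoff is the convention this pipeline follows); BH is available
  for the enrichment stage where it belongs.

Test and validation problem sizes: 1,000 random fixtures for the S2
oracle, 200 seeded replicates (3 genes each) for sinusoid recovery, 100
for specificity, 200 planted genes for consequence truth, exhaustive
hypergeometric enumeration to universe size 12, and 2,000 null queries
for ORA calibration. These sizes give stable rates (recovery estimates
move by <1% between seeds) while keeping the full suite fast.

## Known limitations

* Replicate-aware scoring (and hence a usable p ≤ 0.001 filter for
  oscillating pairs) is not implemented; see above.
* The coding-potential heuristic is a fixed-constant score, not a trained
  classifier; treat its calls on real transcripts as provisional.
* Domain calls are literal motif matches; absence of a hit is not
  evidence of domain absence.
* Isoform-fraction (relative-usage) switches, rhythmicity testing and
  period estimation are out of scope.
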