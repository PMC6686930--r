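---
title: "Methods: poly(A) site cluster discovery from bulk RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) site cluster discovery from bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Cleavage and polyadenylation append a non-templated A homopolymer to the 3'
end of a transcript. In a shotgun RNA-seq library a minority of fragments
straddles the cleavage site, so their reads end (or, after reverse
complementation, begin) in that homopolymer. pacscan treats every such read
as a noisy measurement of one cleavage position and aggregates them into
poly(A) site clusters (PACs). The assumptions are:

* tails are terminal in the read (adapters already removed upstream);
* a genuine tail is absent from the genome, so the untrimmed read cannot
  align end-to-end while the trimmed read can;
* cleavage is imprecise: positions scatter over a few nt around a mode
  (micro-heterogeneity), so nearby sites describe one polyadenylation event;
* oligo(dT)-primed artifacts are recognisable by genomically encoded A
  richness immediately downstream of the called site.

## Tail detection

A 3' tail is the longest suffix that ends at the read terminus in A, begins
with A, and contains no internal non-A run longer than `endgap` (default
2 nt); 5' T tails use the mirrored prefix rule. N bases are replaced
uniformly at random (seeded) *before* scanning, mirroring the
replace-then-filter order of established tail-mining tools; a replacement that is not
A (T) counts toward the impurity tally. The merged tail is accepted only if
it is at least `min_tail` = 8 nt long and its non-A (non-T) fraction is at
most `max_nona_frac` = 0.10, with the merged length as denominator. There is
deliberately no fallback to a shorter pure run when the merged tail fails
the purity test: the merge rule defines *the* tail, and an impure merged
tail disqualifies the read. Under the unstranded protocol both ends are
scanned and the longer accepted tail wins; a tie goes to the 3' A tail, and
reads where both ends qualify are flagged `ambiguous`. Both conventions are
package decisions — the detection rule itself fixes neither.

Two consequences are worth knowing. First, when the templated sequence just
upstream of the true site is A-rich, those bases are absorbed into the tail
and the called site shifts a few nt upstream; the shift is bounded by the
merge rule and stays well inside the 24-nt clustering window, but single-site
coordinates are exact only where the terminal template context is A-free.
Second, the merge can overshoot into the insert and push the impurity
fraction over 10%, discarding a genuine tailed read; this costs a roughly
constant fraction of signal reads and is the detection rule working as
specified, not a bug.

## From alignments to events

Trimmed inserts shorter than `min_trimmed_len` = 20 nt are discarded. 5' T
reads are reverse complemented so all inserts are in mRNA sense. The insert
is aligned (end-to-end, unique reports only); the cleavage position is the
mRNA-sense 3' terminal aligned base — the last templated base, 0-based
internally, 0-based half-open in BED output. Uniqueness is taken from the
aligner's own reporting: the bundled exact-substring aligner enumerates all
occurrences and reports `unique`/`multi`/`unmapped` exactly; for external
SAM/BAM the secondary flag and AS/XS score tags are used.

The internal-priming filter examines the `window` = 10 genomic nt
immediately downstream in mRNA sense and drops the event when the A count
reaches `max_a` = 7 or the longest A run reaches `max_run` = 6. These
thresholds follow common practice in poly(A)-site pipelines (widely used
filtering scripts do not publish their constants) and are exposed as
parameters. A window truncated by a contig end scales both thresholds
proportionally, rounding up; a site at the very end of a contig has no
downstream evidence and is kept.

## Clustering

Sites with fewer than `min_reads` = 3 supporting reads are discarded, then
sites within `window` = 24 nt on the same chromosome and strand are
clustered iteratively: the unassigned site with the highest read count
(ties: smaller coordinate, for determinism) seeds a cluster and absorbs
every unassigned site within ±24 nt; this repeats until exhaustion.
"Within 24" means a distance of at most 24 between 0-based positions. This
support-ranked greedy reading of "iterative clustering" makes the
highest-count site the representative by construction and allows cluster
spans up to twice the window — consistent with published spans not being
universally ≤ 24 nt. A single-linkage alternative (`linkage = "chain"`) is
provided for comparison; it chains consecutive sites ≤ 24 nt apart and has
unbounded spans. Cluster support is the sum of member site counts, and the
heterogeneity summary reports adjacent-site distances, the multi-site PAC
fraction, span fractions, and the Pearson correlation between ln(sites per
PAC) and ln(representative count), left undefined when either log vector is
constant.

## Two-pass annotation

Only the longest transcript per gene is used (span length; ties broken by
transcript id). Introns are exon gaps; UTRs come from explicit GFF3 features
or, failing that, exon-minus-CDS split by side. Pass 1 assigns each PAC
representative to UTR3 / CDS / UTR5 / intron by overlap — when overlapping
genes disagree the priority is UTR3 > CDS > UTR5 > intron (3'-end biology
dominates; the case is flagged `ambiguous`), with ties going to the gene
with the nearest 3' end — or to `intergenic`. From the pass-1 intergenic
PACs, the distance to the 3' end of the nearest upstream same-strand gene is
collected; the extension `ext` is the rounded median of the distances in
(0, 1000] nt (the 1-kb window restricts the median to the near-gene
population that plausibly represents unannotated 3'-UTR). Genes with an
annotated 3'-UTR are extended by `ext`; genes without one by
`utr3_median + ext`, where `utr3_median` is the median 3'-UTR length over
*all* annotated transcripts that have one (not only the longest per gene —
the broader set is the better estimate of typical UTR length and matches the
quantity the method was calibrated on). Extensions are truncated at the next
same-strand gene so no position is claimed twice. Pass 2 relabels intergenic
PACs inside an extension window as `extended_UTR3`. If no intergenic PAC
qualifies, a configurable default (150 nt) is used with a warning.

Known transcript termini are compared by first clustering them with the same
24-nt rule (unit weights; the leftmost member represents a cluster) and then
measuring each clustered terminus against the nearest PAC interval — 0 when
inside the span, otherwise the coordinate gap — with support declared at
≤ 24 nt. Intergenic PACs can be validated against externally assembled
novel-gene intervals (strand-aware, end-inclusive containment).

## APA quantification

Relative expression of a PAC is its cluster support divided by the summed
support of its gene's PACs, extended-3'-UTR PACs included (they are genic
once rescued). Ranks are by descending RE with ties broken by support and
then coordinate. A PAC with RE strictly above 0.7 in a multi-PAC gene is
*strong*; RE = 0.7 exactly is not. The threshold must lie in (0.5, 1) —
below 0.5 two PACs of one gene could both be "strong" and the gene-level
classes would be ill-defined. Rank read fractions sum, over APA genes, the
support at each rank and divide by the total APA-gene support. The
feature-length comparison draws three *disjoint* control groups (disjointness
avoids pseudo-replication; the draws are seeded) of PAC-free feature lengths
and runs a one-sided (greater) Wilcoxon rank-sum test of the PAC-bearing
lengths against the pooled controls.

## Sequence context

Windows of `[-300, +100]` nt around representatives are extracted in mRNA
sense (position 0 = last templated base); windows crossing a contig edge are
skipped and counted. Composition is reported per position over A/C/G/U
(genomic T printed as U, matching the conventional RNA spelling of motifs
such as AAUAAA; all computation stays on DNA). Profiles of non-3'-UTR
categories are compared to the 3'-UTR profile position-by-position with a
4-category χ² (3 df); a reference frequency of zero against a nonzero
observation triggers add-one smoothing of the reference counts at that
position, and any ×10³ scaling is a plotting convention only. The NUE search
region is positions −40…−10 inclusive (31 nt, 26 hexamer placements);
hexamer starts outside −40…−15 are not counted. With `once = TRUE` a motif
counts at most once per window; windows with an N in the scanned subregion
are excluded and logged. Z-scores use a 0-order Bernoulli background with
base frequencies estimated from the scanned subwindows themselves:
`p_word = Π π(letter)`, per-window occurrence `q = 1 − (1 − p_word)^26`,
`z = (obs − nq)/√(nq(1−q))`. Motif-significance tools differ in their
background models and rarely print them; this explicit binomial-occurrence
model is the package's committed choice, and the background estimator is a
parameter.

## The synthetic truth set

`simulate_genome()`/`simulate_reads()` generate the test-bed the suite and
the acceptance script run on. Defaults describe the study conditions: two
300-kb chromosomes of uniform random sequence; 200 non-overlapping genes
(5'-UTR, two CDS exons, one intron, 3'-UTR; 20% of genes lack the 3'-UTR
feature and place their true sites 40–260 nt downstream of the gene end);
1–4 true sites per gene with weights (0.50, 0.30, 0.15, 0.05), i.e. ~1.75
sites per gene; 55% of multi-site genes dominated by one site with usage
0.76–0.90 (matching the reported prevalence of dominant PACs), non-dominant
genes keeping every usage below 0.65 so the strong/medium split is
identifiable at moderate depth; cleavage jitter = rounded Normal, SD 2 nt;
tails 10–25 nt appended *after* extracting the templated fragment, so they
are non-templated by construction; 500,000 100-nt reads, 5% signal, 1%
decoys ending in one of 20 planted genomic A-runs (12–18 nt, kept clear of
genes and true sites), the rest background fragments; per-base substitution
errors at 0.1%; AAUAAA written into the genome 20–30 nt upstream of 60% of
true sites so the motif analysis has signal. Unstranded reads are emitted in
random orientation; the stranded-paired protocol emits mate 2 in mRNA sense
and mate 1 as its reverse complement, so tails appear as 5' T on mate 1 and
3' A on mate 2 (both mates cover the same fragment — a simplification that
doubles support uniformly and leaves every statistic based on fractions
unchanged).

The generator reproduces the statistical *structure* the pipeline assumes,
not real data: expression is uniform across genes, errors are uniform
substitutions, there are no PCR duplicates, indels, quality gradients,
splice-spanning tail reads, repeats, or base-composition biases beyond the
planted elements. Passing tests therefore demonstrate algorithmic
correctness and calibration on data satisfying the model's assumptions, not
performance on real libraries — in particular the near-zero spurious-PAC
rate reflects the high-entropy genome, and real genomes' A-rich regions
lean much harder on the internal-priming filter.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based (GFF3 in/out converts to 1-based
  inclusive; BED is 0-based half-open; TSV prints the internal 0-based
  values).
* Determinism everywhere randomness exists: generator outputs are pure
  functions of the config (reads use seed + 1), N replacement and control
  draws take explicit seeds and restore the caller's RNG state.
* Empty inputs return empty, correctly typed tables; an empty untrimmed
  alignment set keeps all candidates with a warning; zero qualifying
  intergenic PACs fall back to the default extension with a warning; a gene
  with zero support is excluded from profiles with a warning.
* The χ² of a profile against itself is zero up to floating point
  (≤ 1e−12 in the tests); Z-scores are undefined (NA) when the binomial
  variance is zero; the ln–ln correlation is NA for fewer than two PACs or
  zero variance.
* Tests run the generator at reduced sizes (20k–60k reads, 30–100 genes)
  chosen so sampling noise stays far from the tested margins; the
  end-to-end blocks use the full 500k-read study conditions.

## Known limitations

* Single-site coordinates shift upstream where the template ends in A-rich
  sequence (see Tail detection); cluster-level results are unaffected.
* The exact-substring test aligner tolerates no mismatches, so each
  sequencing error in an insert costs that read; at the default 0.1% error
  rate this is a uniform ~8% support haircut.
* The ≥ 3-read site filter is applied after pooling all samples; per-sample
  calling with cross-sample reconciliation is out of scope.
* GO enrichment, de novo assembly and FUE/cleavage-element motif discovery
  are out of scope; novel-gene intervals and transcript termini are consumed
  as external inputs.
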