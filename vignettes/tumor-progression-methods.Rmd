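---
title: "Methods: copy-number and mutation clonality across tumor progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number and mutation clonality across tumor progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnevolve)
```

## The problem

When successive lesions of one cancer are sequenced — pre-invasive regions,
the primary tumor, a later metastasis — the pattern of shared and private
somatic events discriminates between two models of metastatic spread. Under
*linear* progression the metastasis is seeded late by the most advanced
primary clone, so the event sets are perfectly nested: everything found in an
earlier lesion recurs in every later one. Under *parallel* progression the
metastasis disseminates early and evolves independently, so events private to
an earlier lesion are expected. `cnevolve` implements the whole chain of
inference needed to make that call from paired tumor/normal read counts:
copy-number profiling, allelic imbalance, segmentation, event classification
with subclone fractions, somatic-variant clonality, and the cross-sample
concordance analysis itself.

## Copy-number model

### Windows and log2 ratios

Coverage is summarized in genomic windows defined on the normal sample
(`build_windows()`, default 1000 normal reads per window, so window width
adapts to coverage). Per window the signal is

$$\mathrm{log2}_i = \log_2\!\frac{n^{tumor}_i}{n^{normal}_i} - \mathrm{median},$$

with the genome-wide median subtracted so that — provided most of the genome
is copy-neutral — a diploid window sits at 0, a 3:2 single-copy gain at
0.585 and a 1:2 heterozygous loss at −1 (`compute_log2()`). Windows that are
under-filled at a chromosome end are kept but excluded from the median;
windows with zero tumor reads are floored at −5 (configurable) to keep the
track finite.

For an event of total copy $c$ carried by a fraction $f$ of tumor cells in a
sample of purity $p$, the expected centered ratio is

$$\mathrm{E}[\mathrm{log2}] = \log_2\frac{2(1-p) + p\,(2(1-f) + cf)}{2},$$

implemented as `expected_log2(c, p, f)`. Two consequences shape everything
downstream: normal admixture and subclonality both compress the signal toward
0, and the mapping is many-to-one — a homozygous loss in half the cells and a
clonal heterozygous loss both sit at −1. The BAF track exists to break that
degeneracy.

### B-allele frequencies

At germline-heterozygous known-SNP sites, `BAF = b/(a+b)`. Sites are filtered
to known SNPs, heterozygous in the normal, and ≥ 30× in both samples
(`select_informative_sites()`). Without an explicit genotype flag,
heterozygosity is called from the normal BAF in \[0.25, 0.75\] — a package
decision; the window is configurable. Under a heterozygous loss carried by
the cell fraction $pf$ the BAF splits to

$$m = \frac{1-pf}{2-pf}, \qquad 1 - m,$$

(`expected_baf()`): 0/1 for a pure clonal loss, pulled inward by admixture or
subclonality. Because haplotype orientation is arbitrary, imbalance is
averaged on the folded scale $|BAF - 0.5|$. Raw folding is biased upward by
binomial noise (at 30–150× the fold of pure noise is 0.03–0.06, the same
order as the subtle imbalances being measured), so segment summaries use the
noise-corrected deviation

$$\hat\Delta = \sqrt{\max\!\Big(0,\ \overline{(BAF-0.5)^2} - \overline{0.25/d}\Big)}$$

(`baf_deviation()`), which removes the $\mathrm{Var}[BAF] \approx 0.25/d$
noise floor. This correction is what keeps cell-fraction recovery unbiased
down to $pf \approx 0.2$.

### Aneuploidy baseline correction

Median centering fails when more than half the genome is altered. To correct
it, `recenter_baseline()` looks for genuinely diploid territory: it segments
the track, keeps segments spanning ≥ 50 windows whose site-level median
folded BAF is below ε = 0.03 and whose log2 spread is unremarkable, picks the
longest such span, and subtracts its mean log2 from the whole track. The
median-folded-BAF statistic is used (rather than the mean) because it is
robust to scattered imbalanced sites; ε = 0.03 assumes SNP depth of a few
hundred reads — at 30× the noise floor alone reaches ε, and the function
would then simply warn and leave the track unchanged rather than shift it
wrongly. If no span qualifies (fully aberrant genome) the track is returned
unchanged with a warning.

## Segmentation

Tracks are partitioned per chromosome by an exact penalized least-squares
changepoint search (`segment_track()`): a dynamic program over all admissible
changepoints under a Gaussian mean cost, with no emitted segment shorter than
`min_probes` windows (default 10, the minimum-probes-per-call rule). The
default penalty is $2\hat\sigma^2\log n$ per changepoint with $\hat\sigma$
estimated robustly from first differences (MAD/√2), which makes the
segmentation invariant to adding a constant to the track and deterministic
for fixed input. This is a deliberate substitution: the segmentation engine
used by the commercial viewer this analysis style comes from is proprietary
and undocumented, so a reproducible open equivalent honoring the same
minimum-probe rule is used instead. Log2 and folded-BAF tracks can be
segmented jointly by cutting at the union of their breakpoints
(`combine_breakpoints()`); `merge_adjacent()` re-fuses abutting segments
whose log2 and BAF states are indistinguishable, iterating to a fixed point
so the operation is idempotent.

## Event classification

`classify_segments()` maps segments to the event vocabulary — LOH
(heterozygous loss), HL (homozygous loss), OCL (one-copy loss inside
previously amplified territory), and the graded gains CG / HCG / VHCG / EHCG.
Thresholds (see `cn_thresholds()`) act on the purity-corrected log2 scale
$\hat c = (2^{L+1} - 2(1-p))/p$:

* **Gains** bin at log2 0.15 / 0.55 / 1.0 / 1.8. These grade boundaries are
  package defaults, exposed in the configuration, because the source
  vocabulary never quantifies its grades. Gains never receive a clonality
  call: a moderate gain in all tumor cells and a strong gain in a subclone
  are indistinguishable in coverage, so their clonality is `indeterminate`
  by construction.
* **Losses** are called below log2 −0.1. The BAF-based fraction estimate
  $pf = (1-2m)/(1-m)$ (`estimate_fraction()`) drives the clonality call:
  `complete` when it reaches the sample purity within 0.1, `subclonal` below,
  `indeterminate` without BAF support. The log2-based inversion
  $pf = 2 - 2^{L+1}$ is carried as an internal consistency diagnostic.
* **HL** is called when $\hat c < 0.35$ (configurable); a complete HL's
  expected $\hat c$ is 0 and the floor allows for noise.
* **OCL** is assigned only when a loss interval lies inside gain territory of
  an *earlier* sample — the interpretation chosen for the loss-within-
  amplification category, since the source vocabulary never defines the
  LOH/OCL boundary; it is flagged here as an interpretation.

`detect_loss_levels()` clusters loss-segment log2 means by the exact 1-D
two-means split and accepts two levels only if the centers are ≥ 0.25 log2
apart (package default; the phenomenon is shown only graphically in the
source material). The deeper level is Level 2 (complete), the shallower
Level 1 (subclonal). Finally `resolve_homozygous_subclonal()` handles the
signature case where depth and allele data disagree: a Level-2-deep loss
whose folded BAF stays near 0 cannot be a complete heterozygous loss and is
reclassified as a homozygous loss in one subclone (fraction $1 - 2^{L}$),
the balanced BAF coming from the sibling subclone that kept both alleles.

## Somatic variant clonality

`filter_somatic()` applies fixed thresholds: normal depth ≥ 10, normal BAF
< 0.02, population allele frequency ≤ 1% (or unknown), and at least one tumor
sample with ≥ 3 alternate reads and BAF > 0.15; presence is then flagged in
every sample with BAF > 0.05. Candidate generation itself (a full caller) is
out of scope — the filter consumes any per-sample allele-depth table.
`presence_matrix()` counts every cross-sample membership pattern;
`detect_purification()` flags variants subclonal early (BAF in
\[0.05, 0.25\]) and clonal-heterozygous late (BAF in \[0.35, 0.55\]) — bands
chosen to bracket the 10–15% → 40–48% signature of a metastasis descending
from a primary-tumor subclone, and exposed in the configuration.
`vaf_density()` summarizes mutation-frequency structure per sample (kernel
density, Silverman bandwidth, peaks pruned by a valley-depth rule at 10% of
the maximum) after excluding variants inside copy-number events, whose BAFs
reflect copy state rather than clone size; fewer than 5 usable variants give
an undefined mode count.

## Progression analysis

Per-sample totals (`totals()`) sum the printed per-row Mb lengths by class
without merging overlaps — the convention that reproduces published
per-sample totals from this table layout exactly. Concordance
(`concordance()`) is the Mb-weighted fraction of query events covered by
same-class reference territory, which makes it invariant to row order and to
splitting a row into abutting halves. `classify_progression()` declares
`linear-consistent` only under perfect nesting (every earlier event matched
in every later stage, within `bp_tol`); otherwise it returns
`parallel-evidence` with the violating events listed.
`stage_acquisition()` orders events in molecular time by the first stage
carrying them and emits the cumulative Mb-per-stage table. For tabulated
event lists matching is exact (`bp_tol = 0`); for pipeline-derived events the
default tolerance is two window widths.

One documented discrepancy: in the bundled four-stage event table the printed
per-sample totals are reproduced exactly by row summation for all loss totals
and the first three gain totals, but the published metastasis gain total
(239.55 Mb) is not recoverable from the table's rows by summation (293.94 Mb)
or territorial union; the package reports row-sum totals and leaves the
difference documented rather than guessing the original overlap rule. Two
table rows also carry printed lengths inconsistent with their own coordinates
by more than the 0.011 Mb rounding allowance; `read_event_table()` warns on
them and keeps the printed values.

## The simulator

Because no raw sequencing data accompany the analysis this package
re-implements, a clone-tree simulator supplies ground truth
(`clone_tree()`, `simulate_counts()`, `simulate_snp_counts()`,
`simulate_snvs()`). Clones carry per-sample *cellular prevalences* (fraction
of tumor cells carrying the clone's genotype, cumulative over descent, child
≤ parent); purity is separate. Expected copy per window is
$2(1-p) + p(2 + \sum_e \mathrm{prev}_e \Delta_e)$; events are inherited by
all descendants, and overlapping same-haplotype events within a lineage are
rejected. Count noise is Poisson for window totals and binomial for allele
splits — the simplest model consistent with shot noise; overdispersion is
deliberately not modelled. Two parental haplotypes are tracked explicitly so
the direction of an LOH BAF split (toward 0 vs 1) is well defined. All
outputs are byte-reproducible for a fixed seed.

What the simulator emulates: purity compression, subclonal fractions, nested
multi-sample clone structure, graded gains, homozygous losses, germline-het
SNP allele counts consistent with every event, and somatic SNVs at
$VAF = pf/2$ in copy-neutral territory. What it does not: GC/mappability
waves, FFPE artifacts, replication timing, read-level errors, indels, or
overdispersed coverage. Passing tests therefore demonstrate correctness of
the inference chain under shot noise, not robustness to platform artifacts
on real data.

The bundled study conditions are fixed, not tuned: `demo_scenario()` builds
a four-stage nested progression (purities 0.75–0.85, matching the ≥ 75%
histology floor of the case it mimics; a truncal clone; a side branch private
to the second pre-invasive lesion; a founder clone subclonal at prevalence
0.3 in the primary and fixed in the metastasis, carrying the variants that
purify from BAF ≈ 0.11 to ≈ 0.40; 23 truncal, 1 second-lesion-private,
17 metastasis-private variants). `metastasis_scenario()` builds one sample
with a clonal loss background plus 17 subclonal losses at prevalence 0.5 —
the two-level loss picture left by a catastrophic burst in half the
population.

## Numerical choices and problem sizes

* Windows default to 100 kb on a 200 Mb five-chromosome miniature genome
  (2000 windows/sample) at 1000 reads/window; SNP sites default to 120×,
  variant tables to 377× (deep-resequencing scale). These sizes keep a full
  four-stage simulation-plus-analysis run around two seconds while leaving
  every effect several noise standard deviations wide.
* Ties in the two-means loss split resolve to the first minimal split in
  sorted order; a single loss event is Level 2 by definition.
* Degenerate inputs: empty coverage gives an empty track; chromosomes
  shorter than `2 * min_probes` windows form one segment; an all-aberrant
  genome leaves the baseline unchanged with a warning; an empty query set
  makes concordance `NA` rather than 0.
* The per-genome (not per-chromosome) median is used for centering, matching
  the "entire vector" convention of the source technique.

## Known limitations

* OCL assignment depends on sample ordering (gain territory must be seen in
  an earlier sample first).
* The BAF model assumes a single event per region per lineage; nested or
  allele-crossing rearrangements are out of scope, as is phasing.
* Gain-grade boundaries are conventions, not estimates; only the loss/gain
  class (never the grade) enters cross-sample matching.
* The two-level loss clustering assumes at most two coexisting loss levels;
  more finely structured subclonal mixtures would need a general mixture
  model.
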