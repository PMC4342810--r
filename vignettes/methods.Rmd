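---
title: "Methods: cross-laboratory concordance of segmented tumour profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-laboratory concordance of segmented tumour profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnconcord)
```

## Scope and data model

`cnconcord` quantifies how reproducible a molecular tumour-profiling assay
is when the same FFPE-derived samples are run in triplicate across three
laboratories. The unit of analysis is the *sample run*: one laboratory's
segmented copy-number/LOH profile of one sample, together with its QC
metrics (MAPD, ndSNPQC), its ploidy and aberrant-cell-fraction (ACF)
estimates, and its per-mutation scores. Three runs of one sample form a
*triplicate*. The package consumes the outputs of upstream segmentation
and calling software — it never re-estimates segments, ploidy, ACF, or
mutation scores, and the vendor-internal ndSNPQC metric is consumed as a
given value.

Coordinates are 0-based half-open internally, which makes interval lengths
and adjacency unambiguous; SEG files on disk use the 1-based inclusive IGV
dialect, and gene regions use 0-based half-open BED. Chromosome order is
whatever the genome build configuration states, never lexicographic, so
genome-wide concatenation is deterministic. The build is user-supplied
configuration: the statistics are coordinate-generic and work identically
on a scaled test genome and on full human chromosomes.

## The agreement statistic

Numeric copy number is first simplified to one of five categorical calls
(High Loss < 1, Loss in [1, 2), ND at 2, Gain in (2, 3], High Gain > 3).
Agreement always operates on these calls (or on the binary LOH flag), never
on raw numeric CN — two labs reporting CN 4 and CN 7 agree that the region
is a high gain.

Replicate segmentations rarely share breakpoints, so agreement is evaluated
on their *common refinement*: the union of all breakpoints cuts the genome
into atomic intervals on which every replicate's call is constant. The
denominator is the intersection of the covered spans — where any replicate
has no call, neither agreement nor disagreement can be asserted, so such
regions are excluded from numerator and denominator alike. Whether the
original probe backbone included centromeric or telomeric gaps is therefore
a property of the input profiles, not of the statistic. The genome-wide
percentage agreement is the length-weighted fraction of agreeing atomic
intervals, times 100. Sub-megabase events participate fully; smallness is a
display concern, not a statistical one.

Two properties make this definition robust, and both are enforced by
property-style tests: it is invariant under call-preserving refinement
(splitting a segment without changing its call changes nothing), and it is
symmetric under permutation of the replicates. Three-way agreement can
never exceed any pairwise agreement. The implementation (interval sweep via
`GenomicRanges::disjoin`) is checked for exact equality — in basepairs, not
within tolerance — against a brute-force oracle that evaluates the call at
every single base, on random genomes of a few kilobases where that oracle
is affordable.

Sex chromosomes are carried in profiles but excluded from agreement
denominators and genome baselines by default (`include_sex = FALSE`): a
hemizygous male X is CN 1 without being an aberration, and would otherwise
register as wall-to-wall loss against a diploid convention.

## Small-set concordance conventions

Ploidy, ACF and mutation-call concordance within a triplicate use the
largest-agreeing-group convention: 100 × (size of the largest group of
equal values) / 3, i.e. 33 / 66 / 100. Two conventions were genuinely open
and are fixed as follows:

* **Ploidy** uses a strict 0/66/100 scale: three mutually distinct ploidies
  score 0, not 33 — "no two labs agree" is reported as no concordance.
  Mutation calls keep the plain max-agreement scale.
* Two-thirds is reported as **66** (floor to integer), matching the
  conventional reporting scale; the exact fraction is retained in the
  returned object, and cohort means are taken over the integer-scale
  values.

ACF equality is not well defined for continuous estimates, so two ACF
values agree when both carry the label `"homogeneous"` or both are numeric
and differ by at most 1 percentage point (`acf_tol`, configurable). An
exact-match default would be brittle to rounding in upstream software.
Triplicates missing ploidy or ACF in any run are excluded from that
concordance mean only.

Because mutation-call quality tracks ndSNPQC, the ploidy/ACF/SM concordance
means (and all sensitivity analyses) are restricted to triplicates whose
three runs all have ndSNPQC ≥ 26 — the product in-bounds threshold, with
MAPD ≤ 0.3 as the companion bound, both inclusive and both configurable.
CN/LOH agreement is deliberately *not* QC-filtered: reproducibility across
laboratories is of interest regardless of basal sample quality.

## QC statistics

MAPD is the median of |L(i+1) − L(i)| over genome-adjacent probe pairs,
computed within chromosomes only (adjacency across a chromosome boundary is
meaningless). For i.i.d. Gaussian probe noise of sd σ the statistic
converges to σ·√2·qnorm(0.75) ≈ 0.954 σ, which the tests use as a
closed-form recovery target (2% tolerance at 100,000 probes). MAPD is
shift-invariant and scales linearly — it measures noise, not signal level.

Laboratory effects on a QC metric are tested with a one-way ANOVA across
labs; when significant at the 5% level a pairwise follow-up locates the
offending lab. The flavour of that follow-up was left open by the study
design, so it is configuration: Tukey's HSD at the 5% family level by
default (the standard post-hoc companion of a one-way ANOVA), with
unadjusted pairwise Welch t-tests available. The ANOVA is verified against
explicit sum-of-squares formulas to 1e−10 on random tables.

The variance decomposition contrasts the mean of within-sample (triplicate)
variances with the pooled variance over all runs, both with the n−1
denominator. When the global variance is an order of magnitude larger,
sample-intrinsic quality — not laboratory environment — dominates the
metric's spread.

For the focused question "does the flagged lab's pairwise agreement differ
from the rest?", the package uses a two-sample Welch t-test on pairwise
agreement percentages. If both groups are constant the test is degenerate;
the package then reports p = 1 for equal means with a warning flag rather
than failing.

## Mutation classification and sensitivity

Each SM carries two score thresholds defining three tiers: Undetected below
the lower threshold, Lower Confidence between, High Confidence at or above
the high threshold. A score exactly at a threshold takes the *higher* tier;
the boundary convention matters less than its documentation, and ≥ keeps
classification monotone in the score (a property the tests check over
random threshold/score sets).

Sensitivity against orthogonally pre-validated positives counts only
high-confidence calls as detections — lower-confidence calls are treated as
negative. This is deliberately stringent: any false positive in the
orthogonal pre-validation deflates the estimate rather than inflating it.
Panel-wide sensitivity is the mean over SMs weighted by each SM's number of
validated runs. The cross-laboratory SM concordance grand mean pools all
(triplicate × SM) cells rather than averaging per-SM means — the pooled
version weights SMs by available data — and the per-SM table is always
emitted alongside so either reading is available.

The shipped 74-SM panel (`inst/extdata/sm_panel_synthetic.tsv`) is a
representative hotspot list across the nine panel genes with placeholder
thresholds (lower 4, high 6 on the synthetic score scale); real assays
publish per-SM thresholds in their calling software, and users are expected
to override them, which is why the panel is a plain editable TSV.

## Clinical event scans

The genome **baseline** is the length-weighted median of segment CN over
autosomes. The choice among median CN, modal CN and reported ploidy was
open; the length-weighted median is robust to focal events and requires no
upstream estimate, and the reported-ploidy alternative is available by
passing `baseline =` explicitly. A **high focal amplification** is a gene
whose peak overlapping CN (any overlap ≥ 1 bp; amplifications are defined
by their peak) exceeds 2.2 × baseline, strictly — a ratio of exactly 2.2
is not flagged. **Copy-neutral LOH** is LOH at CN call ND; abutting
qualifying segments merge into maximal regions, and every base of a
reported region re-queries as (LOH ∧ ND). Co-occurrence reports
high-confidence mutations whose loci intersect a copy-neutral LOH region
(lower-confidence optionally). Recurrence is the rounded percentage of
samples with a given gene flagged, and `multiple_actionable()` flags
samples with ≥ 2 flagged genes from a user-supplied actionable list — such
lists are curated user data, not shipped.

## The synthetic generator: what it does and does not emulate

`simulate_cohort()` generates triplicates with known truth so the entire
pipeline is testable without any external data. Defaults are fixed once as
a realistic scaled-down study and are not tuning knobs:

* **Genome**: 3 chromosomes × 10 Mb. Agreement arithmetic is
  length-weighted and scale-free, so a scaled genome exercises the same
  code paths as 3.2 Gb while keeping the suite fast; sizes are
  configurable upward.
* **Probes**: 1 kb spacing, log2-ratio noise σ = 0.2, giving MAPD ≈ 0.19 —
  an in-bounds but realistically noisy FFPE run. Probe ratios follow the
  tumour-fraction-adjusted copy number log2((a·CN + (1−a)·2)/2) at ACF =
  100a%, floored at 0.1 so homozygous losses stay finite.
* **QC**: ndSNPQC drawn from N(32, 3) — mostly in-bounds with occasional
  dips below 26, as in real cohorts; MAPD assigned at its σ-implied value
  plus small jitter.
* **Truth profiles**: baseline at the sample's ploidy plus 4 random events
  per sample (gains, losses, LOH, and with probability 0.25 copy-neutral
  LOH), placed on a slot grid so events never overlap.
* **Scores**: positives at mean 9, negatives at mean 1, sd 0.8 against
  thresholds 4/6 — ≥ 95% of positives classify high-confidence, and moving
  the positive mean between the thresholds reproduces the
  low-tumour-fraction failure mode in which real positives surface only as
  lower-confidence calls.

Replicate 1 always equals the truth, so discordance is attributable. In
*deterministic mode* (`discordant_fraction` given) the third replicate's
CN call is altered over exactly the designed fraction of the covered span
— realized agreement equals 100(1 − f) exactly, which the acceptance tests
exploit. In *stochastic mode* replicates 2 and 3 independently drop each
truth event with probability `drop_prob` (expected discordance over an
event's span is 1 − (1 − p)², an analytic target the tests recover),
jitter each breakpoint by N(0, jitter_sd), and flip the reported ploidy
with probability `flip_prob`. A single seed drives each
`simulate_cohort()` call; identical seeds give byte-identical cohorts.

What the generator does **not** emulate: BAF tracks and allele-specific
evidence, array intensity artefacts, FFPE degradation chemistry, wave
artefacts or GC bias in probe noise (noise is i.i.d. Gaussian), segmenter
behaviour (truth segments are given, not re-estimated), or the joint
ploidy/ACF estimator. Passing tests therefore demonstrate the correctness
of the *statistics* on well-formed segmented inputs, not the performance
of any upstream caller on real arrays.

## Numerical choices and degenerate inputs

* The diploid call uses |CN − 2| ≤ ε with ε = 1e−6: upstream CN is
  effectively integer but arrives as floating point, and 2.0000000001 must
  not register as a gain.
* Reported percentages are kept at full precision internally; display
  rounding is nearest-integer for sensitivity/recurrence and floor for the
  2/3-type concordances (66, not 67).
* Empty common covered span, a cohort with zero QC-passing triplicates, a
  lab with fewer than two observations, a sample with a single run, an
  empty call list, and a zero baseline all raise errors naming the
  offending object rather than returning NaN.
* Overlapping segments, segments beyond the chromosome end, and unknown
  chromosomes are rejected at profile construction, so every downstream
  operation can assume sorted disjoint in-bounds segments.

## Problem sizes used by the test suite

The suite builds everything it needs in code: per-base oracle comparisons
run on 20 random trios over 6–10 kb genomes (exhaustive evaluation at
every base); MAPD recovery uses 100,000 probes; ANOVA oracle comparisons
use 50 random small tables; stochastic-recovery checks average 40 seeded
one-sample cohorts on the default 30 Mb genome. These sizes were chosen so
the full suite completes in a few minutes while leaving each statistical
check comfortably powered.

## Known limitations

* Agreement is binary per interval (all replicates agree or not); no
  partial credit for two-of-three CN agreement is computed on the genome
  sweep, matching the study convention.
* The ACF tolerance (±1 point) and the Tukey default for the pairwise
  follow-up are conventions, not estimates; both are exposed as
  configuration precisely because the underlying study designs leave them
  open.
* Median and mean cohort summaries can differ noticeably in small or
  skewed cohorts; both are always reported, and interpretation is left to
  the user.
* The shipped panel thresholds are placeholders on a synthetic score
  scale; sensitivity numbers on real data are only meaningful with
  calibrated per-SM thresholds.
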