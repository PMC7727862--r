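---
title: "Screening small-RNA expression for treatment-resistance biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening small-RNA expression for treatment-resistance biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirres)
```

## The problem

Many oesophageal adenocarcinoma (OAC) patients receive neoadjuvant
chemoradiotherapy but do not respond to it, and no circulating biomarker
exists to predict who will. One route to such biomarkers is to measure the
*intrinsic* resistance of a panel of OAC cell lines to each treatment
component — radiation, cisplatin, 5-FU — and ask which microRNAs track that
resistance axis, then check whether the same miRNAs separate responders
from non-responders in patient serum small extracellular vesicles (small
EVs). `mirres` implements that entire analytic chain as composable,
tested functions, together with synthetic-data generators that plant known
truth so every stage can be validated end to end without any external
download.

## The resistance axis: survival fractions

The pipeline's outcome variable is the survival fraction (SF). For
clonogenic assays, plating efficiency is PE = colonies/cells seeded, and
SF = mean PE(treated) / mean PE(mock), pooled technical-replicates-first:
wells are averaged into one PE per independent experiment, one SF is
formed per experiment, and a cell line's profile is the mean ± SD over
experiments. That pooling order matches how "three independent experiments
with three technical replicates" designs are conventionally summarised.
For flow-cytometry apoptosis assays, viable, early- and late-apoptotic
percentages are renormalised to 100% (necrotic events and debris are
excluded, so the SF is invariant to the necrotic fraction) and
SF = treated viable % / mean vehicle viable %.

A profile with replicate CV above `cv_flag_threshold` (default 0.3) is
flagged inconsistent but never dropped: excluding a variable cell line is
an analyst's decision, and the flag exists to surface candidates for it.
No quantitative exclusion rule is asserted because none is standard.

## From Ct values to normalized expression

OpenArray-style qPCR reports a cycle threshold Ct per miRNA per sample;
relative level is `2^(max_cycles − Ct)` (default ceiling 40 cycles), so
level 1 means "at the detection floor" and each cycle earlier doubles the
level. Undetected assays (`NA`) are floored to level 1 for detectability
accounting and excluded pairwise from correlations.

Normalization divides each sample by the geometric mean of selected
housekeeping miRNAs (HKGs). HKG selection applies four criteria:

1. detected in all samples at high level (median Ct < 30);
2. no difference between sample groups (two-sided Mann–Whitney U,
   p > 0.1), skipped with a warning when no two-group partition is given;
3. not highly variable — the SD of the candidate's log2 levels must be
   below twice the SD of that statistic across all candidates — and no
   sample outside 5-fold of the candidate's mean level;
4. Pearson r > 0.7 between the candidate's log2 level and the
   geometric-mean reference of the current candidate set, iterated to a
   fixed point by backward elimination: the worst-correlated candidate is
   removed, the reference recomputed, until all survivors pass.

Two numerical choices deserve comment. Variability in criterion 3 is
measured in the log domain because qPCR error is additive on the cycle
scale; the linear-scale CV of lognormal data is bounded above by
`sqrt(n)` and so saturates for highly variable assays, which destroys the
contrast the criterion needs. In criterion 4, one-at-a-time elimination
is used rather than dropping every sub-threshold candidate per round: a
single mass drop can discard the entire stable core in datasets where
sample-loading variation happens to be weak, whereas backward elimination
lets the reference purify progressively. A zero-variance candidate has an
undefined correlation with any reference; it is treated as passing
criterion 4, since a perfectly constant assay is the ideal housekeeper.
The candidate set shrinks monotonically, so the fixed point is reached in
fewer rounds than there are candidates; the selection is invariant to the
order of the input rows.

Criterion 4 only works at all because real qPCR samples share a loading
component (input RNA amount, global efficiency): true housekeepers
correlate with the geometric-mean reference *through* that shared
component, and dividing by the HKG geometric mean is precisely what
removes it.

## Associating miRNAs with resistance

For each treatment the two cell lines with the highest mean SF form the
resistant pair and the two with the lowest the sensitive pair (both
overridable). The screen has two stages:

- **Extremes t-test** — two-sided Welch t-test on log2 normalized levels
  between the pairs (pooled-variance available via `var.equal = TRUE`);
  fold change is reported on the linear scale as the ratio of group
  means. Degenerate inputs (both groups constant and equal) give p = 1.
- **Consistency screen** — Spearman correlation between each miRNA's
  log2 level and the SF across *all* lines, so a hit must track the full
  resistance gradient, not just the extremes. With n ≤ 9 tie-free pairs
  the two-sided p-value is exact by full enumeration of rank
  permutations; above that the t approximation is used. Being
  rank-based, the screen is invariant under monotone transforms of
  either axis.

False-discovery rates for the Spearman-significant set (p ≤ 0.05) are
estimated with the Storey method at fixed λ = 0.5,
`pi0 = min(1, #{p > λ} / (m(1−λ)))`, after pre-filtering to miRNAs with
fold change beyond 1.5-fold in either direction; the pre-filter restricts
estimation only, never the reported table. With only ~100 p-values a
λ-grid smoother is unstable, hence the single-λ default. Both the
set-level FDR `pi0·m·α/|S|` and monotonized per-miRNA q-values are
emitted.

A miRNA is **unique** to treatment T when its Spearman p < 0.05 for T
and, for each other treatment, either both Spearman and t-test p are
≥ 0.1 or the direction of change is opposite. Opposite directions can
let two treatments qualify simultaneously; the call goes to the smaller
Spearman p. Two or more treatments significant with concordant direction
give a **shared** call. A miRNA significant for a single treatment that
fails the independence conditions (e.g. another agent at p = 0.07) is
neither unique nor shared and is called `none` with its evidence
retained — the rule is deliberately conservative about claiming
treatment specificity.

An advisory leave-one-out diagnostic reports, per cell line, the change
in the median |rho| across miRNAs when that line is removed; a line whose
removal raises it by more than 0.1 is flagged as a candidate outlier.
Nothing is excluded automatically.

## Serum small-EV counts

Sequencing counts of serum small-EV miRNAs are normalized with the
trimmed mean of M-values (TMM): reference sample by upper-quartile
closeness, 30%/5% two-sided trims on M and A, inverse-variance weights,
factors rescaled to geometric mean 1. The implementation follows the
canonical published algorithm and is tested to 1e-9 agreement against
edgeR's `calcNormFactors` on random matrices; edgeR serves only as an
independent cross-check, never as the implementation. Note the weighted
estimator is exactly scale-invariant only without precision weights —
the weights depend on absolute counts — so invariance is exact for
`do_weighting = FALSE` and asymptotic otherwise.

Because TMM is undefined on all-zero rows and noisy on near-zero ones, a
default abundance filter (count ≥ 5 in ≥ 25% of samples) is applied
first; it can be disabled. Expression is then TMM-adjusted counts per
million, and differential expression between response classes uses the
two-sided Mann–Whitney U test (exact for small tie-free groups, normal
approximation with tie correction otherwise). Raw p-values are the
screening quantity, matching common practice for small panels;
Benjamini–Hochberg q-values are attached for information only. The
response dichotomization from Mandard tumour-regression grades is left
configurable (good = TRG1–2 is a common but not universal cut).

Cell-line hits with resistance p < 0.1 are cross-referenced against the
serum table: the tier (`strict` cell p < 0.05, `relaxed` otherwise)
records the strength of the cell-line evidence, a serum hit requires
serum p < 0.05, and a suggestive flag marks p < 0.1. Direction
concordance between cell-line and serum effects is annotated but never
filtered on — vesicle export can legitimately invert the sign of an
association (selective retention in resistant cells).

## Small-RNA → mRNA interaction screening

After a perturbation experiment (e.g. 3 control vs 3 inhibitor samples),
candidate regulatory pairs are all (small RNA, mRNA) combinations with
correlation r < −0.5 on log2 expression (Pearson default; Spearman
available, though with n = 6 its rank granularity makes it coarse). With
so few samples this threshold is a filter, not a test, so no p-values
are attached. Candidates are then required to appear in at least three
of a catalogue of local target-database tables (flat TSVs, one per
source); piRNA targets come from a precomputed seed-match table that is
only joined, never predicted de novo.

Gene-set enrichment of the consensus targets uses a hypergeometric
upper-tail score per pathway and an empirical p-value from label
permutations: `n_perm` random query sets of the same size are drawn from
the universe and `empirical_p = (1 + #{score ≤ observed}) / (n_perm + 1)`,
making `1/(n_perm+1)` the attainable floor (default 5000 permutations).
The empirical p converges to the exact hypergeometric tail as the
permutation count grows; the test suite checks agreement within three
Monte-Carlo SDs at 50,000 permutations. Identical seeds give identical
results.

## What the synthetic generators emulate

The default scenario mirrors the study design the pipeline targets:

- **Survival profiles** — 8 cell lines × 3 treatments; per-line mean SFs
  evenly spread over 0.2–0.9 (the span reported for radiation across an
  OAC panel) in an independently shuffled order per treatment, 3
  replicates with SD 0.05, optionally one wildly variable line.
- **Ct matrix** — 112-miRNA panel: 10 planted housekeepers (Ct 25,
  residual noise 0.15 cycles), 12 planted resistance miRNAs per
  treatment whose Ct decreases linearly with SF at 6 cycles per unit SF
  (expression up in resistant lines, assay noise 0.5 cycles), 5 miRNAs
  undetected everywhere, and background miRNAs with 2 cycles of
  biological spread. All rows share a per-sample loading offset of 0.5
  cycles.
- **Serum counts** — 187 miRNAs × 39 patients (20 good vs 19 poor
  responders), negative-binomial with dispersion 0.3, lognormal library
  sizes spanning ~3-fold, 15 planted miRNAs shifted by 2 log2 units
  with alternating sign.
- **Paired expression** — 100 small RNAs × 500 mRNAs over 3 + 3
  samples; 10 planted anti-correlated pairs at target r = −0.9, each
  with its own response profile so pairs are strongly but not perfectly
  collinear; five synthetic database tables giving the first half of the
  planted pairs consensus support ≥ 3 and the second half ≤ 2; a gene-set
  collection in which one pathway is exactly the planted target mRNAs.

Two calibration choices matter for interpretation. First, the loading
offset pattern is standardized to exactly its stated SD and made
orthogonal to the three SF axes, and each background miRNA's residual
spread is standardized to exactly 2 cycles. Without this, individual
realizations can produce a "variable" miRNA that is genuinely
housekeeper-like in the emitted matrix (or a loading pattern confounded
with resistance), in which case the planted labels would be false of the
data itself and no selector could recover them — the generators are
meant to plant truth, not merely expected truth. Second, the effect size
of 6 cycles per unit SF makes the extremes pairs differ by roughly
4 cycles (≈16-fold) for planted miRNAs — strong biomarkers by design, so
that recovery failures indicate implementation defects rather than power
limits.

What the generators do *not* emulate: plate/batch structure, probe
cross-hybridisation, amplification-efficiency differences between
assays, count overdispersion heterogeneity across miRNAs, library
composition bias beyond what TMM models, and any real biological
co-regulation among background features. Passing the planted-truth tests
therefore demonstrates correctness of the computations, not expected
performance on real data, where effects are weaker and the confounders
above exist.

## Problem sizes and reproducibility

All randomized checks run at desk scale: planted-truth recovery uses
three seeded replicates of the default scenario, Storey calibration uses
50 simulations of 1000 p-values, TMM oracle equivalence 50 random
matrices, and the enrichment-vs-hypergeometric comparison 50,000
permutations on a 1000-gene universe — sizes chosen so the whole
validation suite completes in well under a minute while leaving the
Monte-Carlo error far below the tolerances tested. Every random
operation takes an explicit seed, and `run_pipeline()` writes a manifest
recording parameters, seeds and input checksums; reruns with identical
configuration reproduce every output byte for byte.

## Known limitations

- The housekeeping criteria assume a shared loading component; on data
  where samples were already perfectly equalised, criterion 4 loses its
  meaning and the selection degenerates (by design it then errors rather
  than returning an arbitrary set).
- With two-line extreme groups the t-test has 2 + 2 samples; it is a
  screening statistic, not a confirmatory one, and the Spearman stage is
  the real gatekeeper.
- The uniqueness rule's independence thresholds (0.1) are inherited
  conventions; near-threshold evidence produces `none` calls that a
  manual reviewer might adjudicate differently.
- Database-consensus filtering is only as good as the local tables
  supplied; shipped fixtures are synthetic and carry no biological
  content.
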