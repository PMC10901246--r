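---
title: "Methods: an integrative transcription-factor screen for mTEC gene programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrative transcription-factor screen for mTEC gene programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtecscreen)
```

## The screening model

Medullary thymic epithelial cells express tissue-restricted antigens in small,
recurring co-expression groups. The screen implemented here asks which
transcription factors drive such a group, by requiring four independent lines
of evidence to coincide for a candidate TF:

1. **Target expression** — at least one gene whose promoter carries an
   occupied motif of the TF is differentially expressed between the subsets
   being compared (e.g. Tspan8-positive vs Tspan8-negative mTECs).
2. **Motif enrichment** — promoters of the target gene set are enriched for
   the TF's binding motif, measured by total binding affinity (TBA) and
   recovery-curve AUC.
3. **Footprint occupancy** — ATAC insertion profiles show a localized
   depletion at the motif inside otherwise open promoter chromatin, and this
   differential footprint concentrates in the target promoters.
4. **TF expression** — the TF itself is detectably expressed in the subset.

Each criterion alone is weak (motif enrichment has many false positives; a
footprint shows *something* is bound, not *which* factor; expression is
correlative); their conjunction is the screen. The final table ranks TFs that
pass all four flags by differential-footprint AUC, then TBA z-score, followed
by the non-passing remainder in the same order, so the output is a complete,
deterministic permutation of the panel.

### Total binding affinity

A promoter is the −2000..+1000 bp window around the TSS, read 5'→3' in the
gene's direction; minus-strand genes use the reverse complement of the
mirrored genomic window. For a PWM of width $W$ with column probabilities
$p_j(b)$ and a 0-order background $q(b)$,

$$\mathrm{TBA}(s) = \sum_{i} \max\bigl(LR(s_{i..i+W-1}),\; LR(\mathrm{rc}(s_{i..i+W-1}))\bigr),
\qquad LR(w) = \prod_{j=1}^{W} \frac{p_j(w_j)}{q(w_j)}.$$

Summation is on the linear likelihood-ratio scale — "total affinity" semantics
in which one strong site dominates many weak ones; a log-scale sum is exposed
as an option (`log_scale = TRUE`) for sensitivity analysis, not as the default
statistic. The per-window maximum over the two strands makes TBA exactly
invariant under reverse complementation of the promoter, which the test suite
asserts. No PWM-length normalization is applied: scores are only ever compared
*across genes within one PWM* (by ranking), never across PWMs, so a
width-dependent scale is harmless; cross-PWM calibration happens later at the
AUC stage.

Numerical choices: windows containing `N` contribute 0 (conservative and
testable); PWM counts receive a pseudocount of 0.01 per cell before
normalization so no window has strictly zero affinity; the background is
uniform by default and can be set from promoter composition
(`base_background()`). The scanner itself is compiled (Rcpp) and is verified
against a brute-force pure-R scanner that enumerates substrings and their
reverse complements — two independent code paths agreeing to ~1e-15 relative.

### Recovery curves and panel z-scores

Genes are ranked by decreasing TBA (ties broken by gene id, so results are
reproducible under row permutations); `recovered(x)` is the fraction of the
target set found at rank ≤ x; the AUC averages the curve over the first 1000
ranks. Dividing by the depth makes a perfect instantaneous recovery tend
toward 1 regardless of target-set size. Targets absent from the ranked
universe are dropped first; a depth exceeding the universe is clipped with a
warning (synthetic universes are often smaller than 1000). AUCs are converted
to z-scores with the panel mean and *population* standard deviation, so the
panel itself is the null calibration: the tests assert mean 0 and sd 1 to
1e-9, and an all-equal panel yields all-zero z with an explicit degenerate
flag rather than a division by zero.

### Footprint scoring

Each ATAC fragment $[s, e)$ contributes Tn5 insertions at $s+4$ and $e-5$
(the standard transposase offsets; the data this emulates do not state
theirs). A site's score contrasts depth-normalized insertion density in 50 bp
flanks with the motif center:

$$\mathrm{FP} = \log_2 \frac{\overline{\text{flank}} + 1}{\overline{\text{center}} + 1}$$

on insertions-per-million. A uniform profile scores exactly 0; occupancy
scores positive; the pseudocount keeps scores finite and compresses toward 0
at low depth without changing the ranking. Replicates of a condition are
pooled into one profile before scoring — footprinting needs cumulative cut
density, not per-replicate variance. The differential footprint between two
subsets is the per-site score difference; per promoter, the maximum delta
over that PWM's sites (a single occupied site suffices as evidence; mean
aggregation is an option). Sites are motif matches with likelihood ratio
≥ 10 — a deliberately permissive threshold, configurable in
`screen_thresholds()`. Promoters ranked by delta feed the same recovery-AUC
machinery against the TRA promoters.

The "footprint occupied" flag compares the observed AUC against the exact
expectation of the permutation null, $(\mathrm{depth}+1)/(2n)$ for an
$n$-promoter universe — the analytic mean of the AUC under a random ranking —
rather than a Monte-Carlo permutation estimate of the same number; the
permutation route exists in the test suite and agrees within Monte-Carlo
error.

The exact footprint statistic used in the study this emulates is inherited
from external footprinting tools and is not published as a formula; the
flank/center log-ratio here is this package's own documented stand-in, chosen
for testability (closed-form behavior on uniform and depleted profiles), not
claimed to be numerically identical.

### Differential accessibility

A self-contained count-based substitute stands in for a full count-model
engine: per region, `log2FC` of library-normalized counts (pseudocount 1 per
normalized count) and a two-sided exact binomial test of the condition-A
count against the library-ratio expectation, BH-corrected. The screen
consumes ranks and fold changes, not shrinkage estimates, which is why a
transparent test suffices. Calibration is tested on a simulated null (2000
regions): the BH q < 0.05 fraction stays ≤ 5% and the p-values are
KS-uniform. The calibration run uses ~1000 counts per region; at much lower
counts the exact test's discreteness makes p-values visibly conservative —
a known property, not an error.

### ChIP peak assignment

Per-peak fold enrichment uses library-normalized IP and input counts with a
pseudocount of 1. A peak belongs to a gene when any part of it overlaps the
±5 kb window around the TSS (the inclusive reading of "within ±5000 bp";
summit-containment is exposed as `mode = "summit"` since the source
convention is unstated); per gene, maxFC is the maximum enrichment over
assigned peaks. Peak *calling* is out of scope — peaks arrive from outside
(or from the simulator's truth); this is stated rather than re-implemented.
`target_overlap()` reports set sizes, intersection, and mutual percentages to
one decimal.

### Diversity and knockout effects

Shannon (natural log; base 2 optional) and inverse Simpson indices are
computed per sample over within-category proportions (all / TRA / non-TRA),
then compared between groups by the difference of per-sample means with a
label-permutation p-value (1000 permutations, seedable). Computing per sample
first preserves replicate structure; the merging ("coarsening") property —
pooling two genes never increases either index — is asserted by enumeration.
Knockout effects reduce to printed arithmetic: fold change `ctrl/ko` to one
decimal, percent reduction to the nearest integer. On the Tuft-mTEC counts
(1861 vs 527 cells) this yields fold change 3.5 and a 72% reduction — the
nearest-integer value of 71.68; the 39% reduction and fold change 1.6 for
Aire-positive mTECs (22110 vs 13504) reproduce exactly.

## What the generator emulates — and what it does not

`simulate_*` produces the statistical structure the screen assumes, with
ground truth for recovery testing:

* **Geometry.** One synthetic contig; one promoter (3 kb = 2 kb upstream +
  1 kb downstream of the TSS) per gene, laid end-to-end with 1 kb spacers.
  All genes are plus-strand by default; `mixed_strands = TRUE` exercises
  strand-aware extraction (`sim_genome()` assembles the contig so that
  `extract_promoters()` round-trips the simulated sequences exactly).
* **Sequence.** Background bases i.i.d. (uniform by default, configurable
  composition). For every TRA gene and planted TF, with probability
  `p_plant = 0.9` one site is drawn column-wise from the PWM and inserted at
  a uniform, non-overlapping offset on a fair-coin strand. The TRA list is
  the first `n_tra` gene ids — TRA annotation is an *input* in this field,
  not a computation — and doubles as the true-DE set.
* **Motifs.** `simulate_pwms()` draws panel motifs of width 9–12 with a
  dominant base probability of 0.9 per position (~1.5 bits/position), the
  information content typical of curated PWM collections. Weaker motifs
  (e.g. 0.85) produce planted sites whose likelihood ratio sits below the
  promoter-wide TBA background noise, i.e. a generator that fails to emulate
  detectably planted motifs.
* **ATAC.** Tn5 insertions are an inhomogeneous Poisson field:
  `lambda_open = 0.5`/bp across *all* gene promoters (the universe is
  expressed genes, whose chromatin is open in both subsets; criterion I is
  about expression, not differential openness), `lambda_bg = 0.02`/bp in
  spacers, and a factor `1 − d` over sites bound in that condition
  (`footprint_depth` d = 0.5 by default — the emulated study does not state
  its effect size — with d = 0.6 used by the detection check). Keeping
  openness uniform across the universe matters: if only target promoters
  were open, the max-aggregated footprint delta would be noisier in open
  than in closed promoters and *every* PWM's differential AUC would inflate,
  drowning the planted signal. Fragments pair an anchor cut drawn at rate
  λ/2 with a partner cut at Uniform(30, 150) bp, thinned against the local
  field, so the +4/−5 convention recovers the simulated insertion positions
  exactly, total insertions equal twice the fragment count, and full
  depletion (d = 1) yields exactly zero insertions over bound positions.
* **Expression.** Counts are negative binomial (`nb_mean = 100`, dispersion
  0.1; dispersion 0 gives the Poisson limit); TRA genes and active TFs gain
  `de_lfc = 2` log2 units in the Tspan8-positive conditions. Three
  replicates per condition by default — with two, the pooled per-site
  footprint signal (Poisson z ≈ 1.3) is too weak for reliable
  single-TF recovery, while three give a robust margin.
* **ChIP.** Input fragments are uniform at `lambda_bg`; IP rates are
  multiplied by `chip_enrich = 8` over bound-site ± 500 bp zones
  (`chip_halo`), which double as the truth peak set. The halo matters:
  enrichment confined to a 10 bp motif cannot be recovered by
  fragment-overlap counting at any depth, because ~100 bp fragments dilute
  it geometrically.

Not emulated: read-level sequences (no FASTQ, aligner, or sequencing-error
model), Tn5 sequence bias, nucleosome fragment-length structure, peak
calling, mitochondrial contamination, batch effects, and the mosaic 1–5%
single-cell expression heterogeneity that bulk subsets average over. Passing
tests therefore demonstrate that the *statistics* behave as designed on data
with the assumed structure — not that the screen is robust to every artifact
of real ATAC/ChIP libraries.

## Problem sizes and determinism

Every simulation consumes an explicit integer seed through the config;
identical config and seed give byte-identical FASTA/BED/TSV outputs
(asserted in the tests). The heavier properties run at sizes chosen to keep
the full suite comfortably interactive: planted-TF recovery uses 2000 genes ×
200 targets × 10 seeds; screen specificity uses 500 genes × 50 seeds with
zero active TFs, no depletion and no expression shift; the null calibration
of differential accessibility uses 2000 regions from a 1000-gene null
simulation; ChIP recovery uses 300 genes × 10 seeds. `scripts/acceptance.R`
recomputes the headline quantities from scratch at these scales from a
single `--seed`.

## Known limitations

* The footprint statistic and the binomial accessibility test are documented
  stand-ins for external tooling whose formulas are not public; rank-level
  behavior, not numerical identity, is the design goal.
* TBA has no match-level p-value calibration; the across-panel z-score is the
  only calibration, so absolute z thresholds (default 1) are panel-relative.
* The combined ranking (footprint AUC, then TBA z) is one defensible
  composite among several; it is recorded in the run config and trivially
  reordered from the tidy output.
* With a gene pitch of 4 kb and a ±5 kb assignment window, a ChIP peak is
  legitimately within the window of its neighbor genes; on real genomes with
  larger intergenic distances this multiplicity is rarer. The contiguous TRA
  block keeps this from distorting recovery statistics in the tests.
* Expression "TPM" equals CPM in the synthetic data because all genes share
  one effective length; with real quantifications, supply TPMs and the
  thresholds keep their meaning.
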