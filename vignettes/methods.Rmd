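---
title: "Models and methods behind ssrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ssrscape connects four analyses around a draft plant genome: the
microsatellite (SSR) landscape, SSR allele diversity between two source
populations (Restinga, RE; Riparian Forest, RF), negative-binomial
differential expression under drought, and transcriptogram profiling
over a protein-association gene ordering. This vignette explains each
model, the parameters that matter, the numerical choices, and what the
synthetic-data validation does and does not establish.

## SSR detection and canonical classes

`detect_ssrs()` reports every maximal perfect tandem run of a primitive
motif of length 1–6 meeting a per-length minimum repeat count. The
scanner works per period k: positions where the sequence equals itself
shifted by k delimit maximal k-periodic stretches; a stretch of length L
contributes floor(L/k) whole units anchored at its left end. A motif
that is a whole-number power of a shorter string is never reported
(assignment to the shortest primitive motif follows from Fine–Wilf's
periodicity bound, since every reported run spans at least two motif
copies). An N terminates any run. Two or more SSRs separated by at most
`compound_max_interruption_bp` (100 bp) are additionally reported as one
compound record; compound members are flagged so summaries never count
them twice.

Minimum repeat counts default to the common MISA convention — 10 for
mononucleotides and 6/5/5/5/5 for di- through hexanucleotides — and are
fully configurable (`ssr_min_repeats`). Landscape summaries exclude
simple monomeric repeats from tallies and totals by default, so the
per-length counts plus the compound count add up to the reported total;
a compound record containing a monomer member still counts as one
compound.

`canonical_class()` collapses strand and phase: the class of a motif is
"X/Y" where X is the lexicographic minimum over all rotations of the
motif and of its reverse complement, and Y is the minimal rotation of
reverse-complement(X). Dinucleotides form exactly four classes (AC/GT,
AG/CT, AT/AT, CG/CG) and trinucleotides ten; the composition bias test
(`chi2_class_bias()`) is a one-df goodness-of-fit chi-square, without
continuity correction, of each class's (transcribed, untranscribed)
split against its motif-length division's overall split, restricted to
classes above a 0.5% representation floor within the division and
flagged at 0.01 confidence.

Loci merge by single linkage over same-sequence (identical motif
string — not merely same class) records with gaps of at most
`merge_window_bp` (100 bp); "transcribed" means a non-empty half-open
intersection with at least one transcript interval. Coordinates are
0-based half-open internally and 1-based inclusive in every serialized
GFF3.

## Population diversity classes

Alleles are repeat counts observed at a locus; population comparison is
presence-based (set-valued), not frequency-based, because the inputs are
per-sample presence/allele calls rather than genotype frequencies. A
locus is `exclusive` to the only population holding alleles, `equal`
when both allele sets are identical, and `preferential` toward the
population with strictly more distinct alleles. Differing sets of equal
cardinality cannot be attributed to either side — each must hold at
least one private allele — so such loci are surfaced in a separate
`ambiguous` bin rather than silently forced into a class. The
exclusivity test is a one-df chi-square against an expected 50:50 split,
reflecting no prior asymmetry between populations.

## Negative-binomial testing

Counts are modeled as NB(mu, alpha) with variance mu + alpha mu²;
alpha = 0 degenerates to Poisson. Normalization uses median-of-ratios
size factors and enters the likelihood as per-sample offsets (expected
count mu·s_j), which keeps the integer likelihood valid — counts are
never pre-divided.

The two-group test (`nb_lrt_two_group()`) compares a pooled-mean null
against group-specific means and refers 2(l_alt − l_null), floored at
zero, to the chi-square upper tail with df = 1 (shared dispersion; the
default) or df = 2 (separate dispersions). Two numerical decisions
matter:

* **Profile optimization.** For fixed alpha the mean MLE is closed-form
  (sum of counts over sum of offsets) when offsets are constant, and a
  Newton iteration on the score otherwise; alpha is found by bounded
  search over log(alpha) in [log 1e-8, log 1e3], compared against the
  Poisson boundary, with tolerance 1e-6 on log(alpha). All-zero counts
  give mu = 0 with a defined log-likelihood of 0.
* **Where the shared dispersion is estimated.** It is estimated once,
  from the pooled (null) fit, maximizing the Cox–Reid adjusted profile
  likelihood (penalty −½ log of the summed GLM working weights), and
  reused for the alternative's group means. Re-estimating the dispersion
  under the alternative is markedly anti-conservative at RNA-seq sample
  sizes (measured null rejection 0.075 at nominal 0.05 with 6 samples
  per group), and the unadjusted dispersion MLE is biased downward;
  with the pooled Cox–Reid estimate the null rejection rate and the
  95th percentile of the statistic track chi-square(1) closely at 6–9
  samples per group. The cost is conservatism at very small n: with 3
  replicates per group the realized level is about 0.02 and power for a
  2-fold change about 0.4, which the tests assert as such. No
  information is shared across genes (no dispersion shrinkage), by
  design.

DEGs are called at |FC| ≥ 1.5 and raw p < 0.05 (`fc_threshold`,
`p_deg`), with the fold change computed on normalized means with a 0.5
pseudo-count on both sides, interpreted symmetrically (FC ≥ 1.5 or
FC ≤ 1/1.5). The p threshold is applied raw because that is how the
DEG definition is stated; BH q-values are always reported alongside.
Venn partitioning keeps genes regulated in opposite directions across
populations in a dedicated `discordant` bin rather than counting them
as shared.

The SSR–expression link applies the same LRT between SSR-present and
SSR-absent sample groups (both of size ≥ 2; smaller groups are reported
untestable with a reason) for each gene–locus pair within 2 kbp
(`link_window_bp`, boundary inclusive, measured from the gene span with
overlap counting as `within`), with BH adjustment across exactly the
testable set. Term overrepresentation is a one-sided hypergeometric
test with BH and log2 fold-enrichment.

## Transcriptogram

Edges with combined score strictly above `score_threshold` (800) define
the gene universe; isolated genes are excluded. The ordering minimizes
the total edge positional distance Σ|pos(u) − pos(v)| by simulated
annealing: pairwise position swaps, initial temperature cost/N,
geometric cooling with ratio 0.995, and termination after `n_iterations`
sweeps (N proposals each) without improving the best arrangement, which
is the one returned — so the final cost never exceeds the identity
ordering's, and a fixed seed reproduces the ordering exactly (the C++
kernel draws from R's RNG). On two disjoint cliques the annealer reaches
the analytic contiguous-block minimum, and on 5×40-gene block models the
mean same-block positional distance is about a fifth of a random
permutation's.

Projection assigns position i the arithmetic mean over positions
max(0, i−r)..min(N−1, i+r); interior windows at the default radius 30
cover exactly 61 genes, and edge windows truncate (no wrap-around — the
ordering implies no circularity). Projection input is size-factor
normalized counts, log2(x+1)-transformed, because window averaging
behaves additively on the log scale; relative profiles (drought over
control with a 0.5 pseudo-count, banded by ±1 SD of per-replicate
ratios) stay on the untransformed normalized scale to match
fold-change presentation. Per-position tests are Welch t-tests on the
per-replicate windowed means (radius 0 uses the unsmoothed values);
peaks are maximal runs of positions with p below the threshold, with no
multiple-testing correction across positions (the 0.01/0.05 thresholds
are used raw, as in the peak definition; BH remains available). The
combined candidate rule intersects R30 p < 0.01, R0 p < 0.05 and
per-gene DE p < 0.05.

## What the synthetic data emulate — and what they do not

The generator reproduces the study's structure at desk scale: a
multi-chromosome genome with planted SSRs of known motif, length and
position (background i.i.d. uniform A/C/G/T; each plant's flanking base
is forced to break the period so planted coordinates are recovered
exactly; chance background repeats are allowed and handled by
truth-aware evaluation); the 12-library 2-population × 2-condition ×
3-replicate NB count design with log-normal baselines (log-mean
log 100, sd 1), log-normal dispersions (log-mean log 0.1, sd 0.5),
log-normal library size factors (sd 0.15), 10% planted DE genes with
fold changes from {1.5, 2, 3, 4}, and 2-fold SSR-linked presence
effects planted through one locus per gene; per-sample presence/allele
tables with regimes constructed to yield exclusive, equal and
preferential loci; and a 5-block × 40-gene stochastic block model with
intra-block scores above the 800 filter and inter-block scores
straddling it.

These choices make three-replicate power realistic rather than
matching any real data's moments. The generator omits GC skew,
repeat-family structure, imperfect/interrupted SSRs, splicing,
read-level error, and gene-wise dispersion–mean trends; passing the
planted-truth suites therefore demonstrates correctness of the
algorithms under the stated model, not performance on real libraries,
where dispersion estimation and SSR calling are harder. Validation
sizes were chosen to keep the full suite fast on one CPU: 100 kb
genomes with 50 plants, 2,000-replicate null calibrations, 100-locus
power runs, 400-gene pipeline designs, and 10-seed ordering
comparisons.

## Degenerate inputs and edge behavior

Empty sequences yield empty record sets; divisions with zero totals in
the composition test are an error; loci observed in neither population
are an error; groups smaller than two samples are untestable, not
p = 1; zero-variance equal-mean positions give p = 1 while
zero-variance shifted positions report the smallest representable p
rather than 0 (p must stay in (0, 1]); unknown GO terms produce a zero
density profile with a warning; and genes missing from an ordering or
expression vector are imputed as zero or excluded, always with a
warning. Printed percentages round half-up to two decimals.

## Known limitations

The annealer is a heuristic: optimality is guaranteed only empirically
(exhaustively verified at ≤ 8 nodes). The per-gene NB test at three
replicates per group is conservative, trading sensitivity for control
of false positives. Diversity classification ignores allele
frequencies and flanking haplotypes. The transcriptogram's Welch test
treats windowed replicate means as independent across replicates but
makes no claim across positions, where smoothing induces correlation —
peak p-values are descriptive thresholds, not family-wise guarantees.
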