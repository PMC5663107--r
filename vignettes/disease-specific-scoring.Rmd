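---
title: "Disease-specific D-scores: model, assumptions and design choices"
author: "dscoreR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-specific D-scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Most variants that genome-wide association studies (GWAS) link to complex
diseases fall in non-coding DNA, where there is no reading frame to tell a
damaging change from a silent one. Generic deleteriousness scores answer
"is this base functional?", not "is this base relevant to *this*
disease?". dscoreR trains **disease/trait-specific** classifiers: for a
chosen trait, known GWAS risk variants are the positive class, a matched
sample of common, never-associated ("benign") variants is the negative
class, and the feature space is built from epigenomic and genomic
annotations summarized over fixed-width genomic windows. The trained
model assigns every window — hence every base, by inheritance — a
**D-score** in $[0,1]$: the average probability vote of an ensemble of
balanced classifiers, interpretable as the probability that the base is
associated with the trait.

The pipeline has five stages, each its own module:

1. **genome** — partition each chromosome into consecutive windows of
   `window_size` bp (default 200). The final window of a chromosome is
   truncated, never dropped, so window widths sum exactly to the
   chromosome length and every base is scoreable. Coordinates are 1-based
   and inclusive throughout; BED input (0-based half-open) is converted
   on read via `rtracklayer`.
2. **variantdb** — load association and population catalogs; `risk_set()`
   selects a trait's positives (exact, case-insensitive label match — the
   trait vocabularies involved are flat label sets, so no ontology
   expansion is attempted); `benign_candidates()` keeps variants with
   minor allele frequency strictly above `maf_min` (default 0.05) and no
   catalogued association, excluding by identifier first and by
   (chromosome, position) second, because identifiers are not stable
   across catalogs.
3. **matching** — draw the negative training set, `ratio` (default 10)
   negatives per positive, under one of two alternative strategies:
   `tss_matched` reproduces the positives' distance-to-TSS distribution
   bin by bin; `region_matched` restricts negatives to within `max_dist`
   (default 10 kb) of at least one positive. They are alternatives, not a
   composed filter: score archives are built per scheme, and composing
   them would conflate two different background definitions.
4. **annotation** — per-window features: sequencing read counts (midpoint
   assignment), optionally control-adjusted; binary element presence;
   per-window mean conservation. `assemble_matrix()` yields the
   windows × features matrix; a variant's feature vector is simply its
   host window's row.
5. **model / scoretrack** — per-feature two-sample tests, cross-validated
   p-value threshold selection, a balanced classifier ensemble, and the
   genome-wide score track with percentile queries.

## Matching in detail

Distance to the nearest transcription start site is the single matching
covariate, taken **unsigned**: upstream/downstream asymmetry is not part
of the matching claim, and signed bins would halve the per-bin candidate
pools for no stated gain. Default bin edges are log10-spaced on
$1+d$: $\{0, 10^2, 10^{2.5}, \dots, 10^6, \infty\}$ — TSS distances are
heavy-tailed, and half-decade bins keep both the promoter-proximal and
the distal regime resolved. When a bin cannot supply its quota the
shortfall is borrowed from the nearest non-exhausted bin (ties toward the
lower bin) and every borrow is recorded in the returned bin report; the
sampler never silently under-delivers, because the 10:1 ratio is treated
as a hard contract. Sampling is uniform without replacement within bins,
seeded (default seed 17), and applied to a canonical
(chromosome, position) ordering of the candidates, so results depend on
the seed and not on input row order.

## Annotation choices

* **Read counting** assigns each read to the one window containing its
  midpoint. This keeps the conservation invariant (window counts sum to
  the number of in-bounds reads) and avoids double-counting
  boundary-spanning reads; 5′-end or any-overlap assignment would be
  defensible too, but midpoint is the only rule that is both single-count
  and symmetric.
* **Control adjustment** is library-size-scaled subtraction floored at
  zero: $\max(0,\; t_w - \frac{N_t}{N_c} c_w)$. It is the simplest
  adjustment that respects count semantics (non-negative, zero when the
  control fully explains the signal); library sizes default to vector
  sums.
* **Conservation** is the per-window mean with unscored bases counted as
  0, so a fully covered constant-$c$ window scores exactly $c$ and sparse
  coverage is penalized rather than extrapolated.
* Counts enter the matrix **raw**. Any transform belongs to the base
  learner; rank-sum feature tests are invariant to monotone transforms
  anyway, and keeping the matrix a faithful record makes it reusable.

## The feature-selection ensemble

For each feature the positive and negative groups are compared with a
two-sided Wilcoxon rank-sum test (count and score features) or Fisher's
exact test on the 2×2 presence table (binary features) — the standard
nonparametric choices for overdispersed counts and presence/absence
data. Identical degenerate groups return $p = 1$ rather than an error.

A feature is kept when its p-value is at or below a threshold chosen by
$k$-fold cross-validation (default $k=5$) over the grid
$\{10^{-8}, 10^{-7}, \dots, 10^{-2}, 0.05, 0.1\}$: within each training
fold the tests are recomputed (selection inside the fold, so no selection
leakage into the held-out estimate), an ensemble is trained on the
selected features, and its held-out AUC recorded. The threshold with the
best mean held-out AUC wins; ties break toward the smaller (more
stringent) threshold, preferring the sparser model. A threshold that
selects nothing in some fold scores AUC 0.5 there — an uninformative
model, not an error. The grid, fold count and tie-break are this
package's choices, surfaced as arguments.

The ensemble itself handles the 10:1 class imbalance by balanced
undersampling without reuse: the negatives (in canonical row order, then
seed-shuffled) are partitioned into $\lfloor n_-/n_+\rfloor$ disjoint
folds of size $n_+$ — leftovers discarded and logged — and base
classifier $i$ trains on all positives plus negative fold $i$. Each
negative is used at most once; with the default ratio this gives exactly
10 classifiers, each seeing an equal number of risk and benign variants.
Votes are **probability estimates**, not hard labels: averaging 10 hard
votes could only produce D-scores in tenths, whereas probability means
give the graded scores the method is meant to produce. The default base
learner is a depth-limited gradient-boosted tree ensemble
(`xgboost`, depth 3, 30 rounds, single-thread for determinism); a
ridge-penalized logistic regression (`glmnet`) is provided behind the
same fit/vote contract for linear baselines, with an unpenalized
logistic fallback when only one feature is selected (glmnet requires two
or more predictors).

## Score tracks and percentiles

`score_genome()` applies the model row-wise; the track stores **one
value per window**, quantized to 4 decimals (quantization is
$\mathrm{round}(10^4 s)/10^4$, so values survive their text
serialization bit-exactly), with every base inheriting its window's
score. The genome-wide distribution is a fixed-width histogram (bin
width $10^{-4}$ on $[0,1]$) in which each window contributes its width in
bases, so bin counts sum exactly to the genome length and percentiles
computed from the histogram equal percentiles from explicit per-base
expansion. The percentile convention is cumulative and **inclusive** —
$100 \cdot \Pr(S \le s)$ — reported with 2 decimals; the track maximum is
always the 100th percentile. Percentiles are genome-wide; stratifying
the reference distribution (e.g. by TSS distance) is a recognized
alternative not implemented here. Region averages weight window scores
by overlap width and report the **population** (divide-by-$N$) standard
deviation: the region's bases are the entire population of interest, not
a sample. Query outputs follow fixed tab-delimited layouts: by
identifier (id, D-score, chromosome, position, percentile), by region
(region, id, position, D-score, percentile; variants ascending by
position), and region averages (region, mean, mean's percentile, SD).
Unmatched identifiers or malformed region lines are logged and skipped,
never fatal to a batch query.

## The synthetic world

`simulate_world()` fabricates the study conditions end to end: a toy
genome (default 2 chromosomes × 1 Mb, 200-bp windows → 10,000 windows),
TSS sites, 100 risk variants per trait and a 5,000-variant benign pool,
and 60 feature tracks of which 5 per trait are informative. Variant
positions follow a mixture law — probability 0.6 of an exponential
offset (mean 2 kb) from a random TSS, otherwise uniform — shared by risk
and benign variants, so TSS matching is non-degenerate. Counts are
negative-binomial (mean 10, size 5); informative features shift the mean
by `effect_size` standard deviations (default 2 SD) in windows hosting
that trait's risk variants. Benign MAFs are $0.5\cdot\mathrm{Beta}(1,3)$,
leaving roughly 70% of the pool above the 0.05 floor. Everything is a
deterministic function of the config seed.

What the generator does **not** emulate: correlation between assays,
genomic covariates of signal (GC, mappability), linkage disequilibrium
among variants, and realistic trait label structure. Passing tests on
this world therefore demonstrate correctness of the machinery — matching
fidelity, selection behaviour under signal and null, score/percentile
semantics — not real-data performance.

`end_to_end_demo()` trains two traits with disjoint planted signals and
checks the qualitative properties expected of a disease-specific score:
each trait's risk variants score higher under their own model than under
the other trait's (median comparison), and risk-variant D-scores exceed
the genome background by a one-sided rank-sum test. At the default
configuration the whole demo runs in well under a minute; the test suite
and the reproduction script use the same 2 × 1 Mb scale (with
n = 100/1000 training sets) as the package's standard study size, chosen
so the full pipeline stays interactive on a laptop.

## Numerical and degenerate-input behaviour

* Window arithmetic is integer; the last window's width is
  `len − (n−1)·window_size`.
* `wilcox.test` switches to its normal approximation for large or tied
  samples; the exact small-sample case (used by the oracle tests) is
  exact enumeration.
* AUC inside the CV loop is the Mann–Whitney rank statistic, checked
  against an independent implementation in the tests.
* Ensembles refuse to train with fewer negatives than positives
  ("cannot balance") or with an empty feature selection.
* Track archives carry a magic line, version, and a terminator; a
  truncated file errors out rather than yielding a partial track.
* Seeds: every sampling step takes an explicit seed argument; identical
  seeds give byte-identical reports, archives and query outputs.

## Limitations

Scores are window-resolution: two variants in one 200-bp window are
indistinguishable. GWAS p-value ordering, eQTL and methylation features
are not modelled. The matching covariate is TSS distance alone — allele
frequency and LD structure are deliberately out of scope. Real-resource
ingestion (consortium epigenome compendia, public association databases)
is file-based: the package reads the standard formats but ships no
downloaders.
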