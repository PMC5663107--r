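# dscoreR — disease-specific functional scoring of non-coding variants

Most GWAS hits land in non-coding DNA, where a variant's relevance to a
*particular* disease cannot be read off a protein change, and generic
deleteriousness scores cannot distinguish "functional" from "functional
for this trait". dscoreR trains a **disease/trait-specific** model and
assigns every base of a genome a **D-score** in [0, 1] — the probability
that the base is associated with the trait — and ships the query toolkit
to use it: look up scores by variant identifier, by genomic region, or as
region averages, each with its genome-wide percentile.

It is aimed at statistical/regulatory geneticists following up GWAS
signals: given an association catalog, a population variant catalog with
allele frequencies, a TSS annotation and a set of epigenomic/genomic
tracks, it produces a per-base score track for the trait of interest.

## Method in brief

For a trait with risk-variant set $P$ (GWAS-catalogued SNVs) the negative
set $N$ is sampled from common variants (MAF > 0.05, no catalogued
association) at $|N| = 10\,|P|$, matched on distance to the nearest
transcription start site (alternatively: restricted to within 10 kb of a
risk variant). The genome is partitioned into 200-bp windows; window $w$
gets a feature vector $x_w$ of control-adjusted read counts, binary
element presence, and mean conservation. Each feature is tested positive
vs negative (Wilcoxon rank-sum for continuous, Fisher's exact for
binary), and a p-value cutoff $\tau$ is chosen by cross-validation
(tests recomputed inside each training fold; best mean held-out AUC
wins). The classifier is a balanced ensemble: $N$ is partitioned into
$\lfloor|N|/|P|\rfloor$ disjoint folds of size $|P|$, one base classifier
(gradient-boosted trees by default) per fold, and

$$\mathrm{Dscore}(x) \;=\; \frac{1}{m}\sum_{i=1}^{m} \hat p_i(x),$$

the mean of the classifiers' probability votes. Every base inherits its
window's score; percentiles are computed against the genome-wide
empirical score distribution (inclusive convention,
$100\cdot\Pr(S \le s)$).

A synthetic-data module (`simulate_world()`) fabricates a toy genome,
TSS annotation, variant catalogs and feature tracks with planted,
trait-specific signal, so the entire pipeline runs and is tested without
any external resources.

## Worked example

Train a model for one synthetic trait and query the resulting track:

```r
library(dscoreR)

cfg   <- sim_config(traits = c("traitA", "traitB"), seed = 42)
world <- simulate_world(cfg)                       # 2 x 1 Mb toy genome
am    <- assemble_matrix(world$tracks, world$partition)

pos  <- risk_set(world$risk_catalog, "traitA")
cand <- benign_candidates(world$benign_catalog, 0.05, world$risk_catalog)
ms   <- match_negatives_tss(pos, cand, world$tss, ratio = 10, seed = 42)
#> matched sets [tss_matched]: 100 positives, 1000 negatives (ratio 10, seed 42)

pm <- annotate_variants(ms$positives, am)
nm <- annotate_variants(ms$negatives, am)
cv <- select_threshold_cv(pm, nm, am$features$kind, seed = 42)
#> threshold 0.001, mean held-out AUC 0.953
#> selected: assay_001, assay_002, assay_003, assay_004, assay_005

model <- train_ensemble(pm, nm, cv$selected_features, seed = 42,
                        threshold = cv$threshold)
#> ensemble model: 10 xgboost classifier(s), 5 selected feature(s), threshold 0.001

track <- score_genome(model, am, disease = "traitA")
dist  <- build_distribution(track)

query_by_id(pos$id[1:3], track, dist, world$risk_catalog)
#>        id dscore chrom    pos percentile
#>  rsR00001 0.9001  chr2   7905      98.74
#>  rsR00002 0.9766  chr2 650110      99.53
#>  rsR00003 0.9147  chr2  54392      98.86

region_average(data.frame(chrom = "chr1", start = 1, end = 10000),
               track, dist)
#>  chrom start   end mean_dscore mean_percentile sd_dscore
#>   chr1     1 10000     0.11829            65.7  0.172503
```

The cross-validation recovered exactly the five features the generator
planted for traitA; the three risk variants score near the top of the
genome-wide distribution (99th percentile), while the first 10 kb of
chr1 — mostly background — averages a D-score of 0.12.

The same pipeline is scriptable from a shell through the bundled wrapper
(subcommands `simulate`, `train`, `score-genome`, `query`):

```sh
DSCORE=$(Rscript -e 'cat(system.file("scripts", "dscore", package = "dscoreR"))')
Rscript $DSCORE simulate --out fixtures --seed 42
Rscript $DSCORE train --fixtures fixtures --out run --disease traitA --seed 42
Rscript $DSCORE score-genome --fixtures fixtures --model run/model.rds --out run
Rscript $DSCORE query --mode id --track run/scores.track.gz \
        --in variant.txt --out score.variant.txt --catalog fixtures/risk.tsv
```

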