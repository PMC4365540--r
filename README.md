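# subgroupCentering

Subgroup-specific gene centering for centroid-based molecular subtype
classification.

## The problem this package addresses

Intrinsic-subtype classifiers such as PAM50 assign a breast tumor to the
subtype (Basal-like, HER2-enriched, LumA, LumB, Normal-like) whose centroid —
a reference expression profile over a gene signature, built from a centered
training cohort — correlates best with the tumor's expression profile. Before
classification, each gene of the study cohort is conventionally centered on
its own per-gene median ("standard gene centering"), so that expression is
relative rather than absolute.

That convention breaks when the study cohort's clinicopathological
composition differs from the training cohort's. In an ER-positive-only
cohort, the median of an estrogen-pathway gene sits in the middle of the
ER-positive expression mode, far from the mixed training cohort's baseline;
subtracting it misplaces every sample relative to the centroids and corrupts
the subtype calls. The same happens for triple-negative cohorts or any
skewed ER mixture — a ubiquitous situation, since clinical studies routinely
enroll by receptor status.

**Subgroup-specific gene centering** fixes the baseline instead of the data:

1. compute each gene's baseline `mu_gene` on the *full* training cohort (the
   per-gene median, in the PAM50 convention);
2. find the percentile `Q_gene` at which `mu_gene` sits within a training
   *subgroup* whose composition matches the study cohort (ER-positive,
   triple-negative, or a stated mixture realised by stratified subsampling
   or by sample weighting);
3. center each study gene by subtracting the *study cohort's own* expression
   value at percentile `Q_gene`.

The per-gene `(mu_gene, Q_gene)` pairs form a reusable percentile table that
can be precomputed per subgroup, written to TSV, and applied to any study
cohort of that composition. The package implements the transform, a
nearest-centroid classifier (Spearman by default, Pearson optional),
evaluation utilities (confusion summaries, exact/asymptotic McNemar
comparison, an ER-composition sweep), a synthetic breast-cancer cohort
generator that makes the whole pipeline testable without external data,
readers/writers for all tab-delimited formats, and a command-line interface.

## Worked example

A training cohort of 475 synthetic tumors; a 75-sample study cohort drawn at
15% ER-positive / 85% ER-negative (11 + 64 samples); centroids trained on
the standard-centered training remainder:

```r
library(subgroupCentering)

train <- generateCohort(defaultBreastConfig(475, seed = 1))
split <- splitTrainStudy(train, studyErPositiveFraction = 0.15,
                         studySize = 75, seed = 2)
centroids <- trainCentroids(standardCenter(split$train),
                            clinicalTable(split$train))

# percentile table matched to the study composition
mix  <- subgroupSpec(c(er_positive = 0.15, er_negative = 0.85))
ptab <- mixturePercentiles(split$train, mixture = mix,
                           nResamples = 200, seed = 3)

confusionSummary(classifySamples(standardCenter(split$study), centroids),
                 clinicalTable(split$study))
#> ConfusionSummary: accuracy 78.7% (error rate 21.3%) on 75 samples

confusionSummary(classifySamples(subgroupCenter(split$study, ptab), centroids),
                 clinicalTable(split$study))
#> ConfusionSummary: accuracy 98.7% (error rate 1.3%) on 75 samples
```

Standard centering misclassifies 21.3% of the skewed cohort (prototypic
HER2-enriched and Normal-like tumors drift into LumB/LumA calls, as the full
confusion matrices show); subgroup-specific centering reduces the error to
1.3% on the same samples. The paired comparison on identical samples:

```r
lab <- clinicalTable(split$study)$prototypic_subtype
mcnemarTest(predictedSubtype(classifySamples(subgroupCenter(split$study, ptab),
                                             centroids)) == lab,
            predictedSubtype(classifySamples(standardCenter(split$study),
                                             centroids)) == lab)
#> McNemar test (exact-binomial): b = 15, c = 0, P = 6.104e-05
```

The methods vignette (`vignettes/subgroup-centering.Rmd`) documents the
model, the percentile convention, the generator's calibration constants, and
what the synthetic experiments do and do not demonstrate.

## Command-line interface

A thin Rscript wrapper exposes the pipeline as subcommands (`simulate`,
`precompute-baselines`, `center`, `train-centroids`, `classify`, `evaluate`,
`sweep`), all seeded and writing `#`-prefixed provenance headers:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "subgroupcenter.R", package = "subgroupCentering"))')
Rscript "$CLI" simulate --n-samples 200 --seed 7 \
    --expression-out expr.tsv --clinical-out clin.tsv
Rscript "$CLI" precompute-baselines --train expr.tsv --clinical clin.tsv \
    --subgroup er_positive --output ptab.tsv
Rscript "$CLI" center --study expr.tsv --mode subgroup --table ptab.tsv \
    --output centered.tsv
```

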