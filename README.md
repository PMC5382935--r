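# cfnips

Aneuploidy screening from low-pass cell-free DNA sequencing counts.

Non-invasive prenatal screening (NIPS) reads the mixture of maternal and
placental DNA fragments circulating in maternal plasma. A fetal trisomy
shifts the affected chromosome's share of sequenced reads upward by roughly
`FF/2`, where `FF` is the fetal fraction — a change of a few percent at
typical fetal fractions, buried in GC bias, batch artifacts and counting
noise. `cfnips` implements a bin-based calling pipeline for shallow
(~0.2–0.6×) single-end shotgun data, for people building or studying
read-depth NIPS methods: it goes from per-bin read counts to trisomy 13/18/21
calls, sex-chromosome aneuploidy calls, microdeletion region scores,
fetal-fraction estimates, and the maternal-event screens that keep false
positives out of reports.

## The statistic at the core

Counts in ~50 kb genome bins are scaled by each sample's autosomal total,
GC-corrected by per-sample loess regression of bin value on GC fraction,
denoised by projecting out the top principal components of a euploid
training cohort (fitted without chromosomes 13/18/21, so trisomy signal
cannot be absorbed), and smoothed by winsorization plus a 5-bin rolling
median. Chromosome *i*'s representation is then

    chrRep_i = chrTotalRC_i / sum_{j=1..22} chrTotalRC_j

and its calling statistic is a robust Z-score

    Z = (x − μ) / σ

with `x` the sample's representation, `μ` the plate median (plates of 12
samples; small plates fall back to the training median) and `σ` the
1.4826-scaled median absolute deviation from a training cohort. Samples with
`Z ≤ 4` are negative, `Z > 8` positive, and the band in between goes to
review with a per-bin ideogram: a whole-chromosome trisomy elevates every
bin (ratio ≈ `1 + FF/2`), whereas a maternal segmental duplication elevates
a short segment (ratio ≈ 1.5), and multi-chromosome aberrations (e.g. DNA
shed by uterine fibroids) trip a genome-wide screen. Both patterns are
reported as suspected maternal variation, never as fetal trisomy.

Male fetal fraction is the median of four X/Y-based estimators (three
X-underrepresentation variants, `FF = 2(1 − X_i/X_f)`, plus a Y
background/slope inversion); female fetal fraction comes from an
L1-regularized regression on autosomal bin counts (glmnet, `alpha = 1`,
10-fold cross-validation). Results are gated at 9M reads and 5% fetal
fraction. Sex-chromosome aneuploidies are classified in the
(X-based FF, Y-based FF) plane, with guards for maternal 45,X mosaicism
(X-based FF > 50%) and maternal 47,XXX (negative X-based FF).

A negative-binomial simulator with known ground truth (trisomies,
mosaicism, twins, maternal duplications, global aberrations, GC bias,
adult controls) generates every cohort used by the tests.

## Worked example

```r
library(cfnips)

cfg <- sim_config()                      # toy genome, 1.2e7 reads, plates of 12
train <- simulate_cohort(list(
  sim_scenario(120, "EUPLOID"),
  sim_scenario(12, subject = "ADULT_MALE"),
  sim_scenario(12, subject = "ADULT_FEMALE")
), cfg, seed = 101)
roles <- data.frame(sample_id = train$truth$sample_id,
                    role = ifelse(train$truth$subject == "PREGNANT",
                                  "PREGNANT", train$truth$subject))
ref <- train_nips(train$counts, train$bins, roles, nips_config(),
                  regions = toy_regions())

test <- simulate_cohort(list(sim_scenario(100, "EUPLOID"),
                             sim_scenario(20, "T21"),
                             sim_scenario(10, "T18"),
                             sim_scenario(10, "T13")), cfg, seed = 202)
res <- call_cohort(test$counts, ref)

eu <- test$truth$sample_id[test$truth$aneuploidy == "EUPLOID"]
max(res$z[eu, c("13", "18", "21")])
#> [1] 3.474597
range(res$z[test$truth$sample_id[test$truth$aneuploidy == "T21"], "21"])
#> [1] 18.11940 32.43281
table(truth = test$truth$aneuploidy, status = res$reports$status)
#>          status
#> truth     NEGATIVE POSITIVE
#>   EUPLOID      100        0
#>   T13            0       10
#>   T18            0       10
#>   T21            0       20
```

Every euploid sample stays below the negative cutoff (max Z ≈ 3.5 < 4) and
every trisomic sample scores above the positive cutoff (min Z ≈ 15 > 8) —
the separation property that lets intermediate Z-scores be investigated as
possible maternal events instead of being reported. `res$ff` holds the
per-method fetal fractions, `res$sex` the sex calls, `res$region_z` the
microdeletion region scores, and `res$tracks` the ideogram tracks for any
review/positive chromosome.

A thin command-line interface wraps the same functions:

```sh
exec/cfnips simulate --out-dir cohort --seed 5 --n-euploid 100 --n-t21 5
exec/cfnips train    --cohort cohort --out reference.json
exec/cfnips call     --cohort cohort --reference reference.json --out results.tsv
exec/cfnips stats    --results results.tsv --truth cohort/truth.tsv
```

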