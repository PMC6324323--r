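# icutraj

Build and validate in-hospital mortality prediction models for intensive
care unit (ICU) admissions from the first 24 hours of electronic health
record data — and stress-test the whole pipeline on a synthetic multi-site
cohort generator, so no confidential data is needed to exercise any stage.

The package is aimed at biostatisticians and clinical-informatics
researchers who work on ICU risk adjustment and want a tested, reusable
implementation of the "use all the data" modeling recipe:

1. **Clinical trajectories.** Instead of only the most abnormal value of
   each lab and vital sign, every observation in the 24-hour window is
   summarized per variable by eight measures — min, max, mean, SD, first,
   last, last−first, and the least-squares slope (units/hour). Missing
   measures are filled with training-set medians.
2. **Note text.** Each patient's first-day notes are pooled into a note
   set; the k most frequent training terms (default 1000) are weighted by
   sublinear TF-IDF: `w = (1 + ln tf) · idf`, `idf = ln((1+N)/(1+df)) + 1`.
3. **Ridge logistic regression.** In-hospital death is modeled by
   maximizing `ℓ(β₀, β) − (λ/2)‖β‖²` (intercept unpenalized) via IRLS
   with step-halving; λ is chosen by stratified inner cross-validation on
   AUC.
4. **Validation harness.** Repeated nested K-fold cross-validation
   (default 100 × 10 → 1000 fold AUCs per model) with percentile-bootstrap
   CIs, a site×site external-validation transfer matrix, a modified
   Hosmer–Lemeshow calibration test, AUPRC and optimal-cut-point metrics,
   an alive-at-24-hours sensitivity analysis, and construct-validity
   comparisons of every trajectory measure between survivors and
   nonsurvivors.

Three model families are compared on the same cohort: **baseline**
(min/max only; 48 predictors with the default 24 variables), **trajectory**
(all eight measures; 192), and **trajectory + NLP** (plus the TF-IDF
terms; 1192 with a 1000-term vocabulary).

Everything fitted from data — imputation medians, vocabulary, IDF,
standardization, λ — is learned strictly inside each training partition;
the test suite verifies these artifacts are bit-identical under arbitrary
mutation of held-out rows.

## Worked example

Generate a 2000-patient, 3-site synthetic cohort (10.4% mortality,
outcome-dependent trajectories and note terms), then cross-validate the
three model families:

```r
library(icutraj)

cfg    <- generator_config(n_patients = 2000, seed = 42)
cohort <- generate_cohort(cfg)
head(cohort$observations, 3)
#>   patient_id  variable         t    value
#> 1    p000001 bilirubin  8.095325 1.059690
#> 2    p000001 bilirubin 17.633693 0.958178
#> 3    p000001 bilirubin 22.377097 1.255514

hc  <- harness_config(repetitions = 2, outer_folds = 10,
                      lambda_grid = c(1, 10, 100), inner_folds = 3,
                      vocab_k = 100,
                      variables = c("gcs_total", "gcs_eye", "gcs_verbal",
                                    "gcs_motor", "heart_rate", "sbp",
                                    "lactate", "urea"),
                      seed = 42)
res <- nested_cv(cohort$stays, cohort$observations, cohort$notes, hc)
res
#> nested 10-fold cross-validation, 2 repetition(s), n = 2000 (prevalence 0.117)
#>   baseline        AUC 0.885 (95% CI 0.869-0.899; 20 fold values)  AUPRC 0.602  HL C = 37.8 (p = 8.2e-06)
#>   trajectory      AUC 0.926 (95% CI 0.914-0.937; 20 fold values)  AUPRC 0.719  HL C = 23.9 (p = 0.0024)
#>   trajectory_nlp  AUC 0.983 (95% CI 0.976-0.988; 20 fold values)  AUPRC 0.918  HL C = 46.8 (p = 1.7e-07)
```

Each line is one model family: the mean out-of-fold AUC over the 20 fold
values with its bootstrap CI, the area under the precision–recall curve
and the modified Hosmer–Lemeshow statistic on pooled out-of-fold
predictions. Discrimination rises stepwise as trajectory measures and then
note terms are added, with non-overlapping CIs — the ordering the package
is designed to detect.

Construct validity — does an improving Glasgow Coma Scale trend predict
survival? The generator's configured trends are +0.124 points/h for
survivors and −0.034 for nonsurvivors:

```r
fm <- build_feature_matrix(cohort$stays, cohort$observations,
                           variables = "gcs_total", mode = "trajectory")
cv <- construct_validity(fm)
cv[cv$measure == "gcs_total.slope",
   c("measure", "mean_survivor", "mean_nonsurvivor", "t_p_value")]
#>           measure mean_survivor mean_nonsurvivor t_p_value
#> 8 gcs_total.slope         0.117          -0.0602  1.03e-10
```

External validation across sites — fit on one site (with that site's
vocabulary and IDF), test on the others:

```r
xs <- cross_site(cohort$stays, cohort$observations, cohort$notes,
                 harness_config(model_modes = "trajectory_nlp",
                                lambda_grid = 10, vocab_k = 100, seed = 42,
                                variables = hc$variables))
xs
#> cross-site external validation (rows: training site; columns: test site)
#>   mode trajectory_nlp:
#>         test
#> train    site_a site_b site_c
#>   site_a     NA  0.975  0.972
#>   site_b  0.979     NA  0.979
#>   site_c  0.969  0.975     NA
```

A thin command-line wrapper over the same functions lives at
`inst/cli/icutraj.R` (`simulate`, `nested-cv`, `cross-site` subcommands
reading/writing the CSV schemas of `read_events()`/`write_events()`).

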