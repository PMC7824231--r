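# methdelta

Longitudinal epigenome-wide association analysis of infant feeding mode
(exclusive breastfeeding, exclusive formula feeding, mixed feeding) on
the **change** in blood DNA methylation between birth and age 10 years.

Cross-sectional EWAS of breastfeeding cannot separate effects of feeding
from methylation differences already present at birth. `methdelta`
implements the delta-residual design that can: per CpG, beta values are
logit-transformed to M-values, residualized at each age on leukocyte
cell-type proportions and season of blood collection, and the birth
residual is subtracted from the age-10 residual,

    ΔDNAm_ij = residM_ij(age 10) − residM_ij(birth).

These per-CpG, per-subject changes are the outcome of

* **discovery** — training/testing screening: repeated 2/3–1/3 splits of
  the subjects, Huber robust regressions of ΔDNAm on one feeding-mode
  indicator plus surrogate variables in both halves, keeping CpGs that
  replicate (p < 0.05 in both halves in ≥ 50% of 100 splits);
* **confirmation** — OLS per screened CpG with the full confounder set
  (sex, cell composition and season at both ages, maternal age, maternal
  smoking, mode of delivery, birthweight, birth order, SES) under
  Benjamini–Hochberg FDR control within feeding mode;
* **global shift** — per-subject mean ΔDNAm, and the percentage of each
  subject's CpGs falling below/above the population-median per-subject
  quartiles, each regressed on feeding modes (EBF reference) with
  confounders;
* **cohort utilities** — representativeness tests of an analytical
  sample against its cohort, gene-location enrichment tables, a
  mixed-model temporal-stability classifier (ages 10→18), and
  per-feeding-group outcome regressions;
* **a synthetic cohort generator** with known injected effects, used by
  the calibration, power and parameter-recovery studies.

## Worked example

A synthetic cohort of 200 children and 2,000 CpGs with 50 CpGs per
feeding mode carrying a 1.0 M-unit effect on the birth→10y change and a
−0.03 M-unit global shift in the formula-fed group:

```r
library(methdelta)

coh <- simulate_cohort(sim_config(n_subjects = 200, n_cpgs = 2000,
                                  n_effect_cpgs_per_mode = 50,
                                  effect_size_m = 1, noise_sd_m = 0.5,
                                  seed = 42))
pp  <- preprocess_pipeline(coh$birth, coh$age10, coh$sheet)

modes <- as.character(coh$sheet$feeding_mode)
scr <- tt_screen(pp$delta, as.integer(modes == "EFF"),
                 config = screening_config(seed = 42))
sel <- scr$cpg_id[scr$selected]
sum(coh$truth$effect_cpg_ids$EFF %in% sel)
#> 49        # 49 of the 50 injected EFF CpGs survive screening

eff <- run_ewas(pp$delta, coh$sheet, sel, mode = "EFF")
head(eff[order(eff$p_raw), c("cpg_id", "coefficient", "se", "p_raw", "p_fdr")], 3)
#>        cpg_id coefficient    se    p_raw    p_fdr
#> 79 cg00001679        1.29 0.173 4.53e-12 4.26e-10
#> 87 cg00001865        1.21 0.173 5.95e-11 2.35e-09
#> 84 cg00001820        1.29 0.186 7.52e-11 2.35e-09
```

The confirmed coefficients sit near the injected 1.0 M-units: each is
the adjusted change in birth→10y methylation associated with exclusive
formula feeding at that CpG. The global-shift analysis on the same
cohort:

```r
shift <- global_shift_analysis(pp$delta, coh$sheet)
shift$results
#>        outcome  mode coefficient      se  p_value
#> 1   mean_delta   EFF   -3.66e-02 0.00406 3.46e-16
#> 2   mean_delta Mixed   -3.14e-05 0.00264 9.91e-01
#> 3 pct_below_q1   EFF    1.82e+00 0.23971 1.73e-12
#> 4 pct_below_q1 Mixed   -3.49e-01 0.15620 2.69e-02
#> 5 pct_above_q3   EFF   -1.66e+00 0.24940 3.95e-10
#> 6 pct_above_q3 Mixed   -2.94e-01 0.16251 7.22e-02
```

The injected downward EFF shift is recovered in the mean-delta
coefficient (−0.037 ± 0.004 M-units vs the EBF reference) and shows the
expected mirror pattern in the quartile percentages: formula-fed
subjects have ~1.8 percentage points more CpGs below the population Q1
cutoff and fewer above Q3.

Representativeness of an analytical sample against its source cohort,
from the bundled worked-example margins:

```r
margins <- read_cohort_margins(system.file("extdata", "cohort_margins.csv",
                                           package = "methdelta"))
head(representativeness_tests(margins), 3)
#>           variable   test statistic p_value
#> 1             male prop_z     1.798  0.0722
#> 2 maternal_smoking prop_z    -1.828  0.0676
#> 3  maternal_asthma prop_z     0.684  0.4940
```

A thin command-line front end over the same functions ships at
`inst/cli/methdelta` (subcommands `simulate`, `preprocess`, `screen`,
`ewas`, `global`, `report`).

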