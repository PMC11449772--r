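# ironaccord

Quantitative MRI estimates liver iron by fitting the decay of a multi-echo
gradient-echo signal: the effective relaxation time T2* shortens as tissue
iron rises, and a power-law calibration converts T2* (ms) to liver iron
concentration (LIC, mg/g dry weight). Clinically the LIC is then collapsed
to a five-level iron-burden grade (normal / slight / mild / moderate /
severe) that drives chelation decisions. The open question this package
addresses: how reliably does the T2* route reproduce a reference grade, and
how is that reliability shaped by goodness of fit (R²), by the number of
echoes retained in the fit, and by the iron burden itself?

`ironaccord` implements the full analysis chain as reusable, tested R code,
driven by a synthetic cohort generator so every stage has a ground-truth
oracle:

- **Simulation** — mono-exponential ROI-mean decay S₀·exp(−TE/T2\*) on a
  twelve-echo 1.5 T schedule (1.29 … 13.6 ms) with Rician magnitude noise,
  for a cohort whose grade mix and LIC range match a realistic thalassemia
  population.
- **Relaxometry** — nonlinear least-squares fitting of (S₀, T2\*) with the
  *truncation method*: iteratively dropping the longest-TE echoes (which sit
  in the Rician noise floor), recording (echo count, T2\*, R²) at every
  level, and selecting a final fit by "highest 0.01-wide R² bin, then most
  echoes".
- **Calibration** — LIC = 31.94 · T2\*^(−1.014) (coefficients are
  configurable) and the five-grade scale with boundaries 1.8 / 3.2 / 7.0 /
  15.0 mg/g.
- **Accordance** — the diagnostic accordance rate (DAR: fraction of exact
  grade matches) and its directly standardized version
  p′ = Σᵢ (Nᵢ/N) pᵢ, which reweights each subgroup's within-layer rates by
  pooled layer counts so subgroups with different internal composition can
  be compared; single and double (two-confounder) standardization are
  provided.
- **Statistics** — paired Wilcoxon signed rank, Kruskal–Wallis with
  Bonferroni-corrected pairwise follow-ups, Spearman correlation, and a
  two-way random absolute-agreement single-measure ICC.

## Worked example

```r
library(ironaccord)

cfg <- pipeline_config(spec = cohort_spec(n_patients = 108, seed = 3),
                       out_dir = tempfile())
res <- run_pipeline(cfg)

res$bookkeeping$exclusion
#>       n_in n_excluded n_analyzed
#>       1080         51       1029

res$accordance$te
#>    subgroup   n       dar      sdar
#> 1         3 103 0.8834951 0.8761998
#> 2         4 103 0.9320388 0.9266804
#> 3         5 103 0.9611650 0.9670159
#> 4         6 104 0.9807692 0.9802536
#> 5         7 103 0.9805825 0.9804295
#> 6         8 103 0.9805825 0.9805923
#> 7         9 103 0.9708738 0.9681436
#> 8        10 104 0.9519231 0.9515397
#> 9        11 102 0.9607843 0.9619252
#> 10       12 101 0.9603960 0.9604046
```

Reading this: 108 patients × 10 truncation levels give 1,080 record-level
fits; 51 with R² < 0.95 are excluded. Per echo-count subgroup, `dar` is the
crude fraction of records whose estimated grade matches the true grade and
`sdar` is the same rate after standardizing away differences in R²-bin and
iron-grade composition between subgroups. Accuracy rises steeply from 3 to
6 echoes and then plateaus — the truncation method's trade-off made visible.

`res$selected` holds one final fit per patient under the binned selection
policy, with `t2star_hat`, `lic_hat` and `grade_hat` alongside the truth.

## Command line

```sh
Rscript inst/cli/ironaccord run --seed 1 --out /tmp/run1
Rscript inst/cli/ironaccord simulate --config cfg.json
```

Subcommands: `simulate | fit | convert | accordance | report | run`; exit
codes 0 / 1 / 2 for ok / stage error / config error.

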