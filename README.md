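# binNMR

Binned ¹H-NMR metabolite profiling with per-bin differential abundance,
for two-condition × two-age animal cohorts.

## The problem

Untargeted ¹H-NMR profiling of fecal (or digesta) samples asks which
metabolites differ between two husbandry conditions — here high (HSC) vs
low (LSC) sanitary conditions in growing pigs, sampled at 14 and 22 weeks
of age, six animals per treatment per age. The standard bucket-table
route reduces each spectrum to fixed-width chemical-shift bins, filters
uninformative bins, tests each bin, and reports annotated metabolites as
HSC/LSC abundance ratios with FDR tiers. binNMR implements that route as
a tested, reusable pipeline:

1. **Binning** — 0.01-ppm half-open buckets over a [0, 10) ppm window:
   1000 bins per sample; the bin value is the sum of in-bin point
   intensities (total signal is conserved exactly).
2. **Filter cascade** — the 20 water-region bins [4.70, 4.90) are
   excluded (1000 → 980), then bins whose maximum intensity across
   samples never reaches 100,000 units are dropped.
3. **Per-bin tests** — for each week separately, a closed-form OLS fit of
   log₂(intensity + pseudocount) on treatment; the treatment t-statistic
   (n − 2 df, two-sided) is identical to the pooled-variance two-sample
   t-test. A pooled additive treatment + age model is also available.
4. **FDR** — Benjamini–Hochberg step-up within each week across the
   retained bins; tiers q < 0.05, q < 0.1, "ns" (strict bounds).
5. **Aggregation** — annotated bins are combined per metabolite: the
   summary ratio is the unweighted mean of bin ratios and the summary
   FDR the mean of bin q-values; the 2.18 ppm bin shared by butyrate and
   propionate contributes to both means.

A synthetic-spectrum generator (Lorentzian peak mixtures, log-normal
animal effects, Gaussian noise, a dominant water hump, planted HSC/LSC
ratios) emulates the cohort so the entire pipeline is exercisable,
calibratable and power-testable without any data download.

## Worked example

Simulate a cohort with the default planted ratio table and analyse it end
to end:

```r
library(binNMR)
d   <- cohortDesign(pointsPerBin = 16L, seed = 11L)
sim <- runSimulate("demo", d)
res <- runAnalyze(spectraDir = sim$spectraDir,
                  metadataFile = sim$metadata, outDir = "demo_out")
```

The log prints the filter trajectory and per-week significant-bin counts:

```
INFO binned 24 spectra into 1000 bins
INFO excluded 20 bins: 1000 -> 980
INFO threshold 1e+05 (max): 980 -> 30
INFO week 14: 18 bins q<0.05, 0 bins 0.05<=q<0.1
INFO week 22: 28 bins q<0.05, 2 bins 0.05<=q<0.1
```

and `demo_out/table1_report.md` holds the rendered metabolite table
(excerpt):

```
| Expected Origin | Bins | Metabolite              | Ratio (wk 14) | FDR   | Ratio (wk 22) | FDR   |
| Diet            | 7.93 | Xanthine                | 1.35          | <0.05 | 1.25          | <0.05 |
| Microbiome      | 2.18 | Butyrate and propionate | 0.72          | <0.05 | 0.74          | <0.05 |
| Microbiome      |      | Mean butyrate           | 0.77          | <0.05 | 0.81          | <0.1  |
| Microbiome      |      | Mean UDP-glucose        | 1.04          | ns    | 4.30          | <0.05 |
```

Ratios above 1 mean higher abundance in HSC feces (e.g. xanthine), below
1 higher in LSC (the short-chain fatty acids at week 14); the FDR column
is the within-week BH tier of the bin (or the mean-q tier of the
metabolite's bins). The recovered ratios scatter around the planted
values with the sampling noise of n = 6 animals per cell. Full outputs:
`bin_matrix_raw.csv`, `results_bins.csv`, `results_metabolites.csv`,
`table1_report.md`, `run_report.json`, `pipeline.log`.

A thin command-line wrapper over the same functions ships in
`inst/scripts/binNMR-cli.R` (`simulate` and `analyze` subcommands with
`--config` YAML and flag overrides).

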