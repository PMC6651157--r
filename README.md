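# aqmca

Coupled trend and maximum covariance analysis for air-quality
monitoring networks.

Dense national monitoring networks observe PM2.5 and its gaseous
precursors (SO2, NO2) hourly at hundreds of stations. Turning those raw
records into statements like *"PM2.5 and SO2 declined together, the
decline was strongest in high-pollution episodes, and SO2 explains most
of the regional PM2.5 variability"* takes a chain of statistical steps,
each with sharp edges: outlier screening against neighbour stations,
spatial clustering, semi-monthly integration, stratified least-squares
trends, maximum covariance analysis (MCA) between pollutant fields with
Monte Carlo significance, and principal-component regression with
relative-importance decomposition. `aqmca` implements that chain as a
tested R package for researchers in exposure surveillance and
environmental statistics, together with a synthetic network generator
that plants known trends, coupling and artifacts so every stage is
verifiable against ground truth.

## Methods at a glance

* **QC** (two-stage, per cluster): flag hour *t* when
  |x(t) − ref(t)| > m·max(SD₂₄(t), s₀), where ref is the station-median
  reference, SD₂₄ the trailing 24-h reference SD, m = 3 (6 for SO2);
  then flag second differences d = x(i+1) − 2x(i) + x(i−1) outside
  [−100, 100] µg/m³ (one flag per candidate run, at max |d|).
* **Integration**: pooled cluster means per semi-month (days 1–15 /
  16–end), in an all-value and a fourth-quartile-averaged variant
  (mean of values above the within-window 75th percentile).
* **Trends**: OLS slope on fractional-year time, ±t₀.₉₇₅,ₙ₋₂·SE at 95%.
* **MCA**: SVD of C = XᵀY/(n−1) between deseasonalized anomaly fields;
  SCFₖ = σₖ²/Σσ²; per-mode significance against the 95% quantile of the
  SCF under row permutation of one field (UPCI).
* **Attribution**: PM2.5 hotspot mean ~ SO2_PC1 + SO2_PC2 + NO2_PC1 +
  NO2_PC2 on standardized regressors, with VIF (collinearity threshold
  10), exact LMG shares (sum to R²) and last-in/first-in semi-partial
  R² gains.

## Worked example

The `analysis/` scripts run the chain stage by stage on a seeded
synthetic network (16 stations, 8 clusters, 4 years; planted trends
−4 / −2 / +0.5 µg m⁻³ a⁻¹ for PM2.5 / SO2 / NO2; a shared PM2.5–SO2
latent mode over half the clusters; spikes and missing hours):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc_aggregate.R
Rscript analysis/03_trends.R
Rscript analysis/04_mca.R
Rscript analysis/05_attribution.R
```

Stage 3 prints the network trends — the planted declines are recovered
with 95% intervals, and the uncoupled NO2 trend is not significant:

```
PM25  all network trend:  -4.62 +/- 2.62 ug/(m3 a) *
SO2   all network trend:  -1.92 +/- 1.09 ug/(m3 a) *
NO2   all network trend:   0.13 +/- 1.02 ug/(m3 a)
```

Stage 4 shows the coupled-mode structure: the leading PM2.5–SO2 mode
carries 93.7% of the squared covariance and clears its permutation
bound, while no PM2.5–NO2 mode does:

```
PM25 ~ SO2: SCF = 93.7% 5.6% 0.4% 0.2%   95% UPCI = 92.5% ...  significant modes: 1
PM25 ~ NO2: SCF = 74.8% 12.2% 6.0% 2.9%  95% UPCI = 81.1% ...  significant modes: (none)
```

Stage 5 fits the attribution model (R² = 0.773, n = 96 semi-months):
SO2_PC1 dominates the LMG decomposition (0.69 of the 0.77 total) and is
the only strongly significant regressor; the largest VIF is 1.10, far
below the collinearity threshold of 10:

```
 regressor coefficient  p_value  vif     lmg    l_spr   f_spr
   SO2_PC1      5.8463 6.08e-28 1.10 0.69125 0.627810 0.75420
   SO2_PC2      0.0902 8.03e-01 1.05 0.00104 0.000156 0.00188
   NO2_PC1     -0.3260 3.69e-01 1.06 0.02750 0.002031 0.05317
   NO2_PC2     -0.9183 1.43e-02 1.10 0.05324 0.015555 0.09079
```

The same chain runs as one call from a nested config:
`run_pipeline(list(seed = 1), "outdir")`.

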