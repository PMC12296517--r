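# plvnet

Event-related phase-locking network analysis for epoched EEG, built for
pre-cued reaction-time (CNV-type) paradigms: a warning stimulus S1 cues a
lateralized response to an imperative stimulus S2 presented 3.2 s later,
and the question is how transient theta-band (4–7 Hz) phase
synchronization between scalp regions — and the networks it forms —
differs between groups and predicts behavior. The package is aimed at
EEG researchers who have cleaned, epoched (ideally CSD-transformed)
recordings and want a tested, reproducible path from trials to
group-level network statistics, plus a ground-truth simulator to validate
that path.

## What it computes

For channels $i, j$ with instantaneous Morlet phases
$\varphi_i(t, n)$ over trials $n = 1..N$:

* **PLV** — phase-locking value,
  $\mathrm{PLV}_{ij}(t) = \left|\frac1N \sum_{n=1}^{N}
  e^{-\mathrm i\,(\varphi_i(t,n)-\varphi_j(t,n))}\right| \in [0, 1]$;
* **rPLV** — event-related change relative to the pre-S1 baseline mean
  $\bar b$: $\mathrm{rPLV}_{ij}(t) = (\mathrm{PLV}_{ij}(t) - \bar b)/\bar b$,
  computed per 1-Hz bin and averaged over the band;
* **ROI networks** — 465 electrode pairs averaged into a symmetric 6×6
  area matrix (DLPFC, SMA/PMA, M1, S1, PPC, POC) with 21 unique features;
* **graph summaries** — global efficiency
  $E_\mathrm{glob} = \frac{1}{N(N-1)}\sum_{i\ne j} 1/L_{ij}$ and the
  average clustering coefficient $C = \frac1N \sum_i C_i$ on the
  windowed rPLV graph (binary and weighted modes);
* **group layer** — Euclidean distance between group-mean network
  vectors over time, PCA of connectivity patterns, 100-fold
  cross-validated LDA (2 held out, training-set z-scoring, top-10
  ANOVA-F features) with a label-shuffled control, pointwise increase
  maps, Mann-Whitney U contrasts (U, Z, p, r = |Z|/√N) with
  Benjamini-Hochberg correction, behavioral summaries with 150/1500 ms
  RT filters, and efficiency–RT regressions.

A synthetic-cohort generator (hierarchically coupled von Mises phase
oscillators, 1/f noise, behavioral logs tied to the injected coupling)
provides data with known ground truth for all of the above.

## Worked example

```r
library(plvnet)

cfg <- cohort_config(n_per_group = 20, group_deficit_s1 = 0.6,
                     epoch_span = c(-3700, 1100), seed = 1001)
cohort <- generate_cohort(cfg)
analysis <- analyze_cohort(cohort,
                           windows = list(S1 = c(-3200, -2700),
                                          S2 = c(0, 500)),
                           sample_step = 5)

compare_groups(analysis, "mean_rplv")
#>   window   measure median_ts    iqr_ts median_co    iqr_co   u         z
#> 1     S1 mean_rplv 0.9879843 0.2739931  1.420974 0.2356306  31 -4.571465
#> 2     S2 mean_rplv 1.5301564 0.2935988  1.426114 0.1503040 265  1.758256
#>              p         r        p_fdr
#> 1 5.023703e-07 0.7228121 1.004741e-06
#> 2 8.097631e-02 0.2780046 8.097631e-02
```

The TS group's median network rPLV after S1 is visibly reduced (0.99 vs
1.42, U = 31, p ≈ 5e-7) — the injected post-S1 coupling deficit — while
the post-S2 window, which carries no deficit, shows no significant group
difference. The same object feeds the graph metrics and classifier:

```r
grp <- factor(analysis$groups, levels = c("TS", "CO"))
fit  <- lda_cv_classify(analysis$features[, , "S1"], grp, seed = 2)
shuf <- lda_cv_classify(analysis$features[, , "S1"], grp, shuffle = TRUE,
                        seed = 2)
round(100 * c(fitted = fit$mean_accuracy, shuffled = shuf$mean_accuracy))
#>   fitted shuffled
#>       76       47
```

The fitted classifier separates the groups well above the shuffled
control's chance level. `run_study(cfg)` wires the whole chain —
simulation, connectivity, contrasts, classification, efficiency–RT
regressions — into one call.

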