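# octafd

Fractal-dimension vessel density analysis for en-face OCTA angiograms.

Optical coherence tomography angiography (OCTA) maps retinal blood flow
without contrast injection. In systemic inflammatory disease (the motivating
setting is rheumatoid arthritis), macular capillary dropout is subtle,
regional and layer-specific. `octafd` is for researchers who want to turn
6 × 6 mm en-face macular scans of two cohort groups into per-region vessel
densities and group statistics, and for methodologists who want a fully
synthetic, ground-truthed test bed for that measurement chain.

## What it computes

The density metric is the **box-counting fractal dimension** of the
binarized vessel mask. Tiling a region with boxes of side ε and counting
occupied boxes N(ε), a vascular bed follows N(ε) ∝ ε^(−D_f), and

    D_f = log N(ε) / log(1/ε)

is estimated as the OLS slope of log N vs log(1/ε) over a geometric box
schedule. D_f runs from ~1 (sparse, line-like) to 2 (plane-filling); healthy
perifoveal plexuses sit near 1.7–1.8.

The pipeline around it:

1. **Preprocess** — nonlocal-means denoising; Otsu (or fixed) binarization
   into a total vessel mask (TMI); caliber separation into microvascular
   (MIR) and macrovascular (MAR) masks via skeleton + distance-transform
   diameters (an exact pixel partition of TMI).
2. **Partition** — three ROI schemes about the fovea, in mm coordinates:
   ETDRS quadrants (S, I, L, R; diagonal boundaries), hemispheric quadrants
   (SL, SR, IL, IR; horizontal/vertical boundaries), and six central annuli
   C1–C6 between the 0.6 mm foveal avascular zone and a 2.5 mm circle
   (ring width ≈ 0.158 mm), plus a global annulus.
3. **Densities** — D_f per eye × layer (SRL/DRL) × mask kind × region,
   assembled into a long-format density table.
4. **Statistics** — pooled t-tests per region, ROC AUC with DeLong 95% CI
   (oriented so lower density in disease gives AUC > 0.5), demographics
   table, and the conjunctival-vs-superficial-TMI Pearson correlation.
5. **Synthetic cohorts** — a generator of branching-tree angiograms with a
   controllable avascular zone, caliber mix, regional density deficits and
   a conjunctival copula, with per-eye ground truth written alongside.

## Worked example

Simulate the emulated study design — 12 subjects × 2 eyes per group, a 40%
micro-branch deficit confined to the superior (S) ETDRS quadrant of the
disease group — and run the analysis:

```r
library(octafd)

cfg <- synth_config(n_per_group = 12, layers = "SRL", seed = 42,
                    regional_effects = c(S = 0.6))
coh <- synth_cohort(cfg)
tab <- build_density_table(coh$manifest, images = coh$images)
cmp <- compare_all_regions(tab)
subset(as.data.frame(cmp), scheme %in% c("GLOBAL", "ETDRS"),
       select = c(mask_kind, region, mean_control, mean_disease, t, p, auc))
```

```
   mask_kind region mean_control mean_disease       t        p   auc
7        TMI      I         1.62         1.65 -1.2999 2.00e-01 0.375
8        TMI      L         1.65         1.62  1.2370 2.22e-01 0.590
9        TMI      R         1.65         1.68 -1.4408 1.56e-01 0.380
10       TMI      S         1.69         1.51  6.8568 1.49e-08 0.922
11       MAR    ALL         1.30         1.30  0.0473 9.62e-01 0.519
12       MIR    ALL         1.68         1.66  3.8823 3.29e-04 0.780
13       TMI    ALL         1.74         1.72  5.9004 4.08e-07 0.896
```

Reading the output: the deficit was imposed only in S, and only S is
significant among the quadrants (density 1.69 → 1.51, p ≈ 1.5e-8,
AUC 0.92), while the global TMI and MIR densities drop slightly
(S is part of the annulus) and the macrovessel (MAR) density is untouched —
the qualitative signature the pipeline is designed to detect. The
conjunctival correlate:

```r
correlation_summary(tab, coh$manifest)
#              x       y     r       p  n
# 1 conj_density STMI_df 0.401 0.00478 48
```

`run_pipeline(cohort_dir, out_dir)` wraps all of this and writes the
density table, per-layer comparison tables, ROC summary and curve points,
demographics, correlation, a log and a YAML run-record; a thin CLI wrapper
lives at `inst/scripts/octafd.R` (`synth` and `run` subcommands). See the
methods vignette (`vignettes/octafd-methods.Rmd`) for the model, parameter
rationale and the generator's scope.

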