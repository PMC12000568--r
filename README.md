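# metabomat

Natural rubber (NR) is made from *Hevea brasiliensis* latex, and the
metabolites carried along with the rubber particles — sugars, amino acids,
organic acids, fatty acids, nucleotides — change with the season and with
them the material behaviour of the finished rubber. `metabomat` is an R
package for the integrated analysis of a latex **metabolome table**
(9 monthly samples × ~400 annotated metabolite peaks) against a **property
table** (vulcanization, tensile, and heat-aging characterization of rubber
made from the same latexes). It answers, in order:

1. **Which metabolites are seasonal?** Detection accounting per sample and
   season, Jaccard concordance between monthly detection sets, and a
   dry-vs-rainy 2-fold screen where each call carries an *exact* one-tailed
   Mann–Whitney p-value (full enumeration of the C(9,3) = 84 group
   assignments at the 6-vs-3 design).
2. **How does the metabolome correlate with the properties?** A Spearman
   correlation matrix (metabolites × measurement items) with hierarchical
   clustering, and a per-metabolite Kruskal–Wallis contrast of its
   coefficients across the three property families (n = 30, 14, 34 items).
3. **How many metabolites explain each property?** Three regression models
   per measurement item, scored by leave-one-out cross-validation with
   errors normalized by the response IQR (RMSE/IQR; with one held-out
   sample per fold this is the normalized absolute error):
   * the **simple-regression best model** — best single metabolite;
   * the **forced-entry model** — all p ≈ 400 metabolites at once, fitted
     by minimum-norm least squares (SVD pseudo-inverse), which interpolates
     the 9 training points exactly and therefore cannot win out-of-sample;
   * the **sequential selection model** — sequential forward floating
     selection (SFFS): forward steps add the metabolite minimizing the
     leave-one-out RMSE of the subset fit, floating backward steps remove
     members whose removal improves the best-known score at the smaller
     size, stopping at 10 selections.

   A convergence curve (LOOCV error vs number of selected metabolites)
   shows at what complexity each item stops improving, and a one-tailed
   Mann–Whitney test (9 vs 9 fold errors, exact) compares models.
4. **Are the selected metabolites structurally diverse?** Top-5 selection
   overlap counting per property group, then circular (Morgan/ECFP4,
   4096-bit) fingerprints embedded in 2-D with UMAP (n_neighbors 3,
   min_dist 0.5, manhattan, fixed seed) against a bundled background
   compound library, with per-axis rank tests and per-item SD ratios
   (SD_SS/SD_all).

A first-class synthetic-data generator (`synthetic_scenario()`,
`generate_metabolite_matrix()`, `generate_properties()`) plants known
seasonal fold changes, detection dropout, and sparse linear property
supports, so the full pipeline is testable end-to-end with no instrument
data. See `vignettes/metabomat-methods.Rmd` for the model assumptions,
parameter choices, and known limitations (in particular the discussion of
selection information leakage at n = 9).

## Worked example

```r
library(metabomat)

paths <- make_demo("demo_run", seed = 1)      # writes TSV inputs + config
m <- read_metabolite_table(paths$metabolites, paths$sample_metadata)
p <- drop_empty_items(read_property_table(paths$properties,
                                          paths$property_groups))$table
m
#> <metabolite_table> 9 samples x 400 metabolites; 274 non-detects; seasons: dry=3, rainy=6
p
#> <property_table> 9 samples x 78 items (heat_aging=34, tensile=14, vulcanization=30)

scr <- seasonal_screen(m, threshold = 2)
scr
#> <seasonal_screen> threshold 2x: 20 up, 7 down (dry vs rainy) of 400 metabolites
round(range(scr$concordance[upper.tri(scr$concordance)]), 2)
#> [1] 0.82 0.91
```

The scenario behind this demo plants 22 up- and 4 down-regulated
metabolites with a 3-fold seasonal effect plus 7.5% detection dropout; the
screen reports 20/7 because dropout knocks two planted effects under the
threshold and pushes a few null metabolites past it — exactly the
distortion the non-detect policy section of the vignette discusses (with
`dropout_rate = 0` the screen recovers 22/4 exactly).

```r
mi <- apply_nondetect_policy(m, "zero")
cx <- model_complexity(mi, p, analysis_config(),
                       items = c("vul_01", "ten_01", "age_01"))
cx
#> <complexity_result> 3 items (whole_data selection); sequential model beats simple-best (p<0.05) for 3 items
round(cx$per_item$vul_01$convergence$median_error, 3)
#>  [1] 0.593 0.228 0.081 0.023 0.007 0.001 0.000 0.001 0.001 0.003
signif(vapply(cx$per_item, `[[`, 0, "p_value"), 2)
#>  vul_01  ten_01  age_01
#> 2.1e-05 2.1e-05 2.1e-05
```

Each item was generated from 3 planted metabolites, and the convergence
curve flattens after roughly that many selections; 2.1e-05 = 1/48620 is the
smallest p-value an exact 9-vs-9 one-tailed Mann–Whitney test can produce —
the sequential model's nine fold errors all lie below the simple-best
model's.

`run_pipeline(paths$config, "out_dir")` runs every stage in sequence
(seasonal → correlation → complexity → overlap → diversity) and writes the
TSV report bundle plus a JSON manifest with input/output digests for
reproducibility.

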