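---
title: "Methods: linking the latex metabolome to natural-rubber properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking the latex metabolome to natural-rubber properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Natural rubber (NR) is produced from *Hevea brasiliensis* latex, and its
material quality varies with the season because the latex's non-rubber
components — among them hundreds of small-molecule metabolites — vary with
temperature and water stress. `metabomat` implements an integrated analysis
that takes a samples × metabolites relative-abundance table (from annotated
CE-TOFMS / LC-TOFMS peaks), a samples × measurement-items property table
(vulcanization, tensile, and heat-aging characterization of rubber made from
the same latexes), and a metabolite annotation table, and asks three
questions:

1. Which metabolites change between the rainy and the dry season, and by how
   much?
2. How is the metabolome correlated with the measured rubber properties, and
   do those correlations differ between the three property families?
3. How many metabolites are needed to explain each measured property — one,
   a handful, or all of them?

A design constraint shapes every method choice: a monthly sampling campaign
yields on the order of *nine* samples against ~400 metabolites and ~80
measurement items. Everything below is built for that regime.

## Data model and standardization

Non-detected peaks are missing values, not zeros, until a policy is applied
(`apply_nondetect_policy()`): `zero` (default — keeps presence/absence
information as low abundance and retains every metabolite), `half_min`
(half the metabolite's minimum detected value, a limit-of-detection
surrogate), or `drop_metabolite` (restrict to the complete-detection
subset). The default is a genuine choice, not a fact about the data: with
9 samples there is no basis for imputation models, and dropping incomplete
metabolites would discard roughly half the metabolome. Both alternatives
are one argument away.

`standardize()` z-scores each column with the *population* SD (divide by
n). The sample-SD convention differs by a single factor per column and
changes no rank, correlation, or model selection; population SD is used
consistently so that SD ratios in the diversity stage are internally
coherent.

Sample order is the canonical join key between the metabolite and property
tables; mismatched sample sets raise an error rather than silently
intersecting.

## Seasonal screen

`detection_counts()` reports the campaign-level accounting (detected in at
least one sample, throughout each season, in all samples, in only one
season). `concordance_rate()` is the Jaccard index of two samples'
detection sets — symmetric and bounded in [0, 1]; an overlap-coefficient
alternative is available behind the `method` argument since the literature
does not standardize this quantity.

`seasonal_screen()` computes per-metabolite season means under the active
non-detect policy, the dry/rainy fold change, and direction calls at a
2-fold threshold. Metabolites entirely absent in one season are flagged
`presence_only` and excluded from the quantitative calls — an infinite or
zero ratio would otherwise pass any finite threshold and the screen would be
dominated by detection dropout rather than abundance change.

Each screened metabolite carries a one-tailed Mann–Whitney p-value testing
the direction observed in its fold change. `mann_whitney_one_tailed()` is
exact by full enumeration of all C(m+n, n) group assignments of the pooled
mid-ranks whenever m + n ≤ 18 — which covers both the 6-vs-3 seasonal
comparison (84 assignments) and the 9-vs-9 model comparison (48,620) — and
remains exact under ties because mid-ranks are enumerated. Beyond that it
falls back to the tie-corrected normal approximation with continuity
correction. No multiple-testing correction is applied by default (raw
p-values are reported alongside the fold-change criterion, which is the
primary filter); `stats::p.adjust` composes trivially for users who want
BH-adjusted values.

## Correlation structure

Spearman rank correlation is used between every metabolite and every
measurement item because several items are visibly non-normal; pairs with
fewer than three complete observations are set to missing and logged. The
heatmap ordering comes from agglomerative clustering with distance
1 − Pearson correlation between coefficient profiles and average linkage —
the common correlation-heatmap convention; the matrix itself is never
altered, and missing coefficients are imputed as 0 (neutral) for distance
computation only.

Whether a metabolite relates differently to the three property families is
tested per metabolite with a Kruskal–Wallis contrast of its correlation
coefficients across the vulcanization / tensile / heat-aging groups
(tie-corrected H, upper-tail chi-square p — the test is inherently
one-sided toward large H). When all coefficients are identical the
convention H = 0, p = 1 applies. Metabolites significant at raw p < 0.05
are re-clustered and cut into two major groups.

## Model complexity: three regression families under LOOCV

Per measurement item, three linear models are compared:

* **simple-regression best** — the single metabolite with the smallest
  training RMSE (ties broken by column order);
* **forced entry** — all metabolites at once. With p ≈ 400 ≫ n = 9 this
  system is underdetermined, so the fit is the *minimum-norm* least-squares
  solution via the SVD pseudo-inverse of the intercept-augmented design. It
  interpolates the training data exactly (residuals ≈ 1e−15), which is
  precisely why it cannot win out of sample;
* **sequential selection** — sequential forward floating selection (SFFS):
  forward steps add the candidate that minimizes the selection criterion,
  floating backward steps remove any member whose removal strictly improves
  on the best-known criterion value at the resulting size, stopping at
  `sffs_k` (default 10) selections.

**Selection criterion.** The criterion is the leave-one-out RMSE of the
candidate subset's OLS fit, computed exactly via the hat-matrix identity
e_loo = e/(1 − h) (one fit per candidate), with an explicit minimum-norm
leave-one-out loop when the subset is rank-deficient. Plain training error
is offered (`criterion = "training"`) but is not the default for two
structural reasons: removing a feature can never improve a nested
least-squares fit, so a training-scored floating phase would never fire;
and with 8 training points the training error of any 8-feature subset is
exactly zero, making further selection arbitrary. Under the cross-validated
criterion both the floating removals and selection beyond n features remain
meaningful.

**Scoring.** Errors are normalized by the interquartile range of the full
response (linear-interpolation quantiles), so the nine leave-one-out fold
values of one item share a normalizer and are comparable; with a single
held-out sample the fold RMSE reduces to the absolute error, which is why
nine un-averaged RMSE/IQR values per item are reported rather than one
mean.

**Selection scope — an honest caveat.** By default
(`selection = "whole_data"`) the SFFS runs once per item on all nine
samples, and cross-validation then refits only the coefficients — the
procedure that produces the characteristic result that the sequential model
beats the simple-best model for essentially every item. That advantage is
real as a description of the fitted models but is driven largely by
selection information leakage: the feature choice has seen every sample,
including each held-out one. The package also implements
`selection = "per_fold"`, where the entire SFFS reruns inside every
training fold. At the study's design size (9 samples, hundreds of
candidates) the sequential advantage disappears in that mode — spurious
correlations of ~0.8 among hundreds of candidates at n = 8 swamp marginal
screening, and the planted support of simulated items is rarely recovered.
Simulations in the test suite quantify both regimes. Users should read
whole-data fold errors as *descriptive* model comparison, not as unbiased
generalization estimates.

**Convergence.** `convergence_curve()` cross-validates the selection
truncated at k = 1…`sffs_k` and reports the median normalized error per k.
Where the support is identifiable (more samples than the monthly campaign
provides — the test suite uses 30 samples × 50 candidates with 5 planted
predictors), the honest per-fold curve flattens at the planted size: the
median improvement from k = 5 to k = 10 is below 5% (usually negative).
This is the package's quantitative version of "about five metabolites
suffice".

## Overlap and chemical-space diversity

`overlap_count()` takes the first `top_k_overlap` (default 5) selections of
each item in SFFS order and counts, within each property group, how often
each metabolite appears; ties for the maximum are all reported.

For structural diversity, annotated metabolites are fingerprinted with
folded circular substructure (Morgan/ECFP) bit vectors — radius 2, 4096
bits, the ECFP4-equivalent convention — computed by the Open Babel
`obabel` executable in one batch subprocess per call (metabolites without a
SMILES are skipped, mirroring compounds without database identifiers).
Latex metabolites plus a background draw from the bundled compound library
are embedded together in 2-D with UMAP (n_neighbors 3, min_dist 0.5,
manhattan metric, fixed random_state 42, single-threaded so repeated runs
are bit-identical). Per embedding axis, a two-tailed Wilcoxon rank-sum test
compares latex metabolites with the background; the draw is repeated three
times with independent seeds. Selection diversity is the per-axis ratio of
population SDs, SD_SS / SD_all, of the selected subset's coordinates
against all embedded latex metabolites — exactly (1, 1) when the subset is
the full set, and invariant to rigid translation and per-axis scaling of
the embedding.

The bundled library (`inst/extdata/synthetic_compound_library.smi`) is a
*synthetic* stand-in for a random sample of a public compound database: ~1250
drug- and metabolite-like molecules enumerated programmatically from
scaffold × substituent combinations, validated and canonicalized with Open
Babel. It ships with the package so the diversity stage needs no network
access; the default background draw is 1000 compounds (bounded by the
library size), repeated three times.

## The synthetic-data generator

`synthetic_scenario()` encodes the study conditions the analysis assumes:

* 9 monthly samples, May through January — 6 rainy, 3 dry (the
  savannah-climate convention: November–February is the dry season);
* ~400 metabolites with log-normal (multiplicative) noise at 10% CV —
  relative MS peak areas are scale-free, so noise is multiplicative on the
  mean;
* 22 metabolites planted up and 4 down in the dry season with a 3-fold mean
  ratio. The fold is planted at 3 rather than at the screen's own threshold
  of 2 because a "more than two-fold" effect planted exactly at 2.0 sits on
  the decision boundary and is recovered by a 2× screen only half the time;
  3-fold gives the screen a recoverable truth while remaining a realistic
  seasonal effect size;
* per-cell detection dropout at rate 0.075, chosen so that the probability
  a metabolite is detected in all nine samples is 0.925⁹ ≈ 0.5 — matching
  campaigns where about half the metabolome misses at least one sample.
  Dropout is independent Bernoulli per cell; the generator does not emulate
  season-*specific* presence/absence (real campaigns show metabolites
  detected in only one season, which uniform dropout essentially never
  produces), nor chromatographic drift or batch effects — a passing test
  therefore says nothing about robustness to those;
* measurement items in groups of 30 / 14 / 34 (vulcanization / tensile /
  heat-aging, the post-exclusion design), each a linear combination of 3
  standardized planted metabolites with coefficients of magnitude 1–2 and
  Gaussian noise of SD 0.1 on the standardized scale.

All randomness derives from one scenario seed through per-stage hashes, so
adding a stage never perturbs earlier stages' draws, and the full pipeline
is byte-reproducible from the seed.

One generator property deserves a note: with 6-vs-3 samples at 10% CV, the
*empirical* dry/rainy mean ratio of a planted 2-fold metabolite has a
sampling SD of about 0.14 on the ratio scale, so requiring the observed
ratio to fall within [1.8, 2.2] would fail ~18% of the time at this design
for purely statistical reasons. The generator's fidelity is therefore
verified at 60 rainy / 30 dry samples, where sampling noise no longer masks
the planted multiplier; at that size ≥95% of planted ratios land within
±10% of the target.

## Problem sizes used in tests and the acceptance script

Simulation checks run at deliberately modest sizes chosen to make each
property identifiable rather than to stress hardware: the screen-recovery
scenario uses 400 metabolites × 9 samples; model-comparison simulations use
100 metabolites × 9 samples with 3 planted predictors over 50 seeds;
convergence uses 30 samples × 50 candidates with 5 planted predictors over
10 items; the diversity stage embeds ~375 annotated metabolites with a
1000-compound background three times. A full pipeline run at these sizes
completes in a few minutes on one core.

## Known limitations

* Nine samples is the central limitation: every inferential statement
  downstream of the screen is descriptive of the fitted models, not a
  generalization claim (see the selection-scope caveat above).
* The Kruskal–Wallis contrast treats an item's correlation coefficients as
  exchangeable observations within a property group; items within a group
  are in fact correlated, so its p-values are optimistic and are best used
  as a ranking device.
* UMAP coordinates are reproducible only for a fixed library version; the
  run manifest records package versions for that reason.
* The fold-change screen with the `zero` policy mixes abundance change with
  detection change; the `presence_only` flag separates the extreme case,
  but partial dropout still biases fold changes toward extremes. The
  `half_min` policy damps this at the cost of an arbitrary imputation
  constant.
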