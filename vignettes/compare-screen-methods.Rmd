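---
title: "Linking drug response to expression profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking drug response to expression profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compareScreen)
```

## The scientific problem

Large drug screens measure, for each compound, a potency profile: one
log10 IC50 value (log10 molar; more negative = more potent) per cell line
of a fixed panel, classically the NCI-60 panel of 60 human tumor lines
spanning 9 tumor types. Two questions recur:

1. **Cross-resistance.** Do lines resistant to one compound tend to resist
   another? Quantified by the Pearson correlation of the two compounds'
   log10 IC50 profiles across the panel; consistently high positive r
   within a compound class suggests a shared resistance mechanism.
2. **Molecular determinants of response.** Which genes' constitutive mRNA
   expression tracks a compound's potency profile? The COMPARE procedure
   ranks every probe by the correlation of its expression profile with the
   compound's log10 IC50 vector. Positive coefficients (high expression
   where the drug is *least* potent) flag resistance candidates — the
   *standard* list; negative coefficients flag sensitivity candidates —
   the *reverse* list. Clustering the cell lines on the candidate genes and
   testing cluster membership against a sensitive/resistant dichotomy asks
   whether the expression profile as a whole *predicts* response.

`predict_response()` composes the whole chain: COMPARE ranking, candidate
filtering, z-standardization, complete-linkage clustering,
median dichotomization, and a chi-squared association test.

## Statistical components and their assumptions

### Correlation kernel

All correlations — compound versus compound, probe versus compound — go
through one kernel, `pearson_cor()`: the product-moment r over
pairwise-complete observations, with a two-sided p-value from the
t distribution with n − 2 degrees of freedom. Pearson rather than rank
correlation because the inputs are interval-scaled measurements, not
equidistant ranks. Pairwise-complete (not listwise) handling means each
pair of variables uses every line observed for both, so per-pair n can
differ across a table; each result reports its own `n_pairs`. Fewer than
`min_pairs` (default 3) complete pairs, or a constant input, yields a
*missing* result with a reason flag — never r = 0, which would silently
distort rank statistics downstream. The convention p ≤ 0.05 marks a cell
significant; rendered tables print `n.s.` otherwise.

### Cross-resistance calls

`cross_resistance()` computes the full compound-by-compound grid and flags
a pair as cross-resistant when **both** |r| > `threshold` (default 0.6)
and p ≤ 0.05. The |r| bar is the screening field's customary emphasis
threshold for "consistent" cross-resistance; the significance condition
keeps small-n pairs from being flagged on magnitude alone. No
multiple-testing correction is applied across the grid — these tables are
descriptive screens, not confirmatory tests, and correcting would change
the published convention the package reproduces.

### COMPARE ranking

`run_compare()` applies the kernel probe-wise against one compound's
log10 IC50 vector and ranks by descending r, ties broken lexicographically
by probe id so results are reproducible. "Similarity of expression to the
potency profile" is implemented as plain Pearson correlation on the
analysis-scale values; expression input is assumed to be already on the
scale the analyst wants correlated (the package performs no normalization
or log transform — see Limitations). The candidate threshold (default
|r| > 0.6, applied symmetrically to both signs) can be re-applied with
`filter_candidates()` without recomputing: a larger threshold always
selects a subset of a smaller one's lists.

### Clustering recipe

Cell lines are clustered on the candidate-gene submatrix in three steps:

1. **Standardization** (`standardize_matrix()`): each gene to mean 0,
   variance 1 over its non-missing values, using the sample (n − 1)
   standard deviation. The n vs n − 1 choice only rescales all distances
   by a common factor and cannot change the dendrogram topology.
   A constant gene is an error naming the gene, not a silent drop.
2. **Distance** (`profile_dist()`): Euclidean distance between line
   profiles over the coordinates both lines observe, rescaled by
   sqrt(m / m_shared) where m is the total gene count. Missing values are
   thus omitted while the magnitude is corrected for the number of data
   points actually available; with no missingness this is exactly the
   plain Euclidean distance. Euclidean is the standard companion to
   z-standardization and the default of the desktop statistics programs
   this style of screen analysis historically used.
3. **Complete linkage** (`complete_linkage()`): agglomerative clustering
   with inter-cluster distance = maximum pairwise member distance, which
   guarantees non-decreasing merge heights. Equal-distance merge
   candidates are resolved deterministically in favor of the pair whose
   clusters contain the smallest (first, second) original object indices;
   any fixed rule would do statistically, but a stated one makes runs and
   tests exactly reproducible, including under input permutation.

`cut_tree(tree, k)` removes the k − 1 highest merges and numbers the flat
clusters by first appearance in input order.

### Response association

`dichotomize()` splits lines at a log10 IC50 cut-off, by default the
median of the non-missing values (midpoint convention for even counts).
Sensitive is *strictly* below the cut-off; a line exactly at the cut-off
is resistant. The boundary had to be assigned to one side; putting
equality with the resistant class keeps "sensitive" the strict claim.
Lines with missing response are unclassified and excluded downstream —
cross-tabulations therefore report their own grand total rather than
forcing the panel size (the shipped published table classifies 59 of 60
lines).

`chi_square()` computes the plain Pearson statistic: expected counts from
the row/column margins, sum of (O − E)²/E, upper-tail p from the
chi-squared distribution with (rows − 1)(columns − 1) degrees of freedom.
**No Yates continuity correction and no exact test**, although expected
counts below 5 do occur in k × 2 tables on 60 lines (such cells are
flagged in the output). The plain statistic is what this analysis
tradition computes, and it is what reproduces the published association
(chi-squared = 14.71, df = 3, p = 0.00208 on the shipped table); an
asymptotic caveat applies and the flags make it visible.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `threshold` (COMPARE / cross-resistance) | 0.6 | r | the field's customary cut-off for candidate genes and cross-resistance emphasis |
| `k` (flat clusters) | 4 | — | the published response-association table uses four clusters; the upper tree may still show fewer major branches, so k is exposed rather than inferred from the dendrogram |
| `cutoff` (sensitivity) | median | log10 M | median dichotomization is the published rule; any absolute cut-off can be supplied (the published screen used −6.5) |
| `min_pairs` | 3 | lines | below 3 complete pairs a correlation is statistically meaningless |

## What the synthetic generator emulates

`simulate_response()` draws log10 IC50 values from a single-latent-factor
model per compound family: value(c, d) = mu_d + lambda_F · f_c + noise,
with f_c ~ N(0, 1) per line and family, mu_d ~ U(−7.5, −4.5) so values
center in the −8 to −4 window of a 1e-8 to 1e-4 M dosing design, and
Gaussian residual noise (default SD 0.5 log10 units). A one-factor model
is the simplest mechanism producing the block-correlation pattern that
pairwise cross-resistance tables show; the theoretical within-family
correlation is lambda²/(lambda² + sigma²), 0.7 at the defaults — chosen
once to represent the strong within-class cross-resistance regime the
analysis is meant to detect. Panels are assigned round-robin with no
panel effect by default (`panel_shift` can make the first panel uniformly
more sensitive, mimicking the leukemia-line sensitivity real screens
show).

`simulate_expression()` plants genes with a chosen sign and target
correlation rho against one compound's standardized potency vector
(loading a = rho·sigma_e/sqrt(1 − rho²) makes the population correlation
exactly ±rho) among independent standard-normal background genes.
Defaults — 60 lines, 2000 background genes, 20 planted at rho = 0.8 —
are the study conditions under which the package's operating
characteristics are measured. Gaussian noise throughout keeps the Pearson
machinery exact and closed-form checks available.

The generator deliberately does **not** simulate probe-level microarray
artifacts, batch effects, panel-specific expression signatures, or
realistic gene–gene co-expression. Passing tests on synthetic data
therefore demonstrate the *statistical machinery* — recovery of planted
signal, calibration under the null — not robustness to the correlated
noise structure of real microarray data, where effective candidate counts
and cluster stability will be less favorable.

Determinism: every generator is seeded; `simulate_expression()` uses the
configuration seed + 1 so the expression stream never reuses the response
stream's draws.

## Null calibration of the pipeline

The type-I error of `predict_response()` is measured on the null
generator (no planted genes, lambda = 0) with **threshold 0**, i.e. no
candidate filtering: cluster structure is then independent of the
response, and over 400 seeded replicates the rejection rate at
alpha = 0.05 stays within the binomial band around 5% (slightly
conservative, as expected with small expected counts in k × 2 tables on
60 lines). This is the only regime in which the null calibration is
well-defined: at any positive threshold, the genes used for clustering
are selected *because* they correlate with the response in-sample, so
cluster membership is tied to the response by construction even under the
null. Users of the default threshold 0.6 should read the chi-squared
p-value as descriptive of the selected-gene clustering, not as a
selection-adjusted test — the same caveat applies to the published
analysis this package reimplements.

Monte-Carlo problem sizes used by the test suite and the acceptance
script — 50 seeds for planted-gene recovery at the full 2000-background
default, 400 seeds at 200 background genes for the null rate — were chosen
to put the binomial/sampling error of each estimate comfortably inside
the margins being asserted.

## Degenerate inputs and numerical choices

* Correlations clamp |r| to 1 against floating-point overshoot; |r| = 1
  reports p = 0.
* Missing-value vocabulary in delimited input: empty cell, `NA`, `NaN`,
  `n.s.` (case-insensitive). Anything else non-numeric is a hard error
  with row/column coordinates.
* A probe/gene pair sharing no observed line has a missing distance;
  clustering then stops with advice to impute or drop rather than
  guessing.
* All-zero rows of a contingency table are dropped with a warning
  (degrees of freedom adjust); a table left with a single row or column
  is an error.
* Response values outside \[−10, −2\] log10 M only warn — they usually
  indicate a unit mix-up, but extreme tails of a legitimate screen can
  reach them.

## Known limitations

* Expression values are used as given; whether they should be
  log-transformed first is the analyst's call, made upstream.
* No multiple-testing correction across COMPARE's thousands of probes;
  the |r| threshold plays that role informally, as it does in the
  published analyses this package follows.
* The chi-squared test is asymptotic; with 60 lines and k = 4, expected
  counts below 5 are routine and flagged, but no exact test is offered.
* Only complete linkage is implemented; single/average/Ward variants and
  bootstrap cluster stability are out of scope.

## Worked example

```{r example}
cfg <- sim_config(n_background = 200, seed = 42)
resp <- simulate_response(cfg)
sim <- simulate_expression(cfg, resp, "withanolide_1")
fit <- predict_response(sim$expression, resp, "withanolide_1")
summary(fit)
```

The planted structure is strong by design, so the candidate lists recover
the 20 planted genes and the cluster-versus-response association is
overwhelming. The shipped published candidate table shows the same
machinery on real screen output:

```{r published}
chi_square(withaferin_contingency())
nrow(withaferin_candidates())
```
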