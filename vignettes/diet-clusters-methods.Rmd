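---
title: "Methods: diet clusters, footprints and transition scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet clusters, footprints and transition scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshift)
```

## What the package models

`dietshift` implements a complete analysis chain for linking habitual dietary
intake (ingredient-level g/day, as derived from food-frequency
questionnaires) to multi-indicator environmental footprints and diet
quality, and for identifying *self-selected* diet patterns in a population:

1. **Footprint accounting.** Each person's daily impact in category $c$ is
   the linear form $y_{ic} = \sum_f x_{if}\, \phi_{fc}$, where $x_{if}$ is the
   intake of food $f$ (g/day) and $\phi_{fc}$ the per-gram characterization
   factor. Four ReCiPe-style midpoint categories are carried: global warming
   potential (kg CO$_2$-eq/day), land use (m$^2$ annual-crop-eq/day), and
   marine and freshwater eutrophication (g N-eq and g P-eq/day).
2. **Country adaptation of factors.** Foods with an import/export mass ratio
   above one are treated as imported and valued with a European electricity
   mix; a ratio of one or below means domestic production and the domestic
   mix (the boundary is domestic because importing requires a ratio
   *strictly* greater than one). The adaptation acts on characterized
   impacts: an additive electricity-share correction plus a multiplicative
   feed-origin factor for livestock foods. Process-level life-cycle
   inventories are out of scope; the rule logic (who gets which mix) is
   preserved at the impact level, which keeps the step testable with plain
   tables.
3. **Diet quality.** A modified Baltic Sea Diet Score with eight components:
   seven scored 0–3 by sex-specific quartile (fruits & berries, vegetables,
   whole grains, low-fat milk, fish, the PUFA/(SFA+trans) ratio upward; red
   & processed meat reversed) and an alcohol point (intake at or below
   10 g/day for women, 20 g/day for men), total range 0–22. The component
   point allocation is a reconstruction consistent with the published range
   and component list; externally supplied cut points are accepted where
   fidelity to the original score definition matters. Quartiles are
   right-closed (ties fall to the lower bin) and survey-weighted by default.
4. **Energy adjustment and standardization.** Every analysis variable is
   replaced by its weighted-least-squares residual on total energy plus the
   value predicted at the weighted mean energy (the classical residual
   method; the added constant keeps original units and typical magnitudes).
   Adjusted variables are then divided by their weighted population SD
   (denominator $\sum w$). Survey weights enter every moment estimate, so
   results generalize to the source population.
5. **Weighted MFA.** Active variables come in groups (46 nutrients; 4
   impacts). Each group is first reduced by a weighted PCA of its centered
   submatrix; its columns are rescaled by $1/\sqrt{\lambda_1^{(j)}}$, the
   group's first eigenvalue, so no group can contribute more than 1 to the
   first global axis. A weighted PCA of the concatenated rescaled matrix
   yields eigenvalues, person scores and variable–dimension correlations.
   Supplementary variables (food-group intakes, diet quality, energy,
   protein ratios, sociodemographics) are projected afterwards and never
   shape the axes. Eigenvector signs are fixed by orienting each dimension
   so its largest-magnitude loading is positive — the decomposition is
   otherwise sign-ambiguous and this removes platform flakiness.
6. **Clustering.** Ward's minimum-variance hierarchy on the retained factor
   scores (default 5 dimensions) with survey weights as masses: the
   dissimilarity fed to the Lance–Williams recurrence is the Ward cost
   $\frac{w_iw_j}{w_i+w_j}\lVert x_i - x_j\rVert^2$, so merge heights are
   within-inertia increments and sum to the total inertia. The suggested
   cluster count maximizes the ratio of successive between-inertia gains;
   the full gain curve is returned because the final $k$ is an
   interpretability decision, not an automatic one. The cut is consolidated
   by a weighted k-means started from the hierarchical centroids (at most 10
   iterations — consolidation, not re-clustering), which can only decrease
   within-inertia.
7. **Characterization.** Cluster-vs-sample v-tests for quantitative
   variables, $v_k = (\bar x_k - \bar x)\big/\sqrt{\tfrac{s^2}{n_k}\,
   \tfrac{N-n_k}{N-1}}$, and for categories via the normal approximation of
   the hypergeometric; both use survey-weighted moments with weights
   normalized to mean one so the effective counts stay interpretable.
   Between-cluster comparisons use Kruskal–Wallis plus Dunn's pairwise z
   (tie-corrected, Bonferroni-adjusted by default), with Levene (mean-
   centered) and Shapiro–Wilk diagnostics documenting why parametric
   alternatives are not used. Rank tests with survey weights are
   ill-defined, so the post-hoc battery runs unweighted on raw values — a
   documented limitation. Non-ordinal categoricals get an omnibus
   chi-square followed by Marascuilo-style pairwise proportion comparisons
   with a Bonferroni-corrected critical value.
8. **Transition scenario.** If everyone adopted the target cluster's diet:
   percentage change of each impact relative to the sample mean, national
   annual deltas (`daily delta x population x 365`, unit-converted), and
   per-capita annual food-group changes in kg/capita/year. Percentage
   changes use energy-adjusted means so they reflect composition, not
   caloric amount. The year is 365 days; the adult population size is a
   configuration parameter.

## The synthetic population

Real national survey data of this kind is access-restricted, so the package
ships a generator whose defaults emulate the survey's structure: ~5100-like
populations are scaled to the requested `n_persons`; 81 ingredient-level
foods in 25 groups; 46 nutrients plus total energy; five latent diet
clusters with shares 16/38/18/24/4% ranging from a low-impact plant-leaning
pattern through average diets to a meat-heavy high-impact pattern (the
"good-compromise"-like third cluster has high fruit/vegetable, fish, legume
and nut intakes and low red meat). Intakes are log-normal (non-negative,
right-skewed, as FFQ-derived intakes are — and the reason the post-hoc path
is non-parametric); energy is *exactly* $\sum_f x_{if}\,d_f$ with $d_f$ the
energy density, so energy and intakes are perfectly consistent; other
nutrients get 5% multiplicative log-normal noise. Survey weights are the
inverse of a logistic non-response propensity in age and sex, normalized to
mean one so weighted and unweighted sample sizes coincide. Impact factors
are drawn uniformly within food-group ranges whose magnitudes are set so
that per-person daily totals land near published national levels (about
6 kg CO$_2$-eq/day); animal-source groups carry the high GWP and land-use
ranges and fish dominates freshwater eutrophication.

Two generator choices deserve explanation:

* **Marker nutrients.** Each food group dominates one micronutrient column,
  emulating the marker nutrients of real composition tables (vitamin C for
  fruit, B12 for meat, iodine for fish, …). Without them the food-to-
  nutrient aggregation is nearly rank-deficient — distinct diets become
  indistinguishable after aggregation in a way real data is not, and no
  clustering method could recover what the generator planted.
* **Benchmark separation mode.** `population_spec(separation = s)` with
  $s > 1$ switches to a Hadamard $\pm$ design: each cluster raises half the
  food groups by $e^{+s\sigma/2}$ and lowers the rest by the inverse, so any
  two clusters differ by exactly $s\sigma$ in log-mean on about half of all
  groups (far more than five foods). Expected total energy is equalized
  across clusters, because the estimand of the whole method is dietary
  *composition at equal energy*: signatures that differ mainly in energy
  scale would be removed by the residual adjustment by design, not by
  error. The default (`separation = 1`) keeps the survey-like overlapping
  archetypes, where clusters do differ in energy.

What passing tests on this generator do **not** show: robustness to FFQ
measurement error and portion-size conventions, to real food-composition
correlation structure (Fineli-style), to missing data, or to impact-factor
uncertainty. The generator is a test harness for the *pipeline logic*, not
a model of Finnish diets.

## Numerical choices and degenerate inputs

* Weighted variances use the population convention (denominator
  $\sum w$) everywhere, matching the standardization step.
* Quartile scoring uses the left-continuous inverse of the weighted CDF,
  ties to the lower bin; a component constant within a sex stratum is an
  error that advises external cut points.
* Energy adjustment refuses zero-variance energy; standardization refuses
  zero-SD columns by name.
* MFA errors on groups with zero first eigenvalue; dimensions beyond the
  numerical rank (eigenvalues below 1e-12) are not retained.
* Ward ties are broken deterministically by `stats::hclust`; the elbow
  suggestion flags near-flat gain curves (best ratio below twice the median
  ratio) as "weak".
* k-means consolidation re-seeds an emptied cluster with the nearest point
  and warns; reassignments can only lower within-inertia.
* Dunn's z under complete ties (zero rank variance) is defined as 0 with
  p = 1; adapted impact factors that would go negative are clipped at 0
  with a warning; an import/export ratio of 0/0 counts as domestic.
* All randomness flows from a single integer seed; the pipeline derives
  per-stage seeds by fixed offsets so partial reruns stay reproducible.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at
n = 1000 persons (five seeds) for the planted-cluster recovery benchmark,
n = 2000 for the survey-like summary run, 1000 simulated variables at
n = 500 for the v-test null calibration, and 2000 replicates of 3×50
observations for the Levene size check — sizes at which the Monte-Carlo
error of the checked quantities is small relative to their tolerances while
a complete run stays fast on a laptop. Levene's mean-centered statistic is
only asymptotically F-distributed, hence the moderate group size for its
calibration.

## Known limitations

* The adaptation module does not recompute life-cycle inventories; users
  with process-level data should adapt factors upstream and load them as
  tables.
* The mBSDS point allocation is a reconstruction; supply external cut
  points for strict comparability with the published score.
* Post-hoc rank tests ignore survey weights.
* No uncertainty propagation of characterization factors, and no
  supply-side modelling in the transition scenario: a population-wide diet
  change is assumed to translate proportionally into production change.
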