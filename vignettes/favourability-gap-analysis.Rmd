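---
title: "Favourability modelling and Insecurity-Index gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Favourability modelling and Insecurity-Index gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(favsec)
```

## The model

`favsec` assesses how well a protected-area network covers the *favourable
areas* of species, rather than their recorded ranges. The pipeline has four
stages.

**1. Predictor screening.** Atlas-scale predictor pools are large and
redundant, especially within thematic sets (climate, topography, lithology,
land use, human activity). For each species:

* *Within-set correlation pruning.* Among remaining within-set pairs with
  absolute Pearson correlation above 0.8, the pair with the largest |r| is
  resolved by dropping the member with the larger univariate
  likelihood-ratio p-value against the species distribution; this repeats
  until no within-set pair exceeds the threshold. Resolving the largest |r|
  first makes the outcome deterministic; ties in p keep the earlier column.
  Negative collinearity is treated as redundancy too, hence |r| rather than
  r. Zero-variance columns are dropped outright.
* *Trend-surface descriptor.* A logistic regression of presence on the nine
  cubic terms of the standardized coordinates (X, Y, X², XY, Y², X³, X²Y,
  XY², Y³), backward-eliminated by AIC; the retained model's linear
  predictor becomes a single spatial variable (set `"spatial"`) that absorbs
  broad-scale spatial autocorrelation. Coordinates are standardized before
  powering to avoid numerical blow-up. If the retained model diverges
  (complete separation), the descriptor falls back to a flagged constant and
  is withheld from the candidate list.
* *FDR filter.* Univariate likelihood-ratio p-values for all candidates
  (pruning survivors plus the descriptor, which is screened like any other
  candidate) are passed through Benjamini–Hochberg step-up selection at
  q = 0.05 (`method = "BY"` switches to Benjamini–Yekutieli for dependence-
  robust control).

**2. Favourability model.** A forward-backward stepwise logistic regression
by AIC, started from the intercept-only model over the survivor scope: at
each step the single add/drop move with the largest AIC decrease is taken
until no move helps. The fitted logit $y$ is transformed to favourability

$$F = \frac{e^y}{n_1/n_0 + e^y},$$

with $n_1$ presences and $n_0$ absences. $F$ strips prevalence out of the
predicted probability: $F = 0.5$ exactly where probability equals prevalence
$n_1/(n_1+n_0)$, $F$ equals probability when $n_1 = n_0$, and $F$ is a
strictly increasing bijection of probability, so rank-based quantities (AUC)
are identical on either scale. $F$ is read as a fuzzy membership degree of
the cell in the species' favourable areas — including "dark diversity":
cells favourable for a species that is not recorded there.

**3. Evaluation.** Classification at the favourability threshold $F = 0.5$
(equivalent to thresholding probability at prevalence): sensitivity,
specificity, correct classification rate, and Cohen's kappa with chance
agreement from the marginals. Discrimination: rank-based (Mann–Whitney) AUC
with ties counted ½. Calibration: the Hosmer–Lemeshow statistic over ten
*fixed-width* probability bins [0, 0.1), …, [0.9, 1.0] — not deciles — with
$\mathrm{df} = g - 2$ over the $g$ nonempty bins and the p-value suppressed
below three nonempty bins.

**4. Insecurity metrics.** With $P_j \in [0,1]$ the fraction of cell $j$
covered by the network:

* per-cell Insecurity $I_{ij} = F_{ij}(1 - P_j)$ — the favourable area left
  unprotected in that cell;
* Overall Insecurity $I_i = \sum_j I_{ij} / \sum_j F_{ij}$, the share of the
  fuzzy favourable area outside the network (equivalently one minus the
  favourability-weighted mean coverage);
* Security $S_i = 1 - I_i$ and Representativeness $R_i = S_i / c$, where $c$
  is the area-weighted coverage fraction of the whole study area,
  $c = \sum_j P_j a_j / \sum_j a_j$. $R > 1$: favourable areas covered better
  than chance. An occurrence-based variant replaces $F$ with the 0/1
  presence vector.
* Group maps: per-cell sums of $I_{ij}$ over the species of a taxonomic
  group, normalized by the maximum over the study area.
* Null model: each replicate permutes the full vector of $P_j$ values
  uniformly across cells and recomputes Security; the count of replicates
  the actual Security strictly exceeds (out of 20 by default) flags
  well-represented (all) and under-represented (none) species. Ties count
  as failures — conservative, and consistent with a flat coverage layer
  scoring 0. Under this null the expected Security is the mean of $P$, so
  with equal areas the expected Representativeness is 1 — the calibration
  the tests verify.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `r_threshold` | 0.8 | within-set \|r\| above which one variable is pruned |
| `q` | 0.05 | FDR level of the univariate screen |
| `threshold` | 0.5 | favourability classification threshold (unitless) |
| `hl_bins` | 10 | fixed-width Hosmer–Lemeshow bins (width 0.1) |
| `n_reps` | 20 | coverage permutations in the null model |
| `coverage` | `NULL` | override for `c`; defaults to the area-weighted mean of `P` (pin it, e.g. to 0.00667, when reproducing a published network fraction) |
| `seed` | — | master seed; per-species null-model seeds derive by fixed offsets |

Cell areas default to 1 when absent, under which `c = mean(P)`; the area
column exists so partial (e.g. coastal) cells can be down-weighted if the
user's grid calls for it.

## The synthetic generator

`generate_landscape()` builds predictors as smoothed Gaussian fields: white
noise convolved with a separable Gaussian kernel (length-scale `smoothness`,
in cells, reflected at the edges), standardized. Each set has a latent
field; a variable is $\sqrt{\rho}\,L_{set} + \sqrt{1-\rho}\,E$, giving
expected within-set correlation $\rho$. This reproduces the two features
the screening stages exist for — within-set collinearity and spatial
autocorrelation — while staying dependency-light.

`generate_species()` draws presence as
$\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha + X\beta + w\,T))$, where $T$
is a seeded random cubic polynomial of the standardized coordinates scaled
to unit variance (the same family the trend-surface descriptor fits), and
$\alpha$ is calibrated by 1-D root finding (`uniroot`, prevalence tolerance
well below 1e-4) so the mean probability hits `target_prevalence`. The true
favourability — the transform applied to the true logit with the *realized*
$n_1, n_0$ — is returned so parameter recovery can be scored.

`generate_coverage()` grows `n_parks` contiguous blobs by breadth-first
search on the lattice (randomized growth order, or greedy uphill growth on a
supplied surface for `favourability_biased` placement), sets interior cells
to full coverage and boundary cells to uniform(0,1) fractions, then rescales
so the realized area-weighted coverage equals `coverage_fraction` to within
1e-6. The rescale is global (cap-and-iterate when scaling up), so interior
cells typically end slightly below 1: exactness of `c` is the contract the
downstream metrics depend on, and edge distributions are otherwise
arbitrary.

What the generator does *not* emulate: real geography (coastlines, islands,
elevation banding), categorical predictors such as lithology classes
(continuous proxies only), survey effort artefacts, and range dynamics. A
passing suite therefore shows the machinery is correct and calibrated under
the stated generative model — not that any particular real network is well
or poorly configured.

## Numerical choices

* Logits are clipped to ±35 before exponentiation; beyond the clip $F$ is
  returned as exactly 0/1 and flagged via a `clipped` attribute.
* Favourability is computed as $1/(1 + (n_1/n_0)e^{-y})$, stable for large
  $|y|$.
* Stepwise selection is invariant to survivor column order except under AIC
  ties, which R's `step()` resolves by column order.
* Separation in the stepwise fit is reported (warning plus `separation`
  flag) with coefficients as fitted; only the trend-surface stage falls
  back to a constant, because its descriptor would otherwise inject a
  divergent column into later stages.
* Degenerate Hosmer–Lemeshow bins with mean probability exactly 0 or 1
  contribute 0 when observed equals expected, `Inf` otherwise.
* `overall_insecurity()` refuses $\sum F = 0$; `representativeness()`
  refuses $c \le 0$; the occurrence variant refuses empty ranges — all as
  explicit errors rather than NaN propagation.

## Problem sizes

The test suite and examples run on lattices between 4×3 and 100×100 cells.
Calibration properties use 200 permutation replicates on a 50×50 grid;
parameter recovery uses 20 independent 50×50 landscapes (2 500 cells, two
informative predictors with |β| = 1, prevalence 0.3), sizes at which the
stepwise fit and screening complete in seconds while binomial noise is small
enough for the stated bounds.

## Known limitations

* The null model permutes coverage values independently across cells; it
  does not preserve park contiguity. A contiguity-preserving null (relocating
  whole blocks) would be stricter for strongly autocorrelated favourability
  surfaces.
* Only continuous predictors are supported; categorical layers must be
  dummy-coded upstream.
* `run_pipeline()` fits species independently and in sequence; there is no
  multi-species borrowing of strength and no parallelism (runs are
  seconds–minutes on one CPU at atlas scale).
* With unequal cell areas, Overall Insecurity remains a per-cell (not
  area-weighted) ratio, matching its definition; only `c` is area-weighted.
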