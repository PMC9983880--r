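---
title: "Predicting kinase-inhibitor-induced cell viability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting kinase-inhibitor-induced cell viability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinoviab)
```

## The scientific problem

Small-molecule kinase inhibitors are rarely selective: at assay-relevant
concentrations a single compound binds and inhibits dozens of kinases and
kinase-associated proteins, and the set of affected targets shifts with
concentration. Kinobead/mass-spectrometry profiling captures this as a
*kinase inhibition state*: for each compound and concentration, a vector of
relative intensities across the kinome, where 0 means a fully inhibited
target, 1 an unaffected protein, and values above 1 apparent increased
capture. Separately, pooled viability screens provide dose-response curve
parameters for large panels of cancer cell lines, and baseline omics
(expression, copy number, proteomics, gene-dependency scores) characterize
those lines before treatment.

`kinoviab` links the two: it harmonizes inhibition profiles and
dose-response parameters onto a shared concentration grid, assembles a
design matrix over (cell line, compound, concentration) treatments, screens
features by univariate correlation inside grouped cross-validation, fits
tree-ensemble regressions of relative viability, quantifies
protein-interaction enrichment of the selected expression genes, and
predicts complete viability curves for combinations never assayed. Because
the real upstream resources are large external downloads, the package ships
a synthetic-study generator that emulates every input with known planted
ground truth; all tests run against that truth.

## Data model and preprocessing rules

The central containers are S4 classes. `KinaseInhibitionProfile` holds the
dense compound × concentration × protein tensor; `OmicsBundle` the per-cell
line baseline matrices; `FeatureTable` the assembled design matrix with its
response and per-column feature classes.

Sparse inhibition tables list only the proteins a compound affects.
Densification therefore fills every unrecorded (compound, protein) pair
with the default relative intensity of exactly 1 — unlisted proteins are
unaffected, not missing. Within a recorded series, isolated
single-concentration gaps are filled with the mean of the two nearest
concentrations; at a grid end, where only one neighbor exists, that
neighbor's value is copied (the two-neighbor average is undefined there).
Two adjacent gaps violate the isolated-gap premise and raise an error
rather than guessing. Finally, rare outlier readings are truncated to the
99.99th percentile of the full tensor. Three conventions are deliberate and
logged with every run:

* the quantile uses linear interpolation between order statistics (R type
  7), the most common convention, since only a percentile is specified;
* the percentile is computed after densification by default, pooling the
  default-1 cells; computing it over the recorded values only is available
  via `percentileScope = "records"` in `preprocessInhibition()`;
* concentrations are matched by exact decimal equality after
  canonicalization to molar, avoiding float-tolerance ambiguity.

Omics matrices get class prefixes (`exp_`, `cnv_`, `prot_`, `dep_`) so the
same gene measured by different platforms can never be merged accidentally.
Missing proteomics readings are imputed to the protein's observed minimum
minus one standard deviation — just below the detection range; columns with
fewer than two observations have no defined spread and are dropped.
Dependency matrices drop any cell line with incomplete rows.

## Viability imputation

Dose-response parameters follow the four-parameter log-logistic (LL.4)
model with slope $b$, lower asymptote $c$, upper asymptote $d$ and
inflection concentration $e$:

$$ f(x) = c + \frac{d - c}{1 + \exp\!\big(b\,(\ln x - \ln e)\big)}. $$

Natural logarithms are used throughout; the curve is invariant to the log
base given a matching slope, so the convention is fixed and documented.
`imputeViability()` evaluates each combination's curve at the standard
8-concentration grid (3 nM – 30 µM). Combinations whose curve indicates
enhanced growth with increasing concentration are removed first;
"enhanced growth" is operationalized as the curve evaluating higher at the
top of the grid than at the bottom, which is monotone-consistent for LL.4
curves. Imputed viabilities are **not clipped by default** — fitted curves
legitimately exceed 1 and the models should see that — but `clip = c(0,
1.2)` bounds them when a bounded scale is needed; the clip state is logged.

## Feature screening and grouped cross-validation

Every feature's Pearson correlation with imputed viability is computed,
and features enter models in correlation rank order. Two open choices were
resolved as follows:

* Ranking uses $|r|$, not signed $r$, so strong negative predictors are
  retained; `signed = TRUE` restores signed ranking.
* Zero-variance features receive $r = 0$ (flagged) rather than `NA`, so
  the ranking remains a total permutation and selection stays
  deterministic; ties break lexicographically by feature name.
* The raw concentration covariate is always available to models but never
  competes for the feature budget `k` — it defines the dose-only baseline
  and is appended outside the selection.

Cross-validation is grouped: all eight concentrations of one (cell line,
compound) treatment are a single unit, assigned to one of ten folds by a
balanced random partition. Feature correlations and selection are
recomputed inside each fold on training rows only, so the held-out
combinations never influence the feature set — the design the tests verify
with leakage scans. Fold and model seeds are separate arguments, and
per-fold selections are retained so selection stability
(|intersection| / |union| across folds) is recomputable without refitting.

$R^2$ is reported as the squared Pearson correlation of predictions and
observations by default (the convention of the modeling stack this design
follows); the coefficient-of-determination variant is available via
`r2Method = "traditional"` since published values rarely state which was
used. Model families are the feature-free dose-only baseline, ordinary
least squares, random forest (ranger) and gradient boosting (xgboost,
standing in the benchmarking role of the boosted-tree family). Random
forest defaults are 500 trees, 22 predictors per split and minimal node
size 5 — the tuning-grid defaults — with predictors-per-split falling back
to $\lfloor\sqrt{p}\rfloor$ when 22 exceeds the available feature count.

One interface decision deserves emphasis: in ablations, the dose covariate
is included only when inhibition features are (`includeDose` overrides
this). An expression-only model is meant to measure what *baseline* omics
alone predict; giving it the concentration would smuggle in the dose-only
baseline and mask the fact that expression is constant across doses. With
this rule, expression-only models score near zero on dose-dependent
responses, as they should.

## Interaction enrichment

Selected expression genes are compared against the inhibition-state
protein set in a STRING-style network, filtered to edges with confidence
strictly above 0.7. Two statistics are computed: how many query genes have
at least one edge to the target set, and the mean number of target
interactors per query gene (zeros included). Significance comes from
resampling: gene sets of the same size drawn uniformly without replacement
from the expression universe. Percentiles use the mid-probability
convention — the fraction of null draws strictly below the observed value
plus half the ties — which keeps the percentile approximately uniform under
the null even though the count statistic is discrete; a strictly-below
convention would be systematically conservative on degenerate networks.

## Prediction and plate validation

The final model is fitted on all rows with the same ranking-then-top-k
selection, then applied to every (cell line, compound) pair not in the
tested mask for which expression and an inhibition profile exist; pairs
with missing inputs are reported, not errored. Raw plate luminescence is
normalized row-wise to the mean of the DMSO-only control wells on the same
plate row; replicates are averaged *after* normalization, and a row is
discarded when any of its normalized values reaches 120% of control (the
`< 120%` quality criterion, applied per row). Predictions are not clipped,
matching the viability module's default.

## The synthetic study generator

`generateSyntheticStudy()` produces all five inputs with planted truth.
Its defaults are the package's study conditions, chosen once:

* 40 cell lines × 30 compounds × the 8-dose grid, 150 proteins, 200 genes;
* 4 target proteins per compound. Each compound has a potency center drawn
  log-uniformly from 9 nM to 90 µM (so some compounds barely act within
  the grid — compounds genuinely differ), its targets' potencies scatter
  around that center, and one slope per compound is shared by its targets.
  With equal slopes the minimum over target curves *is* the most potent
  target's curve, so the planted viability signal
  $V = 1 - s\,(1 - \min_p I_p(x))$ is exactly LL.4 — which makes the
  generator's curve fitting well-posed and noise-free recovery exact;
* sensitivity $s(l,j) = \mathrm{logit}^{-1}(z_{lj})$, where $z$ is the
  cell line's standardized expression over the compound's 5 driver genes,
  weighted geometrically so the first driver dominates (a marker gene per
  compound, with the remaining drivers modulating). Drivers are drawn from
  a shared pool of 15 genes, mirroring recurrent sensitivity pathways:
  related inhibitors share resistance and sensitivity genes rather than
  each owning a private set, and this sharing — together with the dominant
  marker — is what lets a model transfer expression effects across
  compounds;
* Gaussian viability noise of sd 0.05 before curve fitting; a 1.8%
  single-concentration gap rate and a 0.01% outlier inflation rate — the
  rates reported for real kinobead tables; 2% of combinations receive
  increasing curves to exercise the growth filter;
* the interaction network places background edges with probability
  `p0` and driver-target edges with probability `p0 × strength`,
  confidence uniform on [0.4, 1].

Generator curve fitting uses multi-start nonlinear least squares
(`minpack.lm::nlsLM`) on log-concentration, starting from
$(b, c, d, e) = (1, \min V, \max V, \text{geometric-median dose})$ with
additional slope starts; exactly flat series shortcut to $c = d$. Fit
failures are logged and the combination dropped (about 2% of combinations
under the default noise).

What the generator does *not* emulate: the marginal intensity and
expression distributions of real data beyond scale and sparsity,
measurement correlation structure across proteins, batch effects, or any
compound-class structure. Passing tests therefore demonstrate that the
pipeline's arithmetic, selection and validation logic recover planted
structure — not that the models would reach any particular accuracy on
real kinome data.

## Problem sizes and numerical choices

The test suite exercises tiny studies (≈ 6 × 4 × 8) for unit oracles and
the default 40 × 30 × 8 study for end-to-end recovery; the hyperparameter
sweep uses a 20 × 15 × 8 study, sizes at which the planted signal is
comfortably detectable while a full run stays interactive. Cross-validated
random forests use k = 200 features on the default study; the tree-count
sweep covers the full 500–2000 grid. Degenerate inputs follow fixed rules:
flat dose-response series fit exactly as constant curves; zero-variance
responses error in screening; compounds observed in fewer than two cell
lines are excluded from max-variance dose picking with ties going to the
lower concentration.

## Known limitations

* The generator's sensitivity link is a single logistic of mean driver
  expression; real sensitivity programs are not additive in a handful of
  genes.
* Endpoint comparison implements the growth filter exactly for monotone
  LL.4 curves but would misclassify non-monotone curve families.
* Gradient boosting is benchmarked with fixed, conventional settings; no
  boosting-specific tuning is attempted.
* The enrichment module measures direct adjacency only — no propagation,
  clustering or topology statistics.
* Identifier spaces are assumed pre-harmonized; no gene-identifier
  conversion is performed.

## Reproducing a run

```{r, eval = FALSE}
cfg <- syntheticConfig(seed = 1)
study <- generateSyntheticStudy(cfg)
pre <- preprocessInhibition(study$inhibition$records,
                            sprintf("CMP%03d", 1:30),
                            sprintf("PRT%03d", 1:150), cfg@doseGrid)
filt <- filterGrowthEnhancing(study$doseResponse$params, cfg@doseGrid)
viab <- imputeViability(filt$kept, cfg@doseGrid)
ft <- assembleDesign(viab, pre$profile, prefixFeatures(study$omics))
folds <- makeGroupFolds(rowKeys(ft), K = 10, seed = 1)
rf <- crossValidate(ft, modelSpec("random_forest", nFeatures = 200), folds)
rf
```

The same flow is scripted, stage by stage with caching manifests, in
`runPipeline()`; `scripts/acceptance.R` runs it end to end and writes the
headline quantities as JSON.
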