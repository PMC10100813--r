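---
title: "Integrated trait and herbivory analysis of fossil leaf assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated trait and herbivory analysis of fossil leaf assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoleaf)
```

## The analysis in one paragraph

Fossil dicot leaves carry two complementary signals: the architecture and
economics of the leaves themselves (shape characters, lamina area, leaf mass
per area) and the feeding traces that arthropods left on them (damage types,
DTs). `paleoleaf` chains the steps needed to read both signals from a
specimen table and compare them between assemblages: a nested dataset
cascade that controls preservation bias, a 16-class trait-combination-type
(TCT) spectrum, quantitative traits with LMA from petiole allometry and
phenology classes from LMA thresholds, damage-type metrics with analytic
sample-based rarefaction, chained-equation imputation of missing LMA, and a
multivariate stage (trait PCA, Gamma/binomial GLMs with AIC selection,
type-II likelihood-ratio ANOVA, pseudo R²).

## The dataset cascade

Leaf assemblages are preservation-biased samples, so the pipeline works on
nested subsets, each tied to what can actually be measured on its members:

* **Dataset 1** — all scored leaves (at least half the lamina preserved);
  enough for TCT characters and damage presence.
* **Dataset 2** — leaves at least 70 % preserved (`filter_dataset2()`,
  boundary inclusive: "at least" is read literally). Only these can have
  their outline reconstructed reliably.
* **Dataset 3** — a simple random subsample of a fixed number of leaves per
  site (`sample_dataset3()`, default 400) on which quantitative traits are
  measured. Random, per site, so that the measured subsample inherits each
  site's taxonomic composition rather than the collector's preferences.
* **Dataset 4** — the complete-case modelling set (`build_dataset4()`):
  incomplete cases, Tukey-fence outliers in leaf size or LMA, and members
  of rare fossil-species or rare TCTs (fewer than 5 leaves) are removed.
* **Dataset 5** — as Dataset 4 but after LMA imputation on Dataset 3, so
  that leaves lacking only a petiole re-enter the multivariate stage.

The filter order inside `build_dataset4()` (incomplete → outliers → rare
species → rare TCTs) is a design choice the cascade's description leaves
open; it is fixed this way so that rarity is judged on the cleaned set, and
the removal ledger attached to the result lets any alternative order be
audited. Outlier fences are Tukey's `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` with
linear-interpolation (type 7) quartiles, computed per site because the
sites' size distributions differ; a pooled variant is available via
`by_site = FALSE`. Rare TCTs are deleted by default; `rare_tct = "merge"`
pools them into an `"other"` class instead.

## Trait combination types

Four binary characters — lobation, margin, primary venation, secondary
venation — span 16 leaf architectural types, lettered A–P. The default
letter table (`default_tct_map()`) enumerates the quartets in nested order
(lobation, then margin, then primary, then secondary venation). This
reproduces the anchor letters of the scheme: A (unlobed/entire/pinnate/
looped, the laurophyll type), B (its non-looped counterpart, typical of
legume morphotypes), E and F (unlobed/toothed/pinnate with looped resp.
non-looped secondaries) and P (lobed/toothed/palmate/non-looped). The
assignments of the remaining letters are not fixed by those anchors, so the
map is data: supply any bijective 16-row table to re-letter. An unknown
value in any of the first three characters makes a leaf unclassifiable —
the classifier never guesses.

Assignment modes mirror practice: `specimen` uses only the observed
characters; `taxonomy` uses a species-diagnosis table when the diagnosis
implies exactly one TCT; `combined` (the default) prefers the specimen code
and falls back on taxonomy, the typical case being poorly visible secondary
venation on leaves of a well-determined species. Diagnoses implying several
TCTs leave the leaf unassigned. Spectrum percentages are reported against
two denominators (all leaves, and assigned leaves only) because published
spectra conventionally include the unclassifiable fraction in the base.

For models that should not see secondary venation, `tct_class()` merges the
letter pairs differing only in that character into 8 classes ("E/F", …).

## Quantitative traits, LMA and phenology

Lamina area, length and width come either pre-tabulated or from outline
pairs (`polygon_measurements()`): area by the shoelace formula on the
reconstructed ring, length as the extent along the principal axis of the
outline's vertex cloud, width along the orthogonal axis, and the area index
IA = preserved area / reconstructed area. The principal axis approximates
the manual along-the-midrib measurement; for the elongate, roughly
bilaterally symmetric laminae this pipeline targets, the difference is
negligible, but strongly asymmetric leaves would need a digitised midrib.

Leaf mass per area (g m⁻²) is estimated from the petiole width at the
lamina insertion through the base-10 allometry

log₁₀(LMA) = 3.070 + 0.382 · log₁₀(pw² / area).

The logs are base 10: a natural-log reading produces LMA values far outside
any observed leaf range, which the test suite checks as a sanity property.
The predictor pw²/area is dimensionless under isometric scaling, LMA is
strictly increasing in petiole width and decreasing in area, and the
inverse (`petiole_width_for_lma()`) round-trips to 1e−9 — these are all
tested invariants. Units are fixed (mm, mm², g m⁻²); nothing is inferred.

Species mean LMA (over at least 5 leaves, the same threshold as the rarity
rule) maps to a phenology class: below 87 g m⁻² deciduous, above
129 g m⁻² evergreen, the band between them — boundaries inclusive, reading
"between" literally — the deciduous/evergreen transition
(`"intermediate"`).

## Herbivory metrics and rarefaction

Three sample-based metrics describe the damage record: DAM% (share of
leaves bearing at least one DT; the denominator is all leaves), DTO (count
of (leaf, DT) presences, deliberately not standardised), and DTR (number of
distinct DTs). Because DTR grows with sample size, it is standardised by
sample-based rarefaction with leaves as the sampling units:

E[S_n] = Σᵢ [1 − C(N−Nᵢ, n) / C(N, n)],

with the exact hypergeometric variance including all pairwise co-occurrence
terms, so the SD at the full sample size is zero and the curve ends at the
observed richness. Binomial coefficients are computed in log space; the
estimator is exact, not resampled. A Monte-Carlo twin
(`rarefy_montecarlo()`) exists purely as a cross-check — the tests require
the two to agree to three standard errors, and the analytic version to
match exhaustive subset enumeration exactly on small matrices. Rarefaction
is refused below 20 leaves (`force = TRUE` overrides), and group-wise
curves (`rarefaction_by_group()`) report such groups as skipped rather than
silently computing them.

DTs map to functional feeding groups through a catalog
(`default_dt_catalog()`). The shipped catalog covers the DTs this kind of
record contains; the guild membership of DT 78 (feeding between secondary
veins) is not settled and defaults, provisionally, to surface feeding —
pass a custom catalog to override. Unmapped DTs fall into `"other"` with a
warning instead of being dropped.

The herbivory index HI = damaged area / lamina area is a per-leaf fraction
(× 100 for percent); it feeds the damage-intensity GLMs.

## LMA imputation

Petioles are rarely preserved, so LMA is the limiting variable of the
multivariate stage. Missing values are filled by the "norm" step of
chained-equation imputation — a Bayesian linear regression with proper
posterior draws: residual variance from its scaled inverse-χ² posterior,
coefficients from their conditional normal, and each missing value from the
predictive normal. Locality and leaf size are the regressors, fitted on
both sites pooled with locality as a covariate; species is deliberately not
a predictor (species-wise regressions are too weak at realistic
per-species sample sizes). Only species with at least 5 measured LMA
values in a site have their gaps filled. The reported value is the mean of
10 cycles. Averaging draws shrinks the between-imputation variance that
the "norm" method is designed to preserve; the pipeline reproduces the
averaging convention because the reported value is meant as a point
estimate, and the per-cycle draws remain available in the diagnostics for
anyone propagating imputation uncertainty. A range filter removes imputed
values below the site's measured minimum (the asymmetric form matches how
such checks are reported; `symmetric = TRUE` also removes above-maximum
values). Constant predictors — locality in a one-site assemblage — are
dropped from the design rather than breaking it.

## The statistical battery

* `mann_whitney()` reports the first-sample U (pairs with x > y, ties
  half-weighted), so the statistic itself — not just the p-value — is
  reproducible and order-sensitive; site order is part of the pipeline
  configuration.
* `kruskal_letters()` follows the field's habit of compact letter
  displays: a tie-corrected Kruskal–Wallis statistic, Fisher-LSD pairwise
  tests on mean ranks with the pooled rank variance deflated by
  (N−1−H)/(N−k), and letters from a maximal-interval sweep over groups
  sorted by mean rank.
* `pca_traits()` is a correlation-matrix PCA of the five quantitative
  traits (LMA, area, width, length, length/width); contributions are
  100·loading², summing to 100 per axis.
* `fit_trait_glm()` fits the two families the battery needs: Gamma with
  identity link for positive responses and binomial-logit for damage
  presence. Identity-link Gamma models are numerically fragile, so the
  fitter tries a ladder of feasible starts (least-squares when its fitted
  values are positive, a flat start at the response mean, a damped IRLS
  pre-solve) and records the successful fit with a call that routes any
  refit back through the same ladder.
* `stepwise_aic()` and `anova_type2()` are the greedy both-direction AIC
  search from the full model and the drop-one likelihood-ratio table. They
  are implemented over the robust fitter because the stock selection and
  ANOVA routines refit submodels without feasible starts and abort on
  exactly the damage models this battery contains; on well-conditioned
  models they agree with the stock selector, which the tests check. Exact
  AIC ties cause no move.
* `r2_measures()` reports Nagelkerke's R² (any family) and Tjur's
  coefficient of discrimination (binomial).

The model battery M1–M5 fixes the response/term shapes: LMA and leaf size
against species, size/IA/phenology/locality (Gamma); damage presence
against locality, LMA, TCT class and size (binomial; a Dataset-1 variant
uses locality and full TCTs); damaged area and HI against size, phenology,
locality and LMA (Gamma, damaged leaves only). Terms that cannot be
estimated (single observed level after filtering) are dropped before
fitting rather than crashing the run; a model that still fails is reported
as an explicit error entry.

## The synthetic generator

`generate_assemblage()` draws leaves from species specifications
(abundance, trait quartet, phenology, lognormal laws for area and true
LMA, per-DT incidence rates, Beta law for damaged-area fractions) and then
degrades the truth through a taphonomy layer: preservation fractions from
a rescaled Beta on (0.3, 1], quantitative traits observed only at ≥ 70 %
preservation, petioles surviving with probability 0.4 (mirroring how few
measured leaves retain one), and lognormal measurement noise on petiole
width. The generator returns the full truth record beside the observable
table, so recovery tests never re-derive hidden state, and with masking
disabled the observable record equals the truth exactly — the end-to-end
identity test.

Two presets encode the study conditions the package is exercised under:
`sf_like` (deciduous-dominated, TCT-F-rich, about 5 % of leaves damaged,
4935 leaves) and `sube_like` (evergreen-dominated, TCT A/E-rich, about
12 % damaged, richer damage spectrum, 1349 leaves). Deciduous species'
LMA laws sit below the 87 g m⁻² threshold and evergreen ones above
129 g m⁻², so the phenology classifier has signal to find. Per-(leaf, DT)
draws are independent — the simplest process consistent with the metrics;
there is no overdispersion, no phylogenetic correlation of traits, no
mechanistic taphonomy (transport, decay), and damaged-area fractions are
independent of the DT identity except through the species. Passing tests
on generated data therefore show the estimators recover a known truth
under the assumed sampling process, not that real assemblages satisfy
those assumptions.

## Numerical choices and degenerate inputs

Binomial coefficients in rarefaction are computed via `lchoose`;
variances are clipped at zero before the square root. Quartiles are type 7
(R's default linear interpolation). The Mann–Whitney p-value is exact for
small untied samples and normal-approximated with tie correction
otherwise. Empty assemblages make DAM% an error, not 0. Zero residual
variance in imputation collapses the predictive draws onto the regression
line, so constant responses reproduce exactly. Self-intersecting outline
rings are rejected; rings are closed automatically. All randomness flows
through per-stage seeds derived from one root seed, and every stochastic
function restores the caller's RNG state.

## Problem sizes used by the checks

The test suite works at sizes chosen to make the statistical assertions
sharp but the suite quick: exhaustive rarefaction oracles up to 12 leaves,
Monte-Carlo cross-checks at 10⁴ replicates on 50 × 10 matrices, 20-seed
recovery studies at n = 200 (imputation) and n = 500 (GLMs), and pipeline
fixtures of 500–1500 leaves per site. The acceptance script runs the two
presets at their full sizes (4935 and 1349 leaves) with 400 leaves per
site entering the measured subsample.

## Known limitations

The lettering of TCTs beyond the five anchored letters is conventional and
configurable, not ground truth. Leaf length uses the principal axis, not a
midrib. The DT→FFG catalog is a pragmatic default with two provisional
entries (DTs 78 and 81). The imputation model is a single linear
conditional — adequate for a variable missing mostly at random given
locality and size, but not a multi-variable chained scheme. And the GLM
battery deliberately contains no interactions and no mixed effects; the
models describe assemblage-level contrasts, not within-species dynamics.
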