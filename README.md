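# paleoleaf

Integrated trait and insect-herbivory analysis of fossil dicot leaf
assemblages.

Fossil leaf collections record two things at once: the architecture and
economics of the leaves (shape characters; lamina area; leaf mass per area,
LMA) and the feeding traces arthropods left on them (damage types, DTs,
grouped into functional feeding groups, FFGs). Comparing two assemblages on
both axes requires a chain of steps — preservation filtering, standardised
subsampling, trait measurement, allometric LMA estimation, damage-type
metrics standardised by rarefaction, imputation of the chronically missing
LMA values, and a multivariate stage. `paleoleaf` implements that chain as
composable, tested R functions for paleobotanists and paleoecologists.

## What it computes

**Dataset cascade.** Nested subsets Dataset 1–5: all scored leaves → leaves
≥ 70 % preserved (`filter_dataset2()`) → a random per-site measurement
subsample (`sample_dataset3()`) → a cleaned complete-case set with
Tukey-fence outliers and rare species/TCTs removed (`build_dataset4()`,
with a removal ledger) → the imputation-augmented modelling set.

**Trait combination types.** The 16 TCTs (letters A–P) from four binary
characters — lobation, margin, primary venation, secondary venation — with
specimen-, taxonomy- and combined-mode assignment, 8 venation-free classes
(`tct_class()`), and frequency spectra (`tct_spectrum()`).

**Quantitative traits.** Outline measurements (shoelace area,
principal-axis length/width, area index), and LMA (g m⁻²) from petiole
width and lamina area via

```
log10(LMA) = 3.070 + 0.382 · log10(pw² / area)
```

with phenology classes from species mean LMA (deciduous < 87 ≤ intermediate
≤ 129 < evergreen).

**Herbivory metrics.** Damage frequency DAM%, damage-type occurrence DTO,
observed richness DTR, the herbivory index HI = damaged area / lamina
area, and analytic sample-based rarefaction with leaves as sampling units:

```
E[S_n] = Σ_i [ 1 − C(N−N_i, n) / C(N, n) ]
```

with the exact hypergeometric variance (pairwise co-occurrence terms
included), a Monte-Carlo cross-check, FFG scopes, and a 20-leaf cut-off.

**LMA imputation.** Chained-equation "norm" imputation: Bayesian linear
regression of LMA on locality and leaf size with proper posterior draws,
10 cycles averaged, 5-measured-leaves eligibility per species and site, and
a range filter on out-of-range draws (`impute_lma()`,
`imputation_report()`).

**Multivariate stage.** Correlation-matrix PCA of the five traits with
variable contributions (`pca_traits()`); Gamma-identity and binomial-logit
GLMs M1–M5 with greedy both-direction AIC selection, type-II
likelihood-ratio ANOVA and Nagelkerke/Tjur R² (`fit_trait_glm()`,
`stepwise_aic()`, `anova_type2()`, `r2_measures()`); Mann–Whitney,
Kruskal–Wallis letter displays and Shapiro–Wilk for the univariate side.

**Synthetic assemblages.** A generator with species and taphonomy
specifications and a full truth record (`generate_assemblage()`), plus two
presets (`scenario_presets()`): a deciduous-dominated, TCT-F-rich, sparsely
damaged site and an evergreen-dominated, TCT-A/E-rich site with about 12 %
of leaves damaged.

## Worked example

```r
library(paleoleaf)

sf   <- generate_scenario("sf_like",   seed = 2)   # 4935 leaves
sube <- generate_scenario("sube_like", seed = 3)   # 1349 leaves
leaves <- combine_assemblages(sf$assemblage, sube$assemblage,
                              name = "oligocene-pair")
leaves
#> Leaf assemblage 'oligocene-pair': 6284 specimens, 437 damage observations, sites: Sf, SuBe

res <- run_pipeline(leaves, seed = 1)
res$manifest$stages
#>      stage n_in n_out
#> 1 dataset1   NA  6284
#> 2 dataset2 6284  5020
#> 3 dataset3 5020   800
#> 4 dataset4  800   275
#> 5 dataset5  800   698
```

The cascade kept 5020 leaves at the 70 % preservation threshold, measured
400 per site, retained 275 complete cases and recovered 698 leaves for the
modelling set after imputation (481 LMA values imputed, 8 removed by the
range filter — `res$imputation`).

```r
res$herbivory
#>   site n_leaves dam_pct dto dtr_observed
#> 1   Sf     4935    5.17 259            9
#> 2 SuBe     1349   12.23 178            9
res$rarefaction
#>   site   n expected_richness    sd
#> 1   Sf 400              6.10 1.081
#> 2 SuBe 400              7.82 0.874
```

5.2 % of the first site's leaves are damaged against 12.2 % at the second,
and at a common 400 leaves the second site also carries higher expected DT
richness (7.8 vs 6.1) — the size-free comparison that raw DTR cannot give.

```r
res$pca
#> Trait PCA on 698 leaves, 5 variables
#> Variance explained (%): PC1 65.1, PC2 21.0, PC3 13.5, PC4 0.4, PC5 0.1

deparse(res$models$M1$formula)
#> "lma_gm2 ~ fossil_species + leaf_area_mm2 + phenology_modern + site"
res$models$M1$anova
#>               term lr_chisq df        p
#> 1   fossil_species     43.3 12 2.03e-05
#> 2    leaf_area_mm2     74.0  1 7.96e-18
#> 3 phenology_modern      0.0  0 1.00e+00
#> 4             site     62.3  1 2.97e-15
```

AIC selection kept species, leaf size, phenology and site in the LMA model;
the ANOVA then shows species and size carry independent signal, while
phenology is aliased with species membership (zero extra degrees of
freedom) — exactly the collinearity a reader should notice before
interpreting such models.

## Package layout

* `R/assemblage.R` — data model, CSV dialect, dataset cascade
* `R/tct.R` — TCT map, classification, spectra
* `R/traits.R` — outlines, LMA allometry, phenology, species summaries
* `R/herbivory.R` — DT catalog, metrics, analytic/Monte-Carlo rarefaction
* `R/impute.R` — Bayesian-regression LMA imputation and report
* `R/stats.R` — tests, PCA, GLM battery, selection, ANOVA, R²
* `R/synthetic.R` — generator, taphonomy, scenario presets
* `R/pipeline.R`, `R/reproduce.R` — the one-call driver and the
  published-metrics reproduction surface
* `vignettes/leaf-trait-herbivory.Rmd` — the methods vignette
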