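#' Run the integrated leaf trait and herbivory analysis
#'
#' Chains the full analysis on one assemblage (typically two sites
#' combined): TCT assignment; the nested dataset cascade (all scored leaves
#' -> at least 70\% preserved -> random per-site measurement subsample ->
#' cleaned complete cases -> imputation-augmented modelling set); the TCT
#' spectrum; the herbivory metrics with analytic rarefaction; LMA
#' imputation; the trait PCA; and the GLM battery M1-M5 (LMA, leaf size,
#' damage presence/absence, damaged area, herbivory index) with AIC
#' stepwise selection, type-II LR ANOVA and pseudo R-squared. All
#' randomness (subsampling, imputation draws) derives from `seed`; two runs
#' with the same inputs and seed produce identical tables.
#'
#' @param a a [leaf_assemblage()] (Dataset-1-like).
#' @param seed root integer seed, split internally per stage.
#' @param n_per_site leaves per site for the measured subsample (default 400).
#' @param min_group rarity threshold for species/TCTs (default 5).
#' @param impute_cycles imputation cycles (default 10).
#' @param rarefy_n standard sample size for rarefied richness (default 400).
#' @param diagnoses optional species-to-TCT diagnosis table, see
#'   [assign_tct()].
#' @return object of class `leaf_pipeline`: list with `datasets` (the five
#'   assemblages), `summary` (Table-2-style dataset summary),
#'   `tct_spectrum`, `herbivory`, `rarefaction`, `imputation`, `pca`,
#'   `models` and `manifest` (stage log with row counts and seeds).
#' @export
run_pipeline <- function(a, seed = 1, n_per_site = 400, min_group = 5,
                         impute_cycles = 10, rarefy_n = 400,
                         diagnoses = NULL) {
  stopifnot(inherits(a, "leaf_assemblage"))
  d1 <- assign_tct(a, mode = "combined", diagnoses = diagnoses)
  d2 <- filter_dataset2(d1)
  d3 <- suppressWarnings(sample_dataset3(d2, n_per_site, seed = seed + 1L))
  d4 <- build_dataset4(d3, min_group = min_group)
  d3i <- impute_lma(d3, cycles = impute_cycles, seed = seed + 2L)
  d5 <- build_dataset4(d3i, min_group = min_group)
  attr(d5, "imputation_diagnostics") <- attr(d3i, "imputation_diagnostics")
  datasets <- list(dataset1 = d1, dataset2 = d2, dataset3 = d3,
                   dataset4 = d4, dataset5 = d5)

  summary_tab <- .dataset_summary(datasets)
  spectrum <- tct_spectrum(d1, by_site = TRUE)
  herb <- .herbivory_summary(d1, rarefy_n)
  imput <- imputation_report(d3i)

  model_data <- .model_frame(d5)
  pca <- tryCatch(pca_traits(model_data[, c("lma_gm2", "leaf_area_mm2",
                                            "leaf_width_mm",
                                            "leaf_length_mm", "lw_ratio")]),
                  error = function(e) e)
  models <- .fit_model_battery(model_data, .model_frame(d1))

  manifest <- list(
    seed = seed,
    n_per_site = n_per_site, min_group = min_group,
    impute_cycles = impute_cycles, rarefy_n = rarefy_n,
    stages = data.frame(
      stage = names(datasets),
      n_in = c(NA_integer_, n_specimens(d1), n_specimens(d2),
               n_specimens(d3), n_specimens(d3)),
      n_out = vapply(datasets, n_specimens, 0L),
      row.names = NULL))
  structure(list(datasets = datasets, summary = summary_tab,
                 tct_spectrum = spectrum, herbivory = herb$metrics,
                 rarefaction = herb$rarefaction, imputation = imput,
                 pca = pca, models = models, manifest = manifest),
            class = "leaf_pipeline")
}

#' @export
print.leaf_pipeline <- function(x, ...) {
  cat("Leaf trait / herbivory pipeline\n")
  print(x$manifest$stages)
  cat("\nDataset summary:\n")
  print(x$summary, digits = 4)
  invisible(x)
}

.dataset_summary <- function(datasets) {
  rows <- lapply(names(datasets), function(nm) {
    sp <- datasets[[nm]]$specimens
    sites <- sort(unique(sp$site))
    per_site <- table(factor(sp$site, levels = sites))
    row <- data.frame(dataset = nm, n = nrow(sp),
                      n_by_site = paste(sprintf("%s: %d", sites, per_site),
                                        collapse = ", "),
                      stringsAsFactors = FALSE)
    for (v in c("leaf_area_mm2", "lma_gm2")) {
      lab <- if (v == "leaf_area_mm2") "size" else "lma"
      for (s in sites) {
        vals <- sp[[v]][sp$site == s & !is.na(sp[[v]])]
        row[[paste0("mean_", lab, "_", s)]] <-
          if (length(vals)) mean(vals) else NA_real_
        row[[paste0("sd_", lab, "_", s)]] <-
          if (length(vals) > 1) stats::sd(vals) else NA_real_
      }
      if (length(sites) == 2) {
        x1 <- sp[[v]][sp$site == sites[1] & !is.na(sp[[v]])]
        x2 <- sp[[v]][sp$site == sites[2] & !is.na(sp[[v]])]
        row[[paste0("W_", lab)]] <- if (length(x1) && length(x2))
          mann_whitney(x1, x2)$W else NA_real_
      }
    }
    row
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    allcols <- unique(unlist(lapply(rows, names)))
    for (cn in setdiff(allcols, names(r))) r[[cn]] <- NA
    r[allcols]
  }))
  rownames(out) <- NULL
  out
}

.herbivory_summary <- function(a, rarefy_n) {
  sites <- sort(unique(a$specimens$site))
  metrics <- do.call(rbind, lapply(sites, function(s) {
    sub <- assemblage_subset(a, a$specimens$specimen_id[a$specimens$site == s])
    m <- incidence_matrix(sub)
    data.frame(site = s, n_leaves = n_specimens(sub),
               dam_pct = dam_percent(sub), dto = dto(sub),
               dtr_observed = dtr_observed(m), stringsAsFactors = FALSE)
  }))
  raref <- do.call(rbind, lapply(sites, function(s) {
    sub <- assemblage_subset(a, a$specimens$specimen_id[a$specimens$site == s])
    m <- incidence_matrix(sub)
    n_use <- min(rarefy_n, nrow(m))
    if (nrow(m) < 20) {
      return(data.frame(site = s, n = NA_integer_,
                        expected_richness = NA_real_, sd = NA_real_))
    }
    r <- rarefy_analytic(m, n_use)
    cbind(site = s, r)
  }))
  rownames(metrics) <- rownames(raref) <- NULL
  list(metrics = metrics, rarefaction = raref)
}

.model_frame <- function(a) {
  sp <- a$specimens
  ht <- herbivory_table(a)
  sp$damaged <- ht$damaged[match(sp$specimen_id, ht$specimen_id)]
  sp$damaged_area_mm2 <- ht$damaged_area_mm2[match(sp$specimen_id,
                                                   ht$specimen_id)]
  sp$herbivory_index <- ht$herbivory_index[match(sp$specimen_id,
                                                 ht$specimen_id)]
  sp$lw_ratio <- sp$leaf_length_mm / sp$leaf_width_mm
  sp$tct_cl <- tct_class(sp$tct)
  sp
}

# keep only terms whose columns exist and (for factors) have >= 2 levels
.viable_terms <- function(data, terms) {
  keep <- vapply(terms, function(t) {
    if (!t %in% names(data)) return(FALSE)
    v <- data[[t]][!is.na(data[[t]])]
    if (is.character(v) || is.factor(v)) length(unique(v)) >= 2
    else length(unique(v)) >= 2
  }, logical(1))
  terms[keep]
}

.fit_one_model <- function(data, response, terms, family) {
  terms <- .viable_terms(data, terms)
  if (!length(terms)) return(list(error = "no viable terms"))
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  tryCatch({
    fit <- fit_trait_glm(fml, data, family = family)
    sel <- stepwise_aic(fit)
    sel_terms <- attr(stats::terms(sel$formula), "term.labels")
    an <- if (length(sel_terms)) {
      tryCatch(anova_type2(sel$fit), error = function(e) NULL)
    } else NULL
    list(full_formula = fml, formula = sel$formula, aic = sel$aic,
         full_aic = stats::AIC(fit),
         selected_terms = attr(stats::terms(sel$formula), "term.labels"),
         anova = an, r2 = r2_measures(sel$fit), fit = sel$fit,
         trace = sel$trace)
  }, error = function(e) list(error = conditionMessage(e),
                              full_formula = fml))
}

.fit_model_battery <- function(d5_data, d1_data) {
  d5c <- d5_data[!is.na(d5_data$lma_gm2), , drop = FALSE]
  dmg <- d5c[d5c$damaged & !is.na(d5c$damaged_area_mm2) &
               d5c$damaged_area_mm2 > 0, , drop = FALSE]
  list(
    M1 = .fit_one_model(d5c, "lma_gm2",
                        c("fossil_species", "leaf_area_mm2",
                          "phenology_modern", "area_index", "site"),
                        "gamma_identity"),
    M2 = .fit_one_model(d5c, "leaf_area_mm2",
                        c("fossil_species", "area_index",
                          "phenology_modern", "site"),
                        "gamma_identity"),
    M3 = .fit_one_model(d5c, "damaged",
                        c("site", "lma_gm2", "tct_cl", "leaf_area_mm2"),
                        "binomial_logit"),
    M3_dataset1 = .fit_one_model(
      d1_data[!is.na(d1_data$tct), , drop = FALSE], "damaged",
      c("site", "tct"), "binomial_logit"),
    M4 = .fit_one_model(dmg, "damaged_area_mm2",
                        c("leaf_area_mm2", "phenology_modern", "site",
                          "lma_gm2"),
                        "gamma_identity"),
    M5 = .fit_one_model(dmg[dmg$herbivory_index > 0, , drop = FALSE],
                        "herbivory_index",
                        c("phenology_modern", "lma_gm2", "site"),
                        "gamma_identity"))
}
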