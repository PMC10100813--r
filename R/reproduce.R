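#' Recompute the published headline metrics from supplementary-dialect data
#'
#' Given a directory holding the study's specimen-level data in the
#' package's CSV dialect, recomputes the quantities reported for the two
#' assemblages: per-site damage frequency; rarefied DT richness (with
#' analytic SD) at a standard sample size; total observed DT richness;
#' the TCT spectrum (including the share of the modal TCT and of unlobed
#' leaves); the measured-subsample trait summaries (mean leaf size, mean
#' LMA, number of leaves with measured LMA); the between-site Mann-Whitney
#' W for size and LMA; and the size of the cleaned multivariate dataset.
#'
#' Expected files: `leaves_qualitative.csv` (one row per scored leaf, both
#' sites: TCT characters plus damage in `dt_list` or wide `X<dt>` columns)
#' and `leaves_quantitative.csv` (the measured subsample with quantitative
#' traits). These correspond to the study's qualitative and quantitative
#' supplementary specimen tables, which are not redistributed with this
#' package.
#'
#' @param dir directory containing the two CSV files.
#' @param rarefy_n standard sample size for rarefied richness (default 400).
#' @param min_group rarity threshold for the cleaned dataset (default 5).
#' @return named list of numbers, one entry per metric, organised per site.
#' @export
reproduce_published_metrics <- function(dir, rarefy_n = 400, min_group = 5) {
  qual_path <- file.path(dir, "leaves_qualitative.csv")
  quant_path <- file.path(dir, "leaves_quantitative.csv")
  for (p in c(qual_path, quant_path)) {
    if (!file.exists(p)) stop("supplementary table not found: ", p,
                              call. = FALSE)
  }
  d1 <- assign_tct(read_assemblage(qual_path, name = "dataset1"))
  d3 <- assign_tct(read_assemblage(quant_path, name = "dataset3"))
  sites <- sort(unique(d1$specimens$site))
  out <- list()
  for (s in sites) {
    sub <- assemblage_subset(d1, d1$specimens$specimen_id[
      d1$specimens$site == s])
    m <- incidence_matrix(sub)
    out[[paste0("dam_pct_", s)]] <- dam_percent(sub)
    out[[paste0("dtr_total_", s)]] <- dtr_observed(m)
    if (nrow(m) >= rarefy_n) {
      r <- rarefy_analytic(m, rarefy_n)
      out[[paste0("dtr_rarefied_", rarefy_n, "_", s)]] <- r$expected_richness
      out[[paste0("dtr_rarefied_sd_", rarefy_n, "_", s)]] <- r$sd
    }
    spec <- tct_spectrum(sub)
    modal <- spec[which.max(spec$n), ]
    out[[paste0("tct_modal_", s)]] <- modal$tct
    out[[paste0("tct_modal_pct_", s)]] <- modal$pct_total
    out[[paste0("pct_unlobed_", s)]] <-
      100 * mean(sub$specimens$lobation == "unlobed")
    sp3 <- d3$specimens[d3$specimens$site == s, ]
    out[[paste0("mean_size_", s)]] <- mean(sp3$leaf_area_mm2, na.rm = TRUE)
    out[[paste0("mean_lma_", s)]] <- mean(sp3$lma_gm2, na.rm = TRUE)
    out[[paste0("n_measured_lma_", s)]] <- sum(!is.na(sp3$lma_gm2))
  }
  if (length(sites) == 2) {
    sp <- d3$specimens
    x1 <- function(v) sp[[v]][sp$site == sites[1] & !is.na(sp[[v]])]
    x2 <- function(v) sp[[v]][sp$site == sites[2] & !is.na(sp[[v]])]
    out$W_size <- mann_whitney(x1("leaf_area_mm2"), x2("leaf_area_mm2"))$W
    out$W_lma <- mann_whitney(x1("lma_gm2"), x2("lma_gm2"))$W
  }
  d4 <- build_dataset4(d3, min_group = min_group)
  out$n_dataset4 <- n_specimens(d4)
  out
}
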