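# shared fixtures and independent oracles

# small handcrafted assemblage: 2 sites, quantitative traits, damage
toy_assemblage <- function() {
  sp <- data.frame(
    specimen_id = sprintf("L%02d", 1:12),
    site = rep(c("S1", "S2"), each = 6),
    fossil_species = rep(c("alpha", "beta"), 6),
    phenology_modern = rep(c("deciduous", "evergreen"), 6),
    lobation = "unlobed", margin = "toothed",
    primary_venation = "pinnate", secondary_venation = "non-looped",
    preserved_fraction = rep(c(0.5, 0.7, 0.8, 0.9, 0.95, 1.0), 2),
    area_index = rep(c(0.5, 0.7, 0.8, 0.9, 0.95, 1.0), 2),
    leaf_length_mm = seq(40, 62, 2),
    leaf_width_mm = seq(20, 31, 1),
    leaf_area_mm2 = seq(500, 1600, 100),
    petiole_width_mm = seq(1, 2.1, 0.1),
    stringsAsFactors = FALSE)
  sp$lma_gm2 <- leaf_lma(sp$petiole_width_mm, sp$leaf_area_mm2)
  dmg <- data.frame(specimen_id = c("L01", "L01", "L02", "L07"),
                    dt = c("2", "12", "2", "unknown_gall"),
                    damaged_area_mm2 = c(10, 5, NA, 20),
                    stringsAsFactors = FALSE)
  leaf_assemblage(sp, damage = dmg, name = "toy")
}

# brute-force Mann-Whitney first-sample U with half-weighted ties
brute_force_w <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exhaustive sample-based rarefaction: mean and sd of richness over all
# subsets of n rows (population moments, matching the analytic estimator)
enumerate_rarefaction <- function(m, n) {
  N <- nrow(m)
  subsets <- utils::combn(N, n)
  rich <- apply(subsets, 2, function(idx) {
    sum(colSums(m[idx, , drop = FALSE]) > 0)
  })
  list(mean = mean(rich), sd = sqrt(mean((rich - mean(rich))^2)))
}

# random binary incidence matrix with at least one presence
random_incidence <- function(n_leaves, n_dts, p, seed) {
  set.seed(seed)
  m <- matrix(rbinom(n_leaves * n_dts, 1, p), n_leaves, n_dts,
              dimnames = list(sprintf("l%d", seq_len(n_leaves)),
                              paste0("X", seq_len(n_dts))))
  if (all(m == 0)) m[1, 1] <- 1L
  m
}

# one-species one-site assemblage with a linear LMA law, for imputation
# recovery studies; mask_frac of the LMA values are withheld
linear_lma_assemblage <- function(n = 200, mask_frac = 0.3, seed = 1,
                                  intercept = 60, slope = 0.02,
                                  resid_sd = 5) {
  set.seed(seed)
  area <- runif(n, 200, 3000)
  lma <- intercept + slope * area + rnorm(n, 0, resid_sd)
  lma <- pmax(lma, 1)
  masked <- seq_len(n) %in% sample.int(n, round(mask_frac * n))
  sp <- data.frame(
    specimen_id = sprintf("A%04d", seq_len(n)), site = "S1",
    fossil_species = "gen sp", preserved_fraction = 1, area_index = 1,
    leaf_area_mm2 = area,
    lma_gm2 = ifelse(masked, NA_real_, lma),
    stringsAsFactors = FALSE)
  list(assemblage = leaf_assemblage(sp, name = "linear-lma"),
       true_lma = lma, masked = masked)
}
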