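#' Species specification for the assemblage generator
#'
#' Describes one (synthetic) fossil-species: its trait quartet, phenology,
#' lognormal laws for lamina area and true LMA, relative abundance, per-leaf
#' damage-type incidence probabilities and the Beta law for damaged-area
#' fractions.
#'
#' @param name,family species and family labels.
#' @param phenology `"deciduous"`, `"evergreen"` or `"semi-deciduous"`.
#' @param quartet character vector of length 4: lobation, margin, primary
#'   venation, secondary venation.
#' @param size_lognormal `c(meanlog, sdlog)` for lamina area (mm^2).
#' @param lma_lognormal `c(meanlog, sdlog)` for true LMA (g m^-2).
#' @param abundance non-negative relative abundance (normalised per site).
#' @param dt_rates named numeric vector of per-leaf incidence probabilities
#'   by DT label (independent per (leaf, DT)); may be empty.
#' @param damaged_area_beta `c(alpha, beta)` for the damaged fraction of the
#'   lamina per damage observation (default `c(1, 30)`, mean about 3\%).
#' @param lw_ratio `c(meanlog, sdlog)` for the leaf length/width ratio.
#' @param growth_form growth-form label.
#' @return list of class `species_spec`.
#' @export
species_spec <- function(name, family = "unknown",
                         phenology = c("deciduous", "evergreen",
                                       "semi-deciduous"),
                         quartet = c("unlobed", "toothed", "pinnate",
                                     "non-looped"),
                         size_lognormal = c(log(1000), 0.6),
                         lma_lognormal = c(log(80), 0.15),
                         abundance = 1,
                         dt_rates = numeric(),
                         damaged_area_beta = c(1, 30),
                         lw_ratio = c(log(1.8), 0.1),
                         growth_form = "tree") {
  phenology <- match.arg(phenology)
  stopifnot(length(quartet) == 4, abundance >= 0,
            all(dt_rates >= 0 & dt_rates <= 1),
            all(damaged_area_beta > 0))
  structure(list(name = name, family = family, phenology = phenology,
                 quartet = quartet, size_lognormal = size_lognormal,
                 lma_lognormal = lma_lognormal, abundance = abundance,
                 dt_rates = dt_rates, damaged_area_beta = damaged_area_beta,
                 lw_ratio = lw_ratio, growth_form = growth_form),
            class = "species_spec")
}

#' Taphonomy specification for the assemblage generator
#'
#' Controls how the generative truth is degraded into the observable
#' record: lamina preservation fractions, petiole survival (petiole width
#' is what LMA estimation needs, and petioles are rarely preserved) and
#' multiplicative measurement noise on the preserved petiole width.
#'
#' @param preservation_beta `c(alpha, beta)` for the preserved lamina
#'   fraction, rescaled to (0.3, 1]; `NULL` disables masking entirely
#'   (every leaf fully preserved).
#' @param petiole_presence_prob probability a leaf keeps its petiole
#'   (default 0.4, emulating the scarcity of measurable petioles).
#' @param lma_noise_sd sd of the lognormal noise multiplying the true
#'   petiole width before LMA is recomputed from it (0 = noise-free).
#' @param min_measured preserved fraction required for quantitative
#'   measurements (default 0.7, the reconstruction threshold).
#' @return list of class `taphonomy_spec`.
#' @export
taphonomy_spec <- function(preservation_beta = c(4, 1.5),
                           petiole_presence_prob = 0.4,
                           lma_noise_sd = 0.05,
                           min_measured = 0.7) {
  stopifnot(petiole_presence_prob >= 0, petiole_presence_prob <= 1,
            lma_noise_sd >= 0)
  structure(list(preservation_beta = preservation_beta,
                 petiole_presence_prob = petiole_presence_prob,
                 lma_noise_sd = lma_noise_sd,
                 min_measured = min_measured),
            class = "taphonomy_spec")
}

#' Generate a synthetic leaf assemblage with its truth record
#'
#' Draws `n_leaves` leaves for one site: species by relative abundance;
#' lamina area and true LMA from the species lognormal laws; length/width
#' from the species shape ratio (elliptic lamina, area = 0.7 * length *
#' width); the true petiole width solved from the inverse LMA allometry;
#' damage types independently per (leaf, DT) at the species rates, with
#' damaged areas as Beta fractions of the lamina. Taphonomy then masks the
#' truth: preservation fractions are drawn, quantitative traits are only
#' observed for leaves preserved at or above the measurement threshold,
#' petioles survive with the given probability, and the observed LMA is
#' recomputed from the noisy petiole width. With masking disabled
#' (`preservation_beta = NULL`, `petiole_presence_prob = 1`,
#' `lma_noise_sd = 0`) the observable record equals the truth exactly.
#'
#' @param species list of [species_spec()] objects.
#' @param taph a [taphonomy_spec()].
#' @param n_leaves number of leaves to draw.
#' @param seed integer seed.
#' @param site site label.
#' @param name assemblage label.
#' @return list with `assemblage` (a [leaf_assemblage()]) and `truth` (data
#'   frame of unmasked per-leaf values; generator parameters in attribute
#'   `params`).
#' @export
generate_assemblage <- function(species, taph = taphonomy_spec(),
                                n_leaves = 1000, seed = 1, site = "S1",
                                name = site) {
  stopifnot(length(species) >= 1,
            all(vapply(species, inherits, TRUE, "species_spec")))
  ab <- vapply(species, `[[`, numeric(1), "abundance")
  if (sum(ab) <= 0) stop("abundances sum to zero", call. = FALSE)
  out <- with_seed(seed, {
    sp_idx <- sample.int(length(species), n_leaves, replace = TRUE,
                         prob = ab / sum(ab))
    ids <- sprintf("%s-%05d", site, seq_len(n_leaves))
    area <- lma_true <- lwr <- numeric(n_leaves)
    for (i in seq_along(species)) {
      hit <- sp_idx == i
      s <- species[[i]]
      area[hit] <- stats::rlnorm(sum(hit), s$size_lognormal[1],
                                 s$size_lognormal[2])
      lma_true[hit] <- stats::rlnorm(sum(hit), s$lma_lognormal[1],
                                     s$lma_lognormal[2])
      lwr[hit] <- stats::rlnorm(sum(hit), s$lw_ratio[1], s$lw_ratio[2])
    }
    width <- sqrt(area / (0.7 * lwr))
    length_mm <- lwr * width
    pw_true <- petiole_width_for_lma(lma_true, area)

    pf <- if (is.null(taph$preservation_beta)) rep(1, n_leaves) else
      0.3 + 0.7 * stats::rbeta(n_leaves, taph$preservation_beta[1],
                               taph$preservation_beta[2])
    petiole_kept <- stats::runif(n_leaves) < taph$petiole_presence_prob
    pw_obs <- pw_true * exp(stats::rnorm(n_leaves, 0, taph$lma_noise_sd))

    # damage
    dmg <- list()
    for (i in seq_along(species)) {
      s <- species[[i]]
      if (!length(s$dt_rates)) next
      hit <- which(sp_idx == i)
      for (d in names(s$dt_rates)) {
        on <- hit[stats::runif(length(hit)) < s$dt_rates[[d]]]
        if (!length(on)) next
        frac <- stats::rbeta(length(on), s$damaged_area_beta[1],
                             s$damaged_area_beta[2])
        dmg[[length(dmg) + 1]] <- data.frame(
          specimen_id = ids[on], dt = d,
          damaged_area_mm2 = frac * area[on], stringsAsFactors = FALSE)
      }
    }
    dmg <- if (length(dmg)) do.call(rbind, dmg) else NULL
    list(sp_idx = sp_idx, ids = ids, area = area, lma_true = lma_true,
         width = width, length_mm = length_mm, pw_true = pw_true,
         pf = pf, petiole_kept = petiole_kept, pw_obs = pw_obs, dmg = dmg)
  })

  s_of <- function(field, mode = "character") {
    vapply(species[out$sp_idx], `[[`, vector(mode, 1), field)
  }
  quartets <- t(vapply(species[out$sp_idx], `[[`, character(4), "quartet"))
  measured <- out$pf >= taph$min_measured
  lma_obs <- ifelse(measured & out$petiole_kept,
                    leaf_lma(out$pw_obs, out$area), NA_real_)
  specimens <- data.frame(
    specimen_id = out$ids, site = site,
    family = s_of("family"), fossil_species = s_of("name"),
    growth_form = s_of("growth_form"),
    phenology_modern = s_of("phenology"),
    lobation = quartets[, 1], margin = quartets[, 2],
    primary_venation = quartets[, 3], secondary_venation = quartets[, 4],
    preserved_fraction = out$pf,
    area_index = ifelse(measured, out$pf, NA_real_),
    leaf_length_mm = ifelse(measured, out$length_mm, NA_real_),
    leaf_width_mm = ifelse(measured, out$width, NA_real_),
    leaf_area_mm2 = ifelse(measured, out$area, NA_real_),
    petiole_width_mm = ifelse(measured & out$petiole_kept, out$pw_obs,
                              NA_real_),
    lma_gm2 = lma_obs,
    lma_source = ifelse(is.na(lma_obs), "missing", "measured"),
    stringsAsFactors = FALSE)
  dmg <- out$dmg
  if (!is.null(dmg)) {
    # damaged area only measurable on measured leaves; cap the per-leaf sum
    leaf_area <- out$area[match(dmg$specimen_id, out$ids)]
    tot <- tapply(dmg$damaged_area_mm2, dmg$specimen_id, sum)
    over <- names(tot)[tot > 0.9 * out$area[match(names(tot), out$ids)]]
    if (length(over)) {
      idx <- dmg$specimen_id %in% over
      scale <- (0.9 * leaf_area[idx]) /
        as.numeric(tot[dmg$specimen_id[idx]])
      dmg$damaged_area_mm2[idx] <- dmg$damaged_area_mm2[idx] * scale
    }
    dmg$damaged_area_mm2[!measured[match(dmg$specimen_id, out$ids)]] <-
      NA_real_
  }
  a <- leaf_assemblage(specimens, damage = dmg, name = name)
  truth <- data.frame(
    specimen_id = out$ids, site = site, fossil_species = s_of("name"),
    phenology = s_of("phenology"),
    true_area_mm2 = out$area, true_length_mm = out$length_mm,
    true_width_mm = out$width, true_lma_gm2 = out$lma_true,
    true_petiole_width_mm = out$pw_true,
    preserved_fraction = out$pf, petiole_kept = out$petiole_kept,
    tct_true = classify_tct(quartets[, 1], quartets[, 2], quartets[, 3],
                            quartets[, 4]),
    stringsAsFactors = FALSE)
  attr(truth, "params") <- list(species = species, taphonomy = taph,
                                n_leaves = n_leaves, seed = seed)
  list(assemblage = a, truth = truth)
}

#' Combine assemblages (e.g. the two sites of a study)
#'
#' @param ... [leaf_assemblage()] objects with disjoint specimen ids.
#' @param name label of the combined assemblage.
#' @return a [leaf_assemblage()].
#' @export
combine_assemblages <- function(..., name = "combined") {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "leaf_assemblage")))
  leaf_assemblage(do.call(rbind, lapply(parts, `[[`, "specimens")),
                  damage = do.call(rbind, lapply(parts, `[[`, "damage")),
                  dt_catalog = parts[[1]]$dt_catalog, name = name)
}

#' Built-in two-site scenario presets
#'
#' Two ready-made communities reproducing the qualitative contrast between
#' a deciduous-dominated assemblage rich in unlobed/toothed/non-looped
#' (TCT F) leaves with sparse damage (about 5\% of leaves), and an
#' evergreen-dominated assemblage rich in entire-margined / looped types
#' (TCTs A and E) with markedly more damage (about 12\%) and higher
#' damage-type richness. Evergreen species have their LMA law above the
#' 129 g m^-2 evergreen threshold, deciduous species below the 87 g m^-2
#' deciduous threshold.
#'
#' @return named list of scenarios; each has `site`, `species` (list of
#'   [species_spec()]), `taph` ([taphonomy_spec()]) and a default
#'   `n_leaves`.
#' @export
scenario_presets <- function() {
  dec_size <- c(log(1100), 0.6)
  dec_lma <- c(log(75), 0.14)
  evg_size <- c(log(550), 0.55)
  evg_lma <- c(log(145), 0.13)
  Fq <- c("unlobed", "toothed", "pinnate", "non-looped")
  Eq <- c("unlobed", "toothed", "pinnate", "looped")
  Aq <- c("unlobed", "entire", "pinnate", "looped")
  Bq <- c("unlobed", "entire", "pinnate", "non-looped")
  Pq <- c("lobed", "toothed", "palmate", "non-looped")
  sf <- list(
    species_spec("Juglandacea synthetica", "Juglandaceae", "deciduous", Fq,
                 dec_size, dec_lma, abundance = 0.30,
                 dt_rates = c("2" = 0.030, "5" = 0.015, "14" = 0.015,
                              "78" = 0.015, "50" = 0.0075)),
    species_spec("Betulacea synthetica", "Betulaceae", "deciduous", Fq,
                 dec_size, dec_lma, abundance = 0.20,
                 dt_rates = c("2" = 0.030, "78" = 0.0225, "214" = 0.0075)),
    species_spec("Betulacea altera", "Betulaceae", "deciduous", Fq,
                 dec_size, dec_lma, abundance = 0.15,
                 dt_rates = c("2" = 0.015, "12" = 0.015)),
    species_spec("Ulmacea synthetica", "Ulmaceae", "deciduous", Fq,
                 dec_size, dec_lma, abundance = 0.10,
                 dt_rates = c("2" = 0.0225, "3" = 0.0075)),
    species_spec("Salicacea synthetica", "Salicaceae", "deciduous", Fq,
                 c(log(1500), 0.5), dec_lma, abundance = 0.05,
                 dt_rates = c("12" = 0.015)),
    species_spec("Platanacea synthetica", "Platanaceae", "deciduous", Eq,
                 dec_size, c(log(95), 0.12), abundance = 0.08,
                 dt_rates = c("2" = 0.015, "5" = 0.015)),
    species_spec("Lauracea synthetica", "Lauraceae", "evergreen", Aq,
                 evg_size, evg_lma, abundance = 0.07,
                 dt_rates = c("2" = 0.015), growth_form = "shrub"),
    species_spec("Aceroides syntheticum", "Sapindaceae", "deciduous", Pq,
                 c(log(1300), 0.55), dec_lma, abundance = 0.05,
                 dt_rates = c("2" = 0.030, "unknown_gall" = 0.015)))
  sube <- list(
    species_spec("Juglandacea viridis", "Juglandaceae", "evergreen", Eq,
                 evg_size, evg_lma, abundance = 0.30,
                 dt_rates = c("2" = 0.072, "5" = 0.036, "20" = 0.054,
                              "12" = 0.018),
                 damaged_area_beta = c(2, 25)),
    species_spec("Lauracea viridis", "Lauraceae", "evergreen", Aq,
                 evg_size, evg_lma, abundance = 0.22,
                 dt_rates = c("2" = 0.072, "3" = 0.036, "12" = 0.036),
                 damaged_area_beta = c(2, 25), growth_form = "shrub"),
    species_spec("Lauracea cinnamomea", "Lauraceae", "evergreen", Aq,
                 evg_size, evg_lma, abundance = 0.08,
                 dt_rates = c("2" = 0.054, "50" = 0.018),
                 damaged_area_beta = c(2, 25)),
    species_spec("Platanacea synthetica", "Platanaceae", "deciduous", Eq,
                 dec_size, c(log(95), 0.12), abundance = 0.10,
                 dt_rates = c("2" = 0.054, "18" = 0.018, "38" = 0.018)),
    species_spec("Elaeocarpacea synthetica", "Elaeocarpaceae", "evergreen",
                 Fq, evg_size, evg_lma, abundance = 0.08,
                 dt_rates = c("20" = 0.090, "2" = 0.036),
                 damaged_area_beta = c(2, 25)),
    species_spec("Ulmacea altera", "Ulmaceae", "deciduous", Fq,
                 dec_size, dec_lma, abundance = 0.07,
                 dt_rates = c("2" = 0.054, "12" = 0.036)),
    species_spec("Aceroides alter", "Sapindaceae", "deciduous", Pq,
                 c(log(1300), 0.55), dec_lma, abundance = 0.07,
                 dt_rates = c("2" = 0.072, "unknown_gall" = 0.036)),
    species_spec("Fabacea synthetica", "Fabaceae", "semi-deciduous", Bq,
                 c(log(400), 0.5), c(log(110), 0.12), abundance = 0.08,
                 dt_rates = c("2" = 0.036), growth_form = "shrub"))
  list(
    sf_like = list(site = "Sf", species = sf, taph = taphonomy_spec(),
                   n_leaves = 4935),
    sube_like = list(site = "SuBe", species = sube, taph = taphonomy_spec(),
                     n_leaves = 1349))
}

#' Generate a preset scenario
#'
#' @param preset `"sf_like"` or `"sube_like"`.
#' @param n_leaves override of the preset's default leaf count.
#' @param seed integer seed.
#' @return as [generate_assemblage()].
#' @export
generate_scenario <- function(preset = c("sf_like", "sube_like"),
                              n_leaves = NULL, seed = 1) {
  preset <- match.arg(preset)
  sc <- scenario_presets()[[preset]]
  generate_assemblage(sc$species, sc$taph,
                      n_leaves = if (is.null(n_leaves)) sc$n_leaves
                                 else n_leaves,
                      seed = seed, site = sc$site, name = sc$site)
}
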