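#' Damage-type catalog
#'
#' Maps damage-type (DT) labels to functional feeding groups (FFGs). The
#' default catalog covers the DTs recorded in the study assemblages: hole
#' feeding (DTs 1-5, 16, 81), margin feeding (12-14), surface feeding
#' (29-31, 50, 57, and provisionally DT 78, feeding concentrated between
#' secondary veins), skeletonization (20-22, 61), mining
#' (18, 35-41, 45), galling (32-34, 80, 85, 214 and `"unknown_gall"`),
#' piercing-and-sucking (46-48). The FFG of DTs 78 and 81 is not fixed by
#' the source record and the defaults are provisional; pass your own table
#' to override. DTs absent from the catalog fall into `"other"` with a
#' warning when metrics are scoped by FFG.
#'
#' @param entries data frame with columns `dt` (character label) and `ffg`.
#' @return data frame of class `dt_catalog`.
#' @export
dt_catalog <- function(entries) {
  stopifnot(is.data.frame(entries), all(c("dt", "ffg") %in% names(entries)))
  entries$dt <- as.character(entries$dt)
  ok <- c("hole_feeding", "margin_feeding", "surface_feeding",
          "skeletonization", "mining", "galling", "piercing_sucking", "other")
  bad <- setdiff(unique(entries$ffg), ok)
  if (length(bad)) stop("unknown FFG: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyDuplicated(entries$dt)) stop("duplicate DT in catalog", call. = FALSE)
  structure(entries[, c("dt", "ffg")], class = c("dt_catalog", "data.frame"))
}

#' @rdname dt_catalog
#' @export
default_dt_catalog <- function() {
  dt_catalog(data.frame(
    dt = c("1", "2", "3", "4", "5", "16", "81",
           "12", "13", "14",
           "29", "30", "31", "50", "57", "78",
           "20", "21", "22", "61",
           "18", "35", "36", "37", "38", "39", "40", "41", "45",
           "unknown_mine",
           "32", "33", "34", "80", "85", "214", "unknown_gall",
           "46", "47", "48"),
    ffg = c(rep("hole_feeding", 7),
            rep("margin_feeding", 3),
            rep("surface_feeding", 6),
            rep("skeletonization", 4),
            rep("mining", 10),
            rep("galling", 7),
            rep("piercing_sucking", 3)),
    stringsAsFactors = FALSE))
}

#' FFGs making up the external foliage-feeding guild
#' @return character vector of the four external FFGs.
#' @export
external_ffgs <- function() {
  c("hole_feeding", "margin_feeding", "surface_feeding", "skeletonization")
}

# resolve an ffg scope ("total"/"external"/FFG names) to a DT subset
.scope_dts <- function(dts, catalog, scope) {
  if (is.null(scope) || identical(scope, "total")) return(unique(dts))
  ffgs <- if (identical(scope, "external")) external_ffgs() else scope
  hit <- match(dts, catalog$dt)
  unmapped <- unique(dts[is.na(hit)])
  if (length(unmapped)) {
    warning("DT(s) not in catalog mapped to 'other': ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  ffg_of <- ifelse(is.na(hit), "other", catalog$ffg[hit])
  unique(dts[ffg_of %in% ffgs])
}

#' Damage frequency (DAM\%)
#'
#' Percentage of leaves bearing at least one damage type, optionally
#' restricted to an FFG scope. The denominator is all leaves in the sample.
#'
#' @param a a [leaf_assemblage()].
#' @param scope `"total"` (default), `"external"`, or a vector of FFG names.
#' @return percentage in \[0, 100\].
#' @export
dam_percent <- function(a, scope = "total") {
  stopifnot(inherits(a, "leaf_assemblage"))
  n <- nrow(a$specimens)
  if (n == 0) stop("damage frequency undefined for an empty assemblage",
                   call. = FALSE)
  dts <- .scope_dts(unique(a$damage$dt), a$dt_catalog, scope)
  dmg <- a$damage[a$damage$dt %in% dts, , drop = FALSE]
  100 * length(unique(dmg$specimen_id)) / n
}

#' Damage-type occurrence (DTO)
#'
#' Total count of (leaf, DT) presences; a DT present on k leaves contributes
#' k, and a leaf with several DTs counts once per DT. Not standardised by
#' sample size.
#'
#' @inheritParams dam_percent
#' @return non-negative integer.
#' @export
dto <- function(a, scope = "total") {
  stopifnot(inherits(a, "leaf_assemblage"))
  dts <- .scope_dts(unique(a$damage$dt), a$dt_catalog, scope)
  dmg <- a$damage[a$damage$dt %in% dts, , drop = FALSE]
  nrow(unique(dmg[, c("specimen_id", "dt")]))
}

#' Leaves-by-DT incidence matrix
#'
#' Binary matrix with one row per leaf (sampling unit, input order) and one
#' column per damage type, columns labelled `X<dt>`.
#'
#' @param a a [leaf_assemblage()].
#' @param scope FFG scope as in [dam_percent()].
#' @return integer 0/1 matrix with specimen ids as row names; zero columns
#'   when no damage falls in scope.
#' @export
incidence_matrix <- function(a, scope = "total") {
  stopifnot(inherits(a, "leaf_assemblage"))
  ids <- a$specimens$specimen_id
  dts <- .scope_dts(unique(a$damage$dt), a$dt_catalog, scope)
  dts <- .sort_dts(dts)
  m <- matrix(0L, nrow = length(ids), ncol = length(dts),
              dimnames = list(ids, if (length(dts)) paste0("X", dts)))
  dmg <- unique(a$damage[a$damage$dt %in% dts, c("specimen_id", "dt")])
  if (nrow(dmg)) {
    m[cbind(match(dmg$specimen_id, ids), match(dmg$dt, dts))] <- 1L
  }
  m
}

.sort_dts <- function(dts) {
  num <- suppressWarnings(as.numeric(dts))
  c(dts[!is.na(num)][order(num[!is.na(num)])], sort(dts[is.na(num)]))
}

#' Write / read an incidence matrix in the wide CSV dialect
#'
#' First column `specimen_id`, then 0/1 columns `X<dt>`.
#' @param m incidence matrix from [incidence_matrix()].
#' @param path file path.
#' @return `path` invisibly; `read_incidence_matrix()` returns the matrix.
#' @export
write_incidence_matrix <- function(m, path) {
  df <- data.frame(specimen_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence_matrix
#' @export
read_incidence_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "specimen_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$specimen_id
  m
}

#' Observed damage-type richness (DTR)
#'
#' Number of damage types present in the sample (columns of the incidence
#' matrix with at least one presence).
#' @param m incidence matrix.
#' @return non-negative integer.
#' @export
dtr_observed <- function(m) {
  if (!length(m)) return(0L)
  sum(colSums(m) > 0)
}

#' Analytic sample-based rarefaction of damage-type richness
#'
#' Expected DT richness in a random subset of `n` of the `N` leaves, with
#' the leaves as sampling units:
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N-N_i}{n} \Big/ \binom{N}{n}\right],}
#' where `N_i` is the number of leaves bearing DT i. The variance is the
#' exact hypergeometric form including pairwise co-occurrence terms
#' (Heck-type): with `q_i` the absence probability of DT i and `q_{ij}` the
#' joint absence probability (from the union count of leaves bearing i or
#' j), \eqn{Var = \sum_i q_i(1-q_i) + 2\sum_{i<j}(q_{ij} - q_i q_j)}. All
#' binomial coefficients are computed in log space. At `n = N` the estimator
#' returns the observed richness with SD 0.
#'
#' Richness standardisation is conventionally not attempted on very small
#' samples; below `cutoff` leaves (default 20) the function refuses unless
#' `force = TRUE`.
#'
#' @param m incidence matrix (leaves x DTs).
#' @param n subset size(s), `1 <= n <= nrow(m)`; may be a vector.
#' @param cutoff minimum number of leaves (default 20).
#' @param force compute even below the cut-off.
#' @return data frame with columns `n`, `expected_richness`, `sd`.
#' @export
rarefy_analytic <- function(m, n, cutoff = 20, force = FALSE) {
  N <- nrow(m)
  if (is.null(N) || N == 0) stop("empty incidence matrix", call. = FALSE)
  if (N < cutoff && !force) {
    stop("sample below cut-off for rarefaction (", N, " < ", cutoff,
         " leaves); use force = TRUE to override", call. = FALSE)
  }
  if (any(n < 1 | n > N)) {
    stop("n must satisfy 1 <= n <= ", N, call. = FALSE)
  }
  Ni <- colSums(m > 0)
  Ni <- Ni[Ni > 0]
  S <- length(Ni)
  if (S == 0) {
    return(data.frame(n = n, expected_richness = 0, sd = 0))
  }
  pres <- m[, colSums(m > 0) > 0, drop = FALSE] > 0
  union_mat <- outer(Ni, Ni, "+") - crossprod(pres)  # |U_i u U_j|
  res <- vapply(n, function(nn) {
    lq <- function(k) {
      # log P(a DT borne by k leaves is absent from the subset)
      out <- ifelse(k > N - nn, -Inf,
                    lchoose(N - k, nn) - lchoose(N, nn))
      out
    }
    qi <- exp(lq(Ni))
    e <- sum(1 - qi)
    qij <- matrix(exp(lq(as.vector(union_mat))), S, S)
    cov_term <- qij - outer(qi, qi)
    v <- sum(qi * (1 - qi)) + sum(cov_term[upper.tri(cov_term)]) * 2
    c(e, sqrt(max(v, 0)))
  }, numeric(2))
  data.frame(n = n, expected_richness = res[1, ], sd = res[2, ])
}

#' Monte-Carlo sample-based rarefaction
#'
#' Resampling counterpart of [rarefy_analytic()]: mean and SD of richness
#' over random leaf subsets without replacement. Serves as the simulation
#' cross-check of the analytic estimator.
#'
#' @inheritParams rarefy_analytic
#' @param n single subset size.
#' @param reps number of random subsets.
#' @param seed integer seed (private RNG stream).
#' @return list with `mean`, `sd`, `reps`.
#' @export
rarefy_montecarlo <- function(m, n, reps = 1000, seed, cutoff = 20,
                              force = FALSE) {
  N <- nrow(m)
  if (is.null(N) || N == 0) stop("empty incidence matrix", call. = FALSE)
  if (N < cutoff && !force) {
    stop("sample below cut-off for rarefaction (", N, " < ", cutoff,
         " leaves); use force = TRUE to override", call. = FALSE)
  }
  if (length(n) != 1 || n < 1 || n > N) {
    stop("n must satisfy 1 <= n <= ", N, call. = FALSE)
  }
  pres <- m > 0
  rich <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- sample.int(N, n)
      sum(colSums(pres[idx, , drop = FALSE]) > 0)
    }, numeric(1))
  })
  list(mean = mean(rich), sd = stats::sd(rich), reps = reps)
}

#' Rarefaction curves by group and FFG scope
#'
#' Splits the assemblage by the grouping variable, scopes the damage to an
#' FFG guild, and rarefies each group's incidence matrix over `n_grid`
#' (truncated at the group size). Groups below the leaf cut-off are reported
#' as skipped, not computed.
#'
#' @param a a [leaf_assemblage()].
#' @param grouping `"assemblage"`, `"site"`, `"phenology"`, `"tct"`, or
#'   `"species"`.
#' @param scope `"total"`, `"external"`, `"mining"`, `"galling"`, or FFG names.
#' @param n_grid subset sizes to evaluate (default 1..min(400, group size)).
#' @param cutoff minimum group size (default 20 leaves).
#' @return list with `curves` (named list of [rarefy_analytic()] tables) and
#'   `skipped` (data frame of group, size, reason).
#' @export
rarefaction_by_group <- function(a, grouping = "site", scope = "total",
                                 n_grid = NULL, cutoff = 20) {
  stopifnot(inherits(a, "leaf_assemblage"))
  scope <- if (identical(scope, "mining")) "mining"
           else if (identical(scope, "galling")) "galling" else scope
  key <- switch(grouping,
    assemblage = rep(a$name, nrow(a$specimens)),
    site = a$specimens$site,
    phenology = a$specimens$phenology_modern,
    tct = a$specimens$tct,
    species = a$specimens$fossil_species,
    stop("unknown grouping: ", grouping, call. = FALSE))
  curves <- list()
  skipped <- data.frame(group = character(), n_leaves = integer(),
                        reason = character(), stringsAsFactors = FALSE)
  for (g in sort(unique(stats::na.omit(key)))) {
    ids <- a$specimens$specimen_id[!is.na(key) & key == g]
    if (length(ids) < cutoff) {
      skipped <- rbind(skipped, data.frame(group = g,
                                           n_leaves = length(ids),
                                           reason = "below cut-off"))
      next
    }
    sub <- assemblage_subset(a, ids)
    m <- incidence_matrix(sub, scope = scope)
    grid <- if (is.null(n_grid)) seq_len(min(400, length(ids)))
            else n_grid[n_grid <= length(ids)]
    curves[[g]] <- rarefy_analytic(m, grid, cutoff = cutoff)
  }
  list(curves = curves, skipped = skipped)
}

#' Herbivory index (HI)
#'
#' Damaged lamina area divided by lamina area: a dimensionless fraction
#' (multiply by 100 for percent display).
#'
#' @param damaged_area_mm2 damaged area in mm^2, non-negative.
#' @param leaf_area_mm2 lamina area in mm^2, strictly positive.
#' @return fraction in \[0, 1\].
#' @export
herbivory_index <- function(damaged_area_mm2, leaf_area_mm2) {
  if (any(!is.na(leaf_area_mm2) & leaf_area_mm2 <= 0)) {
    stop("leaf area must be strictly positive", call. = FALSE)
  }
  if (any(!is.na(damaged_area_mm2) & damaged_area_mm2 < 0)) {
    stop("damaged area must be non-negative", call. = FALSE)
  }
  bad <- !is.na(damaged_area_mm2) & !is.na(leaf_area_mm2) &
    damaged_area_mm2 > leaf_area_mm2
  if (any(bad)) stop("damaged area exceeds leaf area", call. = FALSE)
  damaged_area_mm2 / leaf_area_mm2
}

#' Specimen-level herbivory table
#'
#' Per-leaf totals used by the damage GLMs: presence/absence of damage,
#' total damaged area (summing the per-DT measurements) and HI.
#' @param a a [leaf_assemblage()].
#' @return data frame with one row per specimen.
#' @export
herbivory_table <- function(a) {
  stopifnot(inherits(a, "leaf_assemblage"))
  sp <- a$specimens
  dmg_ids <- unique(a$damage$specimen_id)
  dam_area <- tapply(a$damage$damaged_area_mm2,
                     factor(a$damage$specimen_id, levels = sp$specimen_id),
                     function(x) if (all(is.na(x))) NA_real_
                                 else sum(x, na.rm = TRUE))
  dam_area <- as.numeric(dam_area)
  dam_area[is.na(dam_area) & !(sp$specimen_id %in% dmg_ids)] <- 0
  hi <- ifelse(is.na(dam_area) | is.na(sp$leaf_area_mm2), NA_real_,
               dam_area / sp$leaf_area_mm2)
  data.frame(specimen_id = sp$specimen_id, site = sp$site,
             damaged = sp$specimen_id %in% dmg_ids,
             damaged_area_mm2 = dam_area,
             herbivory_index = hi, stringsAsFactors = FALSE)
}
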