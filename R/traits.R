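#' Leaf mass per area from petiole-width allometry
#'
#' For dicot leaves, LMA (g m^-2) is estimated from the petiole width at the
#' lamina insertion and the lamina area through the base-10 log-log
#' allometry
#' \deqn{\log_{10}(\mathrm{LMA}) = 3.070 + 0.382\,\log_{10}(\mathrm{pw}^2/\mathrm{area}).}
#' The predictor is dimensionless in the combination pw^2/area, so scaling
#' the leaf isometrically leaves the estimate unchanged.
#'
#' @param petiole_width_mm petiole width in mm, strictly positive.
#' @param leaf_area_mm2 lamina area in mm^2, strictly positive.
#' @return LMA in g m^-2.
#' @export
leaf_lma <- function(petiole_width_mm, leaf_area_mm2) {
  if (any(!is.na(petiole_width_mm) & petiole_width_mm <= 0) ||
      any(!is.na(leaf_area_mm2) & leaf_area_mm2 <= 0)) {
    stop("petiole width and leaf area must be strictly positive",
         call. = FALSE)
  }
  10^(3.070 + 0.382 * log10(petiole_width_mm^2 / leaf_area_mm2))
}

#' Petiole width implied by an LMA value (inverse allometry)
#'
#' Solves the allometry of [leaf_lma()] for petiole width given LMA and
#' lamina area; `leaf_lma(petiole_width_for_lma(l, a), a)` returns `l`.
#'
#' @param lma_gm2 LMA in g m^-2, strictly positive.
#' @param leaf_area_mm2 lamina area in mm^2, strictly positive.
#' @return petiole width in mm.
#' @export
petiole_width_for_lma <- function(lma_gm2, leaf_area_mm2) {
  if (any(!is.na(lma_gm2) & lma_gm2 <= 0) ||
      any(!is.na(leaf_area_mm2) & leaf_area_mm2 <= 0)) {
    stop("LMA and leaf area must be strictly positive", call. = FALSE)
  }
  sqrt(leaf_area_mm2 * 10^((log10(lma_gm2) - 3.070) / 0.382))
}

#' Phenology class from mean LMA
#'
#' Mean LMA below 87 g m^-2 indicates a deciduous habit, above 129 g m^-2 an
#' evergreen habit; the band between them (boundaries inclusive) is the
#' deciduous-evergreen transition, labelled `"intermediate"`. Means should be
#' taken over at least five leaves per species (enforced by
#' [species_trait_summary()]).
#'
#' @param mean_lma mean LMA in g m^-2, strictly positive.
#' @param deciduous_max,evergreen_min thresholds in g m^-2 (defaults 87, 129).
#' @return character vector: `"deciduous"`, `"intermediate"`, `"evergreen"`.
#' @export
phenology_from_lma <- function(mean_lma, deciduous_max = 87,
                               evergreen_min = 129) {
  if (any(!is.na(mean_lma) & mean_lma <= 0)) {
    stop("mean_lma must be strictly positive", call. = FALSE)
  }
  out <- rep(NA_character_, length(mean_lma))
  out[mean_lma < deciduous_max] <- "deciduous"
  out[mean_lma >= deciduous_max & mean_lma <= evergreen_min] <- "intermediate"
  out[mean_lma > evergreen_min] <- "evergreen"
  out
}

#' Per-species trait summary with LMA-based phenology
#'
#' One row per fossil-species with at least `min_n` measured leaves;
#' eligibility is enforced per metric (a species can have enough area
#' measurements but too few LMA values, in which case its mean LMA and
#' phenology are `NA`).
#'
#' @param a a [leaf_assemblage()].
#' @param min_n minimum measured leaves per metric (default 5).
#' @param by_site summarise per (site, species) instead of pooling.
#' @return data frame with n and mean per metric plus `phenology_lma`.
#' @export
species_trait_summary <- function(a, min_n = 5, by_site = FALSE) {
  stopifnot(inherits(a, "leaf_assemblage"))
  sp <- a$specimens
  sp <- sp[!is.na(sp$fossil_species) & sp$fossil_species != "unknown", ,
           drop = FALSE]
  key <- if (by_site) interaction(sp$site, sp$fossil_species, drop = TRUE)
         else factor(sp$fossil_species)
  rows <- lapply(split(sp, key), function(d) {
    area <- d$leaf_area_mm2[!is.na(d$leaf_area_mm2)]
    lma <- d$lma_gm2[!is.na(d$lma_gm2)]
    data.frame(
      site = if (by_site) d$site[1] else NA_character_,
      fossil_species = d$fossil_species[1],
      n_leaves = nrow(d),
      n_area = length(area),
      mean_area_mm2 = if (length(area) >= min_n) mean(area) else NA_real_,
      n_lma = length(lma),
      mean_lma_gm2 = if (length(lma) >= min_n) mean(lma) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- !is.na(out$mean_area_mm2) | !is.na(out$mean_lma_gm2)
  out <- out[keep, , drop = FALSE]
  out$phenology_lma <- ifelse(is.na(out$mean_lma_gm2), NA_character_,
                              phenology_from_lma(out$mean_lma_gm2))
  if (!by_site) out$site <- NULL
  rownames(out) <- NULL
  out
}

# ---- outline geometry -------------------------------------------------------

.close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2 || nrow(ring) < 3) {
    stop("a ring needs >= 3 vertices with 2 coordinates", call. = FALSE)
  }
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

.ring_area <- function(ring) {
  ring <- .close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

.check_simple <- function(ring) {
  ring <- .close_ring(ring)
  n <- nrow(ring) - 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      if (.segments_intersect(ring[i, ], ring[i + 1, ],
                              ring[j, ], ring[j + 1, ])) {
        stop("self-intersecting ring", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Measure a leaf outline pair
#'
#' Given the preserved (minimum) and reconstructed (maximum) lamina outlines
#' as closed rings in mm coordinates, returns the quantities measured on the
#' reconstructed outline: lamina area (shoelace formula), leaf length
#' (extent along the principal axis of the outline's vertex cloud,
#' approximating the manual along-the-midrib measurement), leaf width
#' (extent along the orthogonal axis), plus the area index
#' IA = preserved area / reconstructed area.
#'
#' @param preserved,reconstructed two-column matrices of ring vertices (mm);
#'   rings are closed automatically and must be simple. `preserved` may be a
#'   WKT `POLYGON` string, see [read_wkt_ring()].
#' @return list with `area_mm2`, `length_mm`, `width_mm`, `area_index`.
#' @export
polygon_measurements <- function(preserved, reconstructed) {
  if (is.character(preserved)) preserved <- read_wkt_ring(preserved)
  if (is.character(reconstructed)) reconstructed <- read_wkt_ring(reconstructed)
  preserved <- .close_ring(preserved)
  reconstructed <- .close_ring(reconstructed)
  .check_simple(preserved)
  .check_simple(reconstructed)
  a_min <- .ring_area(preserved)
  a_max <- .ring_area(reconstructed)
  if (a_min > a_max + 1e-9 * a_max) {
    stop("preserved area exceeds reconstructed area", call. = FALSE)
  }
  pts <- reconstructed[-nrow(reconstructed), , drop = FALSE]
  ctr <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(stats::cov(ctr), symmetric = TRUE)$vectors
  proj <- ctr %*% ev
  ext <- apply(proj, 2, function(v) diff(range(v)))
  list(area_mm2 = a_max,
       length_mm = max(ext),
       width_mm = min(ext),
       area_index = min(a_min / a_max, 1))
}

#' Parse a WKT POLYGON outer ring
#'
#' Minimal reader for strings like
#' `"POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))"`; only the outer ring is used.
#' @param wkt a WKT POLYGON string.
#' @return two-column numeric matrix of vertices.
#' @export
read_wkt_ring <- function(wkt) {
  m <- regmatches(wkt, regexpr("\\(\\(([^)]*)\\)", wkt))
  if (!length(m)) stop("not a WKT POLYGON: ", wkt, call. = FALSE)
  body <- gsub("[()]", "", m)
  pts <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  out <- t(vapply(pts, function(p) as.numeric(p[1:2]), numeric(2)))
  if (anyNA(out)) stop("malformed WKT coordinates", call. = FALSE)
  out
}
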