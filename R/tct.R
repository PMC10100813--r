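#' Default trait-combination-type (TCT) letter map
#'
#' The 16 TCTs arise from four binary leaf-architectural characters:
#' lobation (lobed/unlobed), margin (entire/toothed), primary venation
#' (pinnate/palmate) and secondary venation (looped/non-looped). The default
#' map enumerates the quartets in nested order (lobation, then margin, then
#' primary, then secondary venation), assigning letters A..P:
#' unlobed/entire/pinnate/looped = A through lobed/toothed/palmate/non-looped
#' = P. This reproduces the anchor types of the scheme (A the entire-margined
#' laurophyll type, B its non-looped legume counterpart, E/F the toothed
#' pinnate types, P the lobed palmate type). The map is data, not code:
#' supply any 16-row table with the same columns to use another lettering.
#'
#' @return data frame with columns `lobation`, `margin`, `primary_venation`,
#'   `secondary_venation`, `tct` (letters A..P).
#' @export
default_tct_map <- function() {
  grid <- expand.grid(
    secondary_venation = c("looped", "non-looped"),
    primary_venation = c("pinnate", "palmate"),
    margin = c("entire", "toothed"),
    lobation = c("unlobed", "lobed"),
    stringsAsFactors = FALSE)
  grid <- grid[, c("lobation", "margin", "primary_venation",
                   "secondary_venation")]
  grid$tct <- LETTERS[1:16]
  grid
}

.validate_tct_map <- function(map) {
  need <- c("lobation", "margin", "primary_venation", "secondary_venation",
            "tct")
  if (!all(need %in% names(map))) {
    stop("TCT map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(map) != 16 || anyDuplicated(map$tct) ||
      anyDuplicated(map[, need[1:4]])) {
    stop("TCT map must be a bijection between the 16 quartets and 16 letters",
         call. = FALSE)
  }
  map
}

#' Classify a trait quartet into a TCT letter
#'
#' Vectorised over the four characters. Any `"unknown"` among the characters
#' yields `NA` (unclassifiable; no guessing) rather than an error, so that
#' such specimens can be excluded downstream.
#'
#' @param lobation,margin,primary_venation,secondary_venation character
#'   vectors with the level sets of [leaf_assemblage()].
#' @param map a TCT map, default [default_tct_map()].
#' @return character vector of letters A..P, `NA` where unclassifiable.
#' @export
classify_tct <- function(lobation, margin, primary_venation,
                         secondary_venation, map = default_tct_map()) {
  map <- .validate_tct_map(map)
  key <- paste(lobation, margin, primary_venation, secondary_venation,
               sep = "|")
  map_key <- paste(map$lobation, map$margin, map$primary_venation,
                   map$secondary_venation, sep = "|")
  map$tct[match(key, map_key)]
}

#' Assign TCTs to specimens (specimen, taxonomy or combined mode)
#'
#' In `"specimen"` mode each leaf is classified from its own four observed
#' characters. In `"taxonomy"` mode the code comes from the fossil-species
#' diagnosis when the diagnosis implies exactly one TCT. `"combined"` mode
#' prefers the specimen-based code and falls back on the taxonomy-based one
#' (the usual case being poor visibility of secondary venation on leaves of
#' well-determined species); leaves where the diagnosis implies several TCTs
#' stay unassigned.
#'
#' @param a a [leaf_assemblage()].
#' @param mode one of `"specimen"`, `"taxonomy"`, `"combined"`.
#' @param diagnoses optional data frame `fossil_species`, `tct` with one row
#'   per (species, candidate letter); species listed with several rows imply
#'   several TCTs.
#' @param map TCT map, default [default_tct_map()].
#' @return the assemblage with its `tct` specimen column filled (`NA` =
#'   unassigned).
#' @export
assign_tct <- function(a, mode = c("combined", "specimen", "taxonomy"),
                       diagnoses = NULL, map = default_tct_map()) {
  stopifnot(inherits(a, "leaf_assemblage"))
  mode <- match.arg(mode)
  sp <- a$specimens
  own <- classify_tct(sp$lobation, sp$margin, sp$primary_venation,
                      sp$secondary_venation, map)
  tax <- rep(NA_character_, nrow(sp))
  if (!is.null(diagnoses) && nrow(diagnoses)) {
    counts <- table(diagnoses$fossil_species)
    unique_sp <- names(counts)[counts == 1]
    d <- diagnoses[diagnoses$fossil_species %in% unique_sp, , drop = FALSE]
    tax <- d$tct[match(sp$fossil_species, d$fossil_species)]
  }
  a$specimens$tct <- switch(mode,
    specimen = own,
    taxonomy = tax,
    combined = ifelse(!is.na(own), own, tax))
  a
}

#' Merge TCT letters into 8 classes ignoring secondary venation
#'
#' The two letters differing only in secondary venation collapse into one
#' class labelled `"<looped>/<non-looped>"` (e.g. `"E/F"`).
#'
#' @param tct character vector of letters A..P (NA passes through).
#' @param map TCT map, default [default_tct_map()].
#' @return character vector of class labels.
#' @export
tct_class <- function(tct, map = default_tct_map()) {
  map <- .validate_tct_map(map)
  key3 <- paste(map$lobation, map$margin, map$primary_venation, sep = "|")
  labels <- vapply(unique(key3), function(k) {
    part <- map[key3 == k, ]
    part <- part[order(part$secondary_venation != "looped"), ]
    paste(part$tct, collapse = "/")
  }, character(1))
  class_of <- labels[match(key3, unique(key3))]
  names(class_of) <- map$tct
  unname(class_of[tct])
}

#' TCT frequency spectrum of an assemblage
#'
#' Counts and percentages per letter. Percentages are reported with two
#' denominators: all leaves in the assemblage (unassigned included, the
#' convention of the published spectra) and assigned leaves only.
#'
#' @param a a [leaf_assemblage()]; if its `tct` column is empty, codes are
#'   assigned first via [assign_tct()] with the given `mode`.
#' @param mode assignment mode passed to [assign_tct()].
#' @param diagnoses,map passed to [assign_tct()].
#' @param by_site split the spectrum per site.
#' @return data frame with columns `site` (optional), `tct`, `n`,
#'   `pct_total` (over all leaves) and `pct_assigned`; attribute
#'   `n_unassigned` carries the complement.
#' @export
tct_spectrum <- function(a, mode = "combined", diagnoses = NULL,
                         map = default_tct_map(), by_site = FALSE) {
  stopifnot(inherits(a, "leaf_assemblage"))
  if (all(is.na(a$specimens$tct))) {
    a <- assign_tct(a, mode = mode, diagnoses = diagnoses, map = map)
  }
  one <- function(sp, site = NA_character_) {
    tab <- table(factor(sp$tct, levels = sort(unique(stats::na.omit(sp$tct)))))
    n_total <- nrow(sp)
    n_assigned <- sum(!is.na(sp$tct))
    out <- data.frame(tct = names(tab), n = as.integer(tab),
                      pct_total = 100 * as.integer(tab) / n_total,
                      pct_assigned = if (n_assigned)
                        100 * as.integer(tab) / n_assigned else NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.na(site)) out <- cbind(site = site, out)
    attr(out, "n_unassigned") <- n_total - n_assigned
    out
  }
  if (!by_site) return(one(a$specimens))
  parts <- lapply(split(a$specimens, a$specimens$site),
                  function(sp) one(sp, sp$site[1]))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- sum(vapply(parts, attr, 0, "n_unassigned"))
  out
}
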