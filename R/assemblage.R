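#' @title Leaf assemblage objects
#' @name leaf_assemblage
#' @description
#' A `leaf_assemblage` bundles one fossil (or simulated) leaf collection:
#' a specimen table (one row per leaf), a long damage table (one row per
#' damage-type observation on a leaf) and a damage-type catalog mapping DT
#' numbers to functional feeding groups (FFGs).
NULL

# canonical specimen columns and their types; anything absent is filled with NA
.specimen_columns <- function() {
  c(specimen_id = "character", site = "character",
    family = "character", fossil_species = "character",
    growth_form = "character", phenology_modern = "character",
    lobation = "character", margin = "character",
    primary_venation = "character", secondary_venation = "character",
    tct = "character",
    preserved_fraction = "numeric", area_index = "numeric",
    leaf_length_mm = "numeric", leaf_width_mm = "numeric",
    leaf_area_mm2 = "numeric", petiole_width_mm = "numeric",
    lma_gm2 = "numeric", lma_source = "character")
}

.categorical_levels <- list(
  growth_form = c("tree", "shrub", "liana", "unknown"),
  phenology_modern = c("deciduous", "evergreen", "semi-deciduous", "unknown"),
  lobation = c("lobed", "unlobed", "unknown"),
  margin = c("entire", "toothed", "unknown"),
  primary_venation = c("pinnate", "palmate", "unknown"),
  secondary_venation = c("looped", "non-looped", "unknown"),
  lma_source = c("measured", "imputed", "missing")
)

#' Construct a leaf assemblage
#'
#' @param specimens data frame with at least `specimen_id` and `site`;
#'   recognised trait columns (see Details) are validated, unknown extra
#'   columns are carried along untouched.
#' @param damage data frame with columns `specimen_id`, `dt` (damage-type
#'   label, e.g. `"2"` or `"unknown_gall"`) and optionally
#'   `damaged_area_mm2`. `NULL` means no damage observations.
#' @param dt_catalog damage-type catalog as returned by [dt_catalog()].
#' @param name assemblage label.
#'
#' @details Recognised specimen columns: identifiers (`specimen_id`, `site`),
#' taxonomy (`family`, `fossil_species`, `growth_form`), the four binary
#' architectural characters (`lobation`, `margin`, `primary_venation`,
#' `secondary_venation`), an assigned trait-combination type (`tct`),
#' preservation (`preserved_fraction`, `area_index`, both in (0, 1]) and
#' quantitative traits in mm / mm^2 / g m^-2 (`leaf_length_mm`,
#' `leaf_width_mm`, `leaf_area_mm2`, `petiole_width_mm`, `lma_gm2`,
#' `lma_source`). Missing categorical values become `"unknown"`.
#'
#' @return An object of class `leaf_assemblage`: a list with elements
#'   `name`, `specimens`, `damage`, `dt_catalog`.
#' @export
leaf_assemblage <- function(specimens, damage = NULL,
                            dt_catalog = default_dt_catalog(),
                            name = "assemblage") {
  stopifnot(is.data.frame(specimens))
  specimens <- as.data.frame(specimens, stringsAsFactors = FALSE)
  for (col in c("specimen_id", "site")) {
    if (!col %in% names(specimens)) {
      stop("mandatory column missing: '", col, "'", call. = FALSE)
    }
  }
  cols <- .specimen_columns()
  for (col in names(cols)) {
    if (!col %in% names(specimens)) {
      specimens[[col]] <- rep(if (cols[[col]] == "numeric") NA_real_
                              else NA_character_, nrow(specimens))
    }
  }
  # free-text columns: empty strings mean absent
  for (col in c("family", "fossil_species", "tct")) {
    x <- as.character(specimens[[col]])
    x[!is.na(x) & trimws(x) == ""] <- NA_character_
    specimens[[col]] <- x
  }
  specimens$specimen_id <- as.character(specimens$specimen_id)
  dup <- unique(specimens$specimen_id[duplicated(specimens$specimen_id)])
  if (length(dup)) {
    stop("duplicated specimen_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (col in names(.categorical_levels)) {
    x <- as.character(specimens[[col]])
    x[is.na(x) | x == ""] <- "unknown"
    bad <- setdiff(unique(x), c(.categorical_levels[[col]], "missing"))
    if (col != "lma_source" && length(bad)) {
      x[x %in% bad] <- "unknown"
    }
    specimens[[col]] <- x
  }
  specimens$lma_source[is.na(specimens$lma_gm2)] <- "missing"
  specimens$lma_source[!is.na(specimens$lma_gm2) &
                         specimens$lma_source == "unknown"] <- "measured"
  for (col in names(cols)[cols == "numeric"]) {
    specimens[[col]] <- .as_numeric_strict(specimens[[col]], col,
                                           specimens$specimen_id)
  }
  .check_positive(specimens, c("leaf_length_mm", "leaf_width_mm",
                               "leaf_area_mm2", "petiole_width_mm", "lma_gm2"))
  for (col in c("preserved_fraction", "area_index")) {
    v <- specimens[[col]]
    bad <- !is.na(v) & (v <= 0 | v > 1)
    if (any(bad)) {
      stop(col, " outside (0,1] for specimen ",
           paste(specimens$specimen_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(damage)) {
    damage <- data.frame(specimen_id = character(), dt = character(),
                         damaged_area_mm2 = numeric(),
                         stringsAsFactors = FALSE)
  }
  damage <- as.data.frame(damage, stringsAsFactors = FALSE)
  if (!"damaged_area_mm2" %in% names(damage)) damage$damaged_area_mm2 <- NA_real_
  if (nrow(damage)) {
    damage$specimen_id <- as.character(damage$specimen_id)
    damage$dt <- as.character(damage$dt)
    orphan <- setdiff(damage$specimen_id, specimens$specimen_id)
    if (length(orphan)) {
      stop("damage rows reference unknown specimen_id: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    la <- specimens$leaf_area_mm2[match(damage$specimen_id,
                                        specimens$specimen_id)]
    bad <- !is.na(damage$damaged_area_mm2) & !is.na(la) &
      damage$damaged_area_mm2 > la
    if (any(bad)) {
      stop("damaged_area_mm2 exceeds leaf area for specimen ",
           paste(unique(damage$specimen_id[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  rownames(specimens) <- NULL
  rownames(damage) <- NULL
  structure(list(name = name, specimens = specimens, damage = damage,
                 dt_catalog = dt_catalog),
            class = "leaf_assemblage")
}

.as_numeric_strict <- function(x, col, ids) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  empty <- is.na(x) | trimws(x) == "" | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !empty
  if (any(bad)) {
    stop("non-numeric value in '", col, "' for specimen ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  out
}

.check_positive <- function(df, cols) {
  for (col in cols) {
    v <- df[[col]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      stop(col, " must be strictly positive; offending specimen ",
           paste(df$specimen_id[bad], collapse = ", "), call. = FALSE)
    }
  }
}

#' @export
print.leaf_assemblage <- function(x, ...) {
  cat("Leaf assemblage '", x$name, "': ", nrow(x$specimens), " specimens, ",
      nrow(x$damage), " damage observations, sites: ",
      paste(sort(unique(x$specimens$site)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of specimens in an assemblage
#' @param a a [leaf_assemblage()].
#' @return integer count.
#' @export
n_specimens <- function(a) nrow(a$specimens)

#' Subset an assemblage by specimen id
#'
#' Keeps the given specimens (in the order supplied) together with their
#' damage observations.
#' @param a a [leaf_assemblage()].
#' @param ids character vector of specimen ids to keep.
#' @return a [leaf_assemblage()].
#' @export
assemblage_subset <- function(a, ids) {
  stopifnot(inherits(a, "leaf_assemblage"))
  missing_ids <- setdiff(ids, a$specimens$specimen_id)
  if (length(missing_ids)) {
    stop("unknown specimen_id: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  sp <- a$specimens[match(ids, a$specimens$specimen_id), , drop = FALSE]
  dm <- a$damage[a$damage$specimen_id %in% ids, , drop = FALSE]
  rownames(sp) <- rownames(dm) <- NULL
  out <- a
  out$specimens <- sp
  out$damage <- dm
  out
}

# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Read an assemblage from a specimen CSV
#'
#' The dialect is UTF-8 comma-separated with a header row and one row per
#' specimen. Damage observations come either as a semicolon list in a
#' `dt_list` column (e.g. `"2;12;78"`, with an optional parallel
#' `damaged_area_list`) or as wide 0/1 incidence columns named `X<dt>`
#' (`X1` ... `X280`); leading zeros in labels such as `DT02` are tolerated.
#'
#' @param path file path.
#' @param dt_catalog damage-type catalog, see [dt_catalog()].
#' @param name assemblage label (defaults to the file name).
#' @return a [leaf_assemblage()].
#' @export
read_assemblage <- function(path, dt_catalog = default_dt_catalog(),
                            name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  for (col in c("specimen_id", "site")) {
    if (!col %in% names(df)) {
      stop("mandatory column missing: '", col, "'", call. = FALSE)
    }
  }
  wide <- grep("^X[0-9A-Za-z_]+$", names(df), value = TRUE)
  dmg <- NULL
  if ("dt_list" %in% names(df)) {
    dmg <- .parse_dt_list(df$specimen_id, df$dt_list, df[["damaged_area_list"]])
    df$dt_list <- NULL
    df$damaged_area_list <- NULL
  } else if (length(wide)) {
    dts <- sub("^X", "", wide)
    rows <- lapply(seq_along(wide), function(j) {
      hit <- !is.na(df[[wide[j]]]) & df[[wide[j]]] %in% c("1", "1.0", "TRUE")
      data.frame(specimen_id = df$specimen_id[hit],
                 dt = rep(dts[j], sum(hit)),
                 damaged_area_mm2 = NA_real_, stringsAsFactors = FALSE)
    })
    dmg <- do.call(rbind, rows)
    df <- df[, setdiff(names(df), wide), drop = FALSE]
  }
  leaf_assemblage(df, damage = dmg, dt_catalog = dt_catalog,
                  name = if (is.null(name)) basename(path) else name)
}

.parse_dt_list <- function(ids, dt_list, area_list = NULL) {
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    raw <- dt_list[i]
    if (is.na(raw) || trimws(raw) == "") next
    dts <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
    dts <- dts[dts != ""]
    dts <- sub("^DT0*", "", dts)          # DT02 -> 2
    dts <- sub("^0+(?=[0-9])", "", dts, perl = TRUE)
    areas <- rep(NA_real_, length(dts))
    if (!is.null(area_list) && !is.na(area_list[i]) &&
        trimws(area_list[i]) != "") {
      av <- suppressWarnings(
        as.numeric(trimws(strsplit(area_list[i], ";", fixed = TRUE)[[1]])))
      areas[seq_along(av)] <- av
    }
    out[[i]] <- data.frame(specimen_id = ids[i], dt = dts,
                           damaged_area_mm2 = areas, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Write an assemblage to the specimen-CSV dialect
#'
#' Inverse of [read_assemblage()] (damage is written in `dt_list` /
#' `damaged_area_list` form). Reading the file back reproduces all fields.
#' @param a a [leaf_assemblage()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assemblage <- function(a, path) {
  stopifnot(inherits(a, "leaf_assemblage"))
  df <- a$specimens
  dl <- rep("", nrow(df))
  al <- rep("", nrow(df))
  if (nrow(a$damage)) {
    sp <- split(a$damage, factor(a$damage$specimen_id,
                                 levels = df$specimen_id))
    for (i in seq_len(nrow(df))) {
      d <- sp[[df$specimen_id[i]]]
      if (is.null(d) || !nrow(d)) next
      dl[i] <- paste(d$dt, collapse = ";")
      if (any(!is.na(d$damaged_area_mm2))) {
        al[i] <- paste(ifelse(is.na(d$damaged_area_mm2), "",
                              format(d$damaged_area_mm2, digits = 15,
                                     scientific = FALSE, trim = TRUE)),
                       collapse = ";")
      }
    }
  }
  df$dt_list <- dl
  df$damaged_area_list <- al
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Keep well-preserved leaves (Dataset 2)
#'
#' Retains specimens whose preserved lamina fraction is at least
#' `min_preserved` ("at least 70% preserved" read inclusively). Specimens
#' without a preservation value are dropped with a message.
#'
#' @param a a [leaf_assemblage()].
#' @param min_preserved minimum preserved fraction, default 0.70.
#' @return filtered [leaf_assemblage()], input order preserved.
#' @export
filter_dataset2 <- function(a, min_preserved = 0.70) {
  stopifnot(inherits(a, "leaf_assemblage"))
  pf <- a$specimens$preserved_fraction
  if (any(is.na(pf))) {
    message(sum(is.na(pf)), " specimen(s) without preserved_fraction dropped")
  }
  keep <- !is.na(pf) & pf >= min_preserved
  assemblage_subset(a, a$specimens$specimen_id[keep])
}

#' Randomly subsample leaves per site (Dataset 3)
#'
#' Simple random sample without replacement of `n_per_site` leaves within
#' each site, reproducible for a fixed seed. Sites with fewer leaves are
#' returned whole with a warning.
#'
#' @param a a [leaf_assemblage()] (typically the Dataset-2 filtrate).
#' @param n_per_site leaves to draw per site (default 400).
#' @param seed integer seed.
#' @return subsampled [leaf_assemblage()] (original row order retained).
#' @export
sample_dataset3 <- function(a, n_per_site = 400, seed) {
  stopifnot(inherits(a, "leaf_assemblage"))
  if (!is.numeric(n_per_site) || length(n_per_site) != 1 || n_per_site <= 0) {
    stop("n_per_site must be a positive integer", call. = FALSE)
  }
  ids <- with_seed(seed, {
    unlist(lapply(split(a$specimens$specimen_id, a$specimens$site),
                  function(x) {
                    if (length(x) < n_per_site) {
                      warning("site with only ", length(x),
                              " specimens; taking all (requested ",
                              n_per_site, ")", call. = FALSE)
                      x
                    } else {
                      sample(x, n_per_site)
                    }
                  }), use.names = FALSE)
  })
  # keep stable input order
  keep <- a$specimens$specimen_id[a$specimens$specimen_id %in% ids]
  assemblage_subset(a, keep)
}

#' Clean the measured subsample for multivariate analysis (Dataset 4)
#'
#' Applies, in order: (1) removal of incomplete cases for the multivariate
#' variable set; (2) removal of leaf-size or LMA outliers beyond the Tukey
#' fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (linear-interpolation quartiles,
#' computed per site by default); (3) removal of fossil-species with fewer
#' than `min_group` remaining leaves; (4) removal (or merging) of
#' trait-combination types with fewer than `min_group` remaining leaves.
#' Rarity is therefore evaluated on the cleaned set.
#'
#' @param a a Dataset-3-like [leaf_assemblage()] with quantitative traits.
#' @param min_group minimum leaves per fossil-species / TCT (default 5).
#' @param complete_vars specimen columns that must be non-missing.
#' @param size_col,lma_col columns screened for outliers.
#' @param by_site logical; compute outlier fences per site (default) or pooled.
#' @param rare_tct `"delete"` (default) drops specimens of rare TCTs;
#'   `"merge"` relabels them `"other"`.
#' @return filtered [leaf_assemblage()] with attribute `removal_ledger`, a
#'   data frame of per-rule removal counts summing to the total loss.
#' @export
build_dataset4 <- function(a, min_group = 5,
                           complete_vars = c("leaf_area_mm2",
                                             "leaf_length_mm",
                                             "leaf_width_mm", "lma_gm2",
                                             "fossil_species", "tct"),
                           size_col = "leaf_area_mm2", lma_col = "lma_gm2",
                           by_site = TRUE,
                           rare_tct = c("delete", "merge")) {
  stopifnot(inherits(a, "leaf_assemblage"))
  rare_tct <- match.arg(rare_tct)
  sp <- a$specimens
  n0 <- nrow(sp)

  vars <- intersect(complete_vars, names(sp))
  complete <- rep(TRUE, nrow(sp))
  for (v in vars) {
    complete <- complete & !is.na(sp[[v]]) &
      !(is.character(sp[[v]]) & sp[[v]] %in% c("unknown", "missing"))
  }
  sp <- sp[complete, , drop = FALSE]
  n_incomplete <- n0 - nrow(sp)

  out_flag <- rep(FALSE, nrow(sp))
  groups <- if (by_site) sp$site else rep("all", nrow(sp))
  for (col in unique(c(size_col, lma_col))) {
    if (!col %in% names(sp)) next
    for (g in unique(groups)) {
      idx <- which(groups == g & !is.na(sp[[col]]))
      if (length(idx) < 4) next
      out_flag[idx] <- out_flag[idx] | tukey_outlier(sp[[col]][idx])
    }
  }
  n_outlier <- sum(out_flag)
  sp <- sp[!out_flag, , drop = FALSE]
  groups <- groups[!out_flag]

  tab <- table(sp$fossil_species)
  rare_sp <- names(tab)[tab < min_group]
  keep <- !(sp$fossil_species %in% rare_sp)
  n_rare_species <- sum(!keep)
  sp <- sp[keep, , drop = FALSE]

  n_rare_tct <- 0L
  if ("tct" %in% names(sp)) {
    tab <- table(sp$tct)
    rare <- names(tab)[tab < min_group]
    hit <- sp$tct %in% rare
    if (rare_tct == "delete") {
      n_rare_tct <- sum(hit)
      sp <- sp[!hit, , drop = FALSE]
    } else {
      sp$tct[hit] <- "other"
    }
  }

  out <- assemblage_subset(a, sp$specimen_id)
  out$specimens$tct <- sp$tct[match(out$specimens$specimen_id,
                                    sp$specimen_id)]
  attr(out, "removal_ledger") <- data.frame(
    rule = c("incomplete", "outlier", "rare_species", "rare_tct"),
    removed = c(n_incomplete, n_outlier, n_rare_species, n_rare_tct))
  out
}

#' Flag Tukey-fence outliers
#'
#' Values outside `[Q1 - k IQR, Q3 + k IQR]` with linear-interpolation
#' (type 7) quartiles.
#' @param x numeric vector.
#' @param k fence multiplier (default 1.5).
#' @return logical vector.
#' @export
tukey_outlier <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  !is.na(x) & (x < q[1] - k * iqr | x > q[2] + k * iqr)
}
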