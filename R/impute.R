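#' Impute missing LMA by chained-equation Bayesian linear regression
#'
#' Fills missing leaf-mass-per-area values with the "norm" scheme of
#' chained-equation imputation: a Bayesian linear regression of LMA on the
#' predictors (by default locality and leaf size) fitted over the complete
#' cases, with proper posterior draws. Per cycle the residual variance is
#' drawn from its scaled inverse-chi-square posterior, the coefficients from
#' their conditional normal posterior, and each missing value from the
#' predictive normal; the reported value is the mean over `cycles` draws
#' (default 10). Only one variable (LMA) is incomplete, so the chained
#' scheme reduces to this single conditional model, fitted on both
#' localities pooled with locality as a covariate.
#'
#' Eligibility: a specimen's missing LMA is imputed only when its
#' fossil-species has at least `min_measured` measured LMA values in the
#' same site; others stay missing. Measured values are never altered.
#'
#' When `range_filter` is on, imputed values below the minimum measured LMA
#' of their site are removed again (set back to missing) and logged;
#' `symmetric = TRUE` also removes values above the site maximum.
#'
#' @param a a [leaf_assemblage()] (Dataset-3-like).
#' @param predictors specimen columns used as regressors; default locality
#'   (`site`) and leaf size (`leaf_area_mm2`).
#' @param cycles imputation cycles averaged per value (default 10).
#' @param min_measured minimum measured LMA values per (site, species) for
#'   eligibility (default 5).
#' @param seed integer seed; output is deterministic given the seed.
#' @param range_filter remove out-of-range imputed values (default TRUE).
#' @param symmetric also remove above-maximum values (default FALSE).
#' @return the assemblage with imputed `lma_gm2` (`lma_source = "imputed"`),
#'   plus attribute `imputation_diagnostics`: counts, per-species table,
#'   per-cycle draws and observed/imputed distribution summaries.
#' @export
impute_lma <- function(a, predictors = c("site", "leaf_area_mm2"),
                       cycles = 10, min_measured = 5, seed = 1,
                       range_filter = TRUE, symmetric = FALSE) {
  stopifnot(inherits(a, "leaf_assemblage"), cycles >= 1, min_measured >= 2)
  sp <- a$specimens
  for (p in predictors) {
    if (!p %in% names(sp)) {
      stop("predictor column missing: '", p, "'", call. = FALSE)
    }
    v <- sp[[p]]
    if (all(is.na(v)) || (is.character(v) && all(v %in% c("unknown", "missing")))) {
      stop("predictor column entirely missing: '", p, "'", call. = FALSE)
    }
  }
  measured <- !is.na(sp$lma_gm2) & sp$lma_source == "measured"

  # eligibility per (site, species)
  key <- paste(sp$site, sp$fossil_species, sep = "\r")
  n_meas <- tapply(measured, key, sum)
  eligible_key <- names(n_meas)[n_meas >= min_measured]
  pred_ok <- rep(TRUE, nrow(sp))
  for (p in predictors) pred_ok <- pred_ok & !is.na(sp[[p]])
  target <- !measured & is.na(sp$lma_gm2) & key %in% eligible_key &
    !is.na(sp$fossil_species) & pred_ok

  diag <- list(n_measured = sum(measured), n_eligible = sum(target),
               n_imputed = 0L, n_removed_range = 0L,
               cycles = cycles, seed = seed)
  if (!any(target)) {
    diag$species <- .impute_species_table(sp, measured, target, logical(0))
    attr(a, "imputation_diagnostics") <- diag
    return(a)
  }

  # constant predictors (e.g. locality in a one-site assemblage) carry no
  # information and would break the design matrix; drop them
  use_pred <- predictors[vapply(predictors, function(p) {
    length(unique(sp[[p]][measured | target])) >= 2
  }, logical(1))]
  fml <- if (length(use_pred)) {
    stats::as.formula(paste("~", paste(use_pred, collapse = " + ")))
  } else {
    ~1
  }
  predictors <- use_pred
  X_all <- stats::model.matrix(fml, data = sp[, predictors, drop = FALSE])
  if (!length(predictors)) X_all <- matrix(1, nrow(sp), 1,
                                           dimnames = list(NULL, "(Intercept)"))
  # model.matrix drops NA rows silently only via model.frame; ensure alignment
  if (nrow(X_all) != nrow(sp)) {
    mf <- stats::model.frame(fml, data = sp[, predictors, drop = FALSE],
                             na.action = stats::na.pass)
    X_all <- stats::model.matrix(fml, mf)
  }
  X_obs <- X_all[measured, , drop = FALSE]
  y_obs <- sp$lma_gm2[measured]
  X_mis <- X_all[target, , drop = FALSE]
  q <- ncol(X_obs)
  n <- nrow(X_obs)
  if (n <= q + 1) {
    stop("too few complete cases (", n, ") for ", q, " regression parameters",
         call. = FALSE)
  }
  XtX <- crossprod(X_obs)
  R <- chol(XtX)
  beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(X_obs, y_obs)))
  resid <- y_obs - X_obs %*% beta_hat
  ss <- sum(resid^2)

  draws <- with_seed(seed, {
    out <- matrix(NA_real_, nrow(X_mis), cycles)
    for (cy in seq_len(cycles)) {
      sigma2 <- ss / stats::rchisq(1, df = n - q)
      beta_star <- beta_hat + backsolve(R, stats::rnorm(q)) * sqrt(sigma2)
      out[, cy] <- as.numeric(X_mis %*% beta_star) +
        stats::rnorm(nrow(X_mis)) * sqrt(sigma2)
    }
    out
  })
  imputed <- rowMeans(draws)

  removed <- rep(FALSE, length(imputed))
  if (range_filter) {
    site_mis <- sp$site[target]
    rng <- tapply(y_obs, sp$site[measured], range)
    for (s in unique(site_mis)) {
      r <- rng[[s]]
      if (is.null(r)) r <- range(y_obs)
      idx <- site_mis == s
      removed[idx] <- imputed[idx] < r[1]
      if (symmetric) removed[idx] <- removed[idx] | (imputed[idx] > r[2])
    }
  }
  keep <- which(target)[!removed]
  a$specimens$lma_gm2[keep] <- imputed[!removed]
  a$specimens$lma_source[keep] <- "imputed"

  diag$n_imputed <- length(keep)
  diag$n_removed_range <- sum(removed)
  diag$cycle_draws <- draws
  diag$specimen_id <- sp$specimen_id[target]
  diag$removed_by_range <- sp$specimen_id[target][removed]
  diag$observed_summary <- summary(y_obs)
  diag$imputed_summary <- if (length(keep)) summary(imputed[!removed]) else NULL
  diag$species <- .impute_species_table(a$specimens, measured,
                                        target, which(target)[removed])
  attr(a, "imputation_diagnostics") <- diag
  a
}

.impute_species_table <- function(sp, measured, target, removed_idx) {
  removed <- rep(FALSE, nrow(sp))
  removed[removed_idx] <- TRUE
  key <- interaction(sp$site, sp$fossil_species, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(sp)), key), function(i) {
    data.frame(site = sp$site[i[1]], fossil_species = sp$fossil_species[i[1]],
               n_leaves = length(i),
               n_measured = sum(measured[i]),
               n_imputed = sum(target[i] & !removed[i] &
                                 sp$lma_source[i] == "imputed"),
               n_removed_range = sum(removed[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site, out$fossil_species), ]
}

#' Imputation quality report
#'
#' Tabulates measured / imputed / range-removed counts per site and
#' fossil-species from the diagnostics attached by [impute_lma()].
#'
#' @param a an assemblage returned by [impute_lma()], or its
#'   `imputation_diagnostics` attribute.
#' @return object of class `lma_imputation_report` (a data frame with
#'   summary attributes); printed with totals.
#' @export
imputation_report <- function(a) {
  diag <- if (inherits(a, "leaf_assemblage")) {
    attr(a, "imputation_diagnostics")
  } else a
  if (is.null(diag)) stop("no imputation diagnostics found; run impute_lma()",
                          call. = FALSE)
  out <- diag$species
  attr(out, "totals") <- c(measured = diag$n_measured,
                           eligible_missing = diag$n_eligible,
                           imputed = diag$n_imputed,
                           removed_by_range = diag$n_removed_range)
  attr(out, "removed_by_range") <- diag$removed_by_range
  class(out) <- c("lma_imputation_report", "data.frame")
  out
}

#' @export
print.lma_imputation_report <- function(x, ...) {
  t <- attr(x, "totals")
  cat("LMA imputation: ", t["measured"], " measured, ",
      t["eligible_missing"], " eligible missing, ",
      t["imputed"], " imputed, ",
      t["removed_by_range"], " removed by range filter\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
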