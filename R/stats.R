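#' Mann-Whitney test with the first-sample W convention
#'
#' Two-sided Mann-Whitney(-Wilcoxon) test. The reported statistic is the
#' first-sample U: the number of (x, y) pairs with `x > y`, ties counted
#' one half, so the sample order is part of the result. p-values are exact
#' for small untied samples and use the tie-corrected normal approximation
#' otherwise (the default behaviour of [stats::wilcox.test()], which this
#' wraps).
#'
#' @param x,y numeric samples, each non-empty.
#' @return list with `W` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Kruskal-Wallis test with post-hoc letter groups
#'
#' Rank-based Kruskal-Wallis statistic (tie-corrected), followed by
#' pairwise Fisher-LSD comparisons on mean ranks with the pooled rank
#' variance adjusted by the KW statistic
#' (\eqn{t = |\bar R_i - \bar R_j| / \sqrt{S^2 \frac{N-1-H}{N-k}(1/n_i + 1/n_j)}},
#' df = N - k), and a compact letter display: groups share a letter iff
#' their pairwise comparison is non-significant at `alpha`.
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`.
#' @param alpha significance level (default 0.05).
#' @return list with `H`, `df`, `p`, `groups` (data frame: group, n,
#'   mean_rank, letters, ordered by decreasing mean rank) and the pairwise
#'   p-value matrix.
#' @export
kruskal_letters <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  tab <- table(groups)
  if (any(tab == 0)) {
    warning("empty group(s) dropped", call. = FALSE)
    tab <- tab[tab > 0]
  }
  k <- length(tab)
  if (k < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n_i <- as.numeric(tab[names(mean_rank)])
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- (sum(tapply(r, groups, sum)^2 / tab[names(mean_rank)]) -
          N * (N + 1)^2 / 4) / S2
  df_kw <- k - 1
  p_kw <- stats::pchisq(H, df_kw, lower.tail = FALSE)
  # pairwise Fisher-LSD on mean ranks
  pmat <- matrix(NA_real_, k, k,
                 dimnames = list(names(mean_rank), names(mean_rank)))
  denom_df <- N - k
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      se <- sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / n_i[i] + 1 / n_i[j]))
      tij <- if (se == 0) 0 else abs(mean_rank[i] - mean_rank[j]) / se
      pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(tij, denom_df,
                                                lower.tail = FALSE)
    }
  }
  ord <- order(mean_rank, decreasing = TRUE)
  sig <- !is.na(pmat) & pmat < alpha
  letters_out <- .compact_letters(sig[ord, ord, drop = FALSE])
  out <- data.frame(group = names(mean_rank)[ord],
                    n = n_i[ord], mean_rank = as.numeric(mean_rank)[ord],
                    letters = letters_out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(H = unname(H), df = df_kw, p = p_kw, groups = out, pairwise_p = pmat)
}

# insert-letter sweep over groups sorted by mean rank: from each start,
# extend a run while the next group is non-different from every member;
# maximal runs each get one letter
.compact_letters <- function(sig_sorted) {
  k <- nrow(sig_sorted)
  runs <- vector("list", k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig_sorted[i:j, j + 1])) j <- j + 1
    runs[[i]] <- i:j
  }
  keep <- rep(TRUE, k)
  for (u in seq_len(k)) {
    for (v in seq_len(k)) {
      if (u != v && keep[u] && keep[v] &&
          all(runs[[u]] %in% runs[[v]]) &&
          length(runs[[v]]) > length(runs[[u]])) keep[u] <- FALSE
    }
  }
  runs <- unique(runs[keep])
  lab <- rep("", k)
  for (u in seq_along(runs)) {
    lab[runs[[u]]] <- paste0(lab[runs[[u]]], letters[u])
  }
  lab
}

#' Standardised PCA of quantitative leaf traits
#'
#' Principal component analysis on centred, unit-variance variables
#' (eigendecomposition of the correlation matrix), with per-axis variable
#' contributions: contribution of variable v to axis k is
#' `100 * loading(v,k)^2` (loadings are unit vectors, so contributions sum
#' to 100 per axis).
#'
#' @param data data frame or matrix of quantitative traits (complete cases
#'   only are used; at least 6 rows required).
#' @return object of class `trait_pca`: list with `eigenvalues`,
#'   `variance_explained` (percent), `scores`, `loadings`, `contributions`
#'   (percent, variables x axes), `n`.
#' @export
pca_traits <- function(data) {
  data <- as.data.frame(data)
  cc <- stats::complete.cases(data)
  data <- data[cc, , drop = FALSE]
  if (nrow(data) < 6) stop("need at least 6 complete rows", call. = FALSE)
  sds <- vapply(data, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant column: ", paste(names(data)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  pc <- stats::prcomp(data, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev,
                 variance_explained = 100 * ev / sum(ev),
                 scores = pc$x,
                 loadings = pc$rotation,
                 contributions = 100 * pc$rotation^2,
                 n = nrow(data)),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait PCA on", x$n, "leaves,", length(x$eigenvalues), "variables\n")
  cat("Variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_along(x$eigenvalues),
                    x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a Gamma-identity or binomial-logit GLM
#'
#' The two model families of the trait/herbivory battery: continuous
#' positive responses (leaf size, LMA, damaged area, herbivory index) use a
#' Gamma distribution with identity link; damage presence/absence uses a
#' binomial with logit link. Gamma-identity fits are started from the
#' least-squares solution and rely on step-halving to keep fitted means
#' positive.
#'
#' @param formula model formula (`response ~ term + term`).
#' @param data data frame.
#' @param family `"gamma_identity"` or `"binomial_logit"`.
#' @return a fitted [stats::glm()] object with attribute `family_tag`.
#' @export
fit_trait_glm <- function(formula, data,
                          family = c("gamma_identity", "binomial_logit")) {
  if (inherits(family, "family")) {
    family <- if (family$family == "Gamma") "gamma_identity"
              else "binomial_logit"
  }
  family <- match.arg(family)
  data <- data[stats::complete.cases(
    data[, intersect(all.vars(formula), names(data)), drop = FALSE]), ,
    drop = FALSE]
  data <- droplevels(data)
  y <- eval(formula[[2]], data)
  fam <- if (family == "gamma_identity") {
    if (any(y <= 0)) stop("gamma_identity requires a strictly positive response",
                          call. = FALSE)
    stats::Gamma(link = "identity")
  } else {
    if (!all(y %in% c(0, 1, TRUE, FALSE))) {
      stop("binomial_logit requires a binary response", call. = FALSE)
    }
    stats::binomial(link = "logit")
  }
  args <- list(formula = formula, family = fam, data = data,
               control = stats::glm.control(maxit = 200))
  fit <- if (family == "gamma_identity") {
    lmfit <- tryCatch(stats::lm(formula, data = data),
                      error = function(e) NULL)
    st <- if (!is.null(lmfit)) stats::coef(lmfit) else NULL
    if (!is.null(st) && anyNA(st)) st <- lmfit <- NULL
    attempts <- list()
    if (!is.null(st) && all(stats::fitted(lmfit) > 0)) {
      attempts <- c(attempts, list(list(start = st)))
    }
    # flat start (intercept = mean response, slopes 0) is always valid for
    # the identity link and lets IRLS step-halve from a feasible point
    X <- tryCatch(stats::model.matrix(formula, data), error = function(e) NULL)
    if (!is.null(X) && "(Intercept)" %in% colnames(X)) {
      st0 <- stats::setNames(rep(0, ncol(X)), colnames(X))
      st0["(Intercept)"] <- mean(y)
      attempts <- c(attempts, list(list(start = st0)))
    }
    if (!is.null(X) && "(Intercept)" %in% colnames(X)) {
      st_irls <- tryCatch(.gamma_identity_irls(X, y), error = function(e) NULL)
      if (!is.null(st_irls)) attempts <- c(attempts, list(list(start = st_irls)))
    }
    if (!is.null(lmfit)) {
      mu0 <- pmax(stats::fitted(lmfit), 0.05 * mean(y))
      attempts <- c(attempts, list(list(mustart = mu0)))
    }
    attempts <- c(attempts,
                  list(list(mustart = rep(mean(y), length(y))),
                       list(mustart = (y + mean(y)) / 2)))
    res <- NULL
    for (at in attempts) {
      res <- tryCatch(suppressWarnings(do.call(stats::glm, c(args, at))),
                      error = function(e) e)
      if (!inherits(res, "error") && res$converged) break
    }
    if (inherits(res, "error")) stop(res)
    res
  } else {
    do.call(stats::glm, args)
  }
  if (!fit$converged) {
    stop("GLM did not converge; last deviance ", format(fit$deviance),
         call. = FALSE)
  }
  # route refits made during model selection (update/add1 re-evaluate the
  # stored call) back through this robust fitter
  # the family object (not its tag) goes into the call so that re-evaluation
  # as a plain stats::glm call (model.frame.glm does this) also works
  fit$call <- as.call(list(quote(paleoleaf::fit_trait_glm),
                           formula = formula, data = data, family = fam))
  attr(fit, "family_tag") <- family
  fit
}

# damped IRLS for the Gamma/identity GLM: working response is y itself,
# weights 1/mu^2; steps are halved until all fitted means stay positive and
# the deviance does not increase. Used to seed stats::glm with a feasible,
# near-optimal start.
.gamma_identity_irls <- function(X, y, maxit = 200, tol = 1e-10) {
  dev_fun <- function(mu) 2 * sum((y - mu) / mu - log(y / mu))
  beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  beta["(Intercept)"] <- mean(y)
  mu <- drop(X %*% beta)
  dev <- dev_fun(mu)
  for (it in seq_len(maxit)) {
    w <- 1 / mu^2
    fit <- stats::lm.wfit(X, y, w)
    prop <- fit$coefficients
    prop[is.na(prop)] <- 0
    step <- 1
    repeat {
      b <- beta + step * (prop - beta)
      mu_new <- drop(X %*% b)
      if (all(mu_new > 0)) {
        d <- dev_fun(mu_new)
        if (is.finite(d) && d <= dev + 1e-8) break
      }
      step <- step / 2
      if (step < 1e-12) {
        return(beta)
      }
    }
    conv <- abs(dev - d) < tol * (abs(dev) + 0.1)
    beta <- b
    mu <- mu_new
    dev <- d
    if (conv) break
  }
  beta
}

#' Stepwise AIC model selection (both directions, greedy)
#'
#' Starting from the full model, repeatedly applies the single-term
#' addition or deletion (within the full model's term set) that most
#' reduces AIC, stopping at a local minimum; exact ties cause no move. All
#' candidate refits go through [fit_trait_glm()], so Gamma-identity
#' submodels keep their feasible starting values. The selected model's AIC
#' is never above the full model's.
#'
#' @param fit a fitted GLM from [fit_trait_glm()].
#' @return list with `fit` (the selected model), `formula`, `aic` and
#'   `trace` (data frame of accepted moves with their AIC).
#' @export
stepwise_aic <- function(fit) {
  family <- attr(fit, "family_tag")
  data <- fit$call$data
  response <- deparse(stats::formula(fit)[[2]])
  scope <- attr(stats::terms(fit), "term.labels")
  refit <- function(terms) {
    fml <- if (length(terms)) stats::reformulate(terms, response)
           else stats::as.formula(paste(response, "~ 1"))
    fit_trait_glm(fml, data, family = family)
  }
  current_terms <- scope
  current <- fit
  aic_cur <- stats::AIC(fit)
  trace <- data.frame(move = "<start>",
                      formula = deparse(stats::formula(fit)),
                      aic = aic_cur, stringsAsFactors = FALSE)
  repeat {
    cands <- list()
    for (t in current_terms) {
      cands[[paste("-", t)]] <- setdiff(current_terms, t)
    }
    for (t in setdiff(scope, current_terms)) {
      cands[[paste("+", t)]] <- c(current_terms, t)
    }
    if (!length(cands)) break
    aics <- rep(Inf, length(cands))
    fits <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      f <- tryCatch(refit(cands[[i]]), error = function(e) NULL)
      if (!is.null(f)) {
        fits[[i]] <- f
        aics[i] <- stats::AIC(f)
      }
    }
    best <- which.min(aics)
    if (!is.finite(aics[best]) || aics[best] >= aic_cur - 1e-10) break
    current_terms <- cands[[best]]
    current <- fits[[best]]
    aic_cur <- aics[best]
    trace <- rbind(trace, data.frame(move = names(cands)[best],
                                     formula = deparse(stats::formula(current)),
                                     aic = aic_cur))
  }
  list(fit = current, formula = stats::formula(current), aic = aic_cur,
       trace = trace)
}

#' Type-II likelihood-ratio ANOVA for a GLM
#'
#' Tests each term by the likelihood-ratio chi-square comparing the model
#' without that term against the full model:
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})}, df = parameters removed.
#' With no interactions in the model (the battery has none), dropping each
#' term from the full model is exactly the type-II scheme. Terms whose
#' reduced model cannot be refitted get `NA` with a warning.
#'
#' @param fit a fitted GLM from [fit_trait_glm()].
#' @return data frame with columns `term`, `lr_chisq`, `df`, `p`; rows are
#'   exactly the model terms.
#' @export
anova_type2 <- function(fit) {
  family <- attr(fit, "family_tag")
  data <- fit$call$data
  response <- deparse(stats::formula(fit)[[2]])
  terms_full <- attr(stats::terms(fit), "term.labels")
  ll1 <- stats::logLik(fit)
  rows <- lapply(terms_full, function(t) {
    red_terms <- setdiff(terms_full, t)
    fml <- if (length(red_terms)) stats::reformulate(red_terms, response)
           else stats::as.formula(paste(response, "~ 1"))
    red <- tryCatch(fit_trait_glm(fml, data, family = family),
                    error = function(e) NULL)
    if (is.null(red)) {
      warning("refit without term '", t, "' failed", call. = FALSE)
      return(data.frame(term = t, lr_chisq = NA_real_, df = NA_integer_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ll0 <- stats::logLik(red)
    df <- attr(ll1, "df") - attr(ll0, "df")
    lr <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
    data.frame(term = t, lr_chisq = lr, df = df,
               p = stats::pchisq(lr, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pseudo R-squared measures for GLMs
#'
#' Nagelkerke's R2 for any GLM
#' (\eqn{[1-(L_0/L_1)^{2/n}]/[1-L_0^{2/n}]}, null model = intercept only)
#' and, for binomial models, Tjur's coefficient of discrimination (mean
#' fitted probability among successes minus mean among failures).
#'
#' @param fit a fitted GLM from [fit_trait_glm()].
#' @return list with `nagelkerke` and (binomial only) `tjur`.
#' @export
r2_measures <- function(fit) {
  ll1 <- as.numeric(stats::logLik(fit))
  null_fit <- stats::update(fit, . ~ 1)
  ll0 <- as.numeric(stats::logLik(null_fit))
  n <- stats::nobs(fit)
  nag <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  out <- list(nagelkerke = nag)
  if (stats::family(fit)$family == "binomial") {
    y <- fit$y
    p <- stats::fitted(fit)
    out$tjur <- mean(p[y == 1]) - mean(p[y == 0])
  }
  out
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (length(unique(x)) == 1) stop("constant sample", call. = FALSE)
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}
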