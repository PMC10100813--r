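test_that("Mann-Whitney uses the first-sample U convention", {
  expect_equal(mann_whitney(c(1, 2), 3)$W, 0)
  expect_equal(mann_whitney(3, c(1, 2))$W, 2)   # brute-force: both pairs x>y
  # exhaustive pair-count oracle on random fixtures (ties included), n <= 30
  set.seed(17)
  for (i in 1:20) {
    nx <- sample(1:30, 1)
    ny <- sample(1:30, 1)
    x <- sample(1:12, nx, replace = TRUE)
    y <- sample(1:12, ny, replace = TRUE)
    expect_equal(mann_whitney(x, y)$W, brute_force_w(x, y))
  }
  # tie-free complement identity W_xy + W_yx = nx * ny
  x <- rnorm(15); y <- rnorm(9)
  expect_equal(mann_whitney(x, y)$W + mann_whitney(y, x)$W, 15 * 9)
  expect_error(mann_whitney(numeric(0), 1), "empty sample")
})

test_that("Kruskal-Wallis letter groups separate what differs", {
  v1 <- c(1:10, 101:110)
  g1 <- rep(c("low", "high"), each = 10)
  out1 <- kruskal_letters(v1, g1)
  expect_lt(out1$p, 0.01)
  expect_setequal(out1$groups$letters, c("a", "b"))

  # identical groups share one letter
  v2 <- c(1:10, 1:10)
  out2 <- kruskal_letters(v2, rep(c("g1", "g2"), each = 10))
  expect_equal(unique(out2$groups$letters), "a")

  # three groups where only the extremes differ -> a / ab / b
  # oracle: explicit pairwise rank tests on this constructed fixture
  set.seed(13)
  v3 <- c(rnorm(12, 0), rnorm(12, 1.0), rnorm(12, 2.0))
  g3 <- rep(c("lo", "mid", "hi"), each = 12)
  out3 <- kruskal_letters(v3, g3)
  pm <- out3$pairwise_p
  expect_lt(pm["lo", "hi"], 0.05)
  expect_gt(pm["lo", "mid"], 0.05)
  expect_gt(pm["mid", "hi"], 0.05)
  lt <- setNames(out3$groups$letters, out3$groups$group)
  expect_equal(unname(nchar(lt[c("lo", "hi")])), c(1, 1))
  expect_false(lt[["lo"]] == lt[["hi"]])
  expect_equal(nchar(lt[["mid"]]), 2)
  expect_error(kruskal_letters(1:5, rep("a", 5)), "at least 2")
})

test_that("trait PCA is a correlation-matrix PCA with proper contributions", {
  set.seed(31)
  n <- 80
  base <- rnorm(n)
  d <- data.frame(v1 = base, v2 = base + rnorm(n, 0, 0.05),
                  v3 = rnorm(n), v4 = rnorm(n), v5 = rnorm(n))
  p <- pca_traits(d)
  expect_equal(sum(p$eigenvalues), 5, tolerance = 1e-9)
  expect_equal(unname(colSums(p$contributions)), rep(100, 5),
               tolerance = 1e-9)
  expect_equal(sum(p$variance_explained), 100, tolerance = 1e-9)
  # the correlated pair dominates PC1 with near-equal contributions
  expect_gt(p$contributions["v1", 1], 30)
  expect_gt(p$contributions["v2", 1], 30)
  expect_equal(p$contributions["v1", 1], p$contributions["v2", 1],
               tolerance = 3)
  # scores' covariance diagonal equals the eigenvalues
  expect_equal(unname(diag(cov(p$scores))), p$eigenvalues, tolerance = 1e-9)

  d$v6 <- 1
  expect_error(pca_traits(d), "constant column: v6")
  expect_error(pca_traits(d[1:4, 1:5]), "at least 6")
})

test_that("GLM fits recover simple and generative truths", {
  # identity-link null model: intercept equals the sample mean
  y <- c(3, 7, 11, 2, 9)
  f0 <- fit_trait_glm(y ~ 1, data.frame(y = y), "gamma_identity")
  expect_equal(unname(coef(f0)), mean(y), tolerance = 1e-8)
  expect_error(fit_trait_glm(y ~ 1, data.frame(y = c(1, -1, 2)),
                             "gamma_identity"), "strictly positive")

  # uninformative balanced predictor: slope near zero
  set.seed(5)
  d <- data.frame(y = rbinom(400, 1, 0.5), g = rep(c("a", "b"), 200))
  fb <- fit_trait_glm(y ~ g, d, "binomial_logit")
  expect_lt(abs(coef(fb)[2]), 3 * summary(fb)$coefficients[2, 2])
  expect_error(fit_trait_glm(y ~ g, data.frame(y = c(1, 2, 3), g = "a"),
                             "binomial_logit"), "binary response")

  # 20-seed generative recovery: y ~ Gamma(shape 20, mean 50 + 10 x), n = 500
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- runif(500)
    mu <- 50 + 10 * x
    dd <- data.frame(x = x, y = rgamma(500, shape = 20, scale = mu / 20))
    fit <- fit_trait_glm(y ~ x, dd, "gamma_identity")
    se <- summary(fit)$coefficients[, 2]
    ok <- abs(coef(fit) - c(50, 10)) < 3 * se
    hits <- hits + all(ok)
  }
  expect_gte(hits, 16)
})

test_that("stepwise selection drops noise, keeps signal, never raises AIC", {
  drops <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    x <- runif(500)
    noise <- runif(500)
    mu <- 50 + 20 * x
    d <- data.frame(x = x, noise = noise,
                    y = rgamma(500, shape = 20, scale = mu / 20))
    full <- fit_trait_glm(y ~ x + noise, d, "gamma_identity")
    sel <- stepwise_aic(full)
    terms_sel <- attr(terms(sel$formula), "term.labels")
    expect_lte(sel$aic, AIC(full) + 1e-9)
    expect_true("x" %in% terms_sel)
    drops <- drops + !("noise" %in% terms_sel)
  }
  expect_gte(drops, 14)   # majority of seeds

  # a single strong term is returned unchanged
  set.seed(9)
  x <- runif(300)
  d1 <- data.frame(x = x, y = rgamma(300, 20, scale = (30 + 30 * x) / 20))
  one <- fit_trait_glm(y ~ x, d1, "gamma_identity")
  sel1 <- stepwise_aic(one)
  expect_equal(attr(terms(sel1$formula), "term.labels"), "x")
})

test_that("stepwise agrees with the stock selector on a well-conditioned model", {
  set.seed(77)
  x <- runif(400)
  z <- runif(400)
  g <- sample(c("a", "b"), 400, TRUE)
  d <- data.frame(x = x, z = z, g = g,
                  y = rgamma(400, 20, scale = (50 + 10 * x) / 20))
  ours <- stepwise_aic(fit_trait_glm(y ~ x + z + g, d, "gamma_identity"))
  ref <- stats::step(glm(y ~ x + z + g, Gamma("identity"), data = d),
                     trace = 0)
  expect_equal(sort(attr(terms(ours$formula), "term.labels")),
               sort(attr(terms(formula(ref)), "term.labels")))
  expect_equal(ours$aic, AIC(ref), tolerance = 1e-6)
})

test_that("type-II ANOVA is a drop-one likelihood-ratio test", {
  set.seed(13)
  d <- data.frame(x = runif(300), g = sample(c("u", "v"), 300, TRUE))
  d$y <- rbinom(300, 1, plogis(-1 + 2 * d$x))
  fit <- fit_trait_glm(y ~ x + g, d, "binomial_logit")
  tab <- anova_type2(fit)
  expect_equal(tab$term, c("x", "g"))
  # definition check: dropping the only term of a one-term model equals the
  # null-model comparison 2 (logLik_full - logLik_null)
  fit1 <- fit_trait_glm(y ~ x, d, "binomial_logit")
  null1 <- fit_trait_glm(y ~ 1, d, "binomial_logit")
  tab1 <- anova_type2(fit1)
  expect_equal(tab1$lr_chisq,
               2 * (as.numeric(logLik(fit1)) - as.numeric(logLik(null1))),
               tolerance = 1e-8)
  expect_equal(tab1$df, 1)
})

test_that("null-effect terms produce uniform ANOVA p-values", {
  pvals <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    d <- data.frame(x = runif(150), dud = runif(150))
    d$y <- rgamma(150, 15, scale = (40 + 15 * d$x) / 15)
    fit <- fit_trait_glm(y ~ x + dud, d, "gamma_identity")
    anova_type2(fit)$p[2]
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("pseudo R-squared measures behave at their anchors", {
  set.seed(3)
  d <- data.frame(y = rbinom(200, 1, 0.4), x = rnorm(200))
  null_fit <- fit_trait_glm(y ~ 1, d, "binomial_logit")
  r0 <- r2_measures(null_fit)
  expect_equal(r0$nagelkerke, 0, tolerance = 1e-9)
  expect_equal(r0$tjur, 0, tolerance = 1e-9)

  # Tjur equals the hand-computed mean fitted-probability difference
  fit <- fit_trait_glm(y ~ x, d, "binomial_logit")
  r1 <- r2_measures(fit)
  p_hat <- fitted(fit)
  expect_equal(r1$tjur, mean(p_hat[d$y == 1]) - mean(p_hat[d$y == 0]),
               tolerance = 1e-12)

  # near-perfect separation pushes Tjur towards 1
  d2 <- data.frame(x = c(rnorm(60, -4), rnorm(60, 4)),
                   y = rep(c(0, 1), each = 60))
  fit2 <- suppressWarnings(fit_trait_glm(y ~ x, d2, "binomial_logit"))
  expect_gt(r2_measures(fit2)$tjur, 0.95)
})

test_that("Shapiro-Wilk wrapper screens input and flags skewness", {
  skew_hits <- sum(vapply(1:20, function(s) {
    set.seed(s)
    shapiro_wilk(exp(rnorm(100)))$p < 0.01
  }, logical(1)))
  expect_gte(skew_hits, 19)
  set.seed(1)
  expect_gt(shapiro_wilk(rnorm(200))$p, 1e-4)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n <= 5000")
})
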