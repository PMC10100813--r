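make_assemblage_from_sets <- function(dt_sets, site = "S") {
  n <- length(dt_sets)
  sp <- data.frame(specimen_id = sprintf("l%03d", seq_len(n)),
                   site = rep(site, length.out = n),
                   stringsAsFactors = FALSE)
  dmg <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (!length(dt_sets[[i]])) return(NULL)
    data.frame(specimen_id = sp$specimen_id[i], dt = dt_sets[[i]],
               stringsAsFactors = FALSE)
  }))
  leaf_assemblage(sp, damage = dmg)
}

test_that("damage frequency and occurrence count leaves and (leaf, DT) pairs", {
  a <- make_assemblage_from_sets(c(list(c("2", "12"), "2", character(0)),
                                   rep(list(character(0)), 9)))
  expect_equal(dam_percent(a), 100 * 2 / 12)
  expect_equal(dto(a), 3)

  a3 <- make_assemblage_from_sets(c(list(c("2", "12"), "2"),
                                    rep(list(character(0)), 10)))
  expect_equal(dam_percent(make_assemblage_from_sets(
    rep(list(character(0)), 5))), 0)
  expect_equal(dto(make_assemblage_from_sets(rep(list(character(0)), 5))), 0)
  empty <- make_assemblage_from_sets(list())
  expect_error(dam_percent(empty), "undefined")

  # per-species-style fixture: one DT on each of 99 leaves
  a99 <- make_assemblage_from_sets(rep(list("2"), 99))
  expect_equal(dto(a99), 99)
  expect_equal(dtr_observed(incidence_matrix(a99)), 1)
})

test_that("FFG scopes filter the damage and partition the external guild", {
  sets <- list("2", "12", "50", "20", "18", "214", c("2", "18"),
               character(0))
  a <- make_assemblage_from_sets(sets)
  expect_equal(dto(a, scope = "hole_feeding"), 2)
  expect_equal(dto(a, scope = "mining"), 2)
  expect_equal(dto(a, scope = "external"), 5)
  # external = union of the four external FFGs
  ext_parts <- vapply(external_ffgs(), function(f) dto(a, scope = f), 0)
  expect_equal(sum(ext_parts), dto(a, scope = "external"))
  expect_true(dtr_observed(incidence_matrix(a)) >=
                dtr_observed(incidence_matrix(a, scope = "external")))
  # unmapped DTs warn and land in "other"
  a2 <- make_assemblage_from_sets(list("999"))
  expect_warning(x <- dto(a2, scope = "other"), "not in catalog")
  expect_equal(x, 1)
})

test_that("observed richness counts non-empty DT columns", {
  m <- rbind(c(1, 0), c(1, 1))
  expect_equal(dtr_observed(m), 2)
  expect_equal(dtr_observed(matrix(0, 3, 2)), 0)
  expect_equal(dtr_observed(matrix(0, 3, 0)), 0)
})

test_that("analytic rarefaction matches exhaustive enumeration exactly", {
  # the 4-leaf fixture: DT A on leaves 1-2, DT B on leaf 3
  m <- cbind(XA = c(1, 1, 0, 0), XB = c(0, 0, 1, 0))
  r <- rarefy_analytic(m, 2, force = TRUE)
  expect_equal(r$expected_richness, 4 / 3, tolerance = 1e-12)
  oracle <- enumerate_rarefaction(m, 2)
  expect_equal(r$expected_richness, oracle$mean, tolerance = 1e-12)
  expect_equal(r$sd, oracle$sd, tolerance = 1e-12)

  # property: equality on random matrices with up to 12 leaves, all n
  cases <- expand.grid(N = c(5, 8, 12), D = c(2, 4), p = c(0.15, 0.5))
  for (i in seq_len(nrow(cases))) {
    m_i <- random_incidence(cases$N[i], cases$D[i], cases$p[i], seed = 100 + i)
    for (n in seq_len(cases$N[i])) {
      r_i <- rarefy_analytic(m_i, n, force = TRUE)
      o_i <- enumerate_rarefaction(m_i, n)
      expect_equal(r_i$expected_richness, o_i$mean, tolerance = 1e-10)
      expect_equal(r_i$sd, o_i$sd, tolerance = 1e-10)
    }
  }
})

test_that("rarefaction endpoints, monotonicity and cut-off behave", {
  m <- random_incidence(30, 6, 0.2, seed = 7)
  r <- rarefy_analytic(m, 1:30)
  expect_equal(r$expected_richness[30], dtr_observed(m))
  expect_equal(r$sd[30], 0, tolerance = 1e-9)
  expect_equal(r$expected_richness[1], mean(rowSums(m)), tolerance = 1e-9)
  expect_true(all(diff(r$expected_richness) > -1e-12))   # non-decreasing
  expect_true(all(diff(diff(r$expected_richness)) < 1e-12))  # concave
  expect_error(rarefy_analytic(m, 31), "1 <= n <= 30")
  expect_error(rarefy_analytic(m, 0), "1 <= n <= 30")
  small <- random_incidence(19, 4, 0.3, seed = 8)
  expect_error(rarefy_analytic(small, 5), "below cut-off")
  expect_silent(rarefy_analytic(small, 5, force = TRUE))
})

test_that("Monte-Carlo rarefaction agrees with the analytic estimator", {
  m <- random_incidence(50, 10, 0.15, seed = 21)
  r <- rarefy_analytic(m, 25)
  mc <- rarefy_montecarlo(m, 25, reps = 10000, seed = 22)
  se <- r$sd / sqrt(mc$reps)
  expect_lt(abs(mc$mean - r$expected_richness), 3 * se + 1e-9)
  expect_equal(mc$sd, r$sd, tolerance = 0.1)
  # n = N: every draw is the full set
  mcN <- rarefy_montecarlo(m, 50, reps = 50, seed = 1)
  expect_equal(mcN$mean, dtr_observed(m))
  expect_equal(mcN$sd, 0)
  # seed determinism
  expect_identical(rarefy_montecarlo(m, 25, reps = 200, seed = 5),
                   rarefy_montecarlo(m, 25, reps = 200, seed = 5))
})

test_that("group-wise rarefaction matches the whole-assemblage curve and skips small groups", {
  gen <- generate_scenario("sube_like", n_leaves = 120, seed = 13)
  a <- gen$assemblage
  by_site <- rarefaction_by_group(a, grouping = "site", n_grid = c(10, 50))
  whole <- rarefy_analytic(incidence_matrix(a), c(10, 50))
  expect_equal(by_site$curves[["SuBe"]], whole)

  sp <- data.frame(specimen_id = sprintf("g%03d", 1:39), site = "S",
                   phenology_modern = c(rep("deciduous", 19),
                                        rep("evergreen", 20)))
  dmg <- data.frame(specimen_id = c("g001", "g020", "g021"), dt = "2")
  a2 <- leaf_assemblage(sp, damage = dmg)
  out <- rarefaction_by_group(a2, grouping = "phenology", n_grid = c(5, 10))
  expect_equal(out$skipped$group, "deciduous")
  expect_equal(out$skipped$reason, "below cut-off")
  expect_true("evergreen" %in% names(out$curves))
})

test_that("the herbivory index is a validated damaged-area fraction", {
  expect_equal(herbivory_index(10, 1000), 0.01)
  expect_equal(herbivory_index(0, 1000), 0)
  expect_error(herbivory_index(20, 10), "exceeds leaf area")
  expect_error(herbivory_index(-1, 10), "non-negative")
  expect_error(herbivory_index(1, 0), "strictly positive")

  # equal-sized leaves: mean HI equals the damaged fraction of total area
  area <- rep(500, 8)
  dmg <- c(5, 0, 10, 0, 0, 20, 0, 5)
  expect_equal(mean(herbivory_index(dmg, area)), sum(dmg) / sum(area))
})

test_that("herbivory tables aggregate per-leaf damage", {
  a <- toy_assemblage()
  ht <- herbivory_table(a)
  expect_equal(sum(ht$damaged), 3)
  expect_equal(ht$damaged_area_mm2[ht$specimen_id == "L01"], 15)
  expect_equal(ht$herbivory_index[ht$specimen_id == "L01"], 15 / 500)
  expect_equal(ht$damaged_area_mm2[ht$specimen_id == "L03"], 0)
})
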