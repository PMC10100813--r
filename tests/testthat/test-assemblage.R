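test_that("assemblage construction validates ids, categories and ranges", {
  a <- toy_assemblage()
  expect_s3_class(a, "leaf_assemblage")
  expect_equal(n_specimens(a), 12)

  sp <- a$specimens
  sp2 <- rbind(sp, sp[1, ])
  expect_error(leaf_assemblage(sp2), "duplicated specimen_id")

  sp3 <- sp
  sp3$margin[1] <- "serrated-ish"
  expect_equal(leaf_assemblage(sp3)$specimens$margin[1], "unknown")

  sp4 <- sp
  sp4$leaf_area_mm2[2] <- -5
  expect_error(leaf_assemblage(sp4), "strictly positive")

  sp5 <- sp
  sp5$preserved_fraction[3] <- 1.2
  expect_error(leaf_assemblage(sp5), "outside \\(0,1\\]")

  dmg_bad <- data.frame(specimen_id = "L01", dt = "2",
                        damaged_area_mm2 = 1e6)
  expect_error(leaf_assemblage(sp, damage = dmg_bad), "exceeds leaf area")
  expect_error(leaf_assemblage(sp, damage = data.frame(
    specimen_id = "nope", dt = "2")), "unknown specimen_id")
})

test_that("specimen CSV round trip preserves all fields", {
  a <- toy_assemblage()
  path <- withr::local_tempfile(fileext = ".csv")
  write_assemblage(a, path)
  b <- read_assemblage(path, name = "toy")
  for (col in names(a$specimens)) {
    if (is.numeric(a$specimens[[col]])) {
      expect_equal(b$specimens[[col]], a$specimens[[col]], tolerance = 1e-9,
                   info = col)
    } else {
      expect_identical(b$specimens[[col]], a$specimens[[col]], info = col)
    }
  }
  ord <- function(d) d[order(d$specimen_id, d$dt), ]
  expect_equal(ord(b$damage)$dt, ord(a$damage)$dt)
  expect_equal(ord(b$damage)$damaged_area_mm2, ord(a$damage)$damaged_area_mm2,
               tolerance = 1e-9)
})

test_that("damage parses from dt_list (with DT-prefixed labels) and wide columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,site,dt_list",
               "a,S,DT02", "b,S,2;12", "c,S,"), path)
  a <- read_assemblage(path)
  expect_equal(n_specimens(a), 3)
  expect_equal(sort(a$damage$dt[a$damage$specimen_id == "b"]), c("12", "2"))
  expect_equal(a$damage$dt[a$damage$specimen_id == "a"], "2")

  writeLines(c("specimen_id,site,X2,X12",
               "a,S,1,0", "b,S,1,1", "c,S,0,0"), path)
  b <- read_assemblage(path)
  m <- incidence_matrix(b)
  expect_equal(unname(m), rbind(c(1L, 0L), c(1L, 1L), c(0L, 0L)))
  expect_equal(colnames(m), c("X2", "X12"))

  writeLines(c("specimen_id,site,leaf_area_mm2", "a,S,12x"), path)
  expect_error(read_assemblage(path), "non-numeric.*specimen a")
  writeLines(c("specimen_id,dt_list", "a,2"), path)
  expect_error(read_assemblage(path), "mandatory column missing: 'site'")
})

test_that("preservation filter keeps the 70% boundary and is idempotent", {
  sp <- data.frame(specimen_id = c("a", "b", "c"), site = "S",
                   preserved_fraction = c(0.5, 0.7, 0.9))
  a <- leaf_assemblage(sp)
  d2 <- filter_dataset2(a)
  expect_equal(d2$specimens$specimen_id, c("b", "c"))
  expect_equal(filter_dataset2(d2)$specimens, d2$specimens)
  empty <- assemblage_subset(a, character(0))
  expect_equal(n_specimens(filter_dataset2(empty)), 0)
})

test_that("per-site subsampling is reproducible and degrades gracefully", {
  a <- toy_assemblage()
  s1 <- sample_dataset3(a, 3, seed = 42)
  s2 <- sample_dataset3(a, 3, seed = 42)
  expect_identical(s1$specimens$specimen_id, s2$specimens$specimen_id)
  expect_equal(as.vector(table(s1$specimens$site)), c(3, 3))
  s3 <- sample_dataset3(a, 3, seed = 43)
  expect_false(identical(s1$specimens$specimen_id,
                         s3$specimens$specimen_id))
  w <- capture_warnings(big <- sample_dataset3(a, 100, seed = 1))
  expect_true(all(grepl("taking all", w)))   # one warning per short site
  expect_length(w, 2)
  expect_equal(n_specimens(big), 12)
  expect_error(sample_dataset3(a, 0, seed = 1), "positive integer")
})

test_that("dataset-4 cleaning flags Tukey outliers and rare groups, with a ledger", {
  n <- 25
  sp <- data.frame(
    specimen_id = sprintf("x%02d", 1:n), site = "S",
    fossil_species = c(rep("common", 21), rep("rare", 4)),
    phenology_modern = "deciduous",
    lobation = "unlobed", margin = "toothed", primary_venation = "pinnate",
    secondary_venation = "non-looped",
    preserved_fraction = 1, area_index = 1,
    leaf_length_mm = 50, leaf_width_mm = 25,
    leaf_area_mm2 = c(rep(c(10, 10, 11, 12, 1000), 5)),
    lma_gm2 = 90, stringsAsFactors = FALSE)
  a <- assign_tct(leaf_assemblage(sp))
  # oracle: direct type-7 quartiles on each site's sizes
  q <- quantile(sp$leaf_area_mm2, c(0.25, 0.75), type = 7)
  expect_true(1000 > q[2] + 1.5 * diff(q))
  d4 <- build_dataset4(a, min_group = 5)
  led <- attr(d4, "removal_ledger")
  expect_equal(sum(led$removed), n - n_specimens(d4))
  expect_equal(led$removed[led$rule == "outlier"], 5)
  expect_false(any(d4$specimens$leaf_area_mm2 == 1000))
  # the outlier rule already took one "rare" leaf; the remaining 3 fall
  # under the species rarity rule
  expect_equal(led$removed[led$rule == "rare_species"], 3)
  expect_true(all(d4$specimens$fossil_species == "common"))

  # a clean homogeneous set with min_group 1 passes unchanged
  sp2 <- sp[sp$leaf_area_mm2 != 1000, ]
  a2 <- assign_tct(leaf_assemblage(sp2))
  d42 <- build_dataset4(a2, min_group = 1)
  expect_equal(n_specimens(d42), nrow(sp2))

  # single tukey_outlier oracle case from the quartile rule
  expect_equal(which(tukey_outlier(c(10, 10, 11, 12, 1000))), 5)
})

test_that("rare TCTs can be merged instead of deleted", {
  sp <- data.frame(
    specimen_id = sprintf("x%02d", 1:12), site = "S",
    fossil_species = "common", phenology_modern = "deciduous",
    lobation = c(rep("unlobed", 10), "lobed", "lobed"),
    margin = "toothed", primary_venation = c(rep("pinnate", 10), "palmate",
                                             "palmate"),
    secondary_venation = "non-looped",
    preserved_fraction = 1, area_index = 1, leaf_length_mm = 50,
    leaf_width_mm = 25, leaf_area_mm2 = 500, lma_gm2 = 90,
    stringsAsFactors = FALSE)
  a <- assign_tct(leaf_assemblage(sp))
  del <- build_dataset4(a, min_group = 5)
  expect_equal(n_specimens(del), 10)
  mrg <- build_dataset4(a, min_group = 5, rare_tct = "merge")
  expect_equal(n_specimens(mrg), 12)
  expect_equal(sum(mrg$specimens$tct == "other"), 2)
})

test_that("the dataset cascade is nested", {
  gen <- generate_scenario("sf_like", n_leaves = 400, seed = 3)
  a <- assign_tct(gen$assemblage)
  d2 <- filter_dataset2(a)
  d3 <- suppressWarnings(sample_dataset3(d2, 100, seed = 4))
  d4 <- build_dataset4(d3)
  ids <- function(x) x$specimens$specimen_id
  expect_true(all(ids(d4) %in% ids(d3)))
  expect_true(all(ids(d3) %in% ids(d2)))
  expect_true(all(ids(d2) %in% ids(a)))
})

test_that("incidence matrices build, write and read back identically", {
  sp <- data.frame(specimen_id = c("a", "b"), site = "S")
  dmg <- data.frame(specimen_id = c("a", "b", "b"), dt = c("2", "2", "12"))
  a <- leaf_assemblage(sp, damage = dmg)
  m <- incidence_matrix(a)
  expect_equal(unname(m), rbind(c(1L, 0L), c(1L, 1L)))
  expect_equal(colnames(m), c("X2", "X12"))

  none <- leaf_assemblage(sp)
  m0 <- incidence_matrix(none)
  expect_equal(ncol(m0), 0)
  expect_equal(nrow(m0), 2)

  path <- withr::local_tempfile(fileext = ".csv")
  write_incidence_matrix(m, path)
  expect_equal(read_incidence_matrix(path), m)
})
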